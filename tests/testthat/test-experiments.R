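test_that("the default grid holds the study conditions", {
  g <- default_grid()
  expect_equal(sum(g$mode == "static"), 1L)
  expect_equal(g$rate_bpm[g$mode == "periodic"], seq(8, 20, by = 2))
  expect_true(all(g$amplitude_mm[g$mode == "periodic"] == 10))
  expect_equal(g$amplitude_mm[g$mode == "timed"], c(5, 10, 15))
  expect_error(
    experiment_config(grid = rbind(g, g[1, ])),
    "exactly one static"
  )
})

test_that("a small grid runs deterministically with MAE anchored at zero", {
  grid <- rbind(
    data.frame(mode = "static", rate_bpm = NA_real_, amplitude_mm = 0),
    data.frame(mode = "periodic", rate_bpm = 12, amplitude_mm = 10),
    data.frame(mode = "timed", rate_bpm = NA_real_, amplitude_mm = 10)
  )
  cfg <- experiment_config(
    shape = c(48, 48),
    protocol = acquisition_protocol(n_offsets = 40, averages = 1),
    grid = grid, master_seed = 4
  )
  res <- run_grid(cfg, quiet = TRUE)
  expect_s3_class(res, "experiment_results")
  expect_equal(res$table$status, rep("ok", 3))
  expect_equal(res$table$mae_pct[1], 0)
  expect_true(all(res$table$mae_pct[-1] > 0))
  # timed readouts are exhaled: no detected motion, single breathing state
  expect_equal(res$table$mean_abs_motion_mm[3], 0)
  expect_equal(res$table$median_state_run[3], 41)
  # per-cell ROI statistics cover 3 ROIs x 3 offsets
  expect_equal(nrow(res$roi_stats), 3 * 9)

  res2 <- run_grid(cfg, quiet = TRUE)
  expect_identical(res$table, res2$table)
  expect_identical(res$roi_stats, res2$roi_stats)

  # results export writes the documented artifacts
  dir <- withr::local_tempdir()
  write_experiment_results(res, dir)
  expect_true(file.exists(file.path(dir, "results.csv")))
  expect_true(file.exists(file.path(dir, "roi_stats.csv")))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(manifest$master_seed, 4L)
  expect_true(file.exists(file.path(dir, "cell_01", "mtr_asym_1ppm.nii.gz")))
})

test_that("a failing cell is recorded while the others proceed", {
  grid <- rbind(
    data.frame(mode = "static", rate_bpm = NA_real_, amplitude_mm = 0),
    # amplitude too large for the field of view -> render error
    data.frame(mode = "periodic", rate_bpm = 12, amplitude_mm = 200)
  )
  cfg <- experiment_config(
    shape = c(48, 48),
    protocol = acquisition_protocol(n_offsets = 20, averages = 1),
    grid = grid
  )
  expect_warning(res <- run_grid(cfg, quiet = TRUE), NA)
  expect_equal(res$table$status[1], "ok")
  expect_match(res$table$status[2], "error")
  expect_true(is.na(res$table$mae_pct[2]))
})

test_that("frames are assigned to breathing states with aliasing run structure", {
  ph <- make_kidney_phantom()
  p <- acquisition_protocol()   # frame period 3.6 s

  # timed: every readout exhaled, one run spanning the scan
  ser_t <- simulate_series(ph, p, breathing_model("timed", amplitude_mm = 10),
                           seed = 1)
  st_t <- state_assignment(ser_t$stack, ser_t$cushion)
  expect_true(all(st_t$states == "exhaled"))
  expect_equal(st_t$run_lengths, nrow(ser_t$stack$meta))

  # half the sampling rate: the per-frame phase alternates between two
  # points of the exhale plateau -> a single state throughout
  r_half <- 60 / (2 * 3.6)
  ser_h <- simulate_series(ph, p,
                           breathing_model("periodic", rate_bpm = r_half),
                           seed = 1)
  st_h <- state_assignment(ser_h$stack, ser_h$cushion)
  expect_equal(length(unique(st_h$states)), 1L)

  # near-resonant 16 bpm drifts slowly -> longer same-state runs than 12 bpm
  ser16 <- simulate_series(ph, p, breathing_model("periodic", rate_bpm = 16),
                           seed = 1)
  ser12 <- simulate_series(ph, p, breathing_model("periodic", rate_bpm = 12),
                           seed = 1)
  st16 <- state_assignment(ser16$stack, ser16$cushion)
  st12 <- state_assignment(ser12$stack, ser12$cushion)
  expect_gt(st16$median_run, st12$median_run)

  # tags outside the log span are rejected
  bad <- ser16$cushion
  bad$time <- bad$time[bad$time < 800]
  bad$value <- bad$value[seq_along(bad$time)]
  expect_error(state_assignment(ser16$stack, bad), "span")
})

test_that("near-resonant motion contaminates spectra in contiguous segments", {
  # the pseudo-CEST mechanism: at 16 bpm the displaced frames form long
  # contiguous blocks of the offset sweep
  ph <- make_kidney_phantom()
  p <- acquisition_protocol()
  ser16 <- simulate_series(ph, p, breathing_model("periodic", rate_bpm = 16),
                           seed = 1)
  disp <- ser16$stack$meta$true_displacement_mm > 5
  runs <- rle(disp)
  expect_gte(max(runs$lengths[runs$values]), 5)
})
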