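test_that("saturation-module and frame-period arithmetic match the protocol", {
  p <- acquisition_protocol()
  fp <- frame_period(p)
  expect_equal(fp$saturation_s, 2.9)
  expect_equal(fp$total_s, 3.6)
  # degenerate train: a single pulse has no inter-pulse gap
  p1 <- acquisition_protocol(n_pulses = 1)
  expect_equal(frame_period(p1)$saturation_s, p1$t_pulse_s)
})

test_that("the schedule enumerates averages x (offsets + reference) frames", {
  p <- acquisition_protocol()
  sch <- acquisition_schedule(p)
  expect_equal(nrow(sch), 3 * (80 + 1))
  expect_equal(sum(sch$is_reference), 3)
  # constant frame spacing at the frame period
  expect_equal(unique(round(diff(sch$readout_mid_s), 10)), 3.6)
  # throughput
  expect_true(60 / frame_period(p)$total_s >= 16.6 &&
                60 / frame_period(p)$total_s <= 16.7)
  # offsets descend from +5 to -5 by default
  expect_equal(sch$offset_ppm[2], 5)
  expect_equal(sch$offset_ppm[81], -5)

  p2 <- acquisition_protocol(n_offsets = 1, averages = 1)
  expect_equal(nrow(acquisition_schedule(p2)), 2)

  # repeats interleave keeps the same frame count
  p3 <- acquisition_protocol(n_offsets = 10, averages = 3,
                             interleave = "repeats")
  sch3 <- acquisition_schedule(p3)
  expect_equal(nrow(sch3), 33)
  expect_equal(sch3$offset_ppm[4], sch3$offset_ppm[5])
})

test_that("protocol validation rejects inconsistent parameters", {
  expect_error(acquisition_protocol(reference_ppm = 3), "outside")
  expect_error(acquisition_protocol(averages = 0))
  expect_error(acquisition_protocol(noise_sd = -1))
})

test_that("the periodic waveform is a bounded trapezoid with the stated dwells", {
  bm <- breathing_model("periodic", rate_bpm = 12, amplitude_mm = 10,
                        phase_s = 0)
  # period 60/12 = 5 s
  t <- seq(0, 20, by = 0.01)
  expect_equal(displacement(bm, t), displacement(bm, t + 5))
  d <- displacement(bm, t)
  expect_true(all(d >= 0 & d <= 10))
  # amplitude reached exactly
  expect_equal(max(d), 10)
  # ramp duration = amplitude/velocity = 0.1 s; max slope = velocity
  slope <- diff(displacement(bm, seq(0, 5, by = 1e-3))) / 1e-3
  expect_equal(max(abs(slope)), 100, tolerance = 1e-6)
  # dwell split: 2/3 exhaled (0 mm), 1/3 inhaled, minus the two ramps
  expect_equal(mean(d[t < 5] == 0), 2 / 3 - 0.1 / 5, tolerance = 0.01)
  expect_equal(mean(d[t < 5] == 10), 1 / 3 - 0.1 / 5, tolerance = 0.01)
})

test_that("static mode is identically zero and timed mode needs the schedule", {
  bm <- breathing_model("static")
  expect_equal(displacement(bm, c(0, 3.3, 100)), c(0, 0, 0))
  expect_error(displacement(breathing_model("timed"), 1), "timed_motion")
})

test_that("breathing-model invariants are rejected at construction", {
  expect_error(breathing_model("periodic", inhale_dwell_frac = 0.5,
                               exhale_dwell_frac = 0.6), "sum to 1")
  # transition longer than the inhale dwell: 60 bpm -> inhale dwell 1/3 s,
  # ramp 50 mm / 100 mm/s = 0.5 s
  expect_error(breathing_model("periodic", rate_bpm = 60, amplitude_mm = 50),
               "transition")
})

test_that("timed motion completes one cycle per frame inside saturation", {
  p <- acquisition_protocol()
  sched <- acquisition_schedule(p)
  bm <- breathing_model("timed", amplitude_mm = 10)
  f <- timed_motion(sched, bm, p)
  # displacement at every readout midpoint is zero
  expect_equal(f(sched$readout_mid_s), rep(0, nrow(sched)))
  # exactly one excursion per frame: count rising crossings of A/2 on a
  # fine time grid
  t <- seq(0, nrow(sched) * 3.6, by = 0.01)
  d <- f(t)
  above <- d > 5
  expect_equal(sum(diff(above) == 1), nrow(sched))
  expect_equal(max(d), 10)
  # zero amplitude reduces to the static waveform
  f0 <- timed_motion(sched, breathing_model("timed", amplitude_mm = 0), p)
  expect_equal(f0(t), rep(0, length(t)))
  # a cycle that cannot fit in the 2.9 s saturation window is an error
  bm_long <- breathing_model("timed", amplitude_mm = 10, hold_s = 2.9)
  expect_error(timed_motion(sched, bm_long, p), "saturation window")
})

test_that("cushion logs cover the scan and round-trip through text files", {
  bm <- breathing_model("periodic", rate_bpm = 12, phase_s = 0)
  log <- cushion_log(bm, duration_s = 30, tags = c(3.25, 10.45),
                     noise_sd = 0.05, seed = 3)
  expect_s3_class(log, "cushion_log")
  expect_equal(length(log$time), length(log$value))
  expect_error(cushion_log(bm, duration_s = 30, tags = c(3.25, 31)),
               "inside the sampled interval")
  path <- withr::local_tempfile(fileext = ".txt")
  write_cushion_log(log, path)
  log2 <- read_cushion_log(path)
  expect_equal(log2$value, log$value, tolerance = 1e-9)
  expect_equal(log2$tags, log$tags)
  expect_equal(log2$sample_rate_hz, log$sample_rate_hz, tolerance = 1e-6)
})
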