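test_that("the edge detector equals the brute-force row-scoring oracle", {
  set.seed(101)
  roi <- list(rows = 3:20, cols = 4:12)
  for (rep in 1:100) {
    # random piecewise-constant step image plus mild noise
    img <- matrix(runif(1) * 0.2, 24, 16)
    k <- sample(6:17, 1)
    img[seq_len(k), ] <- img[seq_len(k), ] + runif(1, 0.5, 1.5)
    img <- img + rnorm(length(img), sd = 0.02)
    expect_identical(detect_edge(img, roi), naive_edge(img, roi))
  }
})

test_that("edge detection finds steps, is translation-equivariant, rejects flats", {
  img <- matrix(0.1, 30, 20)
  img[1:12, ] <- 1
  roi <- list(rows = 5:25, cols = 5:15)
  e <- detect_edge(img, roi)
  expect_true(e %in% 11:13)
  # shifting the pattern down two rows moves the edge by exactly 2
  img2 <- matrix(0.1, 30, 20)
  img2[1:14, ] <- 1
  expect_identical(detect_edge(img2, roi), e + 2L)
  expect_error(detect_edge(matrix(1, 30, 20), roi), "no detectable edge")
  expect_error(detect_edge(img, list(rows = 1:3, cols = 1:10)), "rows")
})

test_that("displacement series match a hand-rolled difference oracle", {
  base <- matrix(0.1, 24, 16)
  base[1:10, ] <- 1
  shift_img <- function(s) {
    out <- matrix(0.1, 24, 16)
    out[seq_len(10 + s), ] <- 1
    out
  }
  # static series
  st <- stack_from_images(replicate(5, base, simplify = FALSE))
  roi <- list(rows = 5:18, cols = 4:12)
  ds <- displacement_series(st, roi)
  expect_equal(ds$displacement_mm, rep(0, 5))
  expect_equal(ds$mean_abs_motion_mm, 0)
  # alternating +/- 1-row shifts at 3 mm pixels
  shifts <- c(0, 1, 0, 1, 0, 1)
  st2 <- stack_from_images(lapply(shifts, shift_img))
  ds2 <- displacement_series(st2, roi)
  expect_equal(ds2$displacement_mm, shifts * 3)
  # oracle: mean over frames of |frame-to-frame difference|
  oracle <- mean(abs(diff(shifts * 3)))
  expect_equal(ds2$mean_abs_motion_mm, oracle)
  expect_equal(ds2$mean_abs_motion_mm, 3)
})

test_that("programmed amplitudes are recovered from periodic series maxima", {
  ph <- make_kidney_phantom()
  p <- acquisition_protocol(n_offsets = 40, averages = 1)
  for (A in c(5, 10, 15)) {
    ser <- simulate_series(ph, p,
                           breathing_model("periodic", rate_bpm = 14,
                                           amplitude_mm = A), seed = 8)
    ds <- displacement_series(ser$stack, cestmotion:::edge_detection_roi(ph))
    expect_lte(abs(max(abs(ds$displacement_mm)) - A), 3)
  }
})

test_that("timed series leave at most sub-pixel residual motion", {
  ph <- make_kidney_phantom()
  p <- acquisition_protocol(n_offsets = 20, averages = 1)
  ser <- simulate_series(ph, p, breathing_model("timed", amplitude_mm = 10),
                         seed = 3)
  ds <- displacement_series(ser$stack, cestmotion:::edge_detection_roi(ph))
  expect_lte(ds$mean_abs_motion_mm, ph$pixel_mm)
})

test_that("breathing rate is recovered across waveforms and the grid", {
  # pure sinusoid at 12 bpm
  t <- seq(0, 60, by = 0.02)
  log <- structure(list(time = t, value = sin(2 * pi * t * 12 / 60),
                        sample_rate_hz = 50, tags = numeric(0)),
                   class = "cushion_log")
  for (thr in c(0.3, 0.5, 0.7)) {
    expect_equal(breathing_rate(log, threshold_frac = thr), 12,
                 tolerance = 0.1 / 12)
  }
  # trapezoidal waveform from the acquisition module at 16 bpm
  bm <- breathing_model("periodic", rate_bpm = 16, phase_s = 0)
  log16 <- cushion_log(bm, duration_s = 45)
  expect_equal(breathing_rate(log16), 16, tolerance = 0.5 / 16)
  # the full 8-20 bpm grid within 0.5 bpm
  for (r in seq(8, 20, by = 2)) {
    lg <- cushion_log(breathing_model("periodic", rate_bpm = r, phase_s = 0),
                      duration_s = 45, noise_sd = 0.1, seed = r)
    expect_lte(abs(breathing_rate(lg) - r), 0.5)
  }
  # degenerate logs are rejected
  const <- structure(list(time = t, value = rep(1, length(t)),
                          sample_rate_hz = 50, tags = numeric(0)),
                     class = "cushion_log")
  expect_error(breathing_rate(const), "constant")
  short <- structure(list(time = seq(0, 4, 0.02),
                          value = sin(2 * pi * seq(0, 4, 0.02) / 5),
                          sample_rate_hz = 50, tags = numeric(0)),
                     class = "cushion_log")
  expect_error(breathing_rate(short), "insufficient cycles")
})

test_that("MAE implements the 9-term mean absolute deviation with interval", {
  x <- rep(1, 9); y <- rep(1, 9)
  m <- mae(x, y)
  expect_equal(m$mae_pct, 0)
  expect_equal(mae(rep(0.5, 9), rep(0, 9))$mae_pct, 0.5)
  expect_equal(mae(c(0.9, rep(0, 8)), rep(0, 9))$mae_pct, 0.1)
  expect_error(mae(rep(1, 8), rep(1, 9)), "exactly")
  expect_error(mae(c(NA, rep(1, 8)), rep(1, 9)), "missing")
  # bootstrap interval brackets the estimate and is reproducible
  set.seed(9)
  a <- runif(9); b <- runif(9)
  mb <- mae(a, b, interval = "bootstrap", seed = 5)
  expect_lte(mb$ci_lower, mb$mae_pct)
  expect_gte(mb$ci_upper, mb$mae_pct)
  expect_identical(mb$ci_lower, mae(a, b, interval = "bootstrap", seed = 5)$ci_lower)
})

test_that("MAE is a metric on the 9-term vectors", {
  set.seed(77)
  for (i in 1:20) {
    a <- rnorm(9); b <- rnorm(9); c <- rnorm(9)
    mab <- mae(a, b)$mae_pct
    expect_gte(mab, 0)
    expect_equal(mab, mae(b, a)$mae_pct)
    expect_equal(mae(a, a)$mae_pct, 0)
    expect_lte(mae(a, c)$mae_pct, mab + mae(b, c)$mae_pct + 1e-12)
  }
})

test_that("MAE from ROI statistics matches terms and flags empties", {
  mkstats <- function(vals, empty_roi = NULL) {
    df <- expand.grid(roi = c("cortex", "medulla", "pelvis"),
                      offset_ppm = c(1, 2, 3.5), stringsAsFactors = FALSE)
    df$mean_pct <- vals
    df$empty <- df$roi %in% empty_roi
    df
  }
  sx <- mkstats(rep(1, 9)); sy <- mkstats(rep(0.5, 9))
  expect_equal(mae_from_stats(sx, sy)$mae_pct, 0.5)
  expect_error(mae_from_stats(mkstats(rep(1, 9), "pelvis"), sy), "empty ROI")
  sz <- sy; sz$roi[1] <- "liver"
  expect_error(mae_from_stats(sx, sz), "unmatched|exactly")
})
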