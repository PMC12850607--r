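test_that("two-point Dixon separates water and fat", {
  expect_error(dixon_water(matrix(0, 2, 2), matrix(0, 3, 3)), "shape")
  # forward-simulate a 60/40 water/fat pixel with s0 = 1 under the synthetic
  # opposed/in-phase convention and invert
  water <- 0.6; fat <- 0.4
  e1 <- water - fat; e2 <- water + fat
  expect_equal(dixon_water(matrix(e1, 1, 1), matrix(e2, 1, 1))[1, 1], 0.6)
  # pure fat pixel -> water ~ 0
  expect_equal(dixon_water(matrix(-1, 1, 1), matrix(1, 1, 1))[1, 1], 0)
  # fat-free pixel -> water equals the echo magnitude
  expect_equal(dixon_water(matrix(0.8, 1, 1), matrix(0.8, 1, 1))[1, 1], 0.8)
})

test_that("gaussian smoothing preserves means and reduces variation", {
  img <- matrix(0, 21, 21)
  expect_equal(gaussian_smooth(img + 3, 0.75), img + 3)      # constant
  expect_identical(gaussian_smooth(img + 3, 0), img + 3)     # identity
  expect_error(gaussian_smooth(img, -1), "sigma")
  # interior unit impulse: the kernel sums to 1
  imp <- img; imp[11, 11] <- 1
  sm <- gaussian_smooth(imp, 0.75)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  expect_lt(max(sm), 1)
  # total variation does not increase
  tv <- function(x) sum(abs(diff(x))) + sum(abs(t(diff(t(x)))))
  set.seed(4)
  noisy <- matrix(rnorm(441), 21, 21)
  expect_lte(tv(gaussian_smooth(noisy, 0.75)), tv(noisy))
})

test_that("normalization round-trips the noiseless static phantom", {
  ph <- make_kidney_phantom(shape = c(48, 48))
  p <- acquisition_protocol(n_offsets = 20, averages = 1, noise_sd = 0)
  ser <- simulate_series(ph, p, breathing_model("static"), seed = 1)
  cube <- normalize_frames(ser$stack, sigma = 0)   # no smoothing: exact
  expect_equal(cube$offsets_ppm, sort(p$offsets_ppm))
  # cortex pixel spectra equal the model
  idx <- which(ph$labels == ph$label_names[["cortex"]], arr.ind = TRUE)[1, ]
  got <- cube$z[idx[1], idx[2], ]
  want <- zvalue(ph$specs$cortex, cube$offsets_ppm,
                 ph$b0_ppm[idx[1], idx[2]]) /
    zvalue(ph$specs$cortex, p$reference_ppm, ph$b0_ppm[idx[1], idx[2]])
  expect_equal(got, want, tolerance = 1e-9)
  # air background falls below the reference floor and is masked
  bg <- ph$labels == 0L
  expect_true(all(!cube$mask[bg]))
  expect_true(all(cube$mask[ph$labels == 2L]))
})

test_that("identical averages change nothing relative to a single average", {
  ph <- make_kidney_phantom(shape = c(48, 48))
  p3 <- acquisition_protocol(n_offsets = 12, averages = 3, noise_sd = 0)
  p1 <- acquisition_protocol(n_offsets = 12, averages = 1, noise_sd = 0)
  c3 <- normalize_frames(simulate_series(ph, p3, breathing_model("static"))$stack)
  c1 <- normalize_frames(simulate_series(ph, p1, breathing_model("static"))$stack)
  expect_equal(c3$z, c1$z, tolerance = 1e-12)
})

test_that("a zero-signal pixel is masked rather than propagated", {
  ph <- make_kidney_phantom(shape = c(48, 48))
  p <- acquisition_protocol(n_offsets = 12, averages = 1, noise_sd = 0)
  ser <- simulate_series(ph, p, breathing_model("static"))
  ser$stack$echo1[5, 5, ] <- 0
  ser$stack$echo2[5, 5, ] <- 0
  cube <- normalize_frames(ser$stack, sigma = 0)
  expect_false(cube$mask[5, 5])
  expect_true(all(is.na(cube$z[5, 5, ])))
})

test_that("B0 correction leaves an on-resonance symmetric spectrum in place", {
  offs <- seq(-5, 5, length.out = 80)
  spec <- compartment_spec("surround", list(water_pool()))
  z <- zvalue(spec, offs)
  cc <- b0_correct(single_pixel_cube(offs, z))
  expect_lt(abs(cc$b0_ppm[1, 1]), 0.01)
  expect_lt(max(abs(cc$z[1, 1, ] - z)), 0.02)
  # asymmetry stays numerically null after correction
  for (d in c(1, 2, 3.5)) {
    expect_lt(abs(mtr_asym(offs, cc$z[1, 1, ], d)), 0.2)
  }
})

test_that("constant field shifts are recovered at grid precision", {
  offs <- seq(-5, 5, length.out = 80)
  spec <- compartment_spec("surround", list(water_pool()))
  for (b0 in c(-0.2, 0.1, 0.2)) {
    z <- zvalue(spec, offs, b0)
    cc <- b0_correct(single_pixel_cube(offs, z))
    expect_lt(abs(cc$b0_ppm[1, 1] - b0), 0.01)
    # pseudo-asymmetry suppressed after realignment
    for (d in c(1, 2, 3.5)) {
      expect_lt(abs(mtr_asym(offs, cc$z[1, 1, ], d)), 0.2)
    }
  }
})

test_that("a linear-gradient field map is reproduced across the phantom", {
  specs <- water_only_specs()
  ph <- make_kidney_phantom(shape = c(48, 48), specs = specs,
                            b0_model = list(type = "linear", axis = "row",
                                            from = -0.25, to = 0.25))
  p <- acquisition_protocol(noise_sd = 0)
  ser <- simulate_series(ph, p, breathing_model("static"))
  cube <- b0_correct(normalize_frames(ser$stack, sigma = 0))
  err <- (cube$b0_ppm - ph$b0_ppm)[cube$mask]
  expect_lt(sqrt(mean(err^2)), 0.01)
})

test_that("the correction is idempotent to within one grid step", {
  offs <- seq(-5, 5, length.out = 80)
  specs <- default_compartment_specs()
  for (nm in c("cortex", "pelvis")) {
    z <- zvalue(specs[[nm]], offs, 0.17)
    c1 <- b0_correct(single_pixel_cube(offs, z))
    c2 <- b0_correct(single_pixel_cube(offs, c1$z[1, 1, ]))
    expect_lte(abs(c2$b0_ppm[1, 1]), 0.01 + 1e-9)
  }
})

test_that("insufficient spectral coverage is rejected", {
  offs <- seq(0.5, 5, length.out = 20)
  z <- rep(0.9, 20)
  expect_error(b0_correct(single_pixel_cube(offs, z)), "margin")
})
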