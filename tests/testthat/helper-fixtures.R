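# Shared fixtures: small spec sets, single-spectrum cubes, and an
# independent brute-force edge-detection oracle.

# wrap one spectrum (or a pixel x offset matrix reshaped to 1x1xk) in a cube
single_pixel_cube <- function(offsets, z, pixel_mm = 3) {
  structure(
    list(offsets_ppm = offsets, z = array(z, c(1, 1, length(offsets))),
         s0 = matrix(1, 1, 1), mask = matrix(TRUE, 1, 1),
         b0_ppm = NULL, b0_flagged = NULL, pixel_mm = pixel_mm),
    class = "zspectrum_cube"
  )
}

water_pool <- function(amplitude = 0.8, width = 1.6) {
  pool_spec(0, amplitude, width)
}

# compartment whose non-water pools come in +/- mirrored pairs: MTR_asym
# is identically zero for these spectra
symmetric_specs <- function() {
  sym_pools <- list(water_pool(),
                    pool_spec(2.0, 0.05, 1.2), pool_spec(-2.0, 0.05, 1.2))
  tissue <- function(nm) compartment_spec(nm, sym_pools)
  list(
    background = compartment_spec("background", list(pool_spec(0, 0, 1.6)),
                                  s0 = 0.05),
    surround = tissue("surround"),
    cortex = tissue("cortex"),
    medulla = tissue("medulla"),
    pelvis = tissue("pelvis")
  )
}

# all tissue compartments carry only the direct-water pool
water_only_specs <- function() {
  tissue <- function(nm) compartment_spec(nm, list(water_pool()))
  list(
    background = compartment_spec("background", list(pool_spec(0, 0, 1.6)),
                                  s0 = 0.05),
    surround = tissue("surround"),
    cortex = tissue("cortex"),
    medulla = tissue("medulla"),
    pelvis = tissue("pelvis")
  )
}

# tissue compartments carrying one solute pool of given amplitude/width at
# +delta on top of the standard water pool
solute_specs <- function(amplitude, width_ppm, delta_ppm) {
  tissue <- function(nm) {
    compartment_spec(nm, list(water_pool(),
                              pool_spec(delta_ppm, amplitude, width_ppm)))
  }
  list(
    background = compartment_spec("background", list(pool_spec(0, 0, 1.6)),
                                  s0 = 0.05),
    surround = compartment_spec("surround", list(water_pool())),
    cortex = tissue("cortex"),
    medulla = tissue("medulla"),
    pelvis = tissue("pelvis")
  )
}

# independent brute-force implementation of the edge detector: explicit
# loops for the 3x3 median, the central-difference gradient and the row
# scoring; ties toward the smaller row
naive_edge <- function(image, roi) {
  crop <- image[roi$rows, roi$cols, drop = FALSE]
  nr <- nrow(crop); nc <- ncol(crop)
  med <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    vals <- c()
    for (di in -1:1) for (dj in -1:1) {
      ii <- min(max(i + di, 1), nr); jj <- min(max(j + dj, 1), nc)
      vals <- c(vals, crop[ii, jj])
    }
    med[i, j] <- median(vals)
  }
  g <- matrix(0, nr, nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      g[i, j] <- if (i == 1) med[2, j] - med[1, j]
      else if (i == nr) med[nr, j] - med[nr - 1, j]
      else (med[i + 1, j] - med[i - 1, j]) / 2
    }
  }
  score <- apply(abs(g), 1, sum)
  best <- 1
  for (i in seq_len(nr)) if (score[i] > score[best]) best <- i
  roi$rows[best]
}

# minimal hand-built frame stack from a list of water images (fat-free:
# echo1 == echo2 == water)
stack_from_images <- function(images, pixel_mm = 3, offsets = NULL) {
  n <- length(images)
  nr <- nrow(images[[1]]); nc <- ncol(images[[1]])
  e <- array(NA_real_, c(nr, nc, n))
  for (i in seq_len(n)) e[, , i] <- images[[i]]
  if (is.null(offsets)) offsets <- seq_len(n)
  structure(
    list(echo1 = e, echo2 = e,
         meta = data.frame(frame = seq_len(n), offset_ppm = offsets,
                           is_reference = FALSE, average = 1L,
                           sat_start_s = (seq_len(n) - 1) * 3.6,
                           readout_mid_s = (seq_len(n) - 1) * 3.6 + 3.25,
                           true_displacement_mm = 0),
         protocol = NULL, pixel_mm = pixel_mm),
    class = "frame_stack"
  )
}
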