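# Frame rendering (rigid translation, dual echoes, noise) and simulation of
# a full CEST series with its respiratory-cushion log.

# Rigid translation along rows (superior-inferior axis) by a fractional
# number of pixels with linear interpolation; edge rows are replicated.
# Positive shift moves image content toward larger row indices.
translate_rows <- function(img, shift_px) {
  if (shift_px == 0) return(img)
  nr <- nrow(img)
  src <- seq_len(nr) - shift_px
  lo <- pmin(pmax(floor(src), 1), nr)
  hi <- pmin(lo + 1, nr)
  f <- pmin(pmax(src - floor(src), 0), 1)
  f[floor(src) < 1] <- 0
  f[floor(src) >= nr] <- 0
  img[lo, , drop = FALSE] * (1 - f) + img[hi, , drop = FALSE] * f
}

# Noise-free water and fat signal maps of the phantom at one offset.
signal_maps <- function(phantom, offset_ppm, b0_map = phantom$b0_ppm) {
  labels <- phantom$labels
  water <- matrix(0, nrow(labels), ncol(labels))
  fat <- matrix(0, nrow(labels), ncol(labels))
  for (nm in names(phantom$label_names)) {
    idx <- which(labels == phantom$label_names[[nm]])
    if (!length(idx)) next
    spec <- phantom$specs[[nm]]
    z <- zvalue(spec, offset_ppm, b0_map[idx])
    water[idx] <- (1 - spec$fat_fraction) * spec$s0 * z
    fat[idx] <- spec$fat_fraction * spec$s0
  }
  list(water = water, fat = fat)
}

#' Render one dual-echo frame of the moving phantom
#'
#' Computes the noise-free water (`(1 - fat_fraction) * s0 * Z`) and fat
#' (`fat_fraction * s0`, unmodulated by saturation) signal maps, translates
#' them rigidly along the row (superior-inferior) axis by
#' `displacement_mm / pixel_mm` pixels with linear interpolation, and forms
#' the synthetic opposed-phase (`echo1 = water - fat`) and in-phase
#' (`echo2 = water + fat`) echoes with additive Gaussian noise.
#'
#' @param phantom A [make_kidney_phantom()] object.
#' @param displacement_mm Rigid displacement along rows, mm.
#' @param offset_ppm Saturation offset of the frame, ppm.
#' @param protocol An [acquisition_protocol()]; supplies the default
#'   `noise_sd`.
#' @param noise_sd Additive noise SD relative to the maximum unsaturated
#'   signal; overrides the protocol value. Noise draws use the current RNG
#'   state.
#' @param sat_displacement_mm Optional position during the saturation phase:
#'   when given, each tissue element experiences the static field at its
#'   displaced saturation-time position (position-dependent B0 option; off
#'   by default).
#' @return List with matrices `echo1`, `echo2`.
#' @export
render_frame <- function(phantom, displacement_mm, offset_ppm, protocol,
                         noise_sd = protocol$noise_sd,
                         sat_displacement_mm = NULL) {
  stopifnot(inherits(phantom, "kidney_phantom"))
  shift_px <- displacement_mm / phantom$pixel_mm
  renal <- phantom$labels >= phantom$label_names[["cortex"]]
  renal_rows <- range(which(rowSums(renal) > 0))
  if (renal_rows[1] + shift_px < 1 || renal_rows[2] + shift_px > nrow(phantom$labels)) {
    stop("displacement shifts renal compartments outside the field of view")
  }
  b0 <- phantom$b0_ppm
  if (!is.null(sat_displacement_mm) && sat_displacement_mm != 0) {
    # field experienced at the saturation-time position
    b0 <- translate_rows(b0, -sat_displacement_mm / phantom$pixel_mm)
  }
  maps <- signal_maps(phantom, offset_ppm, b0)
  water <- translate_rows(maps$water, shift_px)
  fat <- translate_rows(maps$fat, shift_px)
  e1 <- water - fat
  e2 <- water + fat
  if (noise_sd > 0) {
    s0max <- max(vapply(phantom$specs, `[[`, numeric(1), "s0"))
    sd <- noise_sd * s0max
    e1 <- e1 + stats::rnorm(length(e1), sd = sd)
    e2 <- e2 + stats::rnorm(length(e2), sd = sd)
  }
  list(echo1 = e1, echo2 = e2)
}

#' Simulate a full CEST series with cushion log
#'
#' Renders every scheduled frame at the displacement of its readout midpoint,
#' records the true displacement per frame, and samples the same waveform as
#' a respiratory-cushion log with acquisition tags at the readout midpoints.
#' Fully reproducible for a fixed seed.
#'
#' @param phantom A [make_kidney_phantom()] object.
#' @param protocol An [acquisition_protocol()].
#' @param breathing A [breathing_model()].
#' @param seed Integer seed for the echo noise and cushion sensor noise.
#' @param sample_rate_hz Cushion sampling rate, Hz.
#' @param cushion_noise_sd Cushion sensor noise SD (arbitrary units).
#' @param b0_at_saturation If `TRUE`, the saturation of each frame is
#'   evaluated with the B0 field sampled at the tissue's saturation-time
#'   position (reproduces the residual MTR-asymmetry gradient observed under
#'   timed motion when the field differs between motion states). Off by
#'   default.
#' @return List of class `cest_series` with elements `stack` (a
#'   `frame_stack`: `echo1`/`echo2` arrays of dimension rows x cols x frames,
#'   `meta` data frame, `protocol`, `pixel_mm`) and `cushion` (a
#'   [cushion_log()]).
#' @export
simulate_series <- function(phantom, protocol, breathing, seed = 1L,
                            sample_rate_hz = 50, cushion_noise_sd = 0.02,
                            b0_at_saturation = FALSE) {
  stopifnot(inherits(phantom, "kidney_phantom"),
            inherits(protocol, "acquisition_protocol"),
            inherits(breathing, "breathing_model"))
  sched <- acquisition_schedule(protocol)
  fp <- frame_period(protocol)
  n <- nrow(sched)

  if (breathing$mode == "periodic" && is.null(breathing$phase_s)) {
    # exhale plateau starts at the first readout midpoint
    breathing$phase_s <- sched$readout_mid_s[1]
  }
  disp_fn <- switch(breathing$mode,
    static = function(t) rep(0, length(t)),
    periodic = function(t) displacement(breathing, t),
    timed = timed_motion(sched, breathing, protocol)
  )
  # displacement during the saturation phase (midpoint), for the optional
  # position-dependent B0 model
  sat_disp <- if (b0_at_saturation) {
    vapply(sched$sat_start_s, function(t0) {
      mean(disp_fn(seq(t0, t0 + fp$saturation_s, length.out = 9)))
    }, numeric(1))
  } else {
    rep(0, n)
  }
  d_read <- disp_fn(sched$readout_mid_s)

  nr <- nrow(phantom$labels); nc <- ncol(phantom$labels)
  echo1 <- array(NA_real_, c(nr, nc, n))
  echo2 <- array(NA_real_, c(nr, nc, n))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # cache noise-free signal maps per unique offset (b0 fixed case)
  cache <- new.env(parent = emptyenv())
  s0max <- max(vapply(phantom$specs, `[[`, numeric(1), "s0"))
  for (i in seq_len(n)) {
    if (!b0_at_saturation || sat_disp[i] == 0) {
      key <- sprintf("%.6f", sched$offset_ppm[i])
      if (is.null(cache[[key]])) {
        cache[[key]] <- signal_maps(phantom, sched$offset_ppm[i])
      }
      maps <- cache[[key]]
    } else {
      b0 <- translate_rows(phantom$b0_ppm, -sat_disp[i] / phantom$pixel_mm)
      maps <- signal_maps(phantom, sched$offset_ppm[i], b0)
    }
    shift_px <- d_read[i] / phantom$pixel_mm
    water <- translate_rows(maps$water, shift_px)
    fat <- translate_rows(maps$fat, shift_px)
    e1 <- water - fat
    e2 <- water + fat
    if (protocol$noise_sd > 0) {
      sd <- protocol$noise_sd * s0max
      e1 <- e1 + stats::rnorm(length(e1), sd = sd)
      e2 <- e2 + stats::rnorm(length(e2), sd = sd)
    }
    echo1[, , i] <- e1
    echo2[, , i] <- e2
  }

  meta <- sched
  meta$true_displacement_mm <- d_read
  duration <- n * fp$total_s
  cushion <- cushion_log(disp_fn, duration_s = duration,
                         sample_rate_hz = sample_rate_hz,
                         tags = sched$readout_mid_s,
                         noise_sd = cushion_noise_sd,
                         seed = seed + 1L)
  structure(
    list(stack = structure(
           list(echo1 = echo1, echo2 = echo2, meta = meta,
                protocol = protocol, pixel_mm = phantom$pixel_mm),
           class = "frame_stack"),
         cushion = cushion),
    class = "cest_series"
  )
}

#' @export
print.cest_series <- function(x, ...) {
  d <- dim(x$stack$echo1)
  cat("cest_series:", d[3], "frames of", d[1], "x", d[2], "pixels;",
      sum(x$stack$meta$is_reference), "reference frames\n")
  cat("  true displacement [mm]: ",
      sprintf("%.2f .. %.2f", min(x$stack$meta$true_displacement_mm),
              max(x$stack$meta$true_displacement_mm)), "\n")
  invisible(x)
}

#' Export / import a frame stack
#'
#' Writes one NIfTI volume per echo (frames stacked along the third axis)
#' plus a sidecar CSV of per-frame metadata (offset, timestamps, true
#' displacement).
#'
#' @param stack A `frame_stack` (see [simulate_series()]).
#' @param dir Output directory.
#' @export
write_frame_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "frame_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  RNifti::writeNifti(stack$echo1, file.path(dir, "echo1.nii.gz"))
  RNifti::writeNifti(stack$echo2, file.path(dir, "echo2.nii.gz"))
  utils::write.csv(stack$meta, file.path(dir, "frames.csv"), row.names = FALSE)
  yaml::write_yaml(list(schema_version = 1L, pixel_mm = stack$pixel_mm),
                   file.path(dir, "stack.yaml"))
  invisible(dir)
}

#' @rdname write_frame_stack
#' @param protocol Protocol to attach on import (the sidecar stores only
#'   geometry and timing metadata).
#' @export
read_frame_stack <- function(dir, protocol = NULL) {
  e1 <- RNifti::readNifti(file.path(dir, "echo1.nii.gz"))
  e2 <- RNifti::readNifti(file.path(dir, "echo2.nii.gz"))
  meta <- utils::read.csv(file.path(dir, "frames.csv"))
  info <- yaml::read_yaml(file.path(dir, "stack.yaml"))
  structure(
    list(echo1 = array(as.numeric(e1), dim(e1)),
         echo2 = array(as.numeric(e2), dim(e2)),
         meta = meta, protocol = protocol, pixel_mm = info$pixel_mm),
    class = "frame_stack"
  )
}
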