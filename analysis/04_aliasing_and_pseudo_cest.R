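#!/usr/bin/env Rscript
# Characterize the sampling-aliasing interaction between the 3.6 s frame
# period and the breathing rate: per-frame breathing-state sequences, their
# same-state run lengths, and the contaminated ROI Z-spectra behind the
# pseudo-CEST effects of near-resonant motion.
#
# Outputs (results/): state_runs.csv, roi_zspectra_by_mode.csv

suppressPackageStartupMessages(library(cestmotion))
dir.create("results", showWarnings = FALSE)
seed <- 1L

phantom <- make_kidney_phantom(
  b0_model = list(type = "poly", coef = c(0.02, 0.05, -0.04, 0.03, 0.02, -0.03))
)
protocol <- acquisition_protocol()
fp <- frame_period(protocol)

cat("Frame period", fp$total_s, "s; breathing phase advance per frame:\n")
for (r in c(60 / (2 * fp$total_s), seq(8, 20, by = 2))) {
  cat(sprintf("  %5.2f bpm -> %.3f cycles/frame\n", r, (fp$total_s * r / 60) %% 1))
}

runs <- do.call(rbind, lapply(c(60 / (2 * fp$total_s), seq(8, 20, by = 2)),
  function(r) {
    ser <- simulate_series(phantom, protocol,
                           breathing_model("periodic", rate_bpm = r),
                           seed = seed)
    st <- state_assignment(ser$stack, ser$cushion)
    data.frame(rate_bpm = r, n_runs = length(st$run_lengths),
               median_run = st$median_run, max_run = max(st$run_lengths),
               n_states = length(unique(st$states)))
  }))
print(runs, row.names = FALSE, digits = 4)
write.csv(runs, "results/state_runs.csv", row.names = FALSE)
cat("\nAt half the frame rate every readout lands in the exhaled plateau\n")
cat("(one state for the whole scan); near the frame rate (16 bpm) the phase\n")
cat("drifts slowly and frames group into long same-state runs, while 12 bpm\n")
cat("changes state almost every frame.\n\n")

# ROI Z-spectra under static / timed / near-resonant periodic acquisition
modes <- list(
  static = breathing_model("static"),
  timed_10mm = breathing_model("timed", amplitude_mm = 10),
  periodic_16bpm = breathing_model("periodic", rate_bpm = 16)
)
zrows <- list()
for (nm in names(modes)) {
  ser <- simulate_series(phantom, protocol, modes[[nm]],
                         seed = seed + match(nm, names(modes)))
  cube <- b0_correct(normalize_frames(ser$stack))
  for (roi in c("cortex", "medulla", "pelvis")) {
    sel <- phantom$labels == phantom$label_names[[roi]] & cube$mask
    zmat <- matrix(cube$z, prod(dim(cube$z)[1:2]), dim(cube$z)[3])[sel, ]
    zrows[[paste(nm, roi)]] <- data.frame(
      mode = nm, roi = roi, offset_ppm = cube$offsets_ppm,
      z_mean = colMeans(zmat))
  }
}
zdf <- do.call(rbind, zrows)
write.csv(zdf, "results/roi_zspectra_by_mode.csv", row.names = FALSE)

# quantify the spectral contamination: RMS deviation from the static spectrum
cat("RMS deviation of ROI-mean Z-spectra from the static acquisition:\n")
for (roi in c("cortex", "medulla", "pelvis")) {
  zs <- zdf[zdf$mode == "static" & zdf$roi == roi, "z_mean"]
  for (nm in c("timed_10mm", "periodic_16bpm")) {
    zm <- zdf[zdf$mode == nm & zdf$roi == roi, "z_mean"]
    cat(sprintf("  %-8s %-15s %.5f\n", roi, nm, sqrt(mean((zm - zs)^2))))
  }
}
cat("\nNear-resonant periodic motion contaminates contiguous blocks of the\n")
cat("offset sweep (the displaced same-state runs), producing the pseudo-CEST\n")
cat("structure; timed acquisition tracks the static spectra closely.\n")
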