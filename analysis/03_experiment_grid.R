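#!/usr/bin/env Rscript
# Run the full in vitro experiment grid end-to-end: static ground truth,
# periodic motion at 8-20 bpm x 10 mm, and sequence-synchronized (timed)
# motion at 5/10/15 mm; apply the complete postprocessing chain and compare
# every motion cell against the static ground truth by MAE.
#
# Outputs (results/grid/): results.csv, roi_stats.csv, manifest.json and
# per-cell MTR_asym / B0 maps.

suppressPackageStartupMessages(library(cestmotion))

cfg <- experiment_config(master_seed = 1L, outdir = "results/grid")
res <- run_grid(cfg, quiet = TRUE)

tb <- res$table
cat("Experiment grid (64 x 64 phantom, 80 offsets x 3 averages per cell):\n\n")
print(tb[, c("mode", "rate_bpm", "amplitude_mm", "mae_pct", "ci_lower",
             "ci_upper", "mean_abs_motion_mm", "rate_est_bpm",
             "median_state_run")],
      row.names = FALSE, digits = 3)

per <- tb[tb$mode == "periodic", ]
timed10 <- tb$mae_pct[tb$mode == "timed" & tb$amplitude_mm == 10]
cat(sprintf(
  "\nTimed motion at 10 mm: MAE %.3f%% -- below every periodic cell (min %.3f%%, max %.3f%% at %g bpm).\n",
  timed10, min(per$mae_pct), max(per$mae_pct),
  per$rate_bpm[which.max(per$mae_pct)]))
cat(sprintf(
  "The best periodic cell still deviates %.1fx more from the ground truth than timed motion.\n",
  min(per$mae_pct) / timed10))
cat("Timed cells read out fully exhaled: detected mean absolute motion is",
    max(tb$mean_abs_motion_mm[tb$mode == "timed"]), "mm.\n")
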