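#!/usr/bin/env Rscript
# Build the digital kidney phantom and the acquisition protocol; record the
# protocol timing arithmetic and the noise-free compartment Z-spectra.
#
# Outputs (results/):
#   phantom/          serialized phantom (label map, B0 map, specs)
#   protocol_timing.csv
#   compartment_zspectra.csv

suppressPackageStartupMessages(library(cestmotion))
dir.create("results", showWarnings = FALSE)

protocol <- acquisition_protocol()
fp <- frame_period(protocol)
sched <- acquisition_schedule(protocol)
timing <- data.frame(
  quantity = c("saturation_duration_s", "readout_s", "frame_period_s",
               "images_per_minute", "scheduled_frames", "scan_duration_min"),
  value = c(fp$saturation_s, fp$readout_s, fp$total_s, 60 / fp$total_s,
            nrow(sched), nrow(sched) * fp$total_s / 60)
)
write.csv(timing, "results/protocol_timing.csv", row.names = FALSE)
cat("Protocol: 15 x 100 ms pulses with 100 ms gaps ->",
    fp$saturation_s, "s saturation;", fp$total_s, "s per frame;",
    round(60 / fp$total_s, 1), "images/min;",
    nrow(sched), "frames in", round(nrow(sched) * fp$total_s / 60, 1),
    "min.\n")

phantom <- make_kidney_phantom(
  b0_model = list(type = "poly", coef = c(0.02, 0.05, -0.04, 0.03, 0.02, -0.03))
)
print(phantom)
write_phantom(phantom, "results/phantom")

# noise-free Z-spectra and model-level asymmetry of each tissue compartment
offs <- sort(protocol$offsets_ppm)
zs <- do.call(rbind, lapply(c("cortex", "medulla", "pelvis", "surround"),
  function(nm) data.frame(compartment = nm, offset_ppm = offs,
                          z = zvalue(phantom$specs[[nm]], offs))))
write.csv(zs, "results/compartment_zspectra.csv", row.names = FALSE)

cat("\nModel-level MTR_asym of the configured pools [%]:\n")
for (nm in c("cortex", "medulla", "pelvis")) {
  a <- sapply(c(1, 2, 3.5), function(d)
    mtr_asym(offs, zvalue(phantom$specs[[nm]], offs), d))
  cat(sprintf("  %-8s 1.0 ppm: %+5.2f  2.0 ppm: %+5.2f  3.5 ppm: %+5.2f\n",
              nm, a[1], a[2], a[3]))
}
cat("\nThe cortex peaks at 1.0 ppm (glucose-like), the medulla at 2.0 ppm\n")
cat("(creatinine-like), and the pelvis is dominated by the NOE-like pool\n")
cat("at -3.5 ppm, giving a negative 3.5 ppm asymmetry.\n")
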