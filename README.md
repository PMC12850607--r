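# cestmotion

Respiratory motion is the central obstacle to chemical exchange saturation
transfer (CEST) MRI of the kidney: sampling a Z-spectrum takes minutes, and
superior–inferior breathing motion makes the measured water signal
position-dependent, creating spurious "pseudo-CEST" asymmetries that mimic
metabolic contrast. One countermeasure is **timed breathing** — confining
all motion to the saturation phase of each frame and holding the exhaled
position during the readout.

`cestmotion` is a synthetic twin of a phantom study of that strategy, for
people developing or validating CEST postprocessing: a digital kidney
phantom (cortex / medulla / pelvis compartments with distinct saturation
pools, an agarose-like surround, a B0 field) and a frame-accurate
acquisition simulator (80 offsets over ±5 ppm, reference at 300 ppm,
3 averages, 2.9 s saturation + 0.7 s readout = 3.6 s per frame; periodic
trapezoidal breathing at 8–20 bpm or sequence-synchronized "timed" motion;
a respiratory-cushion log) feed the complete analysis chain used on real
data:

* **Two-point Dixon** water-only images from dual echoes, Gaussian
  smoothing (σ = 0.75 px), normalization by the 300 ppm reference;
* **Z-spectrum-based B0 correction**: local-tangent interpolation in
  0.01 ppm steps (0.5 ppm fit interval) and realignment to the spectral
  minimum;
* **MTR asymmetry** by local linear fits,
  `MTR_asym(Δω) = S(−Δω) − S(+Δω)` with `S(Δω) = m·Δω + b` fitted over
  `[Δω ± 0.5]` ppm, at 1.0 / 2.0 / 3.5 ppm, with ROI statistics;
* **Motion quantification**: median-filter + central-difference edge
  tracking of the moving boundary, breathing-rate estimation from
  threshold crossings of the cushion signal;
* **Validation**: the mean absolute error (MAE) over the 9 ROI-mean
  asymmetries (3 offsets × 3 renal ROIs) of a motion experiment against
  the static ground truth, with a 95% interval.

The signal model is phenomenological (sums of Lorentzian pools), so the
package tests pipelines and motion mechanics, not saturation physics; see
`vignettes/cest-motion-methods.Rmd` for the model, every default, and the
documented numerical choices.

## Worked example

```r
library(cestmotion)

# acquisition timing of the emulated protocol
fp <- frame_period(acquisition_protocol())
unlist(fp)
#> saturation_s    readout_s      total_s
#>          2.9          0.7          3.6

# a three-cell experiment: static ground truth, free breathing at 16 bpm,
# and sequence-synchronized (timed) motion, both at 10 mm amplitude
cfg <- experiment_config(
  grid = rbind(
    data.frame(mode = "static",   rate_bpm = NA, amplitude_mm = 0),
    data.frame(mode = "periodic", rate_bpm = 16, amplitude_mm = 10),
    data.frame(mode = "timed",    rate_bpm = NA, amplitude_mm = 10)
  ),
  master_seed = 1
)
res <- run_grid(cfg, quiet = TRUE)
res$table[, c("mode", "rate_bpm", "mae_pct", "ci_lower", "ci_upper",
              "mean_abs_motion_mm", "median_state_run")]
#>       mode rate_bpm mae_pct ci_lower ci_upper mean_abs_motion_mm median_state_run
#> 1   static       NA  0.0000  0.00000   0.0000              0.000                2
#> 2 periodic       16  0.2574  0.07473   0.4400              0.744                8
#> 3    timed       NA  0.0256  0.00963   0.0415              0.000              243
```

Each row is one simulated 14.6-minute scan processed end-to-end. The 16 bpm
cell — a rate near the 16.7 images/min sampling rate, where frames group
into long same-state runs (median run 8) and displaced frames contaminate
contiguous blocks of the Z-spectrum — deviates from the ground truth by an
MAE of 0.26%, ten times the timed cell's 0.026%. The timed cell reads out
fully exhaled: zero detected boundary motion and a single breathing state
across all 243 frames.

The static cell's compartment contrast (ROI-mean MTR_asym in %):

```r
res$roi_stats[res$roi_stats$mode == "static",
              c("roi", "offset_ppm", "mean_pct", "sd_pct", "n_pixels")]
#>       roi offset_ppm mean_pct sd_pct n_pixels
#> 1  cortex        1.0    3.097  0.394      384
#> 2  cortex        2.0    1.488  0.608      384
#> 3  cortex        3.5    0.213  0.131      384
#> 4 medulla        1.0    1.879  0.259      396
#> 5 medulla        2.0    5.858  0.661      396
#> 6 medulla        3.5    0.866  0.475      396
#> 7  pelvis        1.0    2.151  0.153       80
#> 8  pelvis        2.0    0.106  0.963       80
#> 9  pelvis        3.5   -5.255  0.933       80
```

The configured pattern is the qualitative one expected of renal tissue:
the cortex (glucose-like pool) peaks at 1.0 ppm, the medulla
(creatinine-like pool) at 2.0 ppm, and the pelvis is negative at 3.5 ppm
where its NOE-like pool dominates. Magnitudes are set by the synthetic
pool table (`inst/extdata/default_pools.yaml`), not by physiology.

## Analysis workflow

The `analysis/` scripts run the study end-to-end and write their tables
under `results/`:

1. `01_phantom_and_protocol.R` — phantom construction, timing arithmetic,
   noise-free compartment Z-spectra;
2. `02_breathing_and_motion.R` — waveforms, breathing-rate recovery across
   the 8–20 bpm grid, programmed-amplitude recovery from image series;
3. `03_experiment_grid.R` — the full 11-cell grid (static, periodic
   8–20 bpm × 10 mm, timed 5/10/15 mm) with MAE table, maps and manifest;
4. `04_aliasing_and_pseudo_cest.R` — breathing-state run-length structure
   and motion-contaminated ROI Z-spectra.

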