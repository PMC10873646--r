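# sparkq

Quantitative analysis of phase-separated transcription-factor condensates
and their transcriptional consequences.

Transcription factors such as the oncogenic fusion YAP-MAML2, or the Hippo
effector TAZ, can demix inside the nucleus into liquid-like condensates once
their concentration exceeds a saturation concentration c_sat. Whether such
condensates change transcriptional output — beyond what the same amount of
diffuse protein would do — is measured by combining live-cell imaging
(condensate detection, phase curves, droplet-fusion kinetics,
colocalization with the transcription machinery, dissolution time courses)
with expression readouts (RT-qPCR, RNA-seq differential expression with and
without condensate dissolution). `sparkq` implements that entire
measurement chain for R users, together with a ground-truthed synthetic
microscopy/expression generator so that every estimator can be validated by
parameter recovery.

## The quantities the package computes

- **SPARK signal** — the per-cell fraction of fluorescence residing in
  condensates, `SPARK = sum(I_condensate pixels) / sum(I_all cell pixels)`,
  in [0, 1]. Condensates are connected components above a per-cell high
  threshold (dilute median + k·sd, default k = 3); cells are segmented with
  a per-image low threshold.
- **Concentration calibration** — ordinary least squares of mean counts per
  pixel against a purified-fluorophore dilution series converts cell
  fluorescence to protein concentration (nM); stock concentration comes
  from Beer-Lambert, `c = A / (epsilon * L)`.
- **Saturation concentration** — a hinge changepoint fit to the per-cell
  (concentration, SPARK) curve: SPARK = 0 below c_sat and rises as
  `a (1 - c_sat / c)` above it, with a percentile bootstrap CI over cells
  and a paired-bootstrap comparison between conditions (e.g. +/-
  rapamycin).
- **Inverse capillary velocity** — droplet-fusion events are tracked, the
  merged object's aspect ratio is fitted with
  `AR(t) = 1 + (AR0 - 1) exp(-t / tau)`, and `tau / ell` estimates the
  viscosity-to-surface-tension ratio eta/gamma (s/um), with `ell` the
  equivalent radius of the fused droplet.
- **Colocalization** — the directional, object-based fraction of reference
  condensates whose centroid falls inside a partner-channel punctum.
- **Dissolution and mitosis time courses** — normalized SPARK decay,
  total-fluorescence conservation, chromosome volume from a histone
  channel, and signed timing offsets between changepoints.
- **Expression** — ddCt qPCR (`relative expression = 2^(-ddCt)`), a
  negative-binomial differential-expression stage (median-of-ratios
  normalization, trended dispersion shrinkage, exact conditional NB test)
  with the call rule p < 0.01, |log2FC| >= 0.58, BH FDR < 0.1, a
  three-contrast comparison isolating phase-separation-regulated genes, and
  a hypergeometric over-representation test for user-supplied gene sets.

## Worked example

```r
library(sparkq)

## calibrate intensity -> concentration from a synthetic dilution series
gt  <- imaging_ground_truth(csat_nM = 40, seed = 7)
cal <- fit_standard_curve(generate_dilution_table(gt))
cal
#> Calibration curve: I = 2.001 * C + 99.89 (r^2 = 1.0000, n = 7)

## build a phase curve from 60 synthetic cells and estimate c_sat
conc <- exp(seq(log(5), log(500), length.out = 60))
sim  <- generate_cell_images(gt, conc)
meas <- do.call(rbind, lapply(seq_along(sim$images), function(i) {
  m <- measure_cells(sim$images[[i]], curve = cal); m$cell_id <- i; m
}))
fit <- estimate_csat(build_phase_curve(meas), n_bootstrap = 500, seed = 1)
fit
#> Saturation concentration: 40.6 nM (95% bootstrap CI 37.7 to 42.4 nM)
#>   hinge fit (saturating rise) over 60 cells, RSS 0.001488

## droplet-fusion relaxation: inverse capillary velocity
fsim <- generate_fusion_movie(fusion_ground_truth(n_events = 6, seed = 8))
fits <- lapply(fsim$movies,
               function(m) fit_relaxation(track_fusion_events(m)[[1]]))
summarize_inverse_capillary_velocity(fits)
#> Inverse capillary velocity: 1.85 +/- 0.33 s/um (n = 6)

## qPCR: percent change of target genes after condensate dissolution
ddct(generate_ct_table(c(CTGF = 0.16, CYR61 = 0.30), seed = 9))
#> ddCt relative quantification (reference: ACTB, control: control)
#>    gene  ddct rel_expression percent_change   p_value    direction
#> 1  CTGF 2.840         0.1397         -86.03 2.970e-06 86% decrease
#> 2 CYR61 1.894         0.2691         -73.09 4.374e-04 73% decrease
```

The c_sat estimate recovers the generator's 40 nM threshold; the fusion
summary recovers the 1.8 s/um ground-truth inverse capillary velocity
within its event-to-event spread; the qPCR stage converts the simulated
fold changes (0.16, 0.30) back into the percent decreases they encode.

`run_pipeline(default_config(seed = 1), out_dir = "out")` executes every
stage end-to-end, writing per-stage CSV/JSON outputs plus a manifest with
parameter values and file hashes; reruns with the same seed are
byte-identical.

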