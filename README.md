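# acspect

Quantitative SPECT imaging of Actinium-225 for targeted alpha therapy:
reconstruction, scatter correction, partial-volume correction and
dosimetry, exercised end to end on synthetic digital phantoms.

## The problem

Post-therapy imaging after [²²⁵Ac]Ac-PSMA radioligand therapy has to work
with ~8 MBq of administered activity and three imageable photon windows —
440 keV (²¹³Bi, emission probability 25.9%), 218 keV (²²¹Fr, 11.4%) and a
broad X-ray window around 78 keV. At clinically realistic dwell times this
is an extreme low-count regime in which (a) energy-window scatter
estimates are themselves dominated by Poisson noise, and (b) the partial
volume effect suppresses activity — and hence absorbed dose — in
kidney- and lesion-sized structures.

`acspect` implements the analysis chain needed to study these effects:

* digital sphere-in-cylinder phantoms, attenuation maps and seeded Poisson
  projection simulation;
* a rotation-based attenuated projector with distance-dependent Gaussian
  resolution modelling and an exact adjoint;
* MAP-MLEM reconstruction (one-step-late quadratic prior, additive scatter
  term in the Poisson model) with count-to-concentration calibration;
* three scatter corrections: DEW (width-scaled lower window), TEW
  (trapezoid from flanking windows), and transmission-dependent scatter
  correction (TDSC) — per-slice convolution of the image estimate with
  depth-dependent mono-exponential kernels, scaled by a scatter-to-primary
  model `SF(p) = A − B·exp(−γp) − 1` of the attenuation path length and
  recomputed once per EM iteration;
* partial-volume correction by Richardson–Lucy deconvolution (filter
  afterwards) and the Iterative Yang method (filter first, quadrature-
  combined PSF), with matched-filter PSF estimation;
* recovery coefficients (`RC = AC_VOI / AC_true × 100%`),
  contrast-to-noise ratios (`CNR = (μ_VOI − μ_bg)/σ_bg` over four
  background VOIs), and isocontour lesion segmentation with
  threshold calibration;
* MIRD-style dosimetry: mono-exponential two-point time-activity fits,
  `TIA = A₀/λ`, and RBE-weighted dose `D = RBE · TIA · S` (default
  RBE 5, whole-decay-chain S-values as configuration).

See `vignettes/acspect-methods.Rmd` for the model details, parameter
choices and limitations.

## Worked example

Fit the scatter-to-primary model and run one low-count reconstruction
with TDSC:

```r
library(acspect)

# phantom: 8.7 L cylinder, spheres of 191/100/48 ml at 4.2 over 0.5 kBq/ml
spec <- phantom_spec(voxel_mm = 9.6)
ph   <- build_phantom(spec, grid_n = 40)

win <- default_windows()[["440keV"]]
kt  <- make_kernel_table(voxel_cm = 0.96)   # depths 2-40 cm, SF model
acq <- acquisition_spec(n_projections = 32, time_per_projection_s = 10,
                        matrix_size = 40, bin_mm = 9.6, seed = 7)
pc  <- projector_config(psf_sigma0_cm = 1.0, psf_slope = 0.03)

sim <- simulate_projections(ph$activity, ph$mu, win, acq,
                            scatter_model = kt, cfg = pc)
sum(sim$photopeak$counts) / 32          # 902.6 counts per projection: LC regime

rec <- map_mlem(sim$photopeak, ph$mu,
                recon_config(100, beta = 0.01, scatter_mode = "TDSC"),
                pc, tdsc_model = kt)
img <- gaussian_postfilter(rec, 30)
```

The full comparison — both scatter modes per window, calibration, PVC,
RC/CNR per sphere — is one call:

```r
res <- run_phantom_study(phantom_study_config(seed = 1))
head(res$table)
```

which on the default synthetic conditions (seed 1) prints

```
  protocol window scatter_mode  pvc sphere volume_ml segmentation rc_pct    cnr
1       LC 440keV          DEW none      1       191           ct  65.95 10.332
2       LC 440keV          DEW none      2       100           ct  53.16  7.833
3       LC 440keV          DEW none      3        48           ct  40.03  5.267
4       LC 440keV          DEW none      3        48   isocontour  41.65  5.584
```

`rc_pct` is the percentage of the true 4.2 kBq/ml recovered within the
sphere segmentation (partial volume pushes it well below 100 without
PVC), and `cnr` is the sphere-to-background contrast over the background
noise. Across the full table TDSC's noise-free scatter projections beat
the Poisson-noisy energy-window estimates on CNR for every sphere and
window (e.g. 12.81 vs 10.33 for the 191 ml sphere at 440 keV), and both
PVC methods raise every recovery coefficient, the region-based IY method
by far the most.

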