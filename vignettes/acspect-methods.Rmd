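---
title: "Methods: quantitative Ac-225 SPECT with scatter and partial-volume correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative Ac-225 SPECT with scatter and partial-volume correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Post-therapy imaging of Ac-225 radioligand therapy works with roughly 8 MBq
of administered activity and three imageable photon windows: the 440 keV
line of Bi-213 (emission probability 25.9%), the 218 keV line of Fr-221
(11.4%), and a broad X-ray band around 78 keV fed by several daughters and
by collimator lead fluorescence. Counts are extremely low (tens of counts
per detector bin per projection at clinically realistic dwell times), so two
error sources dominate quantification: scatter, whose energy-window
estimates are themselves Poisson-noisy, and the partial-volume effect,
which is aggravated by the heavy regularisation and smoothing these count
levels force.

`acspect` implements the full analysis chain needed to study these effects
on synthetic data: phantom and projection simulation, attenuated
resolution-modelled MAP-MLEM reconstruction with three scatter-correction
strategies, two post-reconstruction partial-volume corrections, phantom
quantification metrics, and region-level RBE-weighted dosimetry.

# Forward model and projector

Volumes are isotropic 3-D grids (`volume_image`). The projector is
rotation-based: for each projection angle the volume is resampled
(bilinear, exact-transpose adjoint; nearest-neighbour available) so that
the detector lies beyond one grid face, each detector-parallel plane is
convolved with an isotropic Gaussian whose width grows linearly with the
distance to the detector,

$$\sigma(d) = \sigma_0 + s\,d,$$

and each voxel is weighted by the attenuation survival factor
$\exp(-\int \mu\,dl)$ along its ray before summation. Attenuation uses the
interleaved convention (half-voxel self-attenuation at the source voxel),
and the back projector applies exactly the same weights, so
$\langle Ax, y\rangle = \langle x, A^\top y\rangle$ holds to floating-point
precision — a property the EM reconstruction relies on and the test suite
asserts at `1e-6`.

The published system response this stands in for is a pre-simulated 2-D
collimator model including septal penetration; a two-parameter
distance-dependent Gaussian was chosen instead because the downstream PVC
methods assume no more than an effective isotropic Gaussian anyway. The
study runner uses window-specific parameters
($\sigma_0 = 1.0$ cm, slope $0.03$ at 440 and 218 keV;
$\sigma_0 = 0.55$ cm, slope $0.02$ at 78 keV), calibrated so the
reconstructed images reproduce the energy ordering of the real system's
matched-filter resolution (the high-energy windows blur more, through
septal penetration, than the X-ray window); the resulting matched-filter
sigmas on this synthetic scanner are 1.0/1.0/0.75 cm. Septal penetration
star artefacts themselves are out of scope.

# Reconstruction

`map_mlem()` runs multiplicative EM on the Poisson model
$y \sim \mathrm{Pois}(Ax + s)$. The scatter estimate $s$ enters only the
forward-model denominator; it is never subtracted from the data, which
preserves the count statistics. With penalty weight $\beta > 0$ a
one-step-late quadratic 6-neighbourhood smoothing term divides the update
denominator. The published algorithm's exact penalty functional is not
specified; the one-step-late quadratic prior is the most common choice for
MAP-MLEM smoothing and is flagged as a non-reproducing detail. Defaults
follow the reference protocol: 100 iterations, $\beta = 0.01$, and a 30 mm
FWHM Gaussian post-filter (boundary-renormalised, so constants are
preserved exactly and interior flux to better than 0.1%).

Counts are converted to activity concentration with calibration factors
measured on a homogeneous cylinder acquisition (16 cm central VOI),
separately per energy window and per scatter-correction mode; applying a
factor across modes is rejected at the type level.

# Scatter correction

Three estimators are implemented:

* **DEW** — lower-window counts scaled by the width ratio $W_p/W_l$
  (440 keV: 20% peak, 10% lower window). The multiplier is the standard
  width normalisation; it is exposed in the window configuration.
* **TEW** — trapezoid estimate $(C_l/W_l + C_u/W_u)/2 \cdot W_p$
  (218 keV: 20% windows at 178 and 267 keV).
* **TDSC** — transmission-dependent scatter correction: each
  detector-parallel slice of the current image estimate is convolved with a
  mono-exponential scatter kernel selected by the slice's depth below the
  surface, each voxel of the convolved slice is scaled by the
  scatter-to-primary fraction
  $$SF(p) = A - B\,[e^{-\sum_i \mu_i \Delta}]^{\gamma} - 1$$
  evaluated at its attenuation path length $p$, and the assembled scatter
  image is summed along the rays without further blurring. The scatter
  projections are recomputed from the image estimate once per full EM
  iteration and are deterministic functionals of it — the property that
  motivates TDSC's noise advantage over energy-window estimates.

Kernel tables index mono-exponential tail slopes by slab depth (2–40 cm in
2 cm steps by default); queries beyond 40 cm clamp to the 40 cm entry
(slope changes fall below 3% per additional 2 cm there), shallower queries
clamp to the shallowest entry with a warning, and interpolation between
entries is linear in slope and amplitude. Kernels are 2-D isotropic,
truncated at radius $5/\mathrm{slope}$ and renormalised to unit sum; only
voxels inside the attenuating medium act as scatter sources (air contains
no scatterers). Because no Monte-Carlo transport is in scope, the package
generates the tables from a smooth synthetic slope law
$b(d) = 0.25 + 0.25\,e^{-d/15\,\mathrm{cm}}$ cm$^{-1}$ — tail slopes of a
few tenths per cm with the required flatness beyond 40 cm — and default SF
coefficients $(A, B, \gamma) = (1.5, 0.45, 0.5)$, giving scatter-to-primary
fractions rising from 0.05 at the surface to about 0.4 behind 25 cm of
water. Real tables fitted from simulation can be supplied through the same
interfaces (`fit_tail_monoexp()`, `fit_sf_model()`).

# Partial-volume correction

Both methods assume a spatially invariant isotropic Gaussian PSF.

* **Richardson–Lucy** deconvolution is applied to the unfiltered
  reconstruction and the 30 mm noise filter afterwards; boundary handling
  renormalises the kernel so total flux is conserved exactly.
* **Iterative Yang** filters first, then corrects with the PSF combined in
  quadrature with the filter sigma
  ($\sqrt{1.5^2 + 1.27^2} \approx 1.97$ cm at 440/218 keV,
  $\sqrt{1.0^2 + 1.27^2} \approx 1.62$ cm at 78 keV); regional means are
  recomputed from the current estimate each iteration, and background and
  exterior are regions in their own right.

The filter ordering follows the optimised protocol (filter after RL,
before IY). The system sigma comes from a matched-filter search: the
ground-truth image is blurred with candidate sigmas (0.5–2.0 cm in 0.25 cm
steps), the RMSE against the unfiltered high-count reconstruction is summed
over spherical VOIs expanded 2 cm beyond each sphere, and the argmin sigma
is selected (ties break toward the smaller, i.e. less aggressive, sigma).
Expanded VOIs must not overlap; the default sphere layout guarantees this.
The study runner keeps the protocol's RL iteration counts (7/15/10 for
440/218/78 keV; 10 IY iterations) and defaults its PVC sigmas to the
matched-filter calibration of the package's own synthetic scanner —
1.0/1.0/0.75 cm — rather than re-running the search on every study;
`estimate_psf_sigma()` performs the search when wanted. The RL iteration
trade-off between recovery and noise has no closed objective; the
iteration count is configuration, with the recovery-vs-iteration curve
available from the functions themselves.

# Metrics

Recovery coefficient $RC = AC_{VOI}/AC_{true} \times 100\%$ (no spill-over
correction) and contrast-to-noise ratio
$CNR = (\mu_{VOI} - \mu_{bg})/\sigma_{bg}$, where the background mean and
standard deviation are the averages of the per-VOI means and standard
deviations over four rectangular background VOIs (54, 145, 260, 280 ml).
The reference measurement only states that these VOIs are evenly
distributed at a safe distance from the spheres; here they are placed by
seeded rejection sampling inside the cylinder at ≥ 3 cm from every sphere
surface, which is deterministic given the seed. Lesion-style segmentation
uses an isocontour at a percentage of the regional maximum, restricted to
the 26-connected component containing the maximum; the percentage is
calibrated against the known 48 ml sphere volume over a 40–95% grid in 5%
steps.

# Dosimetry

With two post-therapy time points, time-activity curves are
mono-exponential and fitted exactly through the points;
$\lambda = \ln(a_1/a_2)/(t_2 - t_1)$ must be positive (non-decaying pairs
are rejected as non-physical). The time-integrated activity is
$A_0/\lambda$, integrating the fitted curve from 0 to infinity — with a
single mono-exponential and two samples this is the only self-consistent
choice, and it is stated prominently because it back-extrapolates to
injection time. Absorbed dose follows the MIRD formalism,
$D = RBE \cdot \tilde{A} \cdot S$, with a whole-decay-chain S-value
supplied as configuration (no transport is computed), local energy
deposition of all daughters assumed, and a default RBE of 5 multiplying
the entire dose.

# The synthetic phantom and what passing tests mean

The generator reproduces the reference measurement conditions: an 8.7 L,
25 cm diameter water cylinder holding 191/100/48 ml spheres at 4.2 kBq/ml
over a 0.5 kBq/ml background (the stated concentrations are used; their
ratio is 8.4 even though the reference text rounds it to 8.1); 32
projections over 360° (the orbit range is not stated in the reference;
360° is the standard body orbit); low-count (10 s) and high-count (120 s)
dwell times; energy windows and scatter windows as above; water attenuation
0.102/0.134/0.184 cm$^{-1}$ at 440/218/78 keV. The X-ray window's
effective emission probability is set to 0.50 per decay as a plausible
effective yield for the overlapping daughter X-rays plus collimator
fluorescence; the reference does not state one. Detector sensitivity is a
single scalar per window (default $10^{-4}$ counts per emitted photon,
about 100 cps/MBq, typical of high-energy collimators), which puts the LC
440 keV acquisition near $10^3$ counts per projection — the extreme
low-count regime. Spheres sit on a 6.5 cm ring at $z = -4.5$ cm: the
smallest ring radius that keeps the expanded matched-filter VOIs disjoint,
with the upper half of the cylinder left free for background VOIs.

Scatter in the simulator uses the same kernel formalism as TDSC (with an
optional mismatch multiplier to exercise the correction under an imperfect
model), and scatter-window counts are width-proportional Poisson samples
of the true scatter. Consequences to keep in mind: TDSC sees a matched
scatter model, so its accuracy here is an upper bound; the simulation is an
inverse crime with respect to the projector (no septal penetration, no
downscatter between windows, no collimator scatter); and Poisson noise is
the only noise source. Passing tests therefore validate the algorithms and
their relative ordering (TDSC's noise advantage, PVC's recovery gains),
not absolute clinical accuracy.

# Numerical choices

* Rotation: bilinear with exact transpose adjoint; nearest-neighbour kept
  for discrete checks. Zero padding outside the grid.
* Gaussian kernels truncated at $4\sigma$ and renormalised;
  boundary-renormalised convolution for all post-reconstruction smoothing.
* EM guards: voxels with near-zero sensitivity are excluded by mask;
  forward projections are floored at $10^{-12}$ before division; the
  one-step-late denominator is floored at $10^{-10}$.
* Matched-filter ties break toward smaller sigma; isocontour-threshold
  ties toward the smaller percentage.
* Seeds: every stochastic stage takes an explicit seed; study-stage seeds
  derive deterministically from the master seed and are recorded in the
  outputs.

# Problem sizes

The study runner defaults to the clinical protocol at half resolution: a
40³ grid with 9.6 mm voxels and bins (the 128 × 4.8 mm matrix halved),
which completes the full three-window LC comparison — twelve
reconstructions, six of them with per-iteration TDSC — in a few minutes
on a single core while keeping the smallest sphere at about five voxels
across. Finer grids (64³ at 7.2 mm, or the clinical 128³ at 4.8 mm) are
available through `phantom_study_config(grid_n =, voxel_mm =)`;
convergence and unit tests that need finer sampling (sphere-volume
convergence, the 64³ uniform-cylinder recovery run) choose their sizes per
test.

# Known limitations

* Under pure Poisson noise with a matched scatter model, RL deconvolution
  amplifies background noise roughly as fast as it restores sphere
  contrast, so its contrast-to-noise benefit is marginal and can be
  negative at these count levels even where its recovery gain is large;
  clinical images carry additional structured noise components the
  synthetic scanner does not reproduce.

* The PSF is modelled as spatially invariant and isotropic end to end;
  distance-dependent anisotropy, septal penetration and collimator scatter
  are not restored by the PVC stage.
* Kernel tables and SF coefficients are synthetic stand-ins calibrated for
  plausibility, not against Monte-Carlo transport.
* Energy-window cross-talk (downscatter of higher-energy photons into the
  440 keV window) is not simulated, mirroring the known DEW limitation.
* Dosimetry is region-level only; no voxel dosimetry, no daughter
  redistribution kinetics, no cohort statistics.
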