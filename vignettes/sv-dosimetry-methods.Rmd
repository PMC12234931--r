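---
title: "Small-volume-of-interest kidney dosimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-volume-of-interest kidney dosimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Kidney absorbed dose limits Lu-177-DOTATATE therapy of neuroendocrine
tumours, so per-cycle kidney dosimetry from quantitative SPECT/CT is
clinically desirable. The reference procedure segments the whole kidney
parenchyma (WKP — cortex plus medulla, excluding the renal pelvis) on CT,
sums SPECT counts in that volume, and corrects for partial-volume spill-out
with a recovery coefficient (RC). Because manual WKP segmentation is slow,
a shortcut samples the parenchyma with one or more small spherical volumes
of interest (SVs, nominally 4, 2 or 0.6 mL) placed in regions representative
of the mean activity concentration. `svdose` implements both methods on
synthetic kidney phantoms and quantifies their agreement, so the SV
method's bias and accuracy can be studied as a function of sphere volume,
number of spheres, and reconstruction smoothness.

## The dose model

Activity concentration in a VOI of volume $V$ at time $t$ is

$$C(t) = \frac{c(t)}{Q \cdot RC(V) \cdot V \cdot \rho},$$

where $c(t)$ is the VOI count rate (cps), $Q$ the system calibration factor
(cps/MBq) measured in a uniform cylinder phantom, $\rho = 1.05$ g/mL the
parenchyma density, and $RC(V)$ the recovery coefficient. The SV variant
uses the same formula with $RC \equiv 1$ and the sphere volume in the
denominator. Washout is fitted with a single exponential
$C(t) = C_0 e^{-\lambda t}$ (the log-linear solution refined by nonlinear
least squares; on noiseless synthetic data the model is exact, since the
phantom kinetics are mono-exponential by construction). The time-integrated
activity concentration is $C_0/\lambda$, integrated from zero to infinity
with no uptake phase. Under the local-energy-deposit assumption all electron
energy (147 keV per Lu-177 decay) is absorbed where emitted:

$$D = \mathrm{TIAC} \times 0.0847872\ \mathrm{Gy\ per\ (MBq\,h/g)},$$

from $3.6\times10^{9}$ decays per MBq·h, $1.602177\times10^{-16}$ J/keV and
1000 g/kg. Photon self- and cross-dose are deliberately omitted.

The RC trend against volume is summarised by
$RC(V) = (1 + a/V)^{-b}$, fitted by unweighted nonlinear least squares with
a log-log linearization providing the start values.

## What the synthetic cohort emulates

`make_cohort()` draws 18 patients with two kidneys each:

| parameter | default | meaning |
|---|---|---|
| volume | uniform 31–243 mL | parenchyma volumes spanning the clinical range |
| rim thickness | uniform 12–22 mm | parenchyma shell thickness |
| $C_0$ | lognormal, log-mean $\log 0.5$, log-sd 0.4 MBq/g | baseline concentration |
| effective half-life | uniform 30–70 h | plausible Lu-177-DOTATATE kidney kinetics |
| texture CV | 0.10 | voxelwise lognormal uptake non-uniformity |
| background | 5% of parenchyma concentration | unspecific surrounding uptake |
| grid | 4.42 mm isotropic | the clinical SPECT grid |
| administered activity | 7.4 GBq | for Gy/GBq reporting |

The kidney is an outer ellipsoid (polar elongation 1.8) minus a concentric
cavity, giving a shell of uniform rim thickness — two interpretable
parameters that capture the feature driving SV-size effects: spheres wider
than the rim unavoidably average in non-parenchyma signal. Kinetic defaults
(half-life range, $C_0$ scale) are chosen to put absorbed dose rates near
0.4–0.6 Gy/GBq, the clinically typical range; they are package choices, not
fitted quantities. Some volume/thickness pairs are geometrically infeasible
(a 31 mL shell cannot be 22 mm thick), so drawn thicknesses are clipped to
95% of the feasible maximum — anatomically consistent, since small atrophic
kidneys have thin rims.

With the default $C_0$ scale, sensitivity $Q = 10$ cps/MBq and 3600 s of
acquisition, typical parenchyma voxels collect on the order of $10^3$
counts, i.e. a few percent Poisson noise — the regime where placement and
fitting behave as in practice.

## The acquisition emulator and its calibration

Projection-space physics is out of scope. The emulator maps true activity
to a reconstructed image by (1) converting to activity per voxel,
(2) convolving with a stationary isotropic Gaussian point-spread function,
(3) scaling by $Q$, (4) optionally Poisson-sampling expected counts over the
acquisition time, and (5) optional Gaussian post-filtering (sigma 0–12 mm).
Smoothing uses a separable kernel truncated at $6\sigma$ and normalised to
unit sum; signal blurred past the grid edge is lost, which is the physical
spill-out of a field embedded in a zero background (phantom grids keep a
35 mm margin so the loss is negligible at protocol resolutions).

Two presets mirror the study protocols. The high-resolution preset
("ASCC": attenuation-, scatter- and collimator-detector-corrected OSEM) has
its PSF sigma *calibrated once* so that the mean RC over a fixed 36-kidney
reference shell cohort equals 0.85; bisection gives 2.374 mm
(`scripts/calibrate_sigma.R`), and the value is stored in
`inst/extdata/presets.yaml`. The low-resolution preset ("AC",
attenuation-only OSEM with heavy post-filtering) is defined as the ASCC PSF
plus 6 mm of smoothing in quadrature; with the calibrated sigma its
reference-cohort mean RC is 0.66 with a larger spread, reproducing the
qualitative high/low-resolution RC separation. Note that the calibrated
sigma is an *effective* image-domain parameter absorbing everything the
surrogate does not model (OSEM convergence, distance-dependent response);
it is deliberately not interpreted as a physical system resolution.

## Recovery coefficients on voxel grids

`simulate_rc()` fills the mask with unit concentration, emulates a
noiseless acquisition, and divides measured by true activity. Two
subtleties:

- RC is defined on *noiseless* emulation only; noise enters patient-image
  emulation, never the RC.
- With partial-weight masks, the weighted-VOI measurement at perfect
  resolution returns $\sum w^2 / \sum w$ of the true activity — a
  boundary-voxel sampling loss. The simulated RC absorbs this factor by
  design, exactly because it is computed with the same measurement
  procedure later applied to the emulated patient images; the correction
  therefore cancels it. For a binary mask the zero-blur RC is exactly 1.

Sphere masks are voxelized with corner/neighbour boundary detection and
adaptive supersampling (up to 41 subdivisions per axis for spheres close to
the voxel size), keeping weighted volumes within 0.5% of nominal — the
independent check against the closed-form blurred-sphere solution agrees
within 1% for 4–200 mL spheres at 2–6 mm blur.

## Deterministic SV placement

The study protocol places SVs visually in "representative" regions, toward
the pelvis, away from the outer cortex, avoiding hot and cold spots. The
package operationalises this as a pure function of the observed image:

1. candidates are in-mask voxels in the inner half of the parenchyma by
   Euclidean distance to background (the pelvis cavity counts as
   background);
2. each candidate is scored by the absolute difference between the
   sphere-kernel image mean at that centre and the median in-mask voxel
   value — the median being a hotspot-robust central tendency;
3. centres are chosen greedily by ascending score with a minimum pairwise
   separation of one sphere diameter, ties broken by voxel index.

The greedy order yields a nested design: the first $k$ centres never change
when more spheres are requested. Spheres are *not* clipped to the
parenchyma; a 4 mL sphere wider than the rim sums whatever its volume
covers, which is the mechanism behind the SV-size bias. The inner-half rule
and the separation are exposed parameters; they are a surrogate for an
operator instruction that the source protocol leaves quantitatively
undefined.

## Normalization factors and agreement statistics

For each (SV volume, post-filter) stratum, the normalization factor is the
arithmetic mean of single-SV over WKP dose ratios across all kidneys — five
placed spheres per kidney, giving 180 terms for the 36-kidney cohort. It is
applied as an apparent RC (dose divided by NF), always per stratum, never
pooled across filter settings. Agreement of the NF-corrected doses is
summarised by the mean (bias) and sample standard deviation (accuracy, n−1)
of the percentage difference to the WKP reference, the Pearson correlation,
and Bland–Altman limits of agreement at bias ± 1.96 SD. In-sample NF
correction zeroes the mean single-SV percentage difference algebraically;
`run_sweep(nf_mode = "split")` additionally quantifies hold-out behaviour
on a patient-level split.

```{r sweep-example}
library(svdose)
cohort <- make_cohort(cohort_spec(seed = 1))
sw <- run_sweep(cohort, model = protocol_preset("ASCC", noise = TRUE),
                sv_volumes = c(4, 2, 0.6), n_svs = 1:5, sigmas = c(0, 4),
                seed = 1)
sweep_markdown(sw, sigma_mm = 4)
autoplot(sw)
```

## Numerical choices

- Volume solving for the shell geometry uses `uniroot` on the closed-form
  shell volume (tolerance 1e-10), then 3x supersampled voxelization; mask
  volumes match requests within 2%.
- The RC curve fit and the mono-exponential refinement use
  Levenberg–Marquardt (`minpack.lm`) with positivity bounds; flat RC data
  return the $b \to 0$ limit explicitly, and washout rates below
  $10^{-6}$ h$^{-1}$ are rejected as non-decaying rather than silently
  extrapolated to enormous integrals.
- COV and accuracy use the sample (n−1) standard deviation throughout.
- Degenerate placement (fewer feasible centres than requested) returns the
  feasible set with an `incomplete` flag and a warning; sweep summaries then
  average the available spheres.
- Problem sizes: the shipped experiments use the 18-patient cohort on
  ~40–60 voxel grids, chosen so a full sweep (two filter settings, three SV
  sizes, five SV counts) completes in about a minute on one CPU.

## What passing tests do and do not show

The generator reproduces the *geometric and statistical skeleton* of the
study: volumes, rim thicknesses, washout kinetics, count statistics,
resolution regimes, and the full analysis chain. It does not reproduce
several features of real reconstructed patient data: OSEM update-dependent
noise texture and Gibbs ringing, distance-dependent detector response,
cortex/medulla uptake gradients, spill-in from hot neighbouring organs, or
CT/SPECT misregistration. One consequence is visible and deliberate: on
uniform-truth phantoms every SV reading is bounded above by the true
concentration (a unit-mass convolution cannot exceed its input's maximum),
while the RC-corrected WKP estimate is unbiased by construction — so
unfiltered SV doses *under*-estimate the reference here (normalization
factors 0.88–0.91 at zero post-filter), whereas the study observed
overestimation on real images. The sign of that unfiltered bias is
therefore a property of real-data heterogeneity that this emulator does not
claim to replicate; the package reports it honestly rather than tuning the
generator to force it. Directional findings that *are* replicated: accuracy
improves (or stays flat) with more SVs, the 2 mL sphere is the most
accurate SV size at moderate post-filtering for thin-rim cohorts, RC falls
with blur and rises with volume, and NF correction centres the method
comparison.

Deterministic placement also compresses between-SV variability relative to
a human operator (the first sphere is already near-optimal), which is why
absolute accuracies here (≈5–6%) are tighter than the 8–12% of the study
and why averaging more spheres helps less than it did there.

## Known limitations

- Stationary isotropic PSF; no projection physics, scatter windows or
  attenuation modelling.
- No tumours, cysts, hot background organs, or respiratory motion.
- Mono-exponential kinetics only; no uptake phase, no bi-exponential or
  trapezoid-plus-tail integration variants.
- The SV placement rule is one defensible formalisation of a visual
  instruction; its parameters are exposed rather than asserted as the
  operators' intent.
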