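---
title: "kerMAR: model, simulator and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kerMAR: model, simulator and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the restoration
model and its assumptions, the physics behind the tissue thresholds and the
range engine, what the synthetic-data generator does and does not emulate,
and the numerical and design choices a maintainer would want written down.

## The restoration model

CT values corrupted by metal artifacts are treated voxel-wise as noisy
observations of a latent true value $y$. Two sources of information are
combined:

* **Prior** $p(y \mid \mathbf{m})$: kernel regression on training pairs
  $(y_j, \mathbf{m}_j)$ of uncorrupted CT values and cuboidal MRI patch
  vectors, harvested from voxels of the same subject that lie in the body,
  outside the corrupted region, and far enough from it (and the grid
  border) that no patch voxel overlaps it.
* **Likelihood** $p(t \mid y) = \mathcal{N}(t;\, y, \sigma^2)$: additive
  Gaussian artifact noise on the observed corrupted value $t$.

The restored value is the posterior expectation

$$\hat y \;=\; \frac{\sum_j K_h(\lVert \mathbf{m}-\mathbf{m}_j\rVert)\,
\varphi(t; y_j, \sigma^2)\, y_j}
{\sum_j K_h(\lVert \mathbf{m}-\mathbf{m}_j\rVert)\,
\varphi(t; y_j, \sigma^2)},$$

a convex combination of training CT values: every output is bounded by the
training range, and voxels outside the corrupted mask (and metal voxels)
are passed through bit-identically. The kernel is an isotropic Gaussian on
Euclidean patch distance — the canonical choice, and the one that makes the
$\sigma$ limits analytic: as $\sigma \to \infty$ the estimate converges to
the Nadaraya–Watson regression mean, as $\sigma \to 0$ to the
kernel-supported training value nearest $t$ in intensity. Both limits are
verified numerically in the test suite against independent oracle
implementations.

The sums are truncated to the $k = 64$ training patches nearest in patch
space. Weights are evaluated in log space with max-subtraction; the
documented fallback ladder (likelihood annihilates every weight → prior
only; prior also vanishes → return $t$ with a warning) triggers only for
degenerate hyperparameters, because the stabilized weights cannot underflow
otherwise.

### Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| patch half-sizes | (2, 2, 0) → 5×5×1 | voxels | MR context per voxel; z-half 0 respects thick MR slices |
| normalization | z-score over body | — | removes MR sequence scaling |
| `h` | fitted | patch units | kernel bandwidth |
| `sigma` | fitted | HU | artifact-noise scale |
| `k` | 64 | — | truncation of the regression sums |
| `subsample` | 8000 | — | training-set cap |
| `sigma_floor` | 20 | HU | lower bound on the fitted `sigma` |
| `metal_hu` | 3000 | HU | pass-through threshold for implants |

`h` is chosen by minimizing leave-one-out Nadaraya–Watson squared error
over a logarithmic grid. The grid spans from half the lower-quartile
nearest-neighbour patch distance up to the 95th percentile of pairwise
distances: bandwidths below the nearest-neighbour scale starve the LOO
regression, and the useful optimum typically sits between the two scales.

`sigma` is the Gaussian maximum-likelihood scale — the RMS — of
$t - \text{prior mean}$ over corrupted voxels, floored at `sigma_floor`.
A robust scale (MAD) was considered and rejected: the severe streaks are
not outliers to be resisted, they are exactly the noise the likelihood
must cover, and a MAD-based $\sigma$ collapses the likelihood onto the
corrupted observation at the worst voxels. The per-case weighting of
prior vs likelihood that this estimator provides is a design choice of
this package, not a claim about any other implementation.

The training subsample default (8000 pairs) is deliberately generous:
patch matching is not rotation invariant, so sparse subsampling
under-represents patch orientations around structures such as the MR
signal void, exactly where the prior is needed most.

## Reference physics: tissue thresholds and RSP

Tissue HU values are derived from bundled ICRU-46 elemental compositions
and a packaged table of NIST-style photon mass attenuation coefficients
(H, C, N, O, Na, Mg, P, S, Cl, K, Ca; 20–150 keV), via the mixture rule
$\sum_i w_i (\mu/\rho)_i(E)$ with **log–log interpolation** in energy —
the standard choice for photon cross sections, which are near power-laws
between grid points. At the 75.2 keV effective energy this computation
gives water 0 HU exactly (by the HU definition), cortical bone ≈ 1472 HU
and mandible ≈ 1075 HU, close to their rounded 1500 / 1000 HU operating
points. Adipose computes to ≈ −73 HU — far from the −200 HU operating
point — and enamel at its nominal 2.89 g/cm³ density computes to
≈ 3460 HU rather than 2600 HU; no straightforward monochromatic
ICRU-46+NIST derivation reproduces those two constants. The package
therefore ships the operating thresholds as fixed named constants
(`hu_threshold_defaults()`: −200/300, 1000/1500, 1500/2600, and the
empirical phantom bone window 1500/1800), decoupled from the derivation
path, which remains available for inspection.

The enamel-density helper implements one documented interpretation of a
constituent-averaging rule: the mass-fraction-weighted mean of bundled
elemental densities of hydroxyapatite, Ca10(PO4)6(OH)2 → ≈ 0.96 g/cm³.
With elemental gases at ambient density the rule cannot reach a solid
enamel density; it is reported as an estimate and never used as the
threshold default. Count-weighting was the rejected alternative
(≈ 0.60 g/cm³ — no better).

HU→RSP conversion is piecewise linear through configurable knots, clamped
outside the span, with the water knot (0 HU, RSP 1) required exactly.
The default 4-knot curve (−1000, 0.001), (0, 1), (1500, 1.85),
(3000, 2.4) is a plausible clinical shape and makes no claim of matching
any treatment planning system.

## The synthetic-data generator

The digital phantom emulates a shank-like body: an elliptical soft-tissue
cylinder (60 HU, muscle-like — deliberately offset from water so a 0 HU
override carries the systematic tissue-vs-water error), two cortical-bone
cylinders (1450 HU), an air cavity, and 1–6 metal pins (default 6000 HU,
2.5 mm radius) spanning only the central slices so that implant-free
slices exist in the same volume. Default grid 64×64×8 at 2 mm isotropic.

The acquisition model is 2-D slice-wise parallel-beam projection with 360
angles: HU are mapped to linear attenuation per spectrum energy
(default 50/75/100 keV, weights 0.3/0.5/0.2), detector intensities are
summed over the spectrum, Poisson noise is drawn at a configurable fluence
(default 1e5 photons/bin), near-zero bins are clamped at a floor (photon
starvation), and the log sinogram is ramp-filtered and back-projected.
Three modelling choices deserve emphasis:

* **Water precorrection.** Each ray is linearized against the
  polychromatic water curve before reconstruction, as clinical scanners
  do. Without it, beam hardening corrupts every bone voxel, leaving no
  uncorrupted bone to train on — unrealistic and fatal to any
  image-space MAR.
* **Metal attenuation boost.** Displayed metal CT numbers are clipped far
  below the physical attenuation of implant alloys; the model multiplies
  the above-3000-HU excess by `metal_boost` (default 16) so that the pins
  actually starve the detector and produce the bright/dark streak classes
  the phantom exists to produce.
* **Implant-free reference scan.** Each simulated case reconstructs the
  same phantom without pins through the same model with an independent
  noise seed — two physical acquisitions. Deterministic reconstruction
  structure (edge ringing, residual hardening) is common to both scans
  and cancels in their difference, so corruption metrics isolate the
  metal-induced change.

The corrupted-region input given to the restoration emulates the broad
visual delineation used in practice: the body support of every
metal-bearing slice. The metal mask used for processing grows the pins by
one in-plane voxel, because adjacent voxels partially contain metal under
center-based voxelization and their blooming values belong to the implant.

The T1w-like MR is piecewise-constant per tissue, with a signal void
extending 3 mm beyond the pins (MR is uninformative exactly where CT is
worst), a smooth multiplicative bias field (±8%), Rician noise
(σ = 0.04), and an optional rigid translation applied before sampling as
a misregistration probe.

What the generator does **not** emulate: fan/helical geometry, scatter,
detector response, anatomical texture, partial-volume tissue mixtures,
deformable MR–CT mismatch, or the appearance of any particular physical
phantom. Passing tests on this simulator therefore demonstrate the
algorithmic properties (restriction, boundedness, limit behavior, artifact
suppression under the modelled physics) — not clinical performance on real
scanners.

## The range engine

Dose is modelled as the analytic water percent-depth-dose composed with
radiological depth: $D(d) = \mathrm{PDD}_\text{water}(\mathrm{WET}(d))$,
with $\mathrm{WET}(d) = \int_0^d \mathrm{RSP}\,ds$ accumulated by
trapezoidal integration of trilinearly sampled HU at 0.5 mm steps. There
is no lateral scatter and no heterogeneity correction beyond radiological
depth — the endpoints are central-axis depths and ranges only. Water
curves: photon $e^{-\mu z} - e^{-\beta z}$ (S_max ≈ 15.8 mm), electron
build-up × distal sigmoid (R_90 ≈ 42 mm), proton entrance plateau +
Gaussian Bragg peak (R_80 ≈ 156 mm; the cohort rescales the peak to 70 mm
so it stops inside the small phantom). Curves are sampled on the dose-grid
resolution (1 mm electrons, 2 mm photons/protons), refined with a
**natural cubic spline** to 1e-3 mm, and the metrics are extracted as:
S_max = argmax (ties to the smallest depth); R_90/R_80 = the largest
crossing beyond the maximum, by linear root bracketing between refined
samples. The engine reproduces the analytic water metrics to within
0.01 mm and recovers imposed sub-resolution peak shifts of 0.1–1 mm to
within 0.1 mm (λ-shaped peak surrogate) — both enforced in the tests.

## Statistics

Conditions (algorithms) are dependent repeated measurements on independent
subjects (pins or phantoms). Contrasts compare unweighted means of
condition subsets; per subject
$d = \overline{f(\text{term}_1)} - \overline{f(\text{term}_2)}$ with $f$
the absolute value for corruption metrics, and
$t = \bar d \sqrt{N} / \mathrm{SD}(d)$ with the sample SD ($N-1$) and
Student's $t$ on $N-1$ df. Where no ground truth exists the per-subject
quantity is $\lvert \Delta \rvert$, strictly positive, tested one-tailed.
Orthogonality of a contrast family is checked via the Gram matrix of the
coefficient vectors, and orthogonal families are deliberately not
corrected for multiple comparisons. Zero-variance differences raise a
typed error rather than emitting $p = 0$. The default cohort uses the
two orthogonal contrasts mean(FBP, kerMAR) vs override and FBP vs kerMAR
over the three available conditions.

## Numerical choices

* Coordinates: 0-based voxel indices, voxel-center world coordinates,
  `world = origin + index * spacing`, mm everywhere. One convention,
  enforced by the container types, prevents half-voxel range errors.
* Resampling: trilinear for intensities, nearest for masks; out-of-support
  fills are physically neutral (−1000 HU CT, 0 MR, FALSE masks).
* Forward projection supersamples 2× in both detector and integration
  directions; the reconstruction kernel is the band-limited spatial-domain
  Ram–Lak (correct DC response) apodized with a Shepp–Logan window. With
  these choices a monochromatic, noiseless acquisition reconstructs the
  phantom interior to < 10 HU RMSE while retaining streak sharpness.
* Threshold counting uses strict inequalities; boundary voxels are
  in-range. Tail fractions are per-region (each region its own
  denominator).
* Determinism: every stochastic step (training subsampling, Poisson noise,
  MR noise/bias) is driven by an explicit seed; fixed seed + fixed inputs
  give bit-identical volumes.

## Problem sizes

The shipped defaults are sized for a desk: 64×64×8 phantoms, 360
projection angles, 8000 training pairs, 5-subject cohorts with 1–3 pins.
A full evaluation cohort — simulation, restoration, metrics, three beams
per subject, contrast tests — runs in about two minutes on one core, and
the complete test suite in under three.

## Known limitations

* oMAR (the commercial projection-replacement algorithm) is not
  implemented; comparisons are against the uncorrected image and bulk
  override only.
* The corrupted-region mask is an input; the streak heuristic
  (`suggest_corrupted_mask()`) is offered for exploration but never
  applied automatically.
* Spatially varying artifact noise is out of scope; `sigma` is constant
  within the corrupted region (the parameter object is the seam where a
  spatial model would attach).
* Voxels whose MR patch is entirely inside the metal signal void and whose
  CT value is severely corrupted are genuinely ambiguous under this model;
  restoration quality there depends on the likelihood alone.
* The dose model is central-axis only; no statement about full 3-D dose
  distributions is made or tested.
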