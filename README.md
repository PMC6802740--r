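# kermar

MR-guided Bayesian metal artifact reduction (MAR) for CT, with the full
evaluation apparatus needed to judge whether a MAR method helps
radiotherapy dose calculation: image-corruption metrics against
tissue-derived HU thresholds, a central-axis water-equivalent range engine
for photon/electron/proton beams, orthogonal-contrast paired statistics,
and a seeded digital phantom simulator that provides ground truth.

## Who this is for

Medical-physics and image-analysis researchers who need a transparent,
desk-scale testbed for CT metal artifact reduction: metal implants (dental
fillings, fixation pins) corrupt CT values with streak and cupping
artifacts, which propagate into the relative stopping power (RSP) and
water-equivalent thickness (WET) estimates behind particle-therapy dose
calculations, where range errors of a few millimetres matter.

## The algorithm

**kerMAR** treats the true CT value `y` at a corrupted voxel as a latent
variable. A prior `p(y | m)` is built by kernel regression on pairs of
uncorrupted CT values and cuboidal MRI patch vectors `m` from a
co-registered MR image; the observed corrupted value `t` enters through an
additive Gaussian artifact-noise likelihood. The restored value is the
posterior expectation

```
            sum_j K_h(||m - m_j||) * phi(t; y_j, sigma^2) * y_j
  y_hat  =  --------------------------------------------------- ,
            sum_j K_h(||m - m_j||) * phi(t; y_j, sigma^2)
```

with a Gaussian kernel `K_h`, restricted to the `k = 64` training patches
nearest to `m`. The bandwidth `h` is fitted by leave-one-out regression
error; the noise scale `sigma` is the RMS of the corrupted-region
residuals against the prior mean. Only voxels inside the supplied
corrupted-region mask are modified; metal voxels are passed through.

Baselines shipped alongside: the uncorrected FBP image and manual bulk
override (0 HU water, or e.g. 60 HU muscle-like).

Evaluation follows the implant-free-reference pattern: artifact burden is
`deltaN_low/high`, the change in the fraction of ROI voxels below/above
tissue HU thresholds relative to an uncorrupted reference; dosimetric
impact is the change in photon depth of maximum dose (`S_max`) and
electron/proton ranges (`R_90`/`R_80`) extracted from central-axis
depth-dose curves cubically refined to 1e-3 mm. Hypotheses are tested with
paired t-tests over orthogonal contrasts, uncorrected for multiplicity.

## Worked example

```r
library(kermar)

case <- simulate_case(default_phantom_spec(n_pins = 2, seed = 42))
restored <- run_kermar(case$corrupted, case$mr, case$masks$corrupted,
                       case$masks$body, case$masks$metal,
                       params = kermar_params(seed = 42))

roi <- mask_volume(case$masks$corrupted$data & case$masks$soft_tissue$data,
                   case$truth$spacing, role = "soft tissue ROI")
th <- tail_thresholds("phantom_soft_tissue", -200, 300)
delta_n(case$corrupted, roi, th = th, reference_volume = case$reference)
delta_n(restored,       roi, th = th, reference_volume = case$reference)
```

which prints

```
fitted h = 1.47, sigma = 374 HU, 5712 voxels restored
<delta_n 'phantom_soft_tissue'> dN_low = +0.0474, dN_high = +0.0570 (n_corr = 5068, n_ref = 5068)
<delta_n 'phantom_soft_tissue'> dN_low = -0.0032, dN_high = -0.0057 (n_corr = 5068, n_ref = 5068)
```

— before restoration, 5.7% more soft-tissue voxels sit above the 300 HU
threshold (and 4.7% more below −200 HU) than in the implant-free scan:
bright and dark streaks. After kerMAR both tails return to the reference
level. Tracing a 150 MeV proton beam through the corrupted region:

```r
water_over <- bulk_override(case$corrupted, case$masks$corrupted, value = 0)
geo <- cohort_beams()
range_comparison(list(reference = case$reference, FBP = case$corrupted,
                      override = water_over, kerMAR = restored),
                 geo$beams, models = geo$models, reference = "reference")
```

```
 algorithm  S_max    range   d_range
 reference 67.162 71.18702  0.000000
       FBP 62.849 66.68448 -4.502537
  override 69.137 73.30514  2.118117
    kerMAR 65.465 69.48734 -1.699682
```

The streaks shift the proton `R_80` by −4.5 mm on the uncorrected image;
kerMAR cuts the error to −1.7 mm, while the 0 HU water override leaves a
systematic +2.1 mm error because the surrounding soft tissue sits near
60 HU, not 0. `run_cohort()` repeats this over seeded phantom subjects and
tests the orthogonal contrasts.

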