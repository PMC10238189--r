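---
title: "Methods: digital MSP array analysis and its simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: digital MSP array analysis and its simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmspr)
```

`dmspr` implements the computational pipeline of a multiplex digital
methylation-specific PCR (dMSP) platform: nanowell-array image analysis,
mixture-model well calling, Poisson absolute quantification, the bulk
MethyLight comparator statistic, and clinical panel evaluation. This
vignette records the models, the tunable parameters, and the design and
numerical choices behind each stage, in the order data flows through them.

## Chip geometry and mask registration

The chip carries four independent, identical modules of 10,040 nanowells
(1 nL each), 40,160 wells in total. The physical grid arrangement within a
module is not fixed by the assay itself, so the package must choose one:
the default is a 40 x 251 row-major grid, chosen because it factorizes
10,040 exactly — no partial row, every grid slot is a well. `build_layout()`
accepts any `grid_rows x grid_cols >= wells_per_module`, with trailing
slots absent from the mask. The default 120 µm pitch and 90 µm diameter
are rendering conventions for the simulator; they set image scale only and
play no role in counting.

Mask placement uses the "known-mask" approach: the user supplies four
geometric inputs per module, interpreted here as the pixel coordinates of
the module's corner wells in TL, TR, BR, BL order. Four point
correspondences determine a projective homography uniquely (up to scale)
by the direct linear transform, and a full projective model — rather than
an affine one — is fitted because flatbed scans can carry keystone
distortion. Degenerate inputs (duplicate or collinear points) are
rejected. Pixel coordinates are 0-based, `x` = column, `y` = row, with
continuous values referring to pixel centres.

An alternative reading of "four geometric inputs" (origin, rotation,
pitch, ...) would constrain the map to a similarity transform; the corner
interpretation subsumes it and degrades gracefully to it when the image is
undistorted, which is why it was chosen.

## Intensity extraction

Per-well signal is the arithmetic mean of the pixels whose centres fall
within a circular aperture at the mapped well centre. The aperture radius
defaults to 0.35 x the well pitch in pixels (2.1 px at the simulator's 20
µm/px sampling): comfortably inside the 90 µm well even with ~1 px of
registration error, and large enough to average read noise. Pixels are
included by a centre-in-disk test without partial-pixel weighting, making
the table deterministic and exactly linear in the image. No background
subtraction is applied at this stage; a constant background simply shifts
the negative population, which the mixture model absorbs.

## Well calling: mixture fit and the five-sigma threshold

Each channel's per-well intensities are fitted with a two-component
location–scale mixture by EM. The platform literature names a "Poisson
mixture model" for this step without defining a likelihood on continuous
fluorescence; `dmspr` uses a two-component Gaussian mixture and notes that
tying the positive weight to Poisson loading, `w = 1 - exp(-lambda)` with
`lambda` free, is only a reparameterization of the free-weight fit — the
two coincide, and the implied loading is reported as `lambda_load` in
`glance()`. Neither variant is claimed to be the original software's
likelihood.

Numerical choices:

* **Initialization** is deterministic from data quantiles — negative
  component at the 10th percentile, positive at the 99.9th, both with the
  sample MAD as scale — so the same input always returns the same fit; no
  random restarts.
* **Convergence** is declared when successive log-likelihoods differ by
  less than `1e-8` (absolute), capped at 500 iterations; component SDs are
  floored at `1e-6`.
* **Large samples**: above `1e5` values the EM runs on a 4,096-bin
  histogram (weighted EM over bin centres). At that resolution the binning
  error is far below sampling noise, and fits to tens of millions of wells
  take seconds. Chip-scale channels (10,040 wells) use the exact path.
* **Component order**: components are sorted by mean after fitting, so the
  first is always the negative population regardless of which dominates.
* **Degenerate-population collapse**: when the fitted positive mean lies
  below the negative component's own five-sigma limit
  (`mu_pos - mu_neg < 5 sigma_neg`), the second component is structure
  inside a single population — typically the upper tail of an all-negative
  channel — not a digital signal. The fit then collapses: positive weight
  0, negative component set to the moments of the whole sample,
  `collapsed = TRUE`. Without this rule the second Gaussian latches onto
  the tail of a pure-negative sample, biasing `sigma_neg` low and the
  threshold with it. A channel whose genuine positives sat below five
  sigma would be uncallable in a digital assay anyway, so the rule costs
  nothing in the regime the platform operates in.

Calling is a strict comparison: a well is positive when its mean intensity
exceeds `mu_neg + 5 sigma_neg`; ties at the threshold are negative
(conservative false-positive control). Under a Gaussian negative
population the five-sigma allowance corresponds to ~2.9 x 10^-7 per well,
i.e. at most a handful of false positives per ten million wells; the test
suite verifies the empirical exceedance against the Gaussian tail at 10^7
simulated wells. Channels are fitted and called independently — the four
dyes are chosen for minimal spectral overlap, and cross-talk unmixing is
deliberately out of scope (the simulator can inject cross-talk to study
its effect, but the caller does not model it).

## Absolute quantification

With `k` positive of `N` wells, the Poisson occupancy estimator gives
`lambda_hat = -ln(1 - k/N)` mean molecules per well and
`lambda_hat x N` molecules in wells; dividing by the plasma-equivalent
volume (default 0.1 mL) and the retention fraction (default 0.5, the
fraction of prepared mix that ends up digitized) yields copies per mL of
plasma. Whether published "detected" counts carry the Poisson or retention
correction is not always stated, so `quantify_calls()` reports raw counts,
corrected copies and copies/mL as separate columns; the headline value is
the corrected, retention-adjusted one. Saturation (`k = N`) is an error,
not an estimate.

Standard-curve metrics follow the dilution-series conventions: OLS of
detected on expected over the nonzero ladder points on untransformed
counts (linear axes); LOD = smallest nominal input detected in at least
one replicate; LOQ = smallest detected in all replicates; analytical
specificity = LOQ / background copies x 100%. The 0-copy point is a
negative control — excluded from the regression and limit search, its
false-positive wells reported separately. Note the specificity numerator
is the LOQ by definition; with an LOQ of 1 copy against 200,000 background
molecules this gives 0.0005%.

## The simulator: what it emulates, and what it does not

`partition_molecules()` realizes `M ~ Poisson(n_copies)` molecules
(dilution of synthetic template is physically Poisson, and fractional
nominals like 6.25 are meaningful), retains each with probability
`retention_fraction` (default 0.5), and scatters the survivors uniformly
over the module's wells. `amplify_wells()` applies a per-molecule
Bernoulli amplification (default probability 1 — the digital format
detects essentially every template) and an optional per-well
false-amplification rate (default 0: methylation-specific primers do not
amplify the unmethylated background, which is therefore carried only as
metadata). For dilution series built from counted, exactly spiked
molecules, `exact_copies = TRUE` loads integer nominals deterministically;
this is the regime in which "every loaded molecule yields a positive well"
and the simulated LOQ of 1 copy are meaningful. Under Poisson loading a
1-copy reaction is empty with probability `exp(-1)`, so the two loading
models answer different experimental questions and both are exposed.

Rendering draws each well as a disk at its mapped centre with a single
per-well amplitude drawn from the positive or negative intensity
distribution, then applies, in order: Gaussian PSF blur, constant
background, per-pixel Gaussian read noise, linear channel cross-talk, and
16-bit rounding/clipping. The imaging defaults — 20 µm/px, background 500
ADU, negatives N(1000, 60), positives N(12000, 800), PSF sigma 1 px, read
noise 30 ADU, identity cross-talk — are invented but physically plausible
values that respect the platform's design premise of cleanly separated
populations (the config warns if separation drops below ten negative SDs).
They are not fitted to any instrument.

The simulator does *not* model fluid dynamics, thermal gradients, bulk
amplification kinetics, scanner optics beyond a Gaussian PSF, spatially
correlated noise, or "rain" (partial-amplification wells). Consequently,
green tests certify the analysis chain — geometry, extraction, calling,
quantification, statistics — under honest sampling noise; they do not
certify robustness to instrument artefacts real chips can show.

`simulate_cohort()` draws per-sample marker concentrations as
`Poisson(rate x V) / V` with `V = 0.1` mL. The default rates (cases 8.2,
6.76, 4.76, 6.76; controls 2, 2.5, 0.5, 2.5 copies/mL for *SOX17*,
*CDO1*, *TAC1*, *HOXA7*) were calibrated once, by root-finding on
large-sample simulations, so that the population AUC of the logistic
panel score is 0.86 — a realistic separation for a four-marker cfDNA
panel — and then frozen. Optional covariates (age ~ N(65, 8) years,
pack-years ~ N(40, 20) truncated at 0) are drawn independently of the
label, emulating risk factors that add no signal beyond the markers. Real
cohorts are overdispersed relative to Poisson and their markers are
correlated through tumour burden; the plain-Poisson generator is a
deliberate simplification that keeps the population AUC analytically
controllable.

## Clinical statistics

Univariate thresholds maximize Youden's J = TPR − FPR over midpoints
between adjacent distinct values (plus ±Inf), ties broken toward the
higher threshold. The platform literature phrases the objective as
maximizing "the difference between the true positive rate and false
negative rate", which is internally inconsistent (TPR − FNR = 2·TPR − 1 is
maximized by calling everything positive); TPR − FPR is the standard
statistic that matches the described sensitivity/specificity trade-off and
is what `dmspr` implements. Printed percentages use
round-half-away-from-zero to integer percent.

Panel evaluation fits logistic regression by IRLS with a `1e-6` ridge
jitter on the Hessian. The jitter exists for leave-one-out
cross-validation: held-out folds of small, well-separated cohorts are
often perfectly separable, where the unpenalized Hessian is singular;
with the jitter the fit proceeds and the held-out probability saturates
harmlessly. Linear predictors are clamped at ±30 before the logistic
transform to avoid overflow, constant features are dropped with a warning,
and non-convergence after 200 iterations yields the last iterate with a
warning. On non-separable data the ridge perturbs coefficients at the
1e-10 level; the test suite checks agreement with `stats::glm` to 1e-6.

The ROC sweeps the distinct held-out probabilities as thresholds
(`prob >= t`), collapsing ties into single vertices; trapezoidal
integration then equals the Mann–Whitney statistic with ties counted one
half, which the suite verifies against a rank-based oracle and `pROC`.
Bootstrap confidence intervals resample cases and controls within class —
stratification is a package choice (it guarantees both classes in every
resample) — and report the percentile interval. The panel operating point
is the Youden-optimal threshold on the LOOCV probabilities.
`panel_search()` evaluates all nonempty subsets (up to 8 markers) and
ranks by LOOCV AUC, ties toward the smaller panel.

## Problem sizes used by the test and acceptance suites

The suites simulate at the platform's native scale where the claim depends
on it, and at reduced scale where it does not: the standard-curve check
runs the full 7-point duplicate ladder at 10,040 wells/channel through
rendering, extraction, calling and quantification; the five-sigma
false-positive check uses 10^7 simulated negative wells; the LOQ series
loads 1–10 copies exactly with 10 replicates; occupancy and threshold
oracles use 10^4 replicates / 200–500 random cohorts; the cohort-recovery
check averages LOOCV AUC over 200 synthetic cohorts of 39 + 33. Because
molecule counts are Poisson, the detected-vs-expected R² of a single
simulated ladder fluctuates (roughly 0.98–0.997 per channel); this is the
assay's intrinsic sampling floor, not an analysis error — calling in these
runs reproduces the true amplified-well counts exactly.

## Known limitations

* The caller assumes exactly two populations per channel; "rain" wells
  between the populations would be assigned by likelihood, not modelled.
* No flat-field or spatial-autocorrelation correction; the mask is a
  single homography per module, so lens distortion beyond keystone is
  unmodelled.
* The Poisson cohort generator understates between-patient dispersion;
  recovery results on it should be read as a consistency check of the
  statistical machinery, not as a clinical-performance claim.
* Reference-gene (LINE-1) quantification for the MethyLight statistic is
  consumed as a precomputed mean Ct; raw qPCR curve processing is out of
  scope.
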