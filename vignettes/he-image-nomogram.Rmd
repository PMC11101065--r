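---
title: "Colour and entropy statistics as a benign/malignant classifier for H&E breast pathology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colour and entropy statistics as a benign/malignant classifier for H&E breast pathology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathnomo)
```

## The problem and the model

Digitised hematoxylin–eosin (H&E) slides of breast tissue differ between
benign lesions (adenosis, fibroadenoma) and infiltrating ductal carcinoma in
ways that are visible even in crude whole-image statistics: malignant tissue
is more cellular and more heterogeneous, so its images are darker in the red
and blue channels and their gray-level histograms are more dispersed.
`pathnomo` operationalises this observation as a three-variable logistic
model. Each image contributes four candidate features:

* `avg_r`, `avg_g`, `avg_b` — the arithmetic mean of each 8-bit colour
  channel over all \(N\) pixels, \(\mathrm{avg}_C = \sum_i C_i / N\), in
  intensity units 0–255;
* `entropy` — the Shannon entropy of the 256-bin gray-level histogram,
  \(H = -\sum_i P_i \log_2 P_i\) (bits), where \(P_i\) is the proportion of
  pixels at gray level \(i\) and \(0\log 0 \equiv 0\). \(H\) ranges from 0
  (constant image) to 8 (all levels equally used).

The classifier is an ordinary maximum-likelihood logistic regression with
malignant coded 1, fitted by IRLS with standard errors from the inverse
observed Fisher information. Under the bundled reference cohort (2,214
malignant / 509 benign images) the informative subset is `avg_r`, `avg_b`
and `entropy`; the green channel, strongly collinear with red and blue, is
removed by the selection path below. The model is presented as a points-scale
nomogram: each feature maps linearly to 0–100 points and the total maps back
to a probability through the linear predictor, so nomogram scoring and direct
logistic scoring are algebraically identical (this equivalence is asserted to
1e-9 in the test suite).

## Feature-extraction conventions

Grayscale conversion is ITU-R BT.601 luma, \(\mathrm{round}(0.299R + 0.587G +
0.114B)\), with half-values rounded away from zero. No convention is imposed
by the underlying science; BT.601 is the dominant library default, and any
fixed weighting that sums to one leaves the entropy of a channel-shifted
image unchanged. The entropy histogram uses exactly the 256 integer levels —
no re-binning — and logarithms are base 2, so the statistic is in bits. The
widely reproduced one-line formula for image entropy sometimes omits the
leading \(P_i\) factor; we implement the standard Shannon form, which is what
"average information per pixel" means and what every reference
implementation computes.

Inputs are 8-bit RGB PNG or TIFF; grayscale files are promoted to three equal
channels, alpha is dropped, and anything that does not decode to 8-bit
integers is rejected with a format diagnostic rather than silently rescaled.

## Univariate statistics and the split

Group comparisons use the two-sample pooled-variance (Student) t-test,
computable either from raw rows or from printed summary cells
\((n, \bar x, s)\) alone; the two paths agree to machine precision, and the
summary path reproduces the reference cohort's printed t statistics to well
under 0.5% (the residual is rounding of the printed inputs). Pooled rather
than Welch is the default because it is what reproduces those printed values;
the Welch variant is available via `var_equal = FALSE`. The sign convention
(which group is subtracted) is an explicit argument because published tables
are inconsistent about it.

The train/validation split is simple random, non-stratified, with
\(|\mathrm{validation}| = \lfloor 0.3N \rfloor\) — the only floor/ceiling
rule consistent with a 2,723-image cohort splitting into 1,907 and 816. The
seed is a required, recorded input.

## Variable selection

The reference analysis reports four univariately significant features but a
three-variable final model, without stating the path between them. We
operationalise it as: univariate logistic screen at \(\alpha = 0.05\),
then backward elimination of the largest multivariable Wald p-value
\(\ge \alpha\) until all survivors clear \(\alpha\). The full elimination
trace is stored in the fitted object so the path is auditable. On simulated
cohorts with identity feature correlations all four features usually survive
(each is genuinely informative and independence removes the collinearity that
suppresses the green channel in real data); that discrepancy is expected and
documented rather than corrected, since class-conditional correlations are
not identifiable from published marginals.

## The synthetic cohort

The generator has two layers.

**Feature tables.** Each class draws feature vectors from a multivariate
Gaussian with the reference cohort's printed means and SDs (malignant:
R 219.969 ± 5.137, G 202.024 ± 13.060, B 220.340 ± 8.827, H 5.425 ± 0.573;
benign: R 226.308 ± 6.265, G 219.060 ± 17.180, B 228.996 ± 7.237,
H 4.146 ± 0.984) at the reference class sizes 2,214/509. Correlation matrices
default to identity because only marginals are published; users can supply
any PSD correlation. Channel features are clipped to [0, 255] and entropy to
[0, 8] after the draw — simpler than truncated sampling, and the clip rate at
the defaults is negligible (every boundary is ≥ 4 SDs from its mean).
Consequences of independence: the Gaussian linear-score closed form
\(\Phi\!\left(\Delta\mu_s / \sqrt{\sigma^2_{s,1} + \sigma^2_{s,2}}\right)\)
predicts AUC ≈ 0.778 for the fixed reference coefficients, and a freshly
fitted model on synthetic data reaches AUC ≈ 0.95–0.97 — deliberately *not*
the reference cohort's observed 0.889, which encodes unknown correlations.
A second structural consequence: because the two classes have unequal
covariances, the true posterior log-odds under this generative model are
quadratic in the features, so the linear-logistic fit is mildly but genuinely
miscalibrated and the Hosmer–Lemeshow test will often reject it at cohort
scale — evidence of the test's power, not of a defect. Passing tests
therefore demonstrate correctness of the machinery, not real-data
performance.

**Rendered images.** To exercise the image-reading path, each feature row can
be realised as actual pixels. A latent gray level per pixel is drawn i.i.d.
from a one-parameter exponential family over \(\{0,\dots,W-1\}\)
(probabilities \(\propto e^{-\lambda g}\), \(\lambda \ge 0\)); entropy is
continuous and monotone decreasing in \(\lambda\), so the \(\lambda\)
matching a target entropy is found by bisection. Each channel is the latent
level plus a rounded constant offset hitting the target mean. Because the
luma weights sum to one, the gray image is the latent field plus a constant,
so extracted entropy equals the latent entropy exactly when nothing clips.
The decay is oriented toward the bright end when the target means exceed
mid-range (the mirrored distribution is the same family with identical
entropy); with the default window \(W = 64\) this keeps offsets clip-free for
the 200–230 channel means typical of H&E tissue, which is also why full
0–255 latent support is not the default. Contract: channel means within
±1.0 intensity units and luma entropy within ±0.1 bits of target whenever
the per-image clipping flag (more than 1% of pixels clipped) is clear; the
flag is recorded per image in the generated manifest. Entropy draws exceeding
\(\log_2 W\) cannot be encoded in the window, so render targets are clamped
to \(\log_2 W - 10^{-3}\) and the manifest records the achieved target. The
renderer makes no attempt at nuclear or stromal morphology, stain variation,
or spatial structure of any kind — features here are histogram statistics,
which are blind to pixel arrangement.

## Evaluation stack

* **AUC** is computed in the tie-aware Mann–Whitney form from mid-ranks; the
  threshold-swept ROC curve's trapezoidal area is cross-checked against it in
  exact integer arithmetic (both must agree to 1e-12) on every call.
* **Bootstrap CI**: case-resampling percentile interval, default
  \(B = 1000\), seeded; replicates that lose a class are redrawn with a
  \(100B\) attempt cap. A normal-approximation interval is available but the
  percentile form is the default, matching common practice when the interval
  type is unstated.
* **Hosmer–Lemeshow**: deciles of risk (\(g = 10\) by default, exposed as an
  argument), tied probabilities kept in one group via quantile breaks, zero
  expected cells merged into a neighbour with a warning,
  \(\chi^2\) referred to \(g - 2\) degrees of freedom.
* **Calibration curve**: equal-frequency bins, one (mean predicted, observed
  fraction) point per bin.
* **Decision-curve analysis**: net benefit
  \(\mathrm{NB}(p_t) = \mathrm{TP}/N - (\mathrm{FP}/N)\,p_t/(1-p_t)\) on a
  0.01-step grid over (0, 1), against treat-all and treat-none, with an
  optional case-resampling percentile band. Two identities anchor the tests:
  a perfect predictor's net benefit equals the prevalence at every threshold,
  and the treat-all curve crosses zero exactly at the prevalence.

## Numerical and degenerate-input choices

IRLS convergence is a relative deviance change below 1e-10 or 100 iterations;
perfect separation is reported as an error (diverging SEs), not returned as a
fit. Both SDs zero with equal means defines \(t = 0\); unequal means is an
error (infinite statistic). The CI multiplier is 1.959964, matching standard
software output rather than the rounded 1.96. Zero-width nomogram ranges
produce a flat zero-point axis with a warning. The pipeline derives per-stage
seeds from the run seed by fixed offsets, so any stage can be reproduced in
isolation.

## Problem sizes in the tests

The test suite verifies sampling-error bounds at 10,000–50,000 rows per
class, the closed-form AUC agreement at 100,000 per class (tolerance ±0.005,
about four times the Monte-Carlo SE), coefficient recovery at 50,000 per
class averaged over five replicates against the single-fit 2-SE band, and
bootstrap behaviour at \(B = 200\)–1000. Rendered-image checks use 16–512 px
squares. These sizes make every Monte-Carlo tolerance a multiple of its
sampling SE while keeping the default suite in the tens of seconds.

## Limitations

Whole-image colour means and histogram entropy ignore spatial structure
entirely, so the model cannot localise lesions or handle mixed slides; the
synthetic cohort inherits the independence caveat above; within-patient
correlation between images is ignored (images are treated as exchangeable,
as in the reference analysis); and JPEG sources must be converted to PNG or
TIFF before extraction.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(seed = 7, bootstrap_B = 1000)
rep <- run_pipeline(cfg)
rep
plot(rep$nomogram)
plot(rep$evaluation$validation, "roc")
```
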