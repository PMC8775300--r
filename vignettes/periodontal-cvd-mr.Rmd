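---
title: "Methods: two-sample Mendelian randomization in perioMR"
author: "perioMR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in perioMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

perioMR implements a summary-statistic Mendelian randomization (MR) screen
of one exposure — genetic liability to periodontal disease (dental caries
and periodontitis) — against a grid of cardiovascular outcomes. This
vignette is the package's own account of the statistical machinery: the
models, the assumptions they lean on, every tunable that matters, and the
places where a design choice had to be made.

## The causal model and its assumptions

For variant $j$, let $\gamma_j$ be its true effect on the exposure and
$\Gamma_j$ its true effect on the outcome. If the variant is a valid
instrument — associated with the exposure, free of confounding with the
outcome, and affecting the outcome only through the exposure — then
$\Gamma_j = \theta\,\gamma_j$, and the per-variant Wald ratio
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ estimates the causal effect
$\theta$. Estimated effects enter with their GWAS standard errors;
throughout we use the first-order standard error
$\mathrm{se}(\hat\theta_j) = \mathrm{se}(\hat\Gamma_j)/|\hat\gamma_j|$,
which ignores exposure-side sampling error (the NOME approximation). This
is accurate when instrument F-statistics are large and buys an exact
algebraic identity used by the test suite: IVW ratio pooling coincides with
weighted regression of $\hat\Gamma$ on $\hat\gamma$ through the origin with
weights $1/\mathrm{se}(\hat\Gamma_j)^2$.

Three pooled estimators, each robust to a different failure mode:

* **IVW** (`mrIVW`): $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$ with
  $w_j = 1/\mathrm{se}(\hat\theta_j)^2$. Efficient when every instrument is
  valid; biased by any net (directional) pleiotropy.
* **MR-Egger** (`mrEgger`): weighted least squares
  $\hat\Gamma_j = \alpha + \theta\,\hat\gamma_j + \varepsilon_j$ with a free
  intercept. Under InSIDE (instrument strength independent of direct
  effects), the slope remains a consistent estimate of $\theta$ even when
  *all* instruments are pleiotropic, and the intercept $\alpha$ estimates
  the average directional pleiotropy; testing $\alpha \ne 0$ is the Egger
  pleiotropy test. We follow this standard decomposition — intercept for
  pleiotropy, slope for the causal effect — throughout.
* **Weighted median** (`mrWeightedMedian`): the weighted 50th percentile of
  the ordered ratios, consistent while valid instruments carry at least
  half the total weight; a 50% breakdown point against invalid instruments.

`cochranQ` supplies the heterogeneity diagnostic
$Q = \sum_j w_j (\hat\theta_j - \theta)^2$, minimized at the IVW estimate.

## Estimator numerics, choice by choice

**IVW dispersion model.** The default is multiplicative random effects: the
fixed-effect standard error $(\sum w_j)^{-1/2}$ is inflated by
$\max\!\big(1, \sqrt{Q/(J-1)}\big)$. The floor at 1 means over-dispersed
instrument sets widen the interval while chance under-dispersion is never
rewarded; a `mode = "fixed"` flag removes the inflation. With a single
instrument IVW degenerates exactly to that instrument's Wald ratio.

**Egger orientation and scaling.** Pairs are first oriented so every
exposure effect is non-negative (both effects of a pair are negated
together — the Wald ratio is unchanged, and all three estimators are
invariant to this reorientation, a property the suite asserts exactly).
Coefficient standard errors are the unit-dispersion weighted-regression
errors scaled by $\max(1, \hat\sigma)$, where $\hat\sigma$ is the residual
standard deviation — the same "no under-dispersion credit" convention as
the IVW floor. Inference is t-based on $J-2$ degrees of freedom, the usual
small-J convention for Egger regression; IVW and the weighted median use
normal inference and the 1.96 quantile for 95% intervals. A set with fewer
than 3 instruments, or with no spread in the oriented exposure effects
(singular design), is refused with a clear error.

**Weighted-median interpolation and bootstrap.** Ratios are sorted and the
standardized cumulative weights $p_j = (S_j - w_j/2)/S_{\mathrm{total}}$
computed; the estimate linearly interpolates the ratio at $p = 0.5$, with
the boundary ratios returned when the crossing falls outside $[p_1, p_J]$.
The standard error is a parametric bootstrap (default `n_boot = 1000`):
both effect vectors are resampled from normals centred on the observed
effects with their stated standard errors, and the SD of the recomputed
medians is taken. The seed is a mandatory argument — a stochastic standard
error without a recorded seed is not reproducible. Internally the pairs are
put in canonical order (sorted by variant id, exposure effects oriented
non-negative) before any random draw, so the bootstrap — not just the point
estimate — is byte-identical under permutation or reorientation of the
input.

**P-value floor.** Two-sided normal/t tails are floored at the smallest
positive double, keeping every reported p-value inside $(0, 1]$ even for
extreme z-scores.

## Instrument handling and harmonization

Selection keeps associations with $p$ strictly below the genome-wide
threshold $5\times10^{-8}$; applied to the bundled 47-variant periodontal
fixture it keeps all 47. The outcome-side exclusion rule drops instruments
that are absent from the outcome table or themselves significant in it —
variants associated with a cardiovascular outcome at genome-wide
significance are suspect of horizontal pleiotropy. The threshold defining
"significant in the outcome GWAS" is not fixed by the study design, so it
defaults to the same $5\times10^{-8}$ and is exposed as `p_outcome` in
`mrConfig()`. Instrument independence (LD clumping) is assumed done by the
source GWAS — the fixture variants are published as independent — and no
LD-panel machinery is included.

Harmonization expresses both effects on the exposure's effect allele. The
decision table, in order: identical allele (pair) — keep; the stated other
allele (or its strand complement) — negate the outcome effect and
complement its frequency; incompatible pairs — drop as `allele_mismatch`.
Palindromic variants (A/T, C/G) carry no strand information in their
labels; under the default `"freq"` policy they are aligned by frequency
concordance when both effect-allele frequencies are available and both
minor-allele frequencies are below 0.42, and dropped otherwise ("drop"
drops them unconditionally). The 0.42 bound is the conventional
conservative cut for "frequency far enough from 0.5 to identify the
strand", and is a policy knob. The bundled instruments publish only their
effect allele, so the harmonizer also runs in effect-allele-only mode: a
differing, non-complementary outcome allele can only be the opposite
allele (flip); a strand-complementary allele is either the same allele read
from the other strand or the opposite allele of a palindromic variant, so
it is resolved by frequency when unambiguous and otherwise dropped as
`ambiguous`. Indel codes (`"d"`/`"i"`) are compared literally and never
complemented — strand complement is undefined for them. Every decision is
logged (`kept`/`flipped`/`dropped` + reason), and harmonization never
touches standard errors or the exposure side.

## The study grid

`runMR()` chains selection, exclusion, harmonization and the three
estimators for each outcome, with the Bonferroni threshold $\alpha/m$
computed from the number of outcome tables actually supplied ($m = 8$
reproduces the motivating design's 0.05/8 = 0.00625, conventionally printed
as 0.006); significance is strict inequality. An outcome with fewer than
three harmonized pairs still reports IVW when at least one pair survives,
with MR-Egger and the weighted median marked unavailable and the reason
recorded; the per-outcome instrument accounting always reconciles exactly
with the audit logs. Results flatten to a forest table (one row per
outcome-method), written in a round-trip-stable tab-separated form.

The per-outcome instrument counts of the motivating study (44 for coronary
artery disease and heart failure, 36 for atrial fibrillation, and so on)
depend on the outcome consortia's full summary tables, which are not
redistributable; they are therefore not reproduced or asserted anywhere in
the package.

## What the simulator emulates — and what it does not

`simulateTwoSample()` generates the *structure* of a two-sample MR dataset:
per-variant minor-allele frequencies uniform on `maf_range`, true
instrument effects, observed effects with the standardized-trait GWAS error
model $\mathrm{se} = (2p(1-p)n)^{-1/2}$, and outcome effects
$\hat\Gamma_j \sim N(\theta\gamma_j + \alpha_j,\ \mathrm{se}_y^2)$ with
pleiotropic effects $\alpha_j$ on a configurable invalid fraction (exactly
`round(prop_invalid * n_snps)` variants). Defaults mirror the motivating
study: 47 instruments, exposure GWAS of 487,823, outcome consortium of
500,000 (the motivating consortia range from ~184,000 to ~977,000), and
`gamma_sd = 0.02`, matching the effect-size scale of the bundled
instruments (typical instrument F around 70 at the exposure sample size).
Raw effects are drawn mean-zero and every variant is then reported on its
exposure-increasing allele — the orientation on which "directional"
pleiotropy is meaningful — so emitted effect magnitudes are half-normal.
An optional `inside_violation` term adds a component of $\alpha_j$
proportional to $\gamma_j$, breaking InSIDE on demand.

Deliberately *not* modeled: LD between instruments (the study design
assumes pre-clumped variants), winner's-curse selection on the exposure
side, sample overlap between the two GWAS, binary-trait liability scaling,
and population stratification. Passing recovery tests therefore show the
estimators are correct *under the stated generating model*; they do not
certify behavior under weak-instrument selection bias or overlapping
samples, which real analyses must consider separately.

Reproducibility is structural: generation is a pure function of the
configuration (including its seed), and `replicateStudy()` derives
replicate `i`'s data seed as `seed + i` and its bootstrap seed as
`seed + n_reps + i`, so any single replicate can be regenerated in
isolation. The caller's RNG stream is always left untouched.

## The simulation experiments and their design

The simulation battery runs four 200-replicate studies (about two minutes in
total; 200 replicates resolve means to Monte-Carlo standard errors a factor
~14 below the per-replicate spread, and give exact-binomial 99% bands of
roughly 0.905–0.985 around a nominal 0.95 coverage):

* **Recovery** — $J = 50$, both GWAS at $n = 10^5$, $\theta = 0.2$, no
  pleiotropy, `gamma_sd = 0.15`. The instrument-strength choice is a power
  analysis, not a tuning: NOME-induced regression dilution shrinks the IVW
  mean by the factor $1/(1 + \mathrm{se}_x^2/\mathrm{E}[\gamma^2])$, and at
  `gamma_sd = 0.15` (mean F ≈ 900, the strong-instrument regime these
  estimators are designed for and the regime of the methodological
  literature's simulations) this bias is an order of magnitude below the
  3-Monte-Carlo-SE resolution of 200 replicates, whereas at Table-1 scale
  with $n = 10^5$ it would not be. Each method's mean estimate must land
  within 3 Monte-Carlo SEs of 0.2 with coverage inside the binomial band.
* **Null calibration** — same design with $\theta = 0$: each method's
  rejection rate at $\alpha = 0.05$ must stay inside the exact binomial
  99% interval.
* **Directional pleiotropy, InSIDE holding** — every instrument receives
  $\alpha_j \sim N(0.02, 0.005^2)$. Here the true effects are a fixed grid
  `seq(0.05, 0.25, length.out = 50)` at fixed MAF 0.3: effects bounded away
  from zero keep sampling noise from flipping the exposure-increasing
  orientation (which would contaminate the directional signal), and a fixed
  MAF makes the weights exchangeable so the IVW bias has the clean
  closed form $\mu_\alpha \sum\gamma_j / \sum\gamma_j^2$ — the "mean
  pleiotropy over mean instrument strength" prediction the test checks to
  10%. The Egger intercept must recover 0.02 and the Egger slope must stay
  on 0.2, both within 3 Monte-Carlo SEs.
* **Contamination** — 30% invalid instruments with strong directional
  pleiotropy ($\mu_\alpha = 0.1$): the weighted median's median absolute
  error must be under half of IVW's, the generous-margin form of the
  robustness ordering.

## Known limitations

The outcome-side consortium data of the motivating study are not
redistributable, so the package cannot reproduce its per-outcome estimates
(for example the heart-failure IVW p of 0.015, non-significant under the
0.006 threshold); those require the original summary tables as inputs.
No mode-based estimators, MR-PRESSO outlier removal, multivariable MR,
Steiger filtering, proxy-variant lookup or F-statistic screening are
included; the first-order Wald standard error understates uncertainty for
genuinely weak instruments; and the simulator's standardized-trait error
model is a simplification of case-control GWAS noise.
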