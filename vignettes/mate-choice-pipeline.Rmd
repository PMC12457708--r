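---
title: "Estimating mate-choice variance components across contexts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mate-choice variance components across contexts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

`matevar` analyzes isofemale-strain mate-choice experiments of the kind run
with *Drosophila melanogaster* panels: males from a set of strains are
offered to virgin (`V+`) and previously mated (`V-`) females, either as
single pairs whose latency to mate is recorded (`C-`, no male-male
competition) or as groups of four color-marked males competing for one
female (`C+`). Among-strain variance in male mating success indexes how
strongly female "choice" discriminates among male genotypes in a context,
and the correlation of strain-level effects between contexts measures
whether virgin and non-virgin females (or competitive and noncompetitive
arenas) favor the same male genotypes. The companion assays — competitive
fitness against a brown-eyed standard, egg-to-adult viability, and wing /
sex-comb morphometrics — ask whether those choices carry genetic benefits
and which male traits predict success.

## The model

All four contexts are reduced to binary success records and modeled
jointly with a hierarchical Bernoulli-logit model:

* noncompetitive rows: `logit(p) = mu_k + a[m, k] + b[f, k]`
* competitive rows: `logit(p) = mu_k + gamma_color + a[m, k]`

where `k` indexes the context, `m` the male strain and `f` the female
strain. Each strain's effect vector `a[m, ]` is four-variate normal with
per-context standard deviations `sigma_k` and correlation matrix `R` —
the joint distribution that *defines* the cross-context genetic
correlations the analysis is after. Female-strain effects are independent
per noncompetitive context (they absorb responsiveness differences, which
are not the target of inference); no male-by-female interaction and no
block term are included, matching the preliminary finding that those
components are negligible when success rates are equalized across blocks.

Priors are half-Student-t(3, 0, 2.5) on every standard deviation,
LKJ(shape 1) — i.e. uniform over valid correlation matrices — on `R`,
Student-t(3, 0, 2.5) on intercepts, and improper flat priors on the color
contrasts. These mirror the weakly informative defaults of mainstream
Bayesian regression software so that "default prior" analyses are
reproduced faithfully.

### Why the model is fit once per resample

Males within a competition vial are not independent: one vial yields one
winner and three losers. To make the vial the unit of replication, one
male per vial is sampled uniformly and scored successful iff his strain
won, so every retained row succeeds with probability 1/4 and rows are
independent across vials. The model is refit once per resample set
(default 100) and the retained draws are concatenated. Pooling is
equivalent to running proportionally more iterations while averaging over
the sampling of males; it leaves the noncompetitive information untouched.

Noncompetitive trials have much higher raw success (most virgin females
mate within the two-hour censor), so their latencies are re-binarized at
the 25th percentile of each block-by-status group to match the
competitive scale: a trial is a success iff it mated and its latency is at
or below the group quantile, censored trials counting as slower than any
observed latency. A group whose raw mated fraction is already below the
target keeps its raw flags — with the default design this reproduces the
behavior of a low-success non-virgin group in a single block. Two
quantile conventions were genuinely open: the percentile is computed over
*all* trials of the group (mated plus censored) with linear interpolation,
and ties at the threshold all count as successes. Both choices are
deterministic and monotone; computing the quantile over mated trials only
would make the threshold depend on the censoring rate, which is exactly
the responsiveness difference the binarization is meant to remove.

### Sampling

The posterior is sampled with a Polya-Gamma-augmented Gibbs sampler
written in C++: conditional on a latent PG(1, eta) variable per row, every
Gaussian-prior coefficient block (intercepts, color contrasts, male- and
female-strain effects) has a conjugate normal update; the Student-t
intercept priors enter through their normal/inverse-gamma scale-mixture
representation; and `(sigma, R)` given the strain effects is updated by
per-coordinate adaptive random-walk Metropolis on the unconstrained scale
(log SDs; correlation matrix through tanh of canonical partial
correlations, whose LKJ(1)-inducing Beta exponents were verified by Monte
Carlo). Because that conditional only involves the strain-effect matrix,
five Metropolis sweeps are run per Gibbs scan at negligible cost, which
removes the slow mixing that a single joint update would give. The exact
PG(1, z) draw uses the alternating-series rejection method; its
closed-form mean is unit-tested. All randomness flows through R's RNG, so
a seed fixes every draw bit for bit.

The default run length is 4 chains of 20,000 iterations, first half
discarded, thinning 10 — 4,000 retained draws. Convergence is gated on
split-chain R-hat: summaries refuse to print above 1.05 unless overridden.

### Summaries

Posterior SDs are right-skewed, so point summaries are kernel-density
modes with 95% highest-density credible intervals (shortest contiguous
window containing 95% of sorted draws). SD draws are reflected at zero
before density estimation to avoid boundary bias, and the mode is only
sought where draws actually lie, since below the smallest draw the
reflected estimate is pure kernel leakage. On multimodal posteriors the
shortest contiguous window is a deliberate simplification (a unimodal
HDI). Correlations are declared distinguishable from zero iff zero lies
strictly outside the interval.

A maximum-likelihood confirmation path is provided alongside:
per-context logistic mixed models (Laplace approximation, i.e. adaptive
Gaussian quadrature with one node — two crossed random effects preclude
more nodes), one-degree-of-freedom likelihood-ratio tests of variances
clamped at the boundary (an estimate at zero prints statistic 0, p 1),
and delete-one-strain jackknifing of cross-context strain-mean
covariances. The boundary clamp rather than a 50:50 mixture correction is
the reporting convention of record; the mixture alternative matters only
for p-values of small positive statistics and is deliberately not the
default.

## Fitness and viability

Competitive fitness is the log-ratio `w = ln((wt + 1)/(be + 1))` of
wild-type to brown-eyed offspring counts; egg-to-adult viability uses the
same form with adults and failed eggs. Viability vials with no eggs are
uninformative and removed first; vials with eggs but no adults (plausibly
never-mated females laying unfertilized eggs) are removed second, with
both counts reported. Scores are decomposed by a Gaussian linear mixed
model with male-strain, female-strain and interaction random effects and
block and cross (within- versus between-strain) fixed effects under
sum-to-zero contrasts; REML variances, ML-refit likelihood-ratio tests,
type-II Wald chi-square tests and equal-weight estimated marginal means
are reported in a variance/marginal-means table. After a first fit,
residuals more than twice the residual interquartile range from zero are
dropped once and the model refit; "from zero" anchors the band at zero
rather than the residual median, the reading that makes the rule symmetric
for a mean-zero residual distribution.

## Morphometrics

Nine-landmark wing configurations are superimposed by iterative full
generalized Procrustes analysis: center, scale to unit centroid size,
rotate to the current mean, update the re-normalized mean, repeat to
convergence (first wing seeds the reference, making output orientation
reproducible). After convergence the aligned coordinates are projected
onto the tangent space at the mean shape; translation and the rotation
direction are already removed exactly, and the projection removes the
residual radial direction of the unit-size constraint, so exactly
2k - 4 = 14 principal components carry variance. PC signs are fixed
(PC1's loading on landmark 2's x-coordinate is non-negative; later PCs by
largest-magnitude loading) so reruns give identical scores. The 14 PCs
plus centroid size feed a pooled-covariance Mahalanobis outlier screen at
the chi-square 0.999 quantile on 15 df (37.70). Wing length is the
landmark 3-to-9 distance in original digitized coordinates times the
per-image scale, and strain means of success are regressed on strain means
of wing length, PC1 and sex-comb tooth count by OLS, each predictor
reported with its marginal F on (1, n - 4) df.

## The synthetic-data generator

Every stage is testable without data because the package generates whole
studies with known truth. Latencies are log-normal races: log latency is a
per-status baseline minus male-strain, female-strain (and, in competition,
color) effects plus Gaussian noise, censored at 120 minutes; the
competitive winner is the fastest of the four males iff he beats the
censor. A log-normal race was chosen because the emulated design never
pins down a latency distribution, and this one has positive support, censors
naturally, and makes the competitive winner emerge as a minimum — with the
same strain effect driving single-pair latency and competitive win
propensity, which is what a cross-context correlation presupposes.
Unmated competition vials are retained but flagged; the preparation stage
excludes them since a vial without an identified winner carries no
outcome.

Defaults describe the emulated design: 5 blocks by 4 strains, 19/15
noncompetitive trials per cell (1,520 virgin and 1,200 non-virgin trials),
21/32 competition vials per cell, baselines calibrated so roughly 91%/39%
of noncompetitive and 93%/47% of competitive trials mate, strain-effect
SDs (0.27, 0.41, 0.32, 0.38) and a correlation structure whose strongest
entry (0.80) links the two noncompetitive contexts, color effects small
enough to keep per-color win shares near 25%, a 0.6 log-ratio inbreeding
deficit with interaction SD 0.45, 44% zero-egg and 9% unfertilized
viability vials, and 39 wings per strain with a 0.8% planted-outlier rate.
Where the emulated design pins no value (female responsiveness SD 0.5,
latency noise SD 1.5, vial-level fitness noise 1.6, wing noise scales),
values were chosen once to give realistic strain-level signal-to-noise and
are documented in `?sim_config`; they are study conditions, not tuning
knobs. Within-strain fitness and viability crosses get double replication
because between-strain crosses are reciprocal.

What the generator does *not* emulate: temporal block structure within
trial days, male courtship dynamics (latency is a single draw, not a
behavioral process), dye-color physiology, overdispersed egg counts, or
selection on which males get measured for morphology. Passing
parameter-recovery tests therefore shows the estimators are correct for
the assumed data-generating process, not that the process matches every
feature of real trials.

## Numerical choices and degenerate inputs

* Empirical quantiles use R's default type-7 interpolation; censored
  latencies enter as +Inf so a threshold interpolating into the censored
  mass returns the raw-flag behavior.
* Strain-effect draws use an eigenvalue square root of the correlation
  matrix so zero variances and singular (perfectly correlated) structures
  remain valid inputs.
* GPA rejects coincident-landmark (zero centroid size) configurations;
  PCA rank is counted against a relative 1e-9 eigenvalue tolerance.
* The Mahalanobis screen refuses singular trait covariances and reports
  the rank.
* Separation (a strain with all successes or all failures) is tolerated
  in the Bayesian fit — priors regularize — with a warning; a context
  containing a single strain is rejected as unidentifiable.
* Master seeds derive per-operation seeds by fixed small offsets, and all
  generators restore the caller's RNG state.

## Problem sizes used in the test suite

The suite exercises the full design at its natural scale where cheap
(generators, preparation, mixed models, morphometrics) and reduced scales
for MCMC-heavy checks: parameter-recovery runs use 10 replicate studies at
the default design size with 10 resamples and 2 chains of 1,000-2,000
iterations; the 50-study coverage check uses 2-block studies with short
single chains. These sizes are the package's chosen trade-off between
Monte-Carlo error and practical test runtimes; the estimators themselves
are size-agnostic.

## Known limitations

* The joint four-context model is the reading of record for
  "correlations directly output from the fit"; a per-context mode (fit
  each context separately) is available by subsetting the input, but then
  cross-context correlations are undefined.
* The Gibbs sampler's strain-effect/covariance coupling mixes more slowly
  than a gradient-based joint sampler would at very small strain counts;
  the R-hat gate makes this visible rather than hiding it.
* Jackknife standard errors for strain-mean covariances assume strains
  are exchangeable units; with fewer than three strains the estimator is
  undefined and rejected.
* The pipeline's marginal means average factor levels with equal weights;
  with severely unbalanced designs this is a choice, not an inevitability,
  and `emmeans` weights can be substituted downstream.
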