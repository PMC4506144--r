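---
title: "Correcting cross-cultural correlations for shared descent and geography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting cross-cultural correlations for shared descent and geography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Languages and the cultures that speak them are related by descent and by
contact. Two societies can share a grammatical feature and an economic habit
because both were inherited from a common ancestor or borrowed from the same
neighbour, not because one causes the other. A regression that treats each
language as an independent observation therefore overstates its evidence —
Galton's problem. The motivating case is the claimed association between
obligatory grammatical future-time reference (strong versus weak FTR) and
whether survey respondents report having saved money in the past year: a
binary group-level trait paired with an individual-level binary outcome,
observed across many languages, families, countries and contact areas.

`galton` implements a battery of corrections for exactly this data shape.
No single correction is definitive; the battery's point is to report how the
correlation behaves under *each* control so that a reader can judge its
robustness as a profile rather than as one p-value.

## The battery and its models

**Crossed random-effects logistic model.** The strictest, non-aggregating
test. The outcome of respondent $i$ speaking language $\ell$ is Bernoulli
with

$$\operatorname{logit} P(y_i = 1) = \beta_0 + \beta_\mathrm{FTR}
w_{\ell} + x_i'\gamma + u_{c(i)} + u_{f(\ell)} + u_{a(\ell)}
+ \left(s_{c(i)} + s_{f(\ell)} + s_{a(\ell)}\right) w_\ell,$$

with crossed random intercepts $u$ and random FTR slopes $s$ for country,
language family and linguistic contact area. Estimation is by Laplace
approximation (`lme4`); significance is assessed both by the Wald z and
by the likelihood-ratio comparison against the model without the fixed
effect, the latter being the conservative reference. When the random
slopes are included, any family- or area-specific component of the
correlation is absorbed by $s$, so a drop in $\hat\beta_\mathrm{FTR}$
between the intercepts-only and random-slopes fits is itself diagnostic:
it says the pooled association is carried by particular lineages or areas.

**Regression on matched samples.** Respondents are grouped into bins that
are identical on all matching variables (fully interacted); bins without
outcome variation are uninformative and are dropped with a count. Two
estimators are provided: a fixed-effects logistic regression with one
dummy per bin (default; in a single 2×2 bin the trait coefficient is the
table's log odds ratio exactly) and the exact conditional logistic
likelihood (`survival::clogit`), which conditions the per-bin success
counts away. Standard errors can be clustered (sandwich estimator) at the
family or country level.

**Residualisation.** The aggregate methods need one savings value per
language. Raw proportions would confound composition (employment rates,
attitudes), so the per-language trait is the mean response-scale residual
(observed − fitted probability) from the matched regression on the
*nuisance* covariates only. The trait of interest must not be among the
residualised predictors: the logistic score equation makes respondent
residuals exactly orthogonal to every included predictor, so residualising
on the trait itself would erase the quantity the aggregate tests are meant
to measure.

**Serendipity scan.** To ask whether the focal trait is special, the same
matched regression is refitted once per alternative linguistic feature,
identical in structure except for the swapped feature, and the features
are ranked by BIC (AIC as a cross-check; the two rankings are expected to
agree almost perfectly). Non-converged fits are excluded and counted.

**Phylogeny.** Without cognate data, the tree comes from the taxonomic
classification: families attach to a common root (default depth 60,000
years), family crowns sit at 6,000 years, and levels inside a family are
spaced at equal height fractions — the paper-scale defaults are
deliberately coarse, and the sweep functions below treat them as
assumptions to vary, not facts. Polytomies are retained; every downstream
statistic accepts them. Terminal branches have a 1-year floor so that all
trait covariance matrices stay positive definite.

**Signal statistics.** Pagel's $\lambda$ is estimated by ML over the GLS
likelihood with $V(\lambda)$ = Brownian covariance with off-diagonals
scaled by $\lambda$; the upper bound is the largest $\lambda$ keeping
$V$ positive definite (slightly above 1 on these ultrametric trees), not a
hard cap at 1. For the binary trait, the Fritz–Purvis $D$ scales the
observed sum of sister-clade differences between its expectations under
tip shuffling ($D = 1$) and under threshold Brownian motion at the
observed prevalence ($D = 0$); ancestral values use equal-weight child
averaging, with polytomies averaged over all children.

**PGLS.** Generalised least squares with error covariance from one of
four models: Brownian, Pagel (λ profiled by ML unless fixed), stationary
Ornstein–Uhlenbeck $\exp(-\alpha d)$ on patristic distance, or
Grafen-rescaled heights raised to $\rho$. With λ fixed at 0 on an
ultrametric tree the fit reduces to OLS exactly, which is the
implementation's sanity anchor. Fragility is probed three ways:
leave-one-out dfbetas (cutoff $2/\sqrt{n}$), sweeps over family/root
depths and over Grafen's $\rho$, and permutation tests that re-assign the
trait and/or the savings values (globally or only within families,
deduplicated) and refit.

**Distance-matrix tests.** The simple Mantel test correlates off-diagonal
entries (Spearman by default) and permutes labels; the p-value is
two-sided on $|r|$, $(1 + \#\{|r_\pi| \ge |r_\mathrm{obs}|\})/(1 +
n_\mathrm{perm})$, with an exhaustive fallback when the permutation space
is small. The partial Mantel residualises both focal matrices on the
controls (rank-transformed first for Spearman) and permutes the residual
matrix. The stratified Mantel permutes only within families — singleton
families are fixed points — and defaults to Kendall's τ. Confidence
intervals, when requested, are percentile bootstraps over tip resampling;
that choice is a convention of this package, not an inherited one.

**Geography.** Great-circle distances use the haversine formula at radius
6,371 km; an optional waypoint graph routes cross-continent pairs through
plausible land corridors (never shorter than the direct arc). Moran's I
uses inverse-distance, row-standardised weights with the exact null
expectation $-1/(n-1)$. The geographically weighted regression uses a
Gaussian kernel with the bandwidth chosen by corrected AIC, and reports
local coefficients, the global OLS coefficient, and an F comparison of
residual variances.

**Independent-family sampling.** One strong-FTR and one weak-FTR language
are drawn per family (families lacking a class are skipped for it, or
excluded entirely with `require_both = TRUE`), the sample means compared,
and the fraction of replicates in which the strong mean is *strictly*
lower reported; ties count against the hypothesis.

## The synthetic-data generator

Every stage is testable offline because the generator reproduces the
statistical structure the methods assume:

- a family ⊃ genus ⊃ language taxonomy with configurable counts;
- continuous traits drawn from the exact multivariate normal law of the
  chosen model (Brownian, λ-scaled, or stationary OU), so replicate
  covariances converge to the closed form;
- binary traits by a two-state Markov chain with exact exponential waiting
  times along branches (safe for polytomies) or by thresholded liabilities;
- coordinates by Brownian dispersal down the tree in lat/lon with a
  cos(latitude) longitude correction, clamped to valid ranges;
- linguistic areas as longitude bands and countries as spatial clusters of
  languages, so both cross-cut families the way contact areas do;
- respondents from the logistic crossed-effects model above, with
  covariates Bernoulli(employment 0.6, sex 0.5, trust 0.3) by default.

Default scenario conditions: 15 families, 1–4 genera per family, 1–5
languages per genus (≈100 languages), 6,000/60,000-year depths, FTR
gain/loss rates 2×10⁻⁵ per year (a few changes per family history),
dispersal 6,000 km over the tree depth, 100 respondents per language,
fixed FTR effect 0.4 logits with intercept −1.1, random-intercept SDs
0.5/0.3/0.2 and slope SDs 0.1 for country/family/area. The original
survey never states a generative model; this scenario is the natural
mirror of the fitted mixed model, and its parameters are chosen once to
give realistic group-level heterogeneity, not tuned to any test.

What the generator does *not* emulate: borrowing networks beyond what the
area effects capture, respondent-level covariate confounding with the
trait, observation waves with drifting baselines, or the idiosyncratic
name-linking of real survey data. Passing tests therefore certify the
statistical machinery, not the substantive claim on real data.

```{r example}
library(galton)
sc <- simulate_scenario(seed = 42)
report <- run_battery(sc, seed = 1)
report
```

## Numerical choices

- GLS likelihoods are computed through Cholesky whitening; σ² is profiled
  (ML for likelihoods, n − p denominator for standard errors).
- λ and the OU/Grafen parameters are profiled with `optimize` at tolerance
  1e-8, with explicit boundary checks at λ ∈ {0, 1, λ_max} because a
  unimodal search can miss a boundary maximum.
- Parsimony uses Hartigan's generalisation of the Fitch pass, which is
  exact on multifurcating trees; the test suite pins it to the exhaustive
  minimum on every topology up to six tips.
- Mantel engines enumerate the permutation space exhaustively whenever it
  fits within the requested permutation count; random permutations
  otherwise, with the +1 correction in the p-value.
- Permutation tests deduplicate on the permuted value sequence and fall
  back to whatever unique permutations exist when the space is small;
  non-converged refits are excluded from denominators and counted.
- Degenerate inputs fail loudly: constant traits (λ, D, Mantel, Moran),
  monomorphic binary traits, all-singleton strata, zero parsimony score
  for the change rate, and separation-prone bins are all signalled rather
  than silently absorbed.

## Problem sizes

The packaged analyses and tests run at deliberately moderate scale —
roughly 100 languages, 10,000 respondents, 200-replicate calibrations and
1,000-permutation tests — which resolves the calibration bands the test
suite asserts (type-I error within [0.03, 0.07] at α = 0.05, λ and D
anchor recovery, ≥90% CI coverage) while keeping a full run on a laptop
in minutes. All counts are arguments; nothing in the implementation
depends on them.

## Known limitations

- The classification tree is an assumption, not an inference; equal
  spacing of within-family levels is a convention chosen here, and the
  sweep utilities exist precisely because such conventions should be
  varied.
- The GWR F-test uses effective degrees of freedom in the
  Fotheringham-style approximation; it is a descriptive comparison, not an
  exact test.
- Conditional logistic fits use the exact likelihood and become expensive
  for large informative bins; the fixed-effects estimator is the default
  for that reason.
- BLUPs from the Laplace fit are shrinkage estimates; their standard
  errors are conditional and should not be read as sampling SEs of group
  means.
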