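# galton

Robustness tests for cross-cultural correlations under phylogenetic and
geographic non-independence.

## The problem

Cross-cultural datasets violate the independence assumption behind
ordinary regression: languages inherit traits from common ancestors and
borrow them from neighbours, so societies are correlated observations
(Galton's problem). A famous example is the reported association between
a language's obligatory grammatical future-time reference (strong vs weak
FTR) and its speakers' propensity to save money. `galton` implements the
full battery of corrections needed to ask whether such a correlation
survives controls for shared descent and geography, for any binary
group-level trait paired with an individual-level binary outcome:

- **crossed random-effects logistic models** (country, language family,
  contact area; random intercepts and trait slopes), with Wald-z and
  likelihood-ratio tests and BLUP extraction;
- **regression on matched samples** (fully interacted bins; fixed-effects
  or exact conditional logistic; cluster-robust SEs) with per-language
  residualisation and a **serendipity scan** ranking the trait against
  alternative features by BIC;
- **Mantel, partial Mantel and stratified (within-family) Mantel**
  permutation tests with exhaustive fallback;
- **Moran's I** (inverse-distance weights, exact null expectation
  −1/(n−1)) and **geographically weighted regression** (AICc bandwidth);
- **phylogenetic signal** — Pagel's λ for continuous traits, Fritz–Purvis
  D for binary traits, Fitch/Hartigan parsimony change counts and rates;
- **PGLS** under Brownian, Pagel-λ, Ornstein–Uhlenbeck and Grafen
  covariances, with leave-one-out dfbeta influence diagnostics,
  branch-depth and Grafen-ρ sweeps, and deduplicated trait permutation
  tests (global or within-family);
- **independent-family Monte-Carlo sampling** (one language per class per
  family);
- a **synthetic-data generator** — taxonomy, dated classification tree,
  binary/continuous traits under explicit evolutionary models, Brownian
  dispersal of coordinates, and respondents from the crossed-effects
  logistic model — so the whole battery is testable without external
  downloads.

The core regression the battery interrogates is

```
logit P(save_i) = β0 + β_FTR · weak_ℓ + x_i'γ
                + u_country + u_family + u_area
                + (s_country + s_family + s_area) · weak_ℓ
```

with crossed random intercepts `u` and trait slopes `s`. The diagnostic
contrast is between the intercepts-only fit (one pooled β_FTR) and the
random-slopes fit (lineage- and area-specific effects absorbed by `s`).

## Worked example

The `analysis/` directory holds the numbered drivers of the full
workflow (simulate → mixed models → matched regression and residuals →
phylogenetic signal → distance tests → battery). The default scenario
(seed 42) simulates 101 languages in 15 families with a planted weak-FTR
effect of 0.4 logits plus crossed group effects:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_mixed_models.R
```

prints, among other things:

```
Simulated 101 languages in 15 families; 10100 respondents.
Saving proportion 0.374; strong-FTR speaker share 0.356.

  fixed_effect estimate     se     z   p_wald  chisq     p_lr
1     weak_ftr   0.4809 0.0782  6.15 7.66e-10  39.57 3.17e-10
3     employed   0.6537 0.0449 14.57 4.34e-48 218.08 2.37e-49

Random-slopes FTR model: estimate 0.334, LR chi2 3.55, p 0.059
```

Read: with random intercepts only, the trait looks strongly significant
(β̂ = 0.48, LR p ≈ 3×10⁻¹⁰); once random slopes let the effect vary by
family, area and country, the estimate drops to 0.33 and the
likelihood-ratio test is marginal (p = 0.059) — exactly the attenuation
pattern that motivates controlling for relatedness, here reproduced on
data where the true pooled effect is 0.4. The remaining drivers compute
the matched-sample regression (weak-FTR odds ratio ≈ 1.5), the
phylogenetic signal of the trait (15 parsimony changes, one per
≈ 82,000 years on the 60,000-year tree), the Mantel family, Moran's I,
GWR, PGLS with influence diagnostics, and the one-row-per-method battery
report written to `results/06_battery.csv`.

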