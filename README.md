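# moltevol

Comparative phylogenetic analysis of binary traits, built around the
question of how seasonal plumage molts evolve in passerines. A species
either has a winter–spring (pre-alternate) molt or not, and when it does,
the molt is partial or complete; explaining which species have it — and
whether its evolution is coupled to migration, sexual selection, foraging
or social behavior — requires methods that account for shared ancestry.

The package provides the full pipeline:

- **Trait handling** — molt scoring under two timing rules (a molt confined
  to November–December can be counted as pre-basic instead), extent and
  feather-tract classification, dichotomization of ordinal/continuous
  predictors at every candidate cut point, and separation detection.
- **Binary phylogenetic mixed model** (`fit_binary_pmm()`) — latent
  liability ℓ = Xβ + a + e with a ~ N(0, σ²ₐC) for the phylogenetic
  correlation matrix C, residual variance fixed at 1, logistic link;
  parameter-expanded prior on σ²ₐ (V = 1, ν = 100 — approximately χ²₁);
  reports per coefficient the posterior mean, 95 % HPD interval, ESS, lag-1
  autocorrelation, Geweke z and pMCMC, plus phylogenetic heritability
  h² = σ²ₐ/(σ²ₐ + 1 + c).
- **Pagel's correlated-evolution models** (`fit_pagel()`,
  `stepping_stone_logml()`, `directional_test()`, `test_battery()`) — the
  4-state joint chain over two binary characters with eight permitted
  transition rates q12…q43, dependent vs independent models, a
  hyper-exponential rate prior (Exp(mean m), m ~ U(0, 10)), reversible-jump
  zero-class assignment with Z-values, stepping-stone marginal likelihoods,
  Bayes factors BF = 2 Δlog ML categorized at the 2/5 thresholds, and
  contingent-change / temporal-order rate-restriction tests.
- **Orchestration** (`run_pmm_over_trees()`, `run_coevo_over_trees()`,
  `dichotomization_sweep()`, `full_report()`) — multi-tree and multi-run
  loops with arithmetic-mean aggregation, the autocorrelation escalation
  rule (r ≥ 0.1 doubles thinning, retained draws unchanged), and TSV report
  bundles with a reproducibility manifest.
- **Synthetic data** (`simulate_yule_tree()`, `simulate_ctmc_pair()`,
  `simulate_liability_dataset()`, `simulate_study_table()`) — generators
  with exactly the statistical structure the models assume, so every stage
  is testable without downloads.

## Worked example

```r
library(moltevol)

# a study-structured table of 188 species and a small tree set
tab   <- simulate_study_table(seed = 1)
trees <- as_tree_set(lapply(1:3, function(i) {
  tr <- simulate_yule_tree(nrow(tab), seed = i)
  tr$tip.label <- sample(tab$species)
  tr
}))

molt_count_summary(tab)[c("n_inclusive", "n_strict")]
#> $n_inclusive
#> [1] 83
#> $n_strict
#> [1] 67

# which predictors associate with molt presence, averaging over trees
dat <- as.data.frame(tab)
dat$prealternate <- as.integer(molt_response(tab, "inclusive"))
ens <- run_pmm_over_trees(prealternate ~ log_body_mass + sexual_selection + migration,
                          dat, trees, settings = mcmc_settings(20000, 4000, 16),
                          seed = 1)
ens
#> Binary phylogenetic mixed model averaged over 3 tree(s)
#>              term estimate    lci   uci ess autocorrelation geweke_z pMCMC
#>       (Intercept)   -3.959 -6.191 -1.77 240           0.566   -0.135 0.002
#>     log_body_mass    0.227 -1.060  1.47 331           0.482    0.786 0.721
#>  sexual_selection    1.000  0.535  1.49 238           0.563   -0.703 0.002
#>         migration    0.984  0.664  1.32 241           0.584   -0.389 0.002
#> Heritability (h2): 0.098 (95% 0.000/0.307)

# correlated evolution: molt presence vs dichotomous migration
resp <- molt_response(tab, "inclusive")
mig  <- setNames(tab$migration, tab$species)
sw <- dichotomization_sweep(trees[[1]], resp, mig, variable = "migration",
                            ss = stepping_stone_settings(8, 250), n_runs = 2,
                            seed = 1)
sw$table
#>   scheme  mean_bf      lci      uci category
#> 1  cut>1 17.11734 16.41100 17.82367   strong
#> 2  cut>2 29.92508 29.59342 30.25674   strong
#> 3  cut>3 37.91508 37.63897 38.19119   strong
#> 4  cut>4 32.52505 31.30751 33.74259   strong
```

The mixed-model rows read like a regression table on the liability scale:
`migration 0.984` with `pMCMC 0.002` means more migratory species have the
molt more often than expected under the phylogeny-only model (the short
demonstration schedule leaves visible autocorrelation; the long default
schedule drives it to ~0). The sweep pits the dependent
(correlated-evolution) model against the independent model under every cut
of the 5-level migration score; `mean_bf > 5` reads as strong evidence, and
the selected cut — between classes 3 and 4, i.e. {1,2,3} vs {4,5} — is
where the coupling between migratory behavior and molt is strongest.

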