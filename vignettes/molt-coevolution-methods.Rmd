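---
title: "Models and methods: binary-trait coevolution on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: binary-trait coevolution on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific setting

Seasonal plumage molts in passerines are binary, species-level characters:
a species either performs a winter--spring (pre-alternate) molt or it does
not, and when it does the molt is either partial or complete. Explaining the
distribution of such a character across a clade requires comparative methods
that respect shared ancestry: closely related species are not independent
data points. This package implements the two complementary analyses used for
that purpose, together with the data-handling, multi-tree orchestration and
synthetic-data machinery needed to run and test them end to end:

1. a **Bayesian phylogenetic mixed model (PMM)** for a binary response,
   which asks which continuous or ordinal predictors (migration intensity,
   habitat openness, aerial foraging, winter gregariousness, sexual
   selection, dichromatism, body mass) are associated with the trait while
   absorbing phylogenetic autocorrelation into a random effect; and
2. **Pagel's dependent/independent models of correlated evolution** for two
   binary characters, which ask whether the evolutionary *dynamics* of the
   two characters are coupled, and in which direction, via Bayes factors
   from stepping-stone marginal likelihoods and rate-restriction tests.

## Trait scoring and dichotomization

A molt observation couples three fields: the presence flag, the set of
calendar months in which molt occurs, the extent (partial/complete), and the
molted feather tracts. Two timing rules classify presence: the *inclusive*
rule accepts any winter--spring molt, while the *strict* rule reassigns a
molt confined to November--December to the pre-basic molt, so only species
with at least one molt month outside those two count. Tract sets split into
flight feathers (primaries, secondaries, tertials, rectrices) and nonflight
feathers (wing coverts, head, body).

Pagel's models need binary characters, so ordinal and continuous predictors
are dichotomized. For an ordinal with K observed levels every cut between
adjacent levels is a candidate scheme (K − 1 schemes); for a continuous
predictor the four statistics mean, median, lower and upper quartile are the
candidate cuts. The package evaluates *all* schemes
(`dichotomization_sweep()`) and selects the one with the largest mean Bayes
factor, breaking ties toward the lower cut. Two conventions are fixed once
and documented rather than left implicit: a value exactly at a continuous
cut scores 1 (state "above"), and quartiles use the type-7
(linear-interpolation) definition.

## The binary phylogenetic mixed model

The response is modeled through a latent liability
$\ell_i = x_i'\beta + a_i + e_i$ with
$a \sim N(0, \sigma^2_a C)$, $e_i \sim N(0, 1)$ (the residual variance is
fixed at 1 and never sampled, as is standard for binary responses where the
residual scale is not identified), and
$\Pr(y_i = 1 \mid \ell_i) = \mathrm{logit}^{-1}(\ell_i)$ (a probit link is
available behind a switch). $C$ is the phylogenetic correlation matrix:
shared root-to-tip path length divided by tree depth, unit diagonal for an
ultrametric tree. Trees are used with untransformed branch lengths; a
relative root-to-tip depth spread up to $10^{-3}$ is tolerated (Newick text
truncation) and depths are averaged.

The phylogenetic variance carries a parameter-expanded prior: a working
variance $v \sim \mathrm{IG}(\nu/2, \nu V/2)$ with $V = 1$, $\nu = 100$, and
an expansion scalar $\alpha \sim N(0, 1)$, with $\sigma^2_a = \alpha^2 v$.
With $\nu = 100$ the working variance is pinned near 1, so the implied prior
on $\sigma^2_a$ is close to a $\chi^2$ with one degree of freedom — the
recommended weakly-informative choice for binary responses. Both the printed
($\nu = 100$) and a tighter ($\nu = 1000$) variant are selectable. Fixed
effects take an improper flat prior by default; when the predictors
(quasi-)separate the response the fit refuses to run under the flat prior
and the user switches on independent $N(0, 9)$ priors on every coefficient,
which is also what the orchestration layer does automatically for degenerate
subsets.

The sampler is Metropolis-within-Gibbs: vectorized random-walk Metropolis on
the liabilities; a joint conjugate Gibbs draw of $(\beta, \alpha)$; Gibbs
draws of the whitened random effects in the eigenbasis of $C$ (so each
iteration costs $O(n^2)$ after one eigendecomposition); and the conjugate
inverse-gamma draw of $v$. The contract is the posterior, not the kernel:
any correct kernel for this model would do, and the test suite checks the
posterior itself (calibration of type-I error, interval coverage,
heritability recovery, agreement with ordinary logistic regression when
$\sigma^2_a$ is pinned near zero).

Reported per coefficient: posterior mean, 95% interval, effective sample
size, lag-1 autocorrelation, Geweke's z (first 10% vs last 50%, spectral
variance from an AIC-selected AR fit; |z| < 1.96 denotes convergence), and
pMCMC — twice the smaller of the posterior probabilities of either sign,
floored at $2/n$ when one sign is unobserved. Intervals are
highest-posterior-density by default (quantile intervals by option): HPD is
the convention of the MCMC software this model family is associated with,
and for the strictly positive, right-skewed variance draws it hugs the mode
rather than the tails.

**Heritability.** Phylogenetic signal is reported as
$h^2 = \sigma^2_a / (\sigma^2_a + 1 + c)$ per draw. Whether the link
variance $c$ belongs in the denominator is a genuine convention split in the
literature; the package defaults to $c = \pi^2/3$ (logistic link) and
exposes $c = 0$ for the latent-scale ratio. The calibration tests use the
$c = 0$ convention with $\sigma^2_a = 1$ (target $h^2 = 0.5$): under the
$\chi^2_1$-like prior the $c = \pi^2/3$ convention would require
$\sigma^2_a \approx 4.3$, which lies in the far upper tail of that prior, so
no correct implementation could recover it from binary data at these sample
sizes — the prior, deliberately informative, dominates. This is a property
of the study's own prior choice, not of the sampler.

The default schedule is 2,000,000 iterations, 100,000 burn-in, thinning
2,000 — exactly 950 retained draws; the retained-count identity
$(\text{iterations} - \text{burn-in})/\text{thinning}$ is enforced by
construction and preserved by the autocorrelation escalation rule (lag-1
$r \ge 0.1$ doubles the thinning and enlarges the iteration count so the
retained count is unchanged). Analyses are averaged over a set of trees
(default 100) by plain arithmetic means of every reported parameter,
including the interval bounds.

## Pagel's correlated-evolution models

Two binary characters define four joint states 00, 01, 10, 11 (first digit:
trait x; second: trait y). Single changes give eight transition rates
$q_{12}, q_{21}, q_{13}, q_{31}, q_{24}, q_{42}, q_{34}, q_{43}$; dual
changes are structurally zero. The *independent* model constrains gains and
losses of each trait to ignore the other's state ($q_{13}=q_{24}$,
$q_{31}=q_{42}$, $q_{12}=q_{34}$, $q_{21}=q_{43}$); the *dependent* model
frees all eight. The likelihood is Felsenstein pruning over the 4-state
chain, implemented in C++ with an eigendecomposition-based propagator per
generator (falling back to scaling-and-squaring when the decomposition is
ill-conditioned). The root takes uniform ¼ weights by default; the
stationary distribution of the generator is available by option.

All rates share a hyper-exponential prior: $q \mid m \sim$ Exponential with
mean $m$, $m \sim U(0, 10)$, with $m$ resampled within the chain. Rate
updates are log-scale random walks whose step sizes adapt toward a ~30%
acceptance rate during burn-in only (the retained chain is a fixed kernel).

**Reversible jump.** With RJ on, the sampler moves over partitions of the
free rates into a zero class plus shared-value bins, with a uniform prior
over partitions and new bin values proposed from the rate prior (so the
acceptance ratio reduces to the likelihood ratio times a destination-count
ratio). The percentage of retained samples a rate spends in the zero class
is its Z-value. Jump moves begin halfway through burn-in, after the
fixed-dimension chain has located the mode — at short schedules a cold RJ
start can freeze in a poor partition. Posterior rate means are reported both
over all retained draws (zeros included — the default, matching the
flow-diagram convention of reporting a mean per arrow) and over nonzero
visits only.

**Marginal likelihoods and Bayes factors.** Stepping-stone sampling
integrates along power posteriors $p(\theta)L(\theta)^\beta$ with the powers
at quantiles of a Beta(0.4, 1) distribution (concentrating stones near the
prior, where the integrand changes fastest), visited from the posterior
toward the prior; defaults are 100 stones × 10,000 iterations. Marginal
likelihoods are computed on the fixed-dimension models (RJ off): whether the
reference implementation integrated over the RJ partition space is not
documented, and the fixed-dimension integral is the cleanly defined object;
a switch allows stepping-stone under RJ. With every rate held fixed the
marginal likelihood equals the likelihood and is returned exactly — a
degenerate case the tests exploit. $\mathrm{BF} = 2(\log \mathrm{ML}_1 -
\log \mathrm{ML}_2)$; with 10 replicate runs per model all 100 pairings are
combined, and the mean is categorized as no evidence (< 2), positive (2–5),
or strong (> 5), with the boundaries themselves counted as positive.

**Directional tests.** A contingent-change or temporal-order hypothesis is
tested by comparing the unrestricted dependent model against one with two
named rates constrained equal; the direction is read off the unrestricted
posterior means. The standard battery runs q12/q34, q21/q43, q13/q24,
q31/q42 (contingent change) and q12/q13, q42/q43 (temporal order); when the
pair is in inverted orientation (state 0 of one character associated with
state 1 of the other) the temporal-order comparisons become q31/q34 and
q21/q24.

## The synthetic-data generator

Every analysis stage is testable without downloads because the generator
produces data with exactly the structure the models assume:

- `simulate_yule_tree()`: pure-birth trees rescaled to unit height — the
  simplest ultrametric generator; the rate heterogeneity and imbalance of
  real avian supertrees are deliberately not emulated.
- `simulate_ctmc_pair()`: exact event-driven simulation of the joint
  4-state chain along every branch.
- `simulate_liability_dataset()`: the generative counterpart of the PMM —
  predictors from stated marginals, liability $X\beta + a + e$, Bernoulli
  response through the logistic link.
- `simulate_study_table()`: a full 188-row trait table with the marginal
  structure of the European-passerine dataset (83 winter--spring molters of
  which 16 molt only in November--December; 48 partial / 35 complete; 37
  partial molters replacing nonflight tracts only; 26 territorial species),
  with assignments randomized given the seed and molting species skewed
  toward migratory, aerially foraging, high-sexual-selection values.

Passing tests on these data demonstrate correctness of the inference
machinery under the model's own assumptions; they do not demonstrate
robustness to the features real data add (tree misspecification,
measurement error in trait scoring, correlated predictors, non-Yule tree
shape).

## Problem sizes and numerical choices in the test suite

The validation suite runs at desk scale, with sizes chosen so each property
is informative yet the whole suite completes quickly: likelihood oracles on
4–6-tip trees (brute-force enumeration over all internal-state assignments,
tolerance 1e-10); stepping-stone vs numeric quadrature for one-free-rate
models on 6-tip trees (tolerance 0.1); Bayes-factor calibration on 100-tip
trees with 10 replicates per scenario (8 stones × 250 iterations);
directional-test power on 300-tip trees (6 stones × 200 iterations); PMM
type-I error over 200 replicates at 100 tips, interval coverage over 40 and
heritability recovery over 20 replicates at 188 tips, with schedules of a
few thousand iterations. For the strong-dependence and directional-power
scenarios the generator couples the pair tightly (off-state gain *and* loss
both two orders of magnitude slower than their on-state counterparts):
power analysis during design showed that a single rate contrast of
twenty-fold leaves the true Bayes factor below the strong-evidence
threshold in a substantial fraction of 100–300-tip datasets — a real
property of these tests' power, worth knowing when interpreting negative
results on data of this size.

Tie-breaks and degenerate inputs are fixed once: ties at continuous cuts
score 1; zero-length terminal branches are allowed; a constant predictor or
a dichotomization that leaves one state empty is an error (or a skipped
scheme, with a warning, inside a sweep); a constant chain has undefined
diagnostics and errors; pMCMC is floored at 2/n. Per-tree seeds derive
deterministically from a master seed plus the tree index, and a run
manifest (seeds, schedule, escalations, versions) makes every reported
number reproducible bit for bit at fixed settings.

## Known limitations

- Missing trait states (ambiguity codes) are not supported in the pruning
  likelihood; species must be fully scored.
- The PMM is single-response and binary-family only.
- Multistate (> 2 states) and covarion models, and ancestral-state
  reconstruction, are out of scope.
- Stepping-stone replicate noise at the reduced schedules used in tests is
  of order ±1 on the Bayes-factor scale; near-threshold categorizations at
  those schedules should be treated accordingly (the full 100 × 10,000
  schedule reduces this by an order of magnitude).
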