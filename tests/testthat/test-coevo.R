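test_that("the joint generator has the single-change structure", {
  Q <- build_generator(dependent_rates(1, 1, 1, 1, 1, 1, 1, 1))
  expect_equal(rowSums(Q), rep(0, 4), ignore_attr = TRUE)
  expect_identical(Q[1, 4], 0); expect_identical(Q[4, 1], 0)
  expect_identical(Q[2, 3], 0); expect_identical(Q[3, 2], 0)
  Qi <- build_generator(independent_rates(alpha1 = .2, beta1 = .3, alpha2 = .5, beta2 = .7))
  expect_equal(Qi[1, 3], 0.2); expect_equal(Qi[2, 4], 0.2)  # q13 = q24 = alpha1
  expect_equal(Qi[1, 2], 0.5); expect_equal(Qi[3, 4], 0.5)  # q12 = q34 = alpha2
  expect_error(build_generator(c(q14 = 1)), "not a permitted")
  expect_error(dependent_rates(1, 1, 1, -1, 1, 1, 1, 1), "nonnegative")
})

test_that("transition probabilities match a power-series oracle and the semigroup law", {
  expect_equal(transition_probabilities(build_generator(dependent_rates(1,1,1,1,1,1,1,1)), 0),
               diag(4))
  expect_equal(transition_probabilities(matrix(0, 4, 4), 2.5), diag(4))
  set.seed(3)
  r <- runif(8, 0.1, 2)
  Q <- build_generator(do.call(dependent_rates, as.list(r)))
  P <- transition_probabilities(Q, 0.7)
  expect_equal(P, expm_series(Q, 0.7), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-12)
  expect_true(all(P >= 0))
  # P(s + t) = P(s) P(t)
  expect_equal(transition_probabilities(Q, 1.1),
               transition_probabilities(Q, 0.4) %*% transition_probabilities(Q, 0.7),
               tolerance = 1e-9)
  expect_error(transition_probabilities(Q, -1), "nonnegative")
})

test_that("pruning likelihood matches closed-form and enumeration oracles", {
  # two tips on a single cherry: log sum_r pi_r P(r -> sA) P(r -> sB)
  cherry <- ape::read.tree(text = "(A:0.6,B:1.3);")
  pair <- binary_trait_pair(c("A", "B"), x = c(0, 1), y = c(1, 1))
  Q <- build_generator(dependent_rates(.4, .3, .6, .2, .5, .4, .8, .3))
  PA <- transition_probabilities(Q, 0.6)
  PB <- transition_probabilities(Q, 1.3)
  sA <- 2; sB <- 4
  closed <- log(sum(0.25 * PA[, sA] * PB[, sB]))
  expect_equal(pruning_loglik(cherry, pair, Q), closed, tolerance = 1e-12)
  # 5-tip tree vs brute-force enumeration over internal states
  tr <- simulate_yule_tree(5, seed = 17)
  pair5 <- simulate_ctmc_pair(tr, Q, seed = 18)
  expect_equal(pruning_loglik(tr, pair5, Q), enum_loglik(tr, pair5, Q),
               tolerance = 1e-10)
})

test_that("the independent model factorizes into two single-trait likelihoods", {
  tr <- simulate_yule_tree(8, seed = 21)
  Qi <- build_generator(independent_rates(.3, .5, .7, .4))
  pair <- simulate_ctmc_pair(tr, Qi, seed = 22)
  joint <- pruning_loglik(tr, pair, Qi)
  lx <- prune2_loglik(tr, setNames(pair$x, pair$taxa), alpha = .3, beta = .5)
  ly <- prune2_loglik(tr, setNames(pair$y, pair$taxa), alpha = .7, beta = .4)
  expect_equal(joint, lx + ly, tolerance = 1e-10)
})

test_that("pruning is invariant to taxon order in the trait pair", {
  tr <- simulate_yule_tree(10, seed = 31)
  Q <- build_generator(dependent_rates(.4, .3, .6, .2, .5, .4, .8, .3))
  pair <- simulate_ctmc_pair(tr, Q, seed = 32)
  perm <- sample(10)
  pair2 <- binary_trait_pair(pair$taxa[perm], pair$x[perm], pair$y[perm])
  expect_equal(pruning_loglik(tr, pair, Q), pruning_loglik(tr, pair2, Q))
  expect_error(pruning_loglik(tr, binary_trait_pair("A", 1, 1), Q), "missing")
})

test_that("Bayes factors are categorized by the 2/5 evidence thresholds", {
  expect_identical(interpret_bf(1.55), "none")
  expect_identical(interpret_bf(-3), "none")
  expect_identical(interpret_bf(4.37), "positive")
  expect_identical(interpret_bf(6.93), "strong")
  expect_identical(interpret_bf(2), "positive")
  expect_identical(interpret_bf(5), "positive")
})

test_that("replicate marginal likelihoods combine into n^2 Bayes factors", {
  bf <- bayes_factor_summary(rep(-100, 10), rep(-102, 10))
  expect_length(bf$bf_values, 100)
  expect_equal(bf$mean, 4)
  expect_equal(bf$lci, 4); expect_equal(bf$uci, 4)
  expect_identical(bf$category, "positive")
  set.seed(9)
  bf2 <- bayes_factor_summary(rnorm(10, -50), rnorm(10, -51))
  expect_length(bf2$bf_values, 100)
  expect_lte(bf2$lci, bf2$mean); expect_gte(bf2$uci, bf2$mean)
  expect_error(bayes_factor_summary(numeric(), 1), "empty")
})

test_that("restrictions must name two distinct permitted rates", {
  tr <- simulate_yule_tree(6, seed = 2)
  pair <- binary_trait_pair(tr$tip.label, c(0,1,0,1,0,1), c(0,0,1,1,0,1))
  expect_error(directional_test(tr, pair, c("q14", "q23")), "structurally zero")
  expect_error(directional_test(tr, pair, c("q12", "q12")), "distinct")
  expect_error(fit_pagel(tr, pair, "restricted", restriction = c("q12", "q41")),
               "structurally zero")
})

test_that("the posterior sampler retains the scheduled number of draws", {
  tr <- simulate_yule_tree(8, seed = 3)
  pair <- simulate_ctmc_pair(tr, build_generator(independent_rates(.5, .5, .5, .5)),
                             seed = 4)
  fit <- fit_pagel(tr, pair, "independent", settings = mcmc_settings(900, 100, 2),
                   seed = 5)
  expect_identical(nrow(fit$chains), 400L)
  expect_identical(colnames(fit$chains), c("q12", "q21", "q13", "q31",
                                           "q24", "q42", "q34", "q43"))
  # independent mapping ties the shared columns together draw by draw
  expect_equal(fit$chains[, "q13"], fit$chains[, "q24"])
  expect_equal(fit$chains[, "q12"], fit$chains[, "q34"])
  # restricted model ties exactly the restricted pair
  fr <- fit_pagel(tr, pair, "restricted", restriction = c("q12", "q34"),
                  settings = mcmc_settings(900, 100, 2), seed = 6)
  expect_equal(fr$chains[, "q12"], fr$chains[, "q34"])
  expect_false(isTRUE(all.equal(fr$chains[, "q21"], fr$chains[, "q43"])))
})

test_that("a prior-only run recovers the hyper-exponential prior mean", {
  tr <- simulate_yule_tree(6, seed = 9)
  pair <- binary_trait_pair(tr$tip.label, c(0,1,0,1,0,1), c(1,0,1,0,1,0))
  fit <- fit_pagel(tr, pair, "dependent", settings = mcmc_settings(42000, 2000, 20),
                   seed = 5, likelihood = FALSE)
  # analytic: E[q] = E[m] = hyper_max / 2 = 5
  expect_equal(mean(fit$chains), 5, tolerance = 0.12)
  expect_equal(mean(fit$hyper_mean), 5, tolerance = 0.12)
})

test_that("reversible jump assigns a truly zero rate to the zero class", {
  Q <- build_generator(dependent_rates(q12 = 0, q21 = 1, q13 = 1, q31 = 1,
                                       q24 = 1, q42 = 1, q34 = 1, q43 = 1))
  tr <- simulate_yule_tree(200, seed = 21)
  hits <- 0
  for (r in 1:10) {
    pr <- simulate_ctmc_pair(tr, Q, root = "stationary", seed = 21 + r)
    fit <- fit_pagel(tr, pr, "dependent", settings = mcmc_settings(8000, 2000, 6),
                     rj = TRUE, seed = 3 + r)
    z <- setNames(fit$rate_summary$z_value, fit$rate_summary$rate)
    hits <- hits + (z[["q12"]] > mean(z[c("q21", "q13", "q31", "q24", "q42", "q34", "q43")]))
  }
  expect_gte(hits, 9)
})

test_that("stepping stone is deterministic given the seed and errors on short schedules", {
  tr <- simulate_yule_tree(6, seed = 9)
  pair <- simulate_ctmc_pair(tr, build_generator(independent_rates(.5, .5, .5, .5)),
                             seed = 10)
  ss <- stepping_stone_settings(6, 150)
  a <- stepping_stone_logml(tr, pair, "independent", ss = ss, seed = 7)
  b <- stepping_stone_logml(tr, pair, "independent", ss = ss, seed = 7)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_error(stepping_stone_settings(stones = 1), "stones")
  expect_true(all(diff(ss$beta) > 0))
  expect_equal(range(ss$beta), c(0, 1))
})

test_that("the dependent model nests the independent model", {
  tr <- simulate_yule_tree(30, seed = 41)
  pair <- simulate_ctmc_pair(tr, build_generator(independent_rates(.6, .4, .8, .5)),
                             seed = 42)
  lay_d <- moltevol:::model_layout("dependent")
  lay_i <- moltevol:::model_layout("independent")
  f_d <- moltevol:::make_loglik(tr, pair, lay_d, "uniform", TRUE)
  f_i <- moltevol:::make_loglik(tr, pair, lay_i, "uniform", TRUE)
  o_i <- optim(rep(0, 4), function(lp) -f_i(exp(lp)), method = "BFGS")
  o_d <- optim(rep(0, 8), function(lp) -f_d(exp(lp)), method = "BFGS")
  expect_gte(-o_d$value, -o_i$value - 1e-6)
})

test_that("the test battery composes the six comparisons per orientation", {
  std <- moltevol:::battery_comparisons("standard")
  expect_length(std, 6)
  expect_identical(std[[1]], c("q12", "q34"))
  expect_identical(std[[5]], c("q12", "q13"))
  expect_identical(std[[6]], c("q42", "q43"))
  inv <- moltevol:::battery_comparisons("inverted")
  expect_identical(inv[[5]], c("q31", "q34"))
  expect_identical(inv[[6]], c("q21", "q24"))
  expect_identical(inv[1:4], std[1:4])
})

test_that("the battery runs end to end and labels each comparison", {
  tr <- simulate_yule_tree(12, seed = 51)
  Q <- build_generator(dependent_rates(.2, 1.5, .5, .5, .5, .5, 1.5, .2))
  pair <- simulate_ctmc_pair(tr, Q, seed = 52, names = c("migration", "molt"))
  out <- test_battery(tr, pair, ss = stepping_stone_settings(4, 80), n_runs = 1,
                      posterior_settings = mcmc_settings(600, 100, 1), seed = 1)
  expect_length(out, 6)
  for (dt in out) {
    expect_s3_class(dt, "directional_test")
    expect_length(dt$bf$bf_values, 1)
    expect_true(nzchar(dt$meaning))
    expect_true(grepl("q", dt$direction))
  }
  expect_true(any(grepl("migration", vapply(out, function(d) d$meaning, character(1)))))
})

test_that("maximum-likelihood fits agree with an independent implementation", {
  skip_if_not_installed("phytools")
  tr <- simulate_yule_tree(60, seed = 5)
  Q <- build_generator(dependent_rates(.2, 1, .5, .5, .5, .5, 1.5, .2))
  pair <- simulate_ctmc_pair(tr, Q, seed = 6)
  x <- setNames(factor(pair$x), pair$taxa)
  y <- setNames(factor(pair$y), pair$taxa)
  fp <- phytools::fitPagel(tr, x, y, pi = "equal")
  f_d <- moltevol:::make_loglik(tr, pair, moltevol:::model_layout("dependent"),
                                "uniform", TRUE)
  f_i <- moltevol:::make_loglik(tr, pair, moltevol:::model_layout("independent"),
                                "uniform", TRUE)
  o_d <- optim(rep(-0.5, 8), function(lp) -f_d(exp(lp)), method = "BFGS",
               control = list(maxit = 500))
  o_i <- optim(rep(-0.5, 4), function(lp) -f_i(exp(lp)), method = "BFGS",
               control = list(maxit = 500))
  expect_equal(-o_d$value, as.numeric(fp$dependent.logL), tolerance = 1e-3)
  expect_equal(-o_i$value, as.numeric(fp$independent.logL), tolerance = 1e-4)
})
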