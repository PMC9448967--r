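test_that("pMCMC is the doubled smaller tail probability with floor and cap", {
  expect_equal(pmcmc(c(1, 2, 3, -1)), 0.5)
  expect_equal(pmcmc(c(-2, -1, 1, 2)), 1)
  expect_equal(pmcmc(rep(1, 950)), 2 / 950)
  x <- rnorm(500)
  expect_equal(pmcmc(x), pmcmc(3.7 * x))   # invariant to positive rescaling
  expect_equal(pmcmc(x), pmcmc(-x))        # sign flip swaps the two tails only
  expect_error(pmcmc(numeric()), "samples")
})

test_that("effective sample size tracks the autocorrelation time", {
  for (s in 1:5) {
    set.seed(s)
    d <- chain_diagnostics(rnorm(950))
    expect_gte(d$ess, 850)
    expect_lte(d$ess, 1050)
  }
  # AR(1) with coefficient 0.9: ESS ~ n (1 - rho) / (1 + rho)
  set.seed(42)
  n <- 5000
  x <- as.vector(arima.sim(list(ar = 0.9), n))
  d <- chain_diagnostics(x)
  expect_equal(d$lag1, 0.9, tolerance = 0.05)
  expect_equal(d$ess, n * 0.1 / 1.9, tolerance = 0.35)
  expect_lt(d$ess, n / 5)
  expect_error(chain_diagnostics(rep(1, 100)), "constant")
  expect_error(chain_diagnostics(rnorm(10)), "at least 50")
})

test_that("Geweke z-score flags convergence for about 95% of iid chains", {
  set.seed(7)
  ok <- sum(replicate(40, abs(chain_diagnostics(rnorm(500))$geweke_z) < 1.96))
  expect_gte(ok, 34)
})

test_that("heritability transforms variance draws with the link-variance term", {
  h <- heritability(rep(1, 100), link_variance = 0)
  expect_equal(h$estimate, 0.5)
  expect_equal(heritability(rep(1e-9, 100), link_variance = 0)$estimate, 0, tolerance = 1e-6)
  # monotone in sigma2_a
  s <- seq(0.1, 5, length.out = 20)
  expect_true(all(diff(s / (s + 1 + pi^2 / 3)) > 0))
  expect_error(heritability(c(1, -1)), "positive")
})

test_that("the MCMC schedule retains exactly (iterations - burn_in)/thinning draws", {
  st <- mcmc_settings()
  expect_identical(st$retained, 950L)
  expect_error(mcmc_settings(1000, 100, 7), "multiple")
  st2 <- mcmc_settings(4000, 1000, 3)
  expect_identical(st2$retained, 1000L)
})

test_that("hpd interval is the shortest interval at the requested mass", {
  set.seed(1)
  x <- rexp(4000)          # right-skewed: HPD hugs zero
  ci <- hpd_interval(x)
  expect_lt(ci[1], 0.06)
  q <- quantile(x, c(0.025, 0.975))
  expect_lt(diff(ci), diff(q) + 1e-9)
})

test_that("fitting errors on separation with a flat prior and on bad responses", {
  tr <- simulate_yule_tree(40, seed = 2)
  dat <- data.frame(species = tr$tip.label,
                    x = rep(c(0, 1), each = 20))
  dat$response <- as.integer(dat$x == 1)  # perfect separation
  expect_error(fit_binary_pmm(response ~ x, dat, tr,
                              settings = mcmc_settings(200, 100, 1)),
               "separation")
  # with the normal fixed-effect prior it runs
  fit <- fit_binary_pmm(response ~ x, dat, tr,
                        settings = mcmc_settings(600, 100, 1),
                        priors = pmm_priors(fixed_effect = "normal"), seed = 1)
  expect_s3_class(fit, "binary_pmm")
  dat$response <- 2 * dat$response
  expect_error(fit_binary_pmm(response ~ x, dat, tr,
                              settings = mcmc_settings(200, 100, 1)),
               "0/1")
})

test_that("a fitted model reports coherent posterior summaries", {
  tr <- simulate_yule_tree(60, seed = 3)
  dat <- simulate_liability_dataset(tr, beta = c("(Intercept)" = 0, x = 1),
                                    sigma2_a = 1, seed = 4)
  fit <- fit_binary_pmm(response ~ x, dat, tr,
                        settings = mcmc_settings(1600, 400, 2), seed = 5)
  st <- fit$summary_table
  expect_identical(nrow(st), 2L)
  expect_true(all(st$lci <= st$estimate & st$estimate <= st$uci))
  expect_true(all(st$pMCMC > 0 & st$pMCMC <= 1))
  expect_true(all(fit$chains[, "sigma2_a"] > 0))
  expect_true(fit$h2[["estimate"]] >= 0 && fit$h2[["estimate"]] <= 1)
  expect_identical(nrow(fit$chains), 600L)
  expect_named(coef(fit), c("(Intercept)", "x"))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sims), c(60L, 3L))
  expect_true(all(sims %in% 0:1))
})

test_that("with the phylogenetic variance pinned near zero the fit matches logistic regression", {
  tr <- simulate_yule_tree(250, seed = 6)
  dat <- simulate_liability_dataset(tr, beta = c("(Intercept)" = 0.4, x = 0.9),
                                    sigma2_a = 0, seed = 7)
  fit <- fit_binary_pmm(response ~ x, dat, tr,
                        settings = mcmc_settings(6000, 1000, 5),
                        priors = pmm_priors(V = 1e-8, nu = 1e6), seed = 8)
  ml <- coef(glm(response ~ x, binomial, dat))
  expect_lt(mean(fit$chains[, "sigma2_a"]), 0.01)
  expect_equal(unname(coef(fit)), unname(ml), tolerance = 0.25)
})
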