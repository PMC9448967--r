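# Pagel's dependent/independent models of correlated evolution for two binary
# characters: the joint states are 1=(0,0), 2=(0,1), 3=(1,0), 4=(1,1) with the
# first digit the state of trait x and the second the state of trait y. Only
# single changes are permitted, giving eight transition rates; dual changes
# (1<->4, 2<->3) have rate zero.

RATE_NAMES <- c("q12", "q21", "q13", "q31", "q24", "q42", "q34", "q43")

# row/column of Q addressed by each rate name
RATE_CELLS <- matrix(c(1,2, 2,1, 1,3, 3,1, 2,4, 4,2, 3,4, 4,3),
                     ncol = 2, byrow = TRUE,
                     dimnames = list(RATE_NAMES, c("from", "to")))

#' Transition rates of the dependent model
#'
#' The eight permitted single-change rates among the four joint states of two
#' binary characters. `q12` is the rate from (0,0) to (0,1): a gain of trait y
#' while trait x is absent; `q34` the same gain while trait x is present, and
#' so on. Under the dependent model all eight vary freely.
#'
#' @param q12,q21,q13,q31,q24,q42,q34,q43 nonnegative rates.
#' @return Named numeric vector of class `"dependent_rates"`.
#' @export
dependent_rates <- function(q12, q21, q13, q31, q24, q42, q34, q43) {
  r <- c(q12 = q12, q21 = q21, q13 = q13, q31 = q31,
         q24 = q24, q42 = q42, q34 = q34, q43 = q43)
  if (any(!is.finite(r)) || any(r < 0)) stop("rates must be finite and nonnegative")
  structure(r, class = "dependent_rates")
}

#' Transition rates of the independent model
#'
#' Each trait gains and loses independently of the other's state:
#' `alpha1`/`beta1` are the gain/loss rates of trait x, `alpha2`/`beta2` of
#' trait y. Mapped into the joint-state rates as q13 = q24 = alpha1,
#' q31 = q42 = beta1, q12 = q34 = alpha2, q21 = q43 = beta2.
#'
#' @param alpha1,beta1,alpha2,beta2 nonnegative rates.
#' @return Named numeric vector of class `"independent_rates"`.
#' @export
independent_rates <- function(alpha1, beta1, alpha2, beta2) {
  r <- c(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2)
  if (any(!is.finite(r)) || any(r < 0)) stop("rates must be finite and nonnegative")
  structure(r, class = "independent_rates")
}

independent_to_dependent <- function(r) {
  dependent_rates(q12 = r[["alpha2"]], q21 = r[["beta2"]],
                  q13 = r[["alpha1"]], q31 = r[["beta1"]],
                  q24 = r[["alpha1"]], q42 = r[["beta1"]],
                  q34 = r[["alpha2"]], q43 = r[["beta2"]])
}

#' Build the 4x4 generator matrix of the joint chain
#'
#' @param rates a [dependent_rates()], [independent_rates()], or named vector
#'   using the eight permitted rate names.
#' @return 4x4 generator: off-diagonals are the supplied rates, dual-change
#'   cells are structurally zero, rows sum to zero.
#' @export
build_generator <- function(rates) {
  if (inherits(rates, "independent_rates")) rates <- independent_to_dependent(rates)
  if (!inherits(rates, "dependent_rates")) {
    if (is.null(names(rates))) stop("rates must be named")
    extra <- setdiff(names(rates), RATE_NAMES)
    if (length(extra))
      stop("not a permitted transition rate: ", paste(extra, collapse = ", "),
           " (dual changes are forbidden)")
    if (!setequal(names(rates), RATE_NAMES)) stop("all eight rates are required")
    rates <- do.call(dependent_rates, as.list(rates[RATE_NAMES]))
  }
  Q <- matrix(0, 4, 4, dimnames = list(c("00","01","10","11"), c("00","01","10","11")))
  for (nm in RATE_NAMES) Q[RATE_CELLS[nm, 1], RATE_CELLS[nm, 2]] <- rates[[nm]]
  diag(Q) <- -rowSums(Q)
  Q
}

#' CTMC transition probabilities over a branch
#'
#' Computes `expm(Q t)` by eigen-decomposition, falling back to a
#' scaling-and-squaring evaluation ([ape::matexpo()]) when the eigenvector
#' matrix is ill-conditioned. Rows are renormalized to sum to one and
#' round-off negatives are clamped at zero.
#'
#' @param Q generator matrix (rows summing to zero).
#' @param t branch length, `t >= 0`.
#' @return Stochastic matrix of the same dimension as `Q`.
#' @export
transition_probabilities <- function(Q, t) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  if (!is.finite(t) || t < 0) stop("branch length must be nonnegative")
  if (t == 0 || all(Q == 0)) return(diag(nrow(Q)))
  E <- eigen(Q)
  P <- NULL
  if (all(is.finite(E$vectors)) && rcond(E$vectors) > 1e-12)
    P <- Re(E$vectors %*% diag(exp(E$values * t), nrow(Q)) %*% solve(E$vectors))
  if (is.null(P) || any(!is.finite(P)) || any(P < -1e-8))
    P <- ape::matexpo(Q * t)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Pair of aligned binary traits
#'
#' @param taxa ordered taxon labels.
#' @param x,y aligned 0/1 vectors (trait x is the first digit of the joint
#'   state, trait y the second).
#' @param orientation `"standard"` when state 1 of each trait is the derived
#'   state of interest in both characters; `"inverted"` when state 0 of one
#'   character is associated with state 1 of the other, which swaps the
#'   temporal-order comparisons in [test_battery()].
#' @param names optional character vector of length 2 naming traits x and y
#'   (used in test meaning labels).
#' @return Object of class `"binary_trait_pair"`.
#' @export
binary_trait_pair <- function(taxa, x, y, orientation = c("standard", "inverted"),
                              names = c("trait x", "trait y")) {
  orientation <- match.arg(orientation)
  if (length(taxa) != length(x) || length(x) != length(y))
    stop("taxa, x and y must have equal lengths")
  if (!all(x %in% c(0, 1)) || !all(y %in% c(0, 1))) stop("traits must be 0/1")
  if (anyDuplicated(taxa)) stop("duplicated taxa")
  structure(list(taxa = as.character(taxa), x = as.integer(x), y = as.integer(y),
                 orientation = orientation, names = names),
            class = "binary_trait_pair")
}

joint_states <- function(pair) 1L + 2L * pair$x + pair$y

root_distribution <- function(Q, root_rule) {
  if (is.numeric(root_rule)) {
    stopifnot(length(root_rule) == 4L, all(root_rule >= 0), sum(root_rule) > 0)
    return(root_rule / sum(root_rule))
  }
  switch(match.arg(root_rule, c("uniform", "stationary")),
         uniform = rep(0.25, 4),
         stationary = {
           ns <- t(Q)
           ns <- rbind(ns, rep(1, 4))
           pi <- qr.solve(ns, c(0, 0, 0, 0, 1))
           pmax(pi, 0) / sum(pmax(pi, 0))
         })
}

#' Pruning log-likelihood of a binary trait pair
#'
#' Felsenstein's pruning algorithm over the 4-state joint chain; the engine
#' behind both the dependent and independent models.
#'
#' @param tree rooted `phylo` with branch lengths; tips must cover the pair's
#'   taxa. Polytomies are allowed.
#' @param pair a [binary_trait_pair()].
#' @param Q 4x4 generator from [build_generator()].
#' @param root_rule `"uniform"` (default), `"stationary"`, or a length-4
#'   probability vector over the joint states at the root.
#' @return Log-likelihood (scalar).
#' @export
pruning_loglik <- function(tree, pair, Q, root_rule = "uniform") {
  validate_phylogeny(tree)
  idx <- match(tree$tip.label, pair$taxa)
  if (anyNA(idx))
    stop("tip state missing for: ",
         paste(tree$tip.label[is.na(idx)], collapse = ", "))
  states <- joint_states(pair)[idx]
  tr <- ape::reorder.phylo(tree, "postorder")
  pruning_loglik_cpp(tr$edge, tr$edge.length, length(tr$tip.label), tr$Nnode,
                     as.integer(states), Q, root_distribution(Q, root_rule))
}

# ---- priors and settings ----------------------------------------------------

#' Hyper-exponential prior on transition rates
#'
#' Every rate is exponential with mean `m`, and `m` itself is uniform on
#' (0, `hyper_max`); `m` is resampled within the chain.
#'
#' @param hyper_max upper bound of the uniform hyper-prior on the exponential
#'   mean (default 10).
#' @return Object of class `"rate_prior"`.
#' @export
rate_prior <- function(hyper_max = 10) {
  stopifnot(is.numeric(hyper_max), hyper_max > 0)
  structure(list(hyper_max = hyper_max), class = "rate_prior")
}

#' MCMC schedule
#'
#' Defaults follow the long-schedule convention used for these analyses:
#' 2,000,000 iterations, 100,000 burn-in, thinning 2,000, so that
#' `(iterations - burn_in) / thinning = 950` draws are retained. Reduced
#' schedules are used for simulation studies; the retained-draw identity must
#' hold exactly.
#'
#' @param iterations,burn_in,thinning MCMC schedule; `(iterations - burn_in)`
#'   must be a positive multiple of `thinning`.
#' @return Object of class `"mcmc_settings"` with a `retained` field.
#' @export
mcmc_settings <- function(iterations = 2e6, burn_in = 1e5, thinning = 2000) {
  stopifnot(iterations > burn_in, burn_in >= 0, thinning >= 1)
  kept <- (iterations - burn_in) / thinning
  if (kept != round(kept) || kept < 1)
    stop("(iterations - burn_in) must be a positive multiple of thinning")
  structure(list(iterations = as.numeric(iterations), burn_in = as.numeric(burn_in),
                 thinning = as.numeric(thinning), retained = as.integer(kept)),
            class = "mcmc_settings")
}

#' Stepping-stone schedule
#'
#' @param stones number of stones (power-posterior steps; default 100).
#' @param iterations_per_stone MCMC iterations sampled at each stone
#'   (default 10,000).
#' @param alpha shape of the Beta(alpha, 1) quantile schedule for the powers;
#'   the default 0.4 concentrates stones near the prior.
#' @return Object of class `"ss_settings"`; the powers rise strictly from 0
#'   to 1.
#' @export
stepping_stone_settings <- function(stones = 100, iterations_per_stone = 10000,
                                    alpha = 0.4) {
  stopifnot(stones >= 2, iterations_per_stone >= 10, alpha > 0)
  beta <- (seq(0, stones, by = 1) / stones)^(1 / alpha)
  structure(list(stones = as.integer(stones),
                 iterations_per_stone = as.integer(iterations_per_stone),
                 beta = beta), class = "ss_settings")
}

# free-rate layout for a model: list(map = integer index of each of the 8
# joint rates into the free-parameter vector (NA = fixed), fixed = values for
# fixed rates, k = number of free parameters, names = free parameter names)
model_layout <- function(model = c("dependent", "independent", "restricted"),
                         restriction = NULL, fixed = NULL) {
  model <- match.arg(model)
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), RATE_NAMES)
    if (length(bad)) stop("cannot fix unknown rate(s): ", paste(bad, collapse = ", "))
  }
  if (model == "independent") {
    free_names <- c("alpha1", "beta1", "alpha2", "beta2")
    assign <- c(q12 = "alpha2", q21 = "beta2", q13 = "alpha1", q31 = "beta1",
                q24 = "alpha1", q42 = "beta1", q34 = "alpha2", q43 = "beta2")
  } else {
    assign <- setNames(RATE_NAMES, RATE_NAMES)
    if (model == "restricted") {
      if (is.null(restriction) || length(restriction) != 2L)
        stop("a restriction names two distinct permitted rates")
      bad <- setdiff(restriction, RATE_NAMES)
      if (length(bad))
        stop("restriction on a structurally zero or unknown rate: ",
             paste(bad, collapse = ", "))
      if (restriction[1] == restriction[2]) stop("restriction must name two distinct rates")
      assign[restriction[2]] <- restriction[1]
    }
    free_names <- unique(unname(assign))
  }
  fixed_vals <- numeric(0)
  if (!is.null(fixed)) {
    # fixing a joint rate fixes its whole shared parameter
    fixed_par <- assign[names(fixed)]
    fixed_vals <- setNames(as.numeric(fixed), fixed_par)
    free_names <- setdiff(free_names, fixed_par)
  }
  list(assign = assign, free = free_names, fixed = fixed_vals,
       k = length(free_names), model = model, restriction = restriction)
}

layout_rates <- function(layout, theta) {
  par <- c(theta, layout$fixed)
  vapply(RATE_NAMES, function(nm) par[[layout$assign[[nm]]]], numeric(1))
}

# log prior density of the free rates given hyper-mean m
log_rate_prior <- function(theta, m) sum(dexp(theta, rate = 1 / m, log = TRUE))

#' Fit a correlated-evolution model by MCMC
#'
#' Samples the posterior of the transition rates of Pagel's dependent,
#' independent, or rate-restricted dependent model under the
#' hyper-exponential prior. With `rj = TRUE` a reversible-jump move set is
#' added: each free rate is assigned to a zero class or to a shared-value bin
#' (uniform prior over such partitions, new bin values proposed from the
#' prior), and the percentage of retained samples spent in the zero class is
#' reported as the rate's Z-value.
#'
#' @param tree rooted `phylo`.
#' @param pair a [binary_trait_pair()].
#' @param model `"dependent"`, `"independent"`, or `"restricted"`.
#' @param restriction for `"restricted"`: two rate names constrained equal.
#' @param prior a [rate_prior()].
#' @param settings an [mcmc_settings()].
#' @param rj logical: reversible-jump over the zero class / shared bins.
#' @param root_rule see [pruning_loglik()].
#' @param seed integer seed; the run is reproducible given the seed.
#' @param likelihood set `FALSE` for a prior-only run (sampler validation).
#' @param proposal_sd log-scale random-walk step for rate updates.
#' @return Object of class `"pagel_fit"`: retained `chains` (one column per
#'   joint rate, zeros recorded when a rate sits in the zero class),
#'   `rate_summary` (posterior mean over all retained draws, mean over
#'   nonzero draws, Z-value), `loglik` trace, acceptance rates and settings.
#' @export
fit_pagel <- function(tree, pair, model = c("dependent", "independent", "restricted"),
                      restriction = NULL, prior = rate_prior(),
                      settings = mcmc_settings(), rj = FALSE,
                      root_rule = "uniform", seed = 1L, likelihood = TRUE,
                      proposal_sd = 0.75) {
  model <- match.arg(model)
  layout <- model_layout(model, restriction)
  set.seed(seed)
  loglik_fun <- make_loglik(tree, pair, layout, root_rule, likelihood)
  run <- pagel_chain(loglik_fun, layout, prior, settings, rj, proposal_sd,
                     power = 1)
  kept <- run$rates
  colnames(kept) <- RATE_NAMES
  zsum <- 100 * colMeans(kept == 0)
  mean_nonzero <- vapply(seq_len(ncol(kept)), function(j) {
    nz <- kept[, j][kept[, j] > 0]
    if (length(nz)) mean(nz) else 0
  }, numeric(1))
  rate_summary <- data.frame(rate = RATE_NAMES,
                             mean = colMeans(kept),
                             mean_nonzero = mean_nonzero,
                             z_value = zsum,
                             row.names = NULL)
  structure(list(model = model, restriction = restriction,
                 chains = kept, rate_summary = rate_summary,
                 loglik = run$loglik, hyper_mean = run$m,
                 acceptance = run$acceptance, settings = settings,
                 prior = prior, rj = rj, seed = seed,
                 n_tips = length(tree$tip.label)),
            class = "pagel_fit")
}

make_loglik <- function(tree, pair, layout, root_rule, likelihood) {
  if (!likelihood) return(function(theta) 0)
  validate_phylogeny(tree)
  idx <- match(tree$tip.label, pair$taxa)
  if (anyNA(idx))
    stop("tip state missing for: ", paste(tree$tip.label[is.na(idx)], collapse = ", "))
  states <- as.integer(joint_states(pair)[idx])
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  edge <- tr$edge
  elen <- tr$edge.length
  # joint-rate vector by integer indexing into c(free, fixed) parameters
  par_names <- c(layout$free, names(layout$fixed))
  assign_idx <- match(unname(layout$assign[RATE_NAMES]), par_names)
  fixed <- unname(layout$fixed)
  stationary_root <- is.character(root_rule) && root_rule[1] == "stationary"
  rootp <- if (stationary_root) NULL else
    if (is.numeric(root_rule)) root_rule / sum(root_rule) else rep(0.25, 4)
  function(theta) {
    rates8 <- c(theta, fixed)[assign_idx]
    rp <- if (stationary_root)
      root_distribution(build_generator(setNames(rates8, RATE_NAMES)), "stationary")
    else rootp
    pruning_loglik_rates_cpp(edge, elen, ntip, nnode, states, rates8, rp)
  }
}

# Core Metropolis(-within-Gibbs) sampler for the rate models, with optional
# reversible jump and a power on the likelihood (for stepping stones).
# Bin-value proposals are log-scale random walks whose scales adapt toward a
# ~30% acceptance rate during burn-in (frozen afterwards, so the retained
# chain is a fixed Markov kernel). With rj on, the jump moves start halfway
# through burn-in so the fixed-dimension chain locates the mode first.
# Returns retained joint-rate draws, log-likelihood trace, hyper-mean draws.
pagel_chain <- function(loglik_fun, layout, prior, settings, rj, proposal_sd,
                        power = 1, init = NULL) {
  k <- layout$k
  m <- if (!is.null(init$m)) init$m else prior$hyper_max / 2
  if (!is.null(init$group)) {
    group <- init$group
    bins <- init$bins
    sds <- init$sds
  } else {
    group <- seq_len(k)                      # bin id per free rate; 0 = zero class
    start <- if (!is.null(init$theta)) unname(init$theta) else rexp(k, 1 / m)
    bins <- setNames(start, as.character(seq_len(k)))  # value per bin id
    sds <- setNames(rep(proposal_sd, k), names(bins))  # per-bin proposal scale
  }
  cur_theta <- function() {
    th <- numeric(k); names(th) <- layout$free
    nz <- group > 0
    th[nz] <- unname(bins[as.character(group[nz])])
    th
  }
  theta <- cur_theta()
  ll <- loglik_fun(theta)
  kept_n <- settings$retained
  rates_out <- matrix(NA_real_, kept_n, 8)
  ll_out <- numeric(kept_n)
  m_out <- numeric(kept_n)
  acc <- c(rate = 0, rate_n = 0, jump = 0, jump_n = 0)
  keep_i <- 0
  n_iter <- settings$iterations
  rj_start <- floor(settings$burn_in / 2)
  for (it in seq_len(n_iter)) {
    adapting <- it <= settings$burn_in
    # update each bin value (log-scale random walk)
    for (b in names(bins)) {
      if (!any(group == as.integer(b))) next
      old <- bins[[b]]
      sd_b <- sds[[b]]
      newv <- old * exp(rnorm(1, 0, sd_b))
      th_new <- { th <- theta; th[group == as.integer(b)] <- newv; th }
      ll_new <- loglik_fun(th_new)
      # the prior applies once per bin value, not per member rate; log(newv/old)
      # is the Jacobian of the log-scale random walk
      lacc <- power * (ll_new - ll) +
        (dexp(newv, 1 / m, log = TRUE) - dexp(old, 1 / m, log = TRUE)) +
        log(newv) - log(old)
      acc[["rate_n"]] <- acc[["rate_n"]] + 1
      took <- log(runif(1)) < lacc
      if (took) {
        bins[[b]] <- newv; theta <- th_new; ll <- ll_new
        acc[["rate"]] <- acc[["rate"]] + 1
      }
      if (adapting)
        sds[[b]] <- min(5, max(0.02, sd_b * exp(0.25 * ((if (took) 1 else 0) - 0.3) / sqrt(1 + it / 50))))
    }
    # update hyper-mean m: reflected random walk on (0, hyper_max), with an
    # independence draw from the uniform hyper-prior every 5th iteration
    vals <- bins[as.character(unique(group[group > 0]))]
    if (it %% 5L == 0L) {
      m_new <- runif(1, 0, prior$hyper_max)
    } else {
      m_new <- m + rnorm(1, 0, prior$hyper_max / 4)
      while (m_new < 0 || m_new > prior$hyper_max) {
        if (m_new < 0) m_new <- -m_new
        if (m_new > prior$hyper_max) m_new <- 2 * prior$hyper_max - m_new
      }
    }
    lacc <- sum(dexp(vals, 1 / m_new, log = TRUE)) - sum(dexp(vals, 1 / m, log = TRUE))
    if (length(vals) == 0) lacc <- 0
    if (log(runif(1)) < lacc) m <- m_new
    # reversible jump: reassign rates between the zero class and value bins
    if (rj && k >= 1 && it > rj_start) {
      for (rep_rj in 1:2) {
        i <- sample.int(k, 1)
        res <- rj_move(i, group, bins, theta, ll, loglik_fun, m, power, layout)
        acc[["jump_n"]] <- acc[["jump_n"]] + 1
        if (res$accepted) {
          group <- res$group; theta <- res$theta; ll <- res$ll
          newb <- setdiff(names(res$bins), names(bins))
          bins <- res$bins
          if (length(newb)) sds[newb] <- proposal_sd
          sds <- sds[names(bins)]
          acc[["jump"]] <- acc[["jump"]] + 1
        }
      }
    }
    if (it > settings$burn_in && (it - settings$burn_in) %% settings$thinning == 0) {
      keep_i <- keep_i + 1
      rates_out[keep_i, ] <- layout_rates(layout, theta)
      ll_out[keep_i] <- ll
      m_out[keep_i] <- m
    }
  }
  list(rates = rates_out, loglik = ll_out, m = m_out,
       acceptance = c(rate = unname(acc[["rate"]] / max(1, acc[["rate_n"]])),
                      jump = if (rj) unname(acc[["jump"]] / max(1, acc[["jump_n"]])) else NA_real_),
       state = list(theta = theta, m = m, group = group, bins = bins, sds = sds))
}

# One reversible-jump reassignment of free rate i among {zero class, existing
# bins, new bin}. Partition prior uniform; new bin values proposed from the
# rate prior, so prior and proposal densities cancel and the acceptance ratio
# reduces to the (powered) likelihood ratio times the destination-count ratio.
rj_move <- function(i, group, bins, theta, ll, loglik_fun, m, power, layout) {
  k <- length(group)
  src <- group[i]
  occupied <- unique(group[group > 0])
  # destinations available after removing i from its block
  other_occ <- unique(group[-i][group[-i] > 0])
  dests <- c(0L, other_occ, -1L)            # -1 codes "new bin"
  dests <- setdiff(dests, src)
  if (src == 0L) dests <- setdiff(dests, 0L)
  if (length(dests) == 0L) return(list(accepted = FALSE))
  dest <- dests[sample.int(length(dests), 1)]
  group_new <- group
  bins_new <- bins
  if (dest == -1L) {
    newid <- max(0L, as.integer(names(bins))) + 1L
    bins_new[[as.character(newid)]] <- rexp(1, 1 / m)
    group_new[i] <- newid
  } else group_new[i] <- dest
  # drop emptied source bin
  if (src > 0L && !any(group_new == src)) bins_new <- bins_new[names(bins_new) != as.character(src)]
  th_new <- theta
  th_new[i] <- if (group_new[i] == 0L) 0 else bins_new[[as.character(group_new[i])]]
  ll_new <- loglik_fun(th_new)
  # reverse destination count
  other_occ_rev <- unique(group_new[-i][group_new[-i] > 0])
  dests_rev <- c(0L, other_occ_rev, -1L)
  dests_rev <- setdiff(dests_rev, group_new[i])
  if (group_new[i] == 0L) dests_rev <- setdiff(dests_rev, 0L)
  lacc <- power * (ll_new - ll) + log(length(dests)) - log(length(dests_rev))
  if (is.finite(lacc) && log(runif(1)) < lacc)
    list(accepted = TRUE, group = group_new, bins = bins_new, theta = th_new, ll = ll_new)
  else list(accepted = FALSE)
}

#' @export
print.pagel_fit <- function(x, ...) {
  cat(sprintf("Pagel %s model%s: %d retained draws, %d tips%s\n",
              x$model,
              if (!is.null(x$restriction))
                sprintf(" (restricted: %s = %s)", x$restriction[1], x$restriction[2]) else "",
              nrow(x$chains), x$n_tips,
              if (x$rj) ", reversible jump" else ""))
  print(x$rate_summary, digits = 3)
  invisible(x)
}

#' @export
summary.pagel_fit <- function(object, ...) {
  ac <- acf(object$loglik, lag.max = 1, plot = FALSE)$acf[2]
  out <- list(rate_summary = object$rate_summary,
              loglik_mean = mean(object$loglik),
              loglik_lag1 = ac,
              acceptance = object$acceptance)
  class(out) <- "summary.pagel_fit"
  out
}

#' @export
print.summary.pagel_fit <- function(x, ...) {
  print(x$rate_summary, digits = 3)
  cat(sprintf("mean logLik %.3f; lag-1 autocorrelation of logLik %.3f\n",
              x$loglik_mean, x$loglik_lag1))
  invisible(x)
}

#' @export
coef.pagel_fit <- function(object, ...) setNames(object$rate_summary$mean, RATE_NAMES)

#' @export
plot.pagel_fit <- function(x, ...) {
  oldpar <- graphics::par(mfrow = c(3, 3), mar = c(3, 3, 2, 1))
  on.exit(graphics::par(oldpar))
  for (nm in RATE_NAMES)
    plot(x$chains[, nm], type = "l", main = nm, xlab = "", ylab = "")
  plot(x$loglik, type = "l", main = "logLik", xlab = "", ylab = "")
  invisible(x)
}

#' Stepping-stone log marginal likelihood
#'
#' Integrates the likelihood against the hyper-exponential prior along a path
#' of power posteriors. Stones are placed at quantiles of a Beta(alpha, 1)
#' distribution and visited from the posterior toward the prior; each stone's
#' importance ratio bridges adjacent powers. Deterministic given `seed`.
#' With every rate fixed (no free parameters) the marginal likelihood equals
#' the likelihood and is returned exactly without sampling.
#'
#' @inheritParams fit_pagel
#' @param ss a [stepping_stone_settings()].
#' @param fixed optional named vector of rates to hold constant.
#' @return Log marginal likelihood (scalar) with attribute `"path"` holding
#'   the per-stone contributions.
#' @export
stepping_stone_logml <- function(tree, pair, model = c("dependent", "independent", "restricted"),
                                 restriction = NULL, prior = rate_prior(),
                                 ss = stepping_stone_settings(), fixed = NULL,
                                 root_rule = "uniform", seed = 1L,
                                 proposal_sd = 0.75) {
  model <- match.arg(model)
  layout <- model_layout(model, restriction, fixed)
  loglik_fun <- make_loglik(tree, pair, layout, root_rule, TRUE)
  if (layout$k == 0L) {
    th <- numeric(0)
    return(structure(loglik_fun(th), path = numeric(0)))
  }
  set.seed(seed)
  beta <- ss$beta
  K <- ss$stones
  n_it <- ss$iterations_per_stone
  per_stone <- numeric(K)
  # mini schedule reused at each stone; small burn-in per stone, no thinning
  stone_burn <- max(10L, round(0.1 * n_it))
  sched <- mcmc_settings(iterations = n_it + stone_burn, burn_in = stone_burn, thinning = 1)
  init <- NULL
  for (j in K:1) {
    run <- pagel_chain(loglik_fun, layout, prior, sched, rj = FALSE,
                       proposal_sd = proposal_sd, power = beta[j], init = init)
    init <- run$state
    d <- beta[j + 1] - beta[j]
    mx <- max(run$loglik)
    per_stone[j] <- d * mx + log(mean(exp(d * (run$loglik - mx))))
  }
  structure(sum(per_stone), path = per_stone)
}

#' Combine replicate marginal likelihoods into a Bayes-factor summary
#'
#' With `n` replicate marginal-likelihood estimates per model, all pairings
#' give `n^2` Bayes-factor estimates `BF = 2 (logML1 - logML2)`; their mean,
#' 95% interval (2.5/97.5 percentiles) and evidence category are reported.
#'
#' @param logml1 numeric vector of log marginal likelihoods of the focal
#'   model (e.g. dependent, or unrestricted).
#' @param logml2 log marginal likelihoods of the reference model (independent
#'   or restricted).
#' @param labels length-2 character: model names for printing.
#' @return Object of class `"bf_summary"`: `bf_values`, `mean`, `lci`, `uci`,
#'   `category`.
#' @export
bayes_factor_summary <- function(logml1, logml2,
                                 labels = c("model 1", "model 2")) {
  if (!length(logml1) || !length(logml2)) stop("empty marginal-likelihood input")
  bf <- as.numeric(2 * outer(logml1, logml2, "-"))
  ci <- unname(quantile(bf, c(0.025, 0.975), type = 7))
  structure(list(bf_values = bf, mean = mean(bf), lci = ci[1], uci = ci[2],
                 category = interpret_bf(mean(bf)), labels = labels),
            class = "bf_summary")
}

#' @export
print.bf_summary <- function(x, ...) {
  cat(sprintf("BF [%s vs %s] = %.2f (95%% CI %.2f/%.2f), evidence: %s (%d estimates)\n",
              x$labels[1], x$labels[2], x$mean, x$lci, x$uci, x$category,
              length(x$bf_values)))
  invisible(x)
}

#' Interpret a Bayes factor
#'
#' `BF < 2`: no evidence; `2 <= BF <= 5`: positive evidence; `BF > 5`: strong
#' evidence that the compared models differ.
#'
#' @param bf mean Bayes factor.
#' @return `"none"`, `"positive"`, or `"strong"`.
#' @export
interpret_bf <- function(bf) {
  stopifnot(is.finite(bf))
  if (bf < 2) "none" else if (bf <= 5) "positive" else "strong"
}

#' Directional rate-restriction test
#'
#' Compares the unrestricted dependent model against a dependent model in
#' which two named rates are constrained equal. Both models' marginal
#' likelihoods are estimated `n_runs` times by stepping-stone sampling; all
#' pairings yield the Bayes-factor summary. The direction reports which rate
#' has the smaller posterior mean under the unrestricted model.
#'
#' @inheritParams fit_pagel
#' @param restriction two permitted rate names to constrain equal.
#' @param ss stepping-stone schedule.
#' @param n_runs replicate runs per model (default 10, giving 100 BF values).
#' @param posterior_settings MCMC schedule for the unrestricted posterior used
#'   to infer the direction.
#' @param meaning optional meaning label; derived from the comparison and the
#'   pair's trait names when `NULL`.
#' @return Object of class `"directional_test"`: restriction, `bf` (a
#'   [bayes_factor_summary()]), `direction` string, rate means, meaning label.
#' @export
directional_test <- function(tree, pair, restriction, prior = rate_prior(),
                             ss = stepping_stone_settings(), n_runs = 10,
                             posterior_settings = mcmc_settings(),
                             root_rule = "uniform", seed = 1L, meaning = NULL,
                             proposal_sd = 0.75) {
  layout <- model_layout("restricted", restriction)  # validates the restriction
  seeds <- seed + seq_len(2 * n_runs)
  unres <- vapply(seq_len(n_runs), function(r)
    stepping_stone_logml(tree, pair, "dependent", prior = prior, ss = ss,
                         root_rule = root_rule, seed = seeds[r],
                         proposal_sd = proposal_sd), numeric(1))
  restr <- vapply(seq_len(n_runs), function(r)
    stepping_stone_logml(tree, pair, "restricted", restriction = restriction,
                         prior = prior, ss = ss, root_rule = root_rule,
                         seed = seeds[n_runs + r], proposal_sd = proposal_sd),
    numeric(1))
  bf <- bayes_factor_summary(unres, restr, labels = c("unrestricted", "restricted"))
  post <- fit_pagel(tree, pair, "dependent", prior = prior,
                    settings = posterior_settings, root_rule = root_rule,
                    seed = seed, proposal_sd = proposal_sd)
  mns <- coef(post)[restriction]
  direction <- if (bf$mean < 2)
    sprintf("%s ≈ %s", restriction[1], restriction[2])
  else if (mns[1] < mns[2])
    sprintf("%s < %s", restriction[1], restriction[2])
  else sprintf("%s > %s", restriction[1], restriction[2])
  if (is.null(meaning)) meaning <- meaning_label(restriction, direction, pair$names)
  structure(list(restriction = restriction, bf = bf, direction = direction,
                 rate_means = mns, meaning = meaning,
                 logml_unrestricted = unres, logml_restricted = restr),
            class = "directional_test")
}

#' @export
print.directional_test <- function(x, ...) {
  cat(sprintf("%s: BF = %.2f (%.2f/%.2f) [%s]\n  %s\n",
              x$direction, x$bf$mean, x$bf$lci, x$bf$uci, x$bf$category, x$meaning))
  invisible(x)
}

# Sentence template for a contingent-change or temporal-order comparison.
# Trait x is the first digit of the joint state, trait y the second.
meaning_label <- function(restriction, direction, names) {
  key <- paste(sort(restriction), collapse = "/")
  nx <- names[1]; ny <- names[2]
  templates <- c(
    "q12/q34" = sprintf("whether gain of %s depends on the state of %s (contingent change)", ny, nx),
    "q21/q43" = sprintf("whether loss of %s depends on the state of %s (contingent change)", ny, nx),
    "q13/q24" = sprintf("whether gain of %s depends on the state of %s (contingent change)", nx, ny),
    "q31/q42" = sprintf("whether loss of %s depends on the state of %s (contingent change)", nx, ny),
    "q12/q13" = sprintf("which of %s and %s is gained first from joint absence (temporal order)", ny, nx),
    "q42/q43" = sprintf("which of %s and %s is lost first from joint presence (temporal order)", nx, ny),
    "q31/q34" = sprintf("temporal order of changes in %s and %s from the (1,0) state (inverted orientation)", nx, ny),
    "q21/q24" = sprintf("temporal order of changes in %s and %s from the (0,1) state (inverted orientation)", nx, ny))
  lbl <- templates[key]
  if (is.na(lbl)) lbl <- sprintf("comparison of rates %s and %s", restriction[1], restriction[2])
  sprintf("%s; resolved as %s", unname(lbl), direction)
}

#' Battery of contingent-change and temporal-order tests
#'
#' Runs the six standard directional tests for a trait pair. In the standard
#' orientation the comparisons are q12/q34, q21/q43, q13/q24, q31/q42
#' (contingent change) and q12/q13, q42/q43 (temporal order). When the pair's
#' orientation is `"inverted"` (state 0 of one character associated with
#' state 1 of the other) the temporal-order comparisons become q31/q34 and
#' q21/q24.
#'
#' @inheritParams directional_test
#' @return List of six [directional_test()] results.
#' @export
test_battery <- function(tree, pair, prior = rate_prior(),
                         ss = stepping_stone_settings(), n_runs = 10,
                         posterior_settings = mcmc_settings(),
                         root_rule = "uniform", seed = 1L, proposal_sd = 0.75) {
  comparisons <- battery_comparisons(pair$orientation)
  out <- vector("list", length(comparisons))
  for (i in seq_along(comparisons)) {
    out[[i]] <- directional_test(tree, pair, comparisons[[i]], prior = prior,
                                 ss = ss, n_runs = n_runs,
                                 posterior_settings = posterior_settings,
                                 root_rule = root_rule,
                                 seed = seed + 1000L * i,
                                 proposal_sd = proposal_sd)
  }
  names(out) <- vapply(comparisons, paste, character(1), collapse = "_vs_")
  out
}

battery_comparisons <- function(orientation = c("standard", "inverted")) {
  orientation <- match.arg(orientation)
  base <- list(c("q12", "q34"), c("q21", "q43"), c("q13", "q24"), c("q31", "q42"))
  temporal <- if (orientation == "standard")
    list(c("q12", "q13"), c("q42", "q43"))
  else
    list(c("q31", "q34"), c("q21", "q24"))
  c(base, temporal)
}
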