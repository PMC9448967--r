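# Whole-analysis drivers: multi-tree and multi-run loops, aggregation across
# trees, dichotomization sweeps, the autocorrelation escalation rule, and the
# report bundle. Aggregation is always the plain arithmetic mean of the
# per-tree quantities, recomputable from the persisted per-tree results.

#' Binary molt response from a species table
#'
#' @param table species table.
#' @param timing_rule passed to [classify_prealternate()].
#' @return Named 0/1 vector (names = species).
#' @export
molt_response <- function(table, timing_rule = c("inclusive", "strict")) {
  timing_rule <- match.arg(timing_rule)
  out <- vapply(seq_len(nrow(table)), function(i)
    classify_prealternate(row_molt(table, i), timing_rule), integer(1))
  setNames(out, table$species)
}

#' Binary molt-extent response (complete = 1) for molting species
#'
#' @inheritParams molt_response
#' @return Named 0/1 vector over the species with a pre-alternate molt under
#'   the chosen timing rule.
#' @export
extent_response <- function(table, timing_rule = c("inclusive", "strict")) {
  pres <- molt_response(table, timing_rule)
  keep <- which(pres == 1L)
  out <- vapply(keep, function(i)
    as.integer(classify_extent(row_molt(table, i)) == "complete"), integer(1))
  setNames(out, table$species[keep])
}

#' Fit the binary mixed model over a set of trees and average
#'
#' Fits one model per tree with per-tree seeds derived from the master seed
#' and averages every reported parameter (estimate, interval bounds, ESS,
#' autocorrelation, Geweke z, pMCMC; heritability estimate and interval
#' bounds) arithmetically across trees.
#'
#' @inheritParams fit_binary_pmm
#' @param trees a `tree_set` (or `multiPhylo`); every tree must contain all
#'   species in `data`.
#' @param seed master seed; tree `i` uses `seed + i`.
#' @param ... passed to [fit_binary_pmm()].
#' @return Object of class `"pmm_ensemble"`: `aggregate` table, `h2` means,
#'   and the list of per-tree fits.
#' @export
run_pmm_over_trees <- function(formula, data, trees, settings = mcmc_settings(),
                               priors = pmm_priors(), seed = 1L, ...) {
  species <- if ("species" %in% names(data)) as.character(data$species) else rownames(data)
  for (i in seq_along(trees)) {
    missing_sp <- setdiff(species, trees[[i]]$tip.label)
    if (length(missing_sp))
      stop("tree ", i, " is missing species: ", paste(missing_sp, collapse = ", "))
  }
  fits <- vector("list", length(trees))
  for (i in seq_along(trees))
    fits[[i]] <- fit_binary_pmm(formula, data, trees[[i]], settings = settings,
                                priors = priors, seed = seed + i, ...)
  num_cols <- c("estimate", "lci", "uci", "ess", "autocorrelation", "geweke_z", "pMCMC")
  agg <- fits[[1]]$summary_table
  for (cl in num_cols)
    agg[[cl]] <- rowMeans(vapply(fits, function(f) f$summary_table[[cl]],
                                 numeric(nrow(agg))))
  h2 <- rowMeans(vapply(fits, function(f) f$h2, numeric(3)))
  structure(list(aggregate = agg, h2 = h2, fits = fits, n_trees = length(trees),
                 seed = seed, settings = settings),
            class = "pmm_ensemble")
}

#' @export
print.pmm_ensemble <- function(x, digits = 3, ...) {
  cat(sprintf("Binary phylogenetic mixed model averaged over %d tree(s)\n", x$n_trees))
  print(format(x$aggregate, digits = digits), row.names = FALSE)
  cat(sprintf("Heritability (h2): %.3f (95%% %.3f/%.3f)\n",
              x$h2[["estimate"]], x$h2[["lci"]], x$h2[["uci"]]))
  invisible(x)
}

#' Apply the autocorrelation escalation rule to an MCMC schedule
#'
#' When the lag-1 autocorrelation of the monitored chain is at or above the
#' threshold (0.1), the thinning interval is doubled and the iteration count
#' enlarged so the number of retained draws is unchanged.
#'
#' @param settings an [mcmc_settings()].
#' @param r lag-1 autocorrelation from a completed run.
#' @param threshold escalation threshold (default 0.1).
#' @return Possibly escalated [mcmc_settings()].
#' @export
escalate_thinning <- function(settings, r, threshold = 0.1) {
  stopifnot(inherits(settings, "mcmc_settings"))
  if (!is.finite(r) || r < threshold) return(settings)
  new_thin <- settings$thinning * 2
  mcmc_settings(iterations = settings$burn_in + settings$retained * new_thin,
                burn_in = settings$burn_in, thinning = new_thin)
}

#' Dependent-vs-independent comparison over a set of trees
#'
#' For each tree and each of `n_runs` replicate runs, stepping-stone marginal
#' likelihoods of the dependent and independent models are estimated; per-run
#' means across trees are combined into the Bayes-factor summary (`n_runs^2`
#' BF estimates). The escalation rule is applied per tree to the dependent
#' model's log-likelihood trace before the marginal-likelihood runs.
#'
#' @inheritParams fit_pagel
#' @param trees a `tree_set` (or list of `phylo`).
#' @param ss stepping-stone schedule.
#' @param n_runs replicate runs per model per tree.
#' @param escalate logical: apply the autocorrelation escalation rule.
#' @param posterior_settings schedule for the escalation check.
#' @param max_escalations cap on successive doublings.
#' @return Object of class `"coevo_ensemble"`: `bf` (a
#'   [bayes_factor_summary()]), per-tree/per-run logML matrices, escalation
#'   log, and seeds.
#' @export
run_coevo_over_trees <- function(trees, pair, prior = rate_prior(),
                                 ss = stepping_stone_settings(), n_runs = 10,
                                 posterior_settings = mcmc_settings(),
                                 escalate = FALSE, max_escalations = 5,
                                 root_rule = "uniform", seed = 1L,
                                 proposal_sd = 0.75) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  n_tree <- length(trees)
  dep <- matrix(NA_real_, n_tree, n_runs)
  ind <- matrix(NA_real_, n_tree, n_runs)
  escalations <- integer(n_tree)
  for (ti in seq_len(n_tree)) {
    st <- posterior_settings
    if (escalate) {
      for (k in seq_len(max_escalations)) {
        fit <- fit_pagel(trees[[ti]], pair, "dependent", prior = prior,
                         settings = st, root_rule = root_rule,
                         seed = seed + 7919L * ti + k, proposal_sd = proposal_sd)
        r <- acf(fit$loglik, lag.max = 1, plot = FALSE)$acf[2]
        st2 <- escalate_thinning(st, r)
        if (identical(st2, st)) break
        st <- st2
        escalations[ti] <- escalations[ti] + 1L
        if (escalations[ti] == max_escalations)
          warning("escalation cap reached for tree ", ti)
      }
    }
    for (r in seq_len(n_runs)) {
      s <- seed + 1000L * ti + r
      dep[ti, r] <- stepping_stone_logml(trees[[ti]], pair, "dependent",
                                         prior = prior, ss = ss,
                                         root_rule = root_rule, seed = s,
                                         proposal_sd = proposal_sd)
      ind[ti, r] <- stepping_stone_logml(trees[[ti]], pair, "independent",
                                         prior = prior, ss = ss,
                                         root_rule = root_rule, seed = s + 500000L,
                                         proposal_sd = proposal_sd)
    }
  }
  bf <- bayes_factor_summary(colMeans(dep), colMeans(ind),
                             labels = c("dependent", "independent"))
  structure(list(bf = bf, dep_logml = dep, ind_logml = ind,
                 escalations = escalations, seed = seed, n_runs = n_runs),
            class = "coevo_ensemble")
}

#' @export
print.coevo_ensemble <- function(x, ...) {
  cat(sprintf("Correlated-evolution comparison over %d tree(s) x %d run(s)\n",
              nrow(x$dep_logml), x$n_runs))
  print(x$bf)
  invisible(x)
}

#' Dichotomization sweep over every cut point of a predictor
#'
#' Enumerates every dichotomization scheme of the predictor, runs the
#' dependent-vs-independent comparison for each resulting binary trait pair,
#' and selects the scheme with the largest mean Bayes factor (ties broken
#' toward the lower cut). Schemes degenerate on the analyzed subset are
#' skipped with a warning.
#'
#' @param trees tree set (or single `phylo`).
#' @param response named 0/1 vector (e.g. from [molt_response()]).
#' @param predictor_values named vector of the predictor over the same
#'   species.
#' @param variable predictor name.
#' @param type passed to [enumerate_schemes()].
#' @param ... passed to [run_coevo_over_trees()] (`prior`, `ss`, `n_runs`,
#'   `seed`, ...).
#' @return Object of class `"dichotomization_sweep"`: per-scheme results and
#'   the selected scheme.
#' @export
dichotomization_sweep <- function(trees, response, predictor_values,
                                  variable = "predictor", type = "auto", ...) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  taxa <- names(response)
  if (is.null(taxa) || is.null(names(predictor_values)))
    stop("response and predictor_values must be named by species")
  predictor_values <- predictor_values[taxa]
  schemes <- enumerate_schemes(predictor_values, variable, type)
  rows <- list()
  for (i in seq_along(schemes)) {
    sc <- schemes[[i]]
    bin <- tryCatch(dichotomize(predictor_values, sc), error = function(e) NULL)
    if (is.null(bin)) {
      warning("skipping degenerate scheme: ",
              paste(sc$kind, sc$cut %||% "", collapse = " "))
      next
    }
    pair <- binary_trait_pair(taxa, x = bin, y = unname(response),
                              names = c(variable, "response"))
    ens <- run_coevo_over_trees(trees, pair, ...)
    rows[[length(rows) + 1L]] <- list(scheme = sc, bf = ens$bf, ensemble = ens)
  }
  if (!length(rows)) stop("all dichotomization schemes are degenerate on this subset")
  means <- vapply(rows, function(r) r$bf$mean, numeric(1))
  cuts <- vapply(rows, function(r) {
    if (r$scheme$kind == "ordinal_cut") r$scheme$cut else match(r$scheme$kind,
      c("q25", "median", "mean", "q75"))
  }, numeric(1))
  best <- order(-means, cuts)[1L]
  structure(list(results = rows, selected = rows[[best]]$scheme,
                 selected_bf = rows[[best]]$bf,
                 table = data.frame(
                   scheme = vapply(rows, function(r)
                     if (r$scheme$kind == "ordinal_cut")
                       sprintf("cut>%s", format(r$scheme$cut)) else r$scheme$kind,
                     character(1)),
                   mean_bf = means,
                   lci = vapply(rows, function(r) r$bf$lci, numeric(1)),
                   uci = vapply(rows, function(r) r$bf$uci, numeric(1)),
                   category = vapply(rows, function(r) r$bf$category, character(1)))),
            class = "dichotomization_sweep")
}

#' @export
print.dichotomization_sweep <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat("selected: "); print(x$selected)
  invisible(x)
}

#' Run a full analysis and write the report bundle
#'
#' Produces the standard outputs for one dataset + tree set: the molt
#' classification counts under both timing rules, the tree-averaged binary
#' mixed model table (coefficient rows plus a heritability row), optionally a
#' dependent-vs-independent comparison with its rate table, and a run
#' manifest (seeds, schedule, escalations, package version) sufficient to
#' reproduce every number.
#'
#' @param output_dir directory to write into (created if needed).
#' @param table species table.
#' @param trees tree set covering the table's species.
#' @param formula mixed-model formula; the response variable must be a
#'   column created by the driver: `prealternate` (molt presence under
#'   `timing_rule`).
#' @param timing_rule `"inclusive"` or `"strict"`.
#' @param settings,priors passed to [run_pmm_over_trees()].
#' @param coevo optional list with elements `predictor` (column name),
#'   `type`, and arguments for [run_coevo_over_trees()] (`ss`, `n_runs`,
#'   `posterior_settings`) to run a dichotomization sweep on that predictor.
#' @param seed master seed.
#' @return Invisibly, a list with the computed objects and file paths.
#' @export
full_report <- function(output_dir, table, trees, formula, timing_rule = "inclusive",
                        settings = mcmc_settings(), priors = pmm_priors(),
                        coevo = NULL, seed = 1L) {
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", output_dir)
  paths <- list()
  counts <- molt_count_summary(table)
  paths$counts <- file.path(output_dir, "counts.tsv")
  write.table(data.frame(quantity = names(counts), value = unlist(counts)),
              paths$counts, sep = "\t", quote = FALSE, row.names = FALSE)

  dat <- as.data.frame(table)
  dat$prealternate <- as.integer(molt_response(table, timing_rule))
  ens <- run_pmm_over_trees(formula, dat, trees, settings = settings,
                            priors = priors, seed = seed)
  paths$pmm <- file.path(output_dir, sprintf("pmm_%s.tsv", timing_rule))
  pmm_tab <- ens$aggregate
  h2row <- pmm_tab[1, ]
  h2row$term <- "Heritability (h2)"
  h2row$estimate <- ens$h2[["estimate"]]; h2row$lci <- ens$h2[["lci"]]
  h2row$uci <- ens$h2[["uci"]]
  h2row[c("ess", "autocorrelation", "geweke_z", "pMCMC")] <- NA
  write.table(rbind(pmm_tab, h2row), paths$pmm, sep = "\t", quote = FALSE,
              row.names = FALSE)

  sweep <- NULL
  if (!is.null(coevo)) {
    response <- molt_response(table, timing_rule)
    vals <- setNames(dat[[coevo$predictor]], table$species)
    sweep <- dichotomization_sweep(trees, response, vals,
                                   variable = coevo$predictor,
                                   type = coevo$type %||% "auto",
                                   ss = coevo$ss %||% stepping_stone_settings(),
                                   n_runs = coevo$n_runs %||% 10,
                                   posterior_settings = coevo$posterior_settings %||% settings,
                                   seed = seed + 100L)
    paths$sweep <- file.path(output_dir, sprintf("bf_sweep_%s.tsv", coevo$predictor))
    write.table(sweep$table, paths$sweep, sep = "\t", quote = FALSE, row.names = FALSE)
    # transition-rate table for the selected scheme (diagram arrows)
    sel_pair <- binary_trait_pair(names(response),
                                  x = dichotomize(vals, sweep$selected),
                                  y = unname(response),
                                  names = c(coevo$predictor, "prealternate"))
    post <- fit_pagel(trees[[1]], sel_pair, "dependent",
                      settings = coevo$posterior_settings %||% settings,
                      rj = TRUE, seed = seed + 200L)
    paths$rates <- file.path(output_dir, sprintf("rates_%s.tsv", coevo$predictor))
    write.table(post$rate_summary, paths$rates, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  manifest <- c(
    sprintf("package_version\t%s", as.character(utils::packageVersion("moltevol"))),
    sprintf("seed\t%d", seed),
    sprintf("timing_rule\t%s", timing_rule),
    sprintf("iterations\t%g", settings$iterations),
    sprintf("burn_in\t%g", settings$burn_in),
    sprintf("thinning\t%g", settings$thinning),
    sprintf("retained\t%d", settings$retained),
    sprintf("n_trees\t%d", length(trees)),
    sprintf("n_species\t%d", nrow(table)))
  paths$manifest <- file.path(output_dir, "manifest.tsv")
  writeLines(manifest, paths$manifest)
  invisible(list(counts = counts, pmm = ens, sweep = sweep, paths = paths))
}
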