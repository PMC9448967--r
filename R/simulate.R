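# Synthetic data with the statistical structure the analyses assume:
# ultrametric trees, jointly evolving binary trait pairs (forward CTMC
# simulation of the 4-state joint chain), liability-model binary responses
# with known fixed effects and phylogenetic variance, and a full
# study-schema trait table. All generators are deterministic given the seed.

#' Simulate a pure-birth tree rescaled to unit height
#'
#' @param n number of tips (at least 2).
#' @param seed integer seed.
#' @return Ultrametric rooted `phylo` with root-to-tip depth exactly 1.
#' @export
simulate_yule_tree <- function(n, seed = 1L) {
  if (n < 2) stop("need at least 2 tips")
  set.seed(seed)
  tree <- ape::rphylo(n, birth = 1, death = 0)
  depth <- max(root_to_tip_depths(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("t%d", seq_len(n))
  tree
}

#' Simulate a pair of binary traits under the joint CTMC
#'
#' Exact event-driven simulation along every branch: in state `s` the waiting
#' time to the next change is exponential with rate `-Q[s, s]` and the new
#' state is drawn from the off-diagonal rates. Tip joint states are split
#' into the two binary traits.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param Q 4x4 generator from [build_generator()].
#' @param root root state (1-4), or `"uniform"`/`"stationary"`/probability
#'   vector as in [pruning_loglik()].
#' @param seed integer seed.
#' @param names trait names passed to [binary_trait_pair()].
#' @param orientation passed to [binary_trait_pair()].
#' @return A [binary_trait_pair()] over the tree's tips.
#' @export
simulate_ctmc_pair <- function(tree, Q, root = "uniform", seed = 1L,
                               names = c("trait x", "trait y"),
                               orientation = "standard") {
  validate_phylogeny(tree)
  stopifnot(is.matrix(Q), all(dim(Q) == 4))
  set.seed(seed)
  root_state <- if (is.numeric(root) && length(root) == 1L) as.integer(root)
  else sample.int(4L, 1L, prob = root_distribution(Q, root))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  state <- integer(ntip + nnode)
  state[ntip + 1L] <- root_state
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  for (e in seq_len(nrow(tr$edge))) {
    s <- state[tr$edge[e, 1L]]
    t_left <- tr$edge.length[e]
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      wait <- rexp(1, rate)
      if (wait >= t_left) break
      t_left <- t_left - wait
      probs <- Q[s, ]; probs[s] <- 0
      s <- sample.int(4L, 1L, prob = probs)
    }
    state[tr$edge[e, 2L]] <- s
  }
  tips <- state[seq_len(ntip)]
  binary_trait_pair(tree$tip.label,
                    x = (tips - 1L) %/% 2L,
                    y = (tips - 1L) %% 2L,
                    orientation = orientation, names = names)
}

#' Simulate a binary response under the liability model
#'
#' The generative counterpart of [fit_binary_pmm()]: predictors are drawn
#' from their marginals (standard normal for continuous predictors, stated
#' category probabilities for ordinals), the liability is
#' `X beta + a + e` with `a ~ N(0, sigma2_a C)` and `e ~ N(0, 1)`, and the
#' response is Bernoulli through the logistic (or probit) link.
#'
#' @param tree ultrametric `phylo`; its tips become the species.
#' @param beta named fixed effects; use `"(Intercept)"` for the intercept,
#'   other names become predictor columns.
#' @param sigma2_a phylogenetic variance (nonnegative).
#' @param ordinal_levels named list: for ordinal predictors, a named numeric
#'   vector of category probabilities (names = integer levels).
#' @param link `"logistic"` or `"probit"`.
#' @param seed integer seed.
#' @return Data frame with `species`, predictor columns and `response`; the
#'   attribute `"truth"` stores `beta`, `sigma2_a` and the drawn
#'   phylogenetic effects.
#' @export
simulate_liability_dataset <- function(tree, beta = c("(Intercept)" = 0),
                                       sigma2_a = 1, ordinal_levels = list(),
                                       link = c("logistic", "probit"), seed = 1L) {
  link <- match.arg(link)
  if (sigma2_a < 0) stop("sigma2_a must be nonnegative")
  validate_phylogeny(tree)
  set.seed(seed)
  n <- length(tree$tip.label)
  pred_names <- setdiff(names(beta), "(Intercept)")
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  dat <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  for (nm in pred_names) {
    x <- if (nm %in% names(ordinal_levels)) {
      pr <- ordinal_levels[[nm]]
      as.numeric(sample(as.numeric(names(pr)), n, replace = TRUE, prob = pr))
    } else rnorm(n)
    dat[[nm]] <- x
    X <- cbind(X, x)
  }
  colnames(X) <- c("(Intercept)", pred_names)
  b <- setNames(numeric(ncol(X)), colnames(X))
  b[names(beta)] <- beta
  a <- if (sigma2_a > 0) {
    C <- phylo_correlation(tree)
    as.vector(t(chol(C + diag(1e-10, n))) %*% rnorm(n)) * sqrt(sigma2_a)
  } else numeric(n)
  l <- as.vector(X %*% b) + a + rnorm(n)
  pr <- if (link == "logistic") plogis(l) else pnorm(l)
  dat$response <- rbinom(n, 1, pr)
  attr(dat, "truth") <- list(beta = b, sigma2_a = sigma2_a, a = a, liability = l)
  dat
}

#' Simulate a full study-schema species table
#'
#' Generates a trait table with every column of the study schema and the
#' marginal structure of the European-passerine dataset the package's
#' analyses are designed for: 188 species of which 83 have a winter--spring
#' molt (16 of them molting only in November--December, so 67 remain under
#' the strict timing rule); 48 of the molters have a partial and 35 a
#' complete molt (the complete molts concentrated in the fully migratory
#' class, and 15 of them confined to November--December); 37 partial molters
#' replace only nonflight tracts; 26 species are winter-territorial.
#' Assignments within those margins, the ordinal predictors, body mass,
#' dichromatism and the sexual-selection index are randomized given the
#' seed, with molting species skewed toward migratory, aerially foraging and
#' high-sexual-selection values so that every downstream analysis has signal
#' to find.
#'
#' @param seed integer seed.
#' @param n_species table size (default 188; counts above scale only with
#'   the default).
#' @return A validated species table (see [read_species_table()]).
#' @export
simulate_study_table <- function(seed = 1L, n_species = 188L) {
  set.seed(seed)
  n <- as.integer(n_species)
  scale_n <- function(k) max(1L, round(k * n / 188L))
  n_molt <- scale_n(83L)
  n_complete <- min(scale_n(35L), n_molt - 1L)
  n_partial <- n_molt - n_complete
  n_novdec <- min(scale_n(16L), n_molt - 1L)
  n_novdec_complete <- min(scale_n(15L), n_novdec, n_complete)
  n_novdec_partial <- n_novdec - n_novdec_complete
  n_nonflight <- min(scale_n(37L), n_partial)
  n_territorial <- scale_n(26L)

  species <- sprintf("Genus%02d_species%03d", 1L + (seq_len(n) - 1L) %/% 8L, seq_len(n))
  molter <- seq_len(n) %in% sample.int(n, n_molt)
  idx_molt <- which(molter)
  complete <- logical(n)
  complete[sample(idx_molt, n_complete)] <- TRUE
  # molt confined to Nov-Dec: mostly complete molts, one partial
  novdec_only <- logical(n)
  novdec_only[sample(which(molter & complete), n_novdec_complete)] <- TRUE
  if (n_novdec_partial > 0)
    novdec_only[sample(which(molter & !complete), n_novdec_partial)] <- TRUE
  # tracts: complete molts replace everything; partial molts mostly nonflight
  nonflight_only <- logical(n)
  nonflight_only[sample(which(molter & !complete), n_nonflight)] <- TRUE

  months <- character(n)
  spring <- c("January", "February", "March", "April")
  for (i in which(molter)) {
    months[i] <- if (novdec_only[i])
      paste(sample(c("November", "December"), sample(1:2, 1)), collapse = ",")
    else {
      base <- sort(sample(spring, sample(1:3, 1)))
      if (runif(1) < 0.3) base <- c("December", base)
      paste(base, collapse = ",")
    }
  }
  tracts <- character(n)
  for (i in which(molter)) {
    tracts[i] <- if (complete[i]) paste(ALL_TRACTS, collapse = ";")
    else if (nonflight_only[i])
      paste(sample(NONFLIGHT_TRACTS, sample(2:3, 1)), collapse = ";")
    else
      paste(c(sample(NONFLIGHT_TRACTS, 2), sample(c("tertials", "rectrices"), 1)),
            collapse = ";")
  }

  # ordinal predictors with molt-linked dependencies; complete molts sit in
  # the fully migratory class
  migration <- integer(n)
  migration[molter & complete] <- 5L
  migration[molter & !complete] <- sample(1:5, sum(molter & !complete), TRUE,
                                          prob = c(.08, .12, .2, .3, .3))
  migration[!molter] <- sample(1:5, sum(!molter), TRUE, prob = c(.3, .25, .2, .15, .1))
  habitat <- pmin(6L, pmax(1L, sample(1:6, n, TRUE, prob = c(.05, .1, .2, .2, .2, .25)) -
                             ifelse(molter, sample(0:1, n, TRUE), 0L)))
  aerial <- ifelse(molter,
                   sample(0:2, n, TRUE, prob = c(.5, .3, .2)),
                   sample(0:2, n, TRUE, prob = c(.75, .18, .07)))
  gregariousness <- integer(n)
  terr <- sample.int(n, n_territorial)
  gregariousness[terr] <- 1L
  gregariousness[-terr] <- sample(2:4, n - n_territorial, TRUE, prob = c(.35, .35, .3))

  body_mass <- round(10^rnorm(n, mean = 1.3, sd = 0.35), 2)
  dichromatism <- round(abs(rnorm(n, 20, 15)) + ifelse(molter & !complete, 8, 0), 2)
  sexual_selection <- round(rnorm(n) + ifelse(molter, 0.5, -0.2), 3)

  tab <- data.frame(species = species, body_mass = body_mass,
                    dichromatism = dichromatism, sexual_selection = sexual_selection,
                    migration = migration, habitat = habitat,
                    aerial_foraging = aerial, gregariousness = gregariousness,
                    has_molt = molter, molt_months = months,
                    extent = ifelse(molter, ifelse(complete, "complete", "partial"), "none"),
                    tracts = tracts, stringsAsFactors = FALSE)
  tab <- validate_species_table(tab)
  tab$log_body_mass <- log10(tab$body_mass)
  class(tab) <- c("species_table", class(tab))
  tab
}
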