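#' @useDynLib moltevol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats acf aggregate ar coef cor dexp integrate median plogis
#'   pnorm qlogis qnorm quantile rbinom rexp rlogis rnorm runif sd setNames
#'   simulate var chisq.test rgamma
#' @importFrom utils read.delim write.table head tail
"_PACKAGE"

MONTH_NAMES <- month.name

FLIGHT_TRACTS    <- c("primaries", "secondaries", "tertials", "rectrices")
NONFLIGHT_TRACTS <- c("wing-coverts", "head", "body")
ALL_TRACTS       <- c(FLIGHT_TRACTS, NONFLIGHT_TRACTS)

#' Construct and validate a molt observation
#'
#' A molt observation records whether a species performs a winter--spring
#' (pre-alternate) molt, in which calendar months it takes place, whether it is
#' partial or complete, and which feather tracts are replaced. The three
#' fields are linked: a species without the molt has no months, no tracts and
#' extent `"none"`; a species with the molt has at least one month, at least
#' one tract and extent `"partial"` or `"complete"`.
#'
#' @param has_molt logical flag: does the species have a winter--spring molt?
#' @param months character vector of calendar month names (e.g. `"November"`).
#' @param extent one of `"none"`, `"partial"`, `"complete"`.
#' @param tracts character vector drawn from `"primaries"`, `"secondaries"`,
#'   `"tertials"`, `"rectrices"`, `"wing-coverts"`, `"head"`, `"body"`.
#' @return An object of class `"molt_observation"`.
#' @examples
#' molt_observation(TRUE, c("February", "March"), "partial", c("head", "body"))
#' molt_observation(FALSE)
#' @export
molt_observation <- function(has_molt, months = character(),
                             extent = if (has_molt) "partial" else "none",
                             tracts = character()) {
  stopifnot(is.logical(has_molt), length(has_molt) == 1L, !is.na(has_molt))
  extent <- match.arg(extent, c("none", "partial", "complete"))
  months <- as.character(months)
  tracts <- as.character(tracts)
  bad_m <- setdiff(months, MONTH_NAMES)
  if (length(bad_m)) stop("unknown month name(s): ", paste(bad_m, collapse = ", "))
  bad_t <- setdiff(tracts, ALL_TRACTS)
  if (length(bad_t)) stop("unknown feather tract(s): ", paste(bad_t, collapse = ", "))
  if (has_molt) {
    if (extent == "none")     stop("species with a winter-spring molt must have extent 'partial' or 'complete'")
    if (!length(months))      stop("species with a winter-spring molt must have at least one molt month")
    if (!length(tracts))      stop("species with a winter-spring molt must have at least one molted tract")
  } else {
    if (extent != "none")     stop("species without a winter-spring molt must have extent 'none'")
    if (length(months))       stop("species without a winter-spring molt must have no molt months")
    if (length(tracts))       stop("species without a winter-spring molt must have no molted tracts")
  }
  structure(list(has_molt = has_molt, months = unique(months),
                 extent = extent, tracts = unique(tracts)),
            class = "molt_observation")
}

#' Score the presence of a pre-alternate molt
#'
#' Under the `"inclusive"` timing rule any winter--spring molt counts as
#' pre-alternate. Under the `"strict"` rule a molt confined to November and
#' December is reassigned to the pre-basic molt, so the species scores 0
#' unless at least one molt month falls outside November--December.
#'
#' @param molt a [molt_observation()].
#' @param timing_rule `"inclusive"` or `"strict"`.
#' @return Integer 0 or 1.
#' @export
classify_prealternate <- function(molt, timing_rule = c("inclusive", "strict")) {
  timing_rule <- match.arg(timing_rule)
  molt <- as_molt_observation(molt)
  if (!molt$has_molt) return(0L)
  if (timing_rule == "inclusive") return(1L)
  as.integer(any(!molt$months %in% c("November", "December")))
}

#' Score the extent of a pre-alternate molt
#'
#' @param molt a [molt_observation()] of a species that has the molt.
#' @return `"partial"` or `"complete"` (scored 0 and 1 in the analyses).
#' @export
classify_extent <- function(molt) {
  molt <- as_molt_observation(molt)
  if (!molt$has_molt || molt$extent == "none")
    stop("extent is undefined for a species without a pre-alternate molt")
  molt$extent
}

#' Classify the molted feather tracts
#'
#' A molt restricted to wing coverts, head or body feathers is
#' `"nonflight_only"`; replacing any primaries, secondaries, tertials or
#' rectrices makes it `"includes_flight"`.
#'
#' @param molt a [molt_observation()] with at least one tract.
#' @return `"nonflight_only"` or `"includes_flight"`.
#' @export
classify_tracts <- function(molt) {
  molt <- as_molt_observation(molt)
  if (!length(molt$tracts)) stop("no molted tracts recorded")
  if (all(molt$tracts %in% NONFLIGHT_TRACTS)) "nonflight_only" else "includes_flight"
}

as_molt_observation <- function(x) {
  if (inherits(x, "molt_observation")) return(x)
  if (is.list(x)) return(molt_observation(x$has_molt, x$months %||% character(),
                                          x$extent %||% if (isTRUE(x$has_molt)) "partial" else "none",
                                          x$tracts %||% character()))
  stop("not a molt observation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dichotomization schemes
#'
#' A scheme turns an ordinal or continuous predictor into a 0/1 trait. For an
#' ordinal predictor a cut between adjacent observed levels `k` and `k+1`
#' scores values above `k` as 1. For a continuous predictor the cut is a
#' statistic of the supplied values (mean, median, lower or upper quartile,
#' type-7 quantiles); values at or above the cut score 1 (the tie at the cut
#' goes to state 1). A binary predictor admits only the identity scheme.
#'
#' @param variable name of the predictor the scheme applies to.
#' @param kind `"ordinal_cut"`, `"mean"`, `"median"`, `"q25"`, `"q75"`, or
#'   `"identity"`.
#' @param cut for `"ordinal_cut"`: the level after which state 1 starts.
#' @return An object of class `"dichotomization_scheme"`.
#' @export
dichotomization_scheme <- function(variable, kind, cut = NULL) {
  kind <- match.arg(kind, c("ordinal_cut", "mean", "median", "q25", "q75", "identity"))
  if (kind == "ordinal_cut" && is.null(cut)) stop("ordinal_cut requires a cut level")
  structure(list(variable = variable, kind = kind, cut = cut),
            class = "dichotomization_scheme")
}

#' @export
print.dichotomization_scheme <- function(x, ...) {
  lab <- if (x$kind == "ordinal_cut")
    sprintf("ordinal cut after level %s", format(x$cut)) else x$kind
  cat(sprintf("dichotomization of '%s': %s\n", x$variable, lab))
  invisible(x)
}

#' Apply a dichotomization scheme
#'
#' @param values numeric vector (ordinal levels or continuous scores).
#' @param scheme a [dichotomization_scheme()].
#' @return Integer 0/1 vector with both states present.
#' @export
dichotomize <- function(values, scheme) {
  stopifnot(inherits(scheme, "dichotomization_scheme"), is.numeric(values))
  if (anyNA(values)) stop("missing values in predictor '", scheme$variable, "'")
  if (length(unique(values)) < 2L)
    stop("degenerate scheme: predictor '", scheme$variable, "' is constant")
  out <- switch(scheme$kind,
    identity = {
      u <- sort(unique(values))
      if (length(u) != 2L) stop("identity scheme requires a binary variable")
      as.integer(values == u[2L])
    },
    ordinal_cut = as.integer(values > scheme$cut),
    as.integer(values >= cut_statistic(values, scheme$kind)))
  if (length(unique(out)) < 2L)
    stop("degenerate scheme: only one state present after dichotomization of '",
         scheme$variable, "'")
  out
}

cut_statistic <- function(values, kind) {
  switch(kind,
         mean   = mean(values),
         median = median(values),
         q25    = quantile(values, 0.25, names = FALSE, type = 7),
         q75    = quantile(values, 0.75, names = FALSE, type = 7),
         stop("unknown scheme kind: ", kind))
}

#' Enumerate all dichotomization schemes for a predictor
#'
#' An ordinal predictor with K observed levels yields the K-1 cuts between
#' adjacent observed levels; a continuous predictor yields the four
#' statistics-based cuts (mean, median, lower quartile, upper quartile); a
#' binary predictor yields the single identity scheme.
#'
#' @param values observed values of the predictor.
#' @param variable predictor name carried into the schemes.
#' @param type `"ordinal"`, `"continuous"`, or `"auto"` (ordinal iff all
#'   values are whole numbers with at most 10 distinct levels).
#' @return List of [dichotomization_scheme()] objects.
#' @export
enumerate_schemes <- function(values, variable = "x", type = c("auto", "ordinal", "continuous")) {
  type <- match.arg(type)
  if (anyNA(values)) stop("missing values in predictor '", variable, "'")
  lev <- sort(unique(values))
  if (length(lev) < 2L) stop("predictor '", variable, "' is constant")
  if (type == "auto")
    type <- if (all(values == round(values)) && length(lev) <= 10L) "ordinal" else "continuous"
  if (length(lev) == 2L)
    return(list(dichotomization_scheme(variable, "identity")))
  if (type == "ordinal")
    lapply(lev[-length(lev)], function(k) dichotomization_scheme(variable, "ordinal_cut", cut = k))
  else
    lapply(c("mean", "median", "q25", "q75"), function(s) dichotomization_scheme(variable, s))
}

#' Detect (quasi-)separation of a binary outcome by predictors
#'
#' Separation occurs when a predictor perfectly predicts the outcome, which
#' destabilizes a logistic-scale model fitted with flat priors. A predictor is
#' flagged when one of its levels (for a discrete predictor) or one sign of
#' its centered values (for a continuous predictor) co-occurs with a single
#' outcome value.
#'
#' @param outcome 0/1 vector.
#' @param predictors data frame of predictors aligned with `outcome`.
#' @return List with `separation` (flag), `predictors` (offending names), and
#'   `degenerate` (`TRUE` when the outcome itself is constant).
#' @export
detect_separation <- function(outcome, predictors) {
  if (!length(outcome)) stop("empty outcome")
  stopifnot(all(outcome %in% c(0, 1)))
  predictors <- as.data.frame(predictors)
  if (nrow(predictors) != length(outcome)) stop("outcome and predictors have different lengths")
  if (length(unique(outcome)) < 2L)
    return(list(separation = TRUE, predictors = names(predictors), degenerate = TRUE))
  offending <- character()
  for (nm in names(predictors)) {
    x <- predictors[[nm]]
    groups <- if (is.numeric(x) && length(unique(x)) > 10L) {
      factor(sign(x - mean(x)) >= 0, levels = c(FALSE, TRUE), labels = c("below", "above"))
    } else factor(x)
    tab <- table(groups, factor(outcome, levels = c(0, 1)))
    if (any(rowSums(tab > 0) == 1L)) offending <- c(offending, nm)
  }
  list(separation = length(offending) > 0L, predictors = offending, degenerate = FALSE)
}

# ---- species table I/O ------------------------------------------------------

SPECIES_COLUMNS <- c("species", "body_mass", "dichromatism", "sexual_selection",
                     "migration", "habitat", "aerial_foraging", "gregariousness",
                     "has_molt", "molt_months", "extent", "tracts")

#' Normalize species labels to match tree tip labels
#'
#' Trims and collapses whitespace and replaces spaces with underscores, the
#' convention of Newick tip labels.
#'
#' @param x character vector of species names.
#' @return Normalized character vector.
#' @export
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(x))
  gsub(" ", "_", x)
}

#' Validate a species trait table
#'
#' Checks the schema used throughout the package: unique species labels,
#' positive body mass, ordinal predictors within their ranges (migration 1-5,
#' habitat 1-6, aerial foraging 0-2, gregariousness 1-4), and internally
#' consistent molt fields (see [molt_observation()]).
#'
#' @param table data frame with the columns listed in the package README.
#' @return The table, invisibly, with `log_body_mass` added if missing.
#' @export
validate_species_table <- function(table) {
  missing_cols <- setdiff(SPECIES_COLUMNS, names(table))
  if (length(missing_cols))
    stop("species table lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(table$species))
    stop("duplicated species labels: ",
         paste(unique(table$species[duplicated(table$species)]), collapse = ", "))
  if (any(table$body_mass <= 0)) stop("body_mass must be positive")
  rng <- list(migration = 1:5, habitat = 1:6, aerial_foraging = 0:2, gregariousness = 1:4)
  for (nm in names(rng))
    if (!all(table[[nm]] %in% rng[[nm]]))
      stop("'", nm, "' outside its ordinal range ",
           rng[[nm]][1], "..", rng[[nm]][length(rng[[nm]])])
  for (i in seq_len(nrow(table))) row_molt(table, i)  # validates molt fields
  if (is.null(table$log_body_mass)) table$log_body_mass <- log10(table$body_mass)
  invisible(table)
}

split_tokens <- function(x, sep) {
  if (is.na(x) || !nzchar(x)) character() else trimws(strsplit(x, sep, fixed = TRUE)[[1L]])
}

row_molt <- function(table, i) {
  molt_observation(as.logical(table$has_molt[i]),
                   months = split_tokens(as.character(table$molt_months[i]), ","),
                   extent = as.character(table$extent[i]),
                   tracts = split_tokens(as.character(table$tracts[i]), ";"))
}

#' Read a species trait table from TSV/CSV
#'
#' Expects one row per species. Months are comma-separated month names, tracts
#' semicolon-separated tract tokens. A `column_map` (named character vector,
#' `internal_name = file_column`) adapts tables with different headers, e.g. a
#' supplementary-archive layout.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param column_map optional named character vector mapping package column
#'   names to file column names.
#' @return A validated species table (data frame) with class
#'   `"species_table"` prepended, species labels normalized, and
#'   `log_body_mass` computed.
#' @export
read_species_table <- function(path, sep = "\t", column_map = NULL) {
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    for (nm in names(column_map)) {
      if (!column_map[[nm]] %in% names(raw))
        stop("column '", column_map[[nm]], "' not found in ", path)
      names(raw)[names(raw) == column_map[[nm]]] <- nm
    }
  }
  raw$species <- normalize_species(raw$species)
  raw$has_molt <- as.logical(raw$has_molt)
  tab <- validate_species_table(raw)
  class(tab) <- c("species_table", class(tab))
  tab
}

#' Write a species trait table
#'
#' Inverse of [read_species_table()]; the round trip preserves every field.
#'
#' @param table species table.
#' @param path output path.
#' @param sep field separator.
#' @return `path`, invisibly.
#' @export
write_species_table <- function(table, path, sep = "\t") {
  cols <- c("species", "body_mass", "log_body_mass", "dichromatism",
            "sexual_selection", "migration", "habitat", "aerial_foraging",
            "gregariousness", "has_molt", "molt_months", "extent", "tracts")
  cols <- intersect(cols, names(table))
  write.table(table[cols], path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Override the molt pattern of a sexually dimorphic species
#'
#' Most species molt alike in both sexes; for the exceptions (e.g. a species
#' whose pre-alternate molt is complete in males but partial in females) the
#' table stores the male pattern by default and this override swaps in an
#' alternative pattern for selected species.
#'
#' @param table species table.
#' @param species species label (normalized form).
#' @param molt a [molt_observation()] replacing that species' molt fields.
#' @return The modified table.
#' @export
set_molt_pattern <- function(table, species, molt) {
  molt <- as_molt_observation(molt)
  i <- match(normalize_species(species), table$species)
  if (is.na(i)) stop("species not in table: ", species)
  table$has_molt[i]    <- molt$has_molt
  table$molt_months[i] <- paste(molt$months, collapse = ",")
  table$extent[i]      <- molt$extent
  table$tracts[i]      <- paste(molt$tracts, collapse = ";")
  table
}

#' Molt classification summary counts
#'
#' Applies [classify_prealternate()] under both timing rules,
#' [classify_extent()] and [classify_tracts()] across a species table and
#' returns the headline counts of the molt classification.
#'
#' @param table species table.
#' @return Named list of counts: species total, molters under the inclusive
#'   and strict rules, partial/complete splits under each rule, number of
#'   partial molters replacing nonflight tracts only, and territorial species
#'   (gregariousness class 1).
#' @export
molt_count_summary <- function(table) {
  molts <- lapply(seq_len(nrow(table)), function(i) row_molt(table, i))
  inc <- vapply(molts, classify_prealternate, integer(1), timing_rule = "inclusive")
  str <- vapply(molts, classify_prealternate, integer(1), timing_rule = "strict")
  ext <- vapply(seq_along(molts), function(i)
    if (inc[i] == 1L) classify_extent(molts[[i]]) else NA_character_, character(1))
  tract_cls <- vapply(seq_along(molts), function(i)
    if (inc[i] == 1L) classify_tracts(molts[[i]]) else NA_character_, character(1))
  list(
    n_species            = nrow(table),
    n_inclusive          = sum(inc),
    n_strict             = sum(str),
    n_partial_inclusive  = sum(ext == "partial",  na.rm = TRUE),
    n_complete_inclusive = sum(ext == "complete", na.rm = TRUE),
    n_partial_strict     = sum(str == 1L & ext == "partial",  na.rm = TRUE),
    n_complete_strict    = sum(str == 1L & ext == "complete", na.rm = TRUE),
    n_nonflight_partial  = sum(ext == "partial" & tract_cls == "nonflight_only", na.rm = TRUE),
    n_territorial        = sum(table$gregariousness == 1)
  )
}
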