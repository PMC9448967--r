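test_that("molt observation invariants are enforced", {
  expect_s3_class(molt_spring(), "molt_observation")
  expect_error(molt_observation(TRUE, months = character(), extent = "partial",
                                tracts = "head"), "at least one molt month")
  expect_error(molt_observation(TRUE, "March", "none", "head"), "extent")
  expect_error(molt_observation(FALSE, months = "March"), "no molt months")
  expect_error(molt_observation(TRUE, "Marchember", "partial", "head"), "month")
  expect_error(molt_observation(TRUE, "March", "partial", "beak"), "tract")
})

test_that("pre-alternate classification follows the November-December timing rule", {
  feb_apr <- molt_observation(TRUE, c("February", "April"), "partial", "head")
  expect_identical(classify_prealternate(feb_apr, "inclusive"), 1L)
  expect_identical(classify_prealternate(feb_apr, "strict"), 1L)
  novdec <- molt_observation(TRUE, c("November", "December"), "complete",
                             c("primaries", "secondaries", "tertials",
                               "rectrices", "wing-coverts", "head", "body"))
  expect_identical(classify_prealternate(novdec, "inclusive"), 1L)
  expect_identical(classify_prealternate(novdec, "strict"), 0L)
  expect_identical(classify_prealternate(molt_none(), "inclusive"), 0L)
  expect_identical(classify_prealternate(molt_none(), "strict"), 0L)
})

test_that("strict timing rule can only remove species relative to inclusive", {
  tab <- simulate_study_table(seed = 4, n_species = 60)
  inc <- molt_response(tab, "inclusive")
  str <- molt_response(tab, "strict")
  expect_true(all(str <= inc))
})

test_that("extent and tract classification match the scoring scheme", {
  full <- molt_observation(TRUE, "March", "complete",
                           c("primaries", "secondaries", "rectrices", "head", "body"))
  expect_identical(classify_extent(full), "complete")
  expect_identical(classify_extent(molt_spring()), "partial")
  expect_error(classify_extent(molt_none()), "without a pre-alternate molt")
  expect_identical(classify_tracts(molt_spring()), "nonflight_only")
  body_tert <- molt_observation(TRUE, "March", "partial", c("body", "tertials"))
  expect_identical(classify_tracts(body_tert), "includes_flight")
  expect_identical(classify_tracts(full), "includes_flight")
})

test_that("dichotomization applies cut points with ties going to state 1", {
  mig <- c(1, 3, 4, 5, 2)
  sc <- dichotomization_scheme("migration", "ordinal_cut", cut = 3)
  expect_identical(dichotomize(mig, sc), c(0L, 0L, 1L, 1L, 0L))
  # tie at a continuous cut scores 1
  x <- c(1, 2, 3)  # mean 2
  expect_identical(dichotomize(x, dichotomization_scheme("x", "mean")), c(0L, 1L, 1L))
  expect_error(dichotomize(rep(2, 5), dichotomization_scheme("x", "mean")), "degenerate")
})

test_that("scheme enumeration yields K-1 ordinal cuts, 4 continuous stats, 1 identity", {
  mig <- c(1, 2, 3, 4, 5, 3, 2)
  sc <- enumerate_schemes(mig, "migration")
  expect_length(sc, 4)
  # each scheme's binary vector is monotone in the ordinal and all distinct
  vecs <- lapply(sc, function(s) dichotomize(mig, s))
  expect_identical(length(unique(vecs)), 4L)
  for (v in vecs) expect_true(all(diff(v[order(mig)]) >= 0))
  cont <- rnorm(30)
  expect_length(enumerate_schemes(cont, type = "continuous"), 4)
  expect_length(enumerate_schemes(c(0, 1, 0, 1), "bin"), 1)
  expect_identical(enumerate_schemes(c(0, 1, 0, 1), "bin")[[1]]$kind, "identity")
})

test_that("separation detection flags perfectly predictive levels", {
  # all non-level-5 species have outcome 0
  mig <- c(1, 2, 3, 4, 5, 5, 5, 2)
  y <- as.integer(mig == 5)
  res <- detect_separation(y, data.frame(migration = mig))
  expect_true(res$separation)
  expect_identical(res$predictors, "migration")
  # balanced 2x2 co-occurrence: no flag
  res2 <- detect_separation(c(0, 1, 0, 1), data.frame(x = c(0, 0, 1, 1)))
  expect_false(res2$separation)
  res3 <- detect_separation(rep(1, 4), data.frame(x = c(0, 0, 1, 1)))
  expect_true(res3$separation)
  expect_true(res3$degenerate)
  expect_error(detect_separation(integer(), data.frame()), "empty")
})

test_that("species table round-trips through the TSV reader unchanged", {
  tab <- simulate_study_table(seed = 11, n_species = 50)
  path <- tempfile(fileext = ".tsv")
  write_species_table(tab, path)
  back <- read_species_table(path)
  for (cl in c("species", "migration", "habitat", "aerial_foraging",
               "gregariousness", "has_molt", "molt_months", "extent", "tracts"))
    expect_identical(back[[cl]], tab[[cl]])
  for (cl in c("body_mass", "dichromatism", "sexual_selection", "log_body_mass"))
    expect_equal(back[[cl]], tab[[cl]], tolerance = 1e-12)
})

test_that("reader applies a column map and normalizes species names", {
  tab <- simulate_study_table(seed = 3, n_species = 30)
  raw <- as.data.frame(tab)
  names(raw)[names(raw) == "species"] <- "Species name"
  raw$`Species name` <- gsub("_", " ", raw$`Species name`)
  path <- tempfile(fileext = ".tsv")
  write.table(raw, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_species_table(path, column_map = c(species = "Species name"))
  expect_identical(back$species, tab$species)
})

test_that("dimorphic molt override replaces a species' pattern", {
  tab <- simulate_study_table(seed = 5, n_species = 30)
  sp <- tab$species[which(tab$extent == "complete")[1]]
  tab2 <- set_molt_pattern(tab, sp, molt_observation(TRUE, "March", "partial", "head"))
  i <- match(sp, tab2$species)
  expect_identical(tab2$extent[i], "partial")
  expect_identical(tab2$tracts[i], "head")
  expect_error(set_molt_pattern(tab, "Nosuchus_species", molt_none()), "not in table")
})

test_that("ordinal ranges and duplicated species are rejected", {
  tab <- simulate_study_table(seed = 6, n_species = 20)
  bad <- tab; bad$migration[1] <- 9
  expect_error(validate_species_table(bad), "migration")
  dup <- tab; dup$species[2] <- dup$species[1]
  expect_error(validate_species_table(dup), "duplicated")
})
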