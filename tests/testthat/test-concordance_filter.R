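# shorthand: build a genotype_matrix from an explicit call matrix
gm_from_calls <- function(calls, classes, ids = NULL) {
  n_sites <- nrow(calls); n_samp <- ncol(calls)
  if (is.null(ids)) ids <- sprintf("X%03d", seq_len(n_samp))
  genotype_matrix(
    data.frame(chrom = "D10", pos = seq_len(n_sites) * 1000L,
               ref = "A", alt = "T"),
    data.frame(id = ids, class = classes),
    calls, matrix(ifelse(is.na(calls), 0L, 5L), n_sites, n_samp))
}

phen_table <- function(ids, labels)
  structure(data.frame(sample = ids,
                       phenotype = factor(labels,
                                          c("tolerant", "sensitive"))),
            class = c("phenotype_table", "data.frame"))

test_that("hand-built 6-sample matrix matches rule-by-rule evaluation", {
  # 2 parents (first sensitive), 2 sensitive RILs, 2 tolerant RILs
  calls <- rbind(
    c(2L, 0L, 2L, 2L, 0L, 0L),   # textbook candidate
    c(2L, 0L, 2L, 0L, 0L, 0L),   # a sensitive RIL is hom_ref -> excluded
    c(2L, 0L, 2L, NA, 0L, 1L),   # missing sensitive / het tolerant
    c(2L, NA, 2L, 2L, 0L, 2L),   # tolerant RIL hom_alt -> rule (d)
    c(1L, 0L, 2L, 2L, 0L, 0L))   # sensitive parent het -> rule (a)
  classes <- c("parent", "parent", "RIL", "RIL", "RIL", "RIL")
  phen_all <- c(NA, NA, "sensitive", "sensitive", "tolerant", "tolerant")
  gm <- gm_from_calls(calls, classes)
  phen <- phen_table(gm$samples$id[3:6], phen_all[3:6])

  for (mode in c("permissive", "strict")) for (rt in c(TRUE, FALSE)) {
    got <- concordance_filter(gm, phen, "X001",
                              filter_config(mode,
                                            require_tolerant_exclusion = rt))
    want <- oracle_filter(calls, classes, phen_all, 1L, mode, rt)
    expect_equal(attr(got, "site_index"), want,
                 info = sprintf("mode=%s rt=%s", mode, rt))
  }
  # spot-check the permissive default judgement per site
  got <- concordance_filter(gm, phen, "X001", filter_config("permissive"))
  expect_equal(attr(got, "site_index"), c(1L, 3L))
  expect_equal(got$n_sens_hom_alt, c(2L, 1L))
  expect_equal(got$n_sens_missing, c(0L, 1L))
  # strict: missing disqualifies
  got_s <- concordance_filter(gm, phen, "X001", filter_config("strict"))
  expect_equal(attr(got_s, "site_index"), 1L)
})

test_that("filter equals the brute-force oracle on random matrices", {
  set.seed(1001)
  for (i in 1:40) {
    n_sites <- sample(5:50, 1); n_samp <- sample(6:20, 1)
    fx <- random_genotype_matrix(n_sites, n_samp)
    mode <- sample(c("permissive", "strict"), 1)
    rt <- sample(c(TRUE, FALSE), 1)
    got <- concordance_filter(fx$gm, fx$phen, fx$gm$samples$id[1],
                              filter_config(mode,
                                            require_tolerant_exclusion = rt))
    want <- oracle_filter(fx$gm$calls, fx$classes, fx$phen_all, 1L, mode, rt)
    expect_equal(attr(got, "site_index"), want)
  }
})

test_that("strict-mode candidates are a subset of permissive-mode ones", {
  set.seed(1011)
  for (i in 1:20) {
    fx <- random_genotype_matrix(30, 12)
    s <- attr(concordance_filter(fx$gm, fx$phen, fx$gm$samples$id[1],
                                 filter_config("strict")), "site_index")
    p <- attr(concordance_filter(fx$gm, fx$phen, fx$gm$samples$id[1],
                                 filter_config("permissive")), "site_index")
    expect_true(all(s %in% p))
  }
})

test_that("a tolerant hom_alt sample never adds a candidate under rule (d)", {
  set.seed(1021)
  fx <- random_genotype_matrix(40, 10)
  base <- attr(concordance_filter(fx$gm, fx$phen, fx$gm$samples$id[1],
                                  filter_config("permissive")), "site_index")
  aug_calls <- cbind(fx$gm$calls, 2L)    # new tolerant sample, all hom_alt
  gm2 <- gm_from_calls(aug_calls, c(fx$classes, "RIL"),
                       ids = c(fx$gm$samples$id, "EXTRA"))
  phen2 <- phen_table(c(as.character(fx$phen$sample), "EXTRA"),
                      c(as.character(fx$phen$phenotype), "tolerant"))
  aug <- attr(concordance_filter(gm2, phen2, fx$gm$samples$id[1],
                                 filter_config("permissive")), "site_index")
  expect_true(all(aug %in% base))
})

test_that("region restriction and input validation work", {
  fx <- random_genotype_matrix(20, 8)
  got <- concordance_filter(fx$gm, fx$phen, fx$gm$samples$id[1],
                            filter_config("permissive",
                                          region = list(chrom = "D10",
                                                        start = 5000,
                                                        end = 10000)))
  expect_true(all(got$pos >= 5000 & got$pos <= 10000))
  expect_error(concordance_filter(fx$gm, fx$phen, "NOPE",
                                  filter_config()), "not found")
  empty_phen <- phen_table(as.character(fx$phen$sample),
                           rep("tolerant", nrow(fx$phen)))
  expect_error(concordance_filter(fx$gm, empty_phen, fx$gm$samples$id[1],
                                  filter_config()), "no sensitive")
  expect_error(filter_config(region = list(chrom = "D10", start = 5, end = 1)),
               "region")
})

test_that("marker concordance counts discordant calls and missing data", {
  # perfect recessive co-segregation: zero discordant
  calls <- c(2L, 2L, 1L, 0L, NA)
  phen <- c("sensitive", "sensitive", "tolerant", "tolerant", "sensitive")
  r <- marker_concordance(calls, phen)
  expect_equal(r$n_discordant, 0L)
  expect_equal(r$n_missing, 1L)
  # inject one sensitive het
  r2 <- marker_concordance(c(calls, 1L), c(phen, "sensitive"))
  expect_equal(r2$n_discordant, 1L)
  # tolerant hom_alt is discordant too
  r3 <- marker_concordance(c(calls, 2L), c(phen, "tolerant"))
  expect_equal(r3$n_discordant, 1L)
  # all missing
  r4 <- marker_concordance(rep(NA_integer_, 4),
                           rep(c("tolerant", "sensitive"), 2))
  expect_equal(r4$n_discordant, 0L)
  expect_equal(r4$n_missing, 4L)
  # dominant_tolerant is the same model from the other side
  expect_equal(marker_concordance(calls, phen,
                                  "dominant_tolerant")$n_discordant, 0L)
  expect_error(marker_concordance(calls, phen, "additive"), "unknown")
})

test_that("screen_panel classifies pooled cultivar calls", {
  calls <- matrix(c(2L, 2L,   # cultivar A: mutant
                    0L, 0L,   # B: wild type
                    2L, 0L,   # C: heterogeneous (mixed pools)
                    1L, 1L,   # D: heterogeneous (het signal)
                    NA, NA),  # E: missing
                  nrow = 1)
  ids <- sprintf("s%d", 1:10)
  gm <- gm_from_calls(calls, rep("cultivar", 10), ids = ids)
  cultivars <- stats::setNames(rep(LETTERS[1:5], each = 2), ids)
  st <- screen_panel(gm, 1L, cultivars)
  expect_equal(st$status[match(LETTERS[1:5], st$cultivar)],
               c("mutant", "wild_type", "heterogeneous", "heterogeneous",
                 "missing"))
})

test_that("a synthetic 384-cultivar panel recovers the 12 planted mutants", {
  set.seed(1031)
  n_panel <- 384L; n_mut <- 12L
  truth <- c(rep(2L, n_mut), rep(0L, n_panel - n_mut))[sample.int(n_panel)]
  panel1 <- toy_panel(matrix(c(0L, 1L), 1, 2), 50)
  gm <- observe_genotypes(matrix(truth, nrow = 1), panel1,
                          coverage_model(c(cultivar = 20), 0), "cultivar",
                          ids = sprintf("CV%03d", seq_len(n_panel)),
                          seed = 1032)
  st <- screen_panel(gm, 1L)
  expect_equal(sort(st$cultivar[st$status == "mutant"]),
               sort(sprintf("CV%03d", which(truth == 2L))))
  expect_equal(sum(st$status == "mutant"), 12L)
})
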