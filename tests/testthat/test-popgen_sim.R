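test_that("simulate_founders plants one causal carrier and is seeded", {
  p <- simulate_founders(11, 200, seed = 11)
  expect_equal(sum(p$alleles[p$causal_site, ]), 1)
  expect_equal(which(p$alleles[p$causal_site, ] == 1L), c(P01 = 1L))
  expect_equal(p$sites$ref[p$causal_site], "A")
  expect_equal(p$sites$alt[p$causal_site], "AA")
  expect_true(all(rowSums(p$alleles) >= 1 &
                    rowSums(p$alleles) <= p$n_founders - 1))  # biallelic
  p2 <- simulate_founders(11, 200, seed = 11)
  expect_identical(p, p2)
  expect_false(identical(p, simulate_founders(11, 200, seed = 12)))
})

test_that("simulate_founders validates its inputs", {
  expect_error(simulate_founders(1, 10, seed = 1), "2 founders")
  expect_error(simulate_founders(5, 0, seed = 1), "n_sites")
  expect_error(simulate_founders(5, 10,
                                 causal = list(chrom = "D10", pos = 99e6,
                                               founder = 1),
                                 seed = 1), "outside")
  expect_error(simulate_founders(5, 10,
                                 causal = list(chrom = "Z9", pos = 10,
                                               founder = 1),
                                 seed = 1), "chromosome")
})

test_that("founder-pair allele differences match the binomial expectation", {
  # each non-causal site differs between two founders w.p. 2 f (1 - f)
  f <- 0.3; n_sites <- 1000
  p <- simulate_founders(11, n_sites, maf = f, seed = 21)
  d <- sum(p$alleles[, 1] != p$alleles[, 2])
  expected <- 2 * f * (1 - f) * n_sites
  sd3 <- 3 * sqrt(n_sites * 2 * f * (1 - f) * (1 - 2 * f * (1 - f)))
  expect_lt(abs(d - expected), sd3)
})

test_that("half_diallel yields one family per unordered founder pair", {
  expect_length(half_diallel(simulate_founders(11, 10, seed = 1)), 55)
  expect_length(half_diallel(simulate_founders(2, 10, seed = 1)), 1)
  fams <- half_diallel(simulate_founders(4, 10, seed = 1))
  expect_length(fams, 6)
  pairs <- t(vapply(fams, `[[`, c(1L, 1L), "parents"))
  expect_true(all(pairs[, 1] < pairs[, 2]))        # no selfs, no reciprocals
  expect_false(anyDuplicated(pairs) > 0)
})

test_that("meiosis of a homozygote reproduces the parental haplotype", {
  p <- simulate_founders(5, 50, seed = 31)
  ind <- founder_individual(p$map, 3L)
  set.seed(1)
  for (i in 1:5) {
    gam <- meiosis(ind, p$map)
    child <- structure(list(hap = list(gam, gam)), class = "individual")
    expect_tiles(child, p$map)
    expect_equal(population_genotypes(list(child), p)[, 1],
                 2L * p$alleles[, 3])
  }
})

test_that("recombinant fraction between two loci follows Haldane's map", {
  d_cM <- 20
  r_expected <- (1 - exp(-2 * d_cM / 100)) / 2
  panel <- toy_panel(cbind(c(0L, 0L), c(1L, 1L)), c(40, 40 + d_cM))
  f1 <- cross(founder_individual(panel$map, 1L),
              founder_individual(panel$map, 2L), panel$map)
  set.seed(41)
  n <- 10000
  rec <- 0L
  for (i in seq_len(n)) {
    gam <- meiosis(f1, panel$map)
    child <- structure(list(hap = list(gam, gam)), class = "individual")
    a <- individual_alleles(child, panel)[, 1]
    rec <- rec + (a[1] != a[2])
  }
  sd3 <- 3 * sqrt(n * r_expected * (1 - r_expected))
  expect_lt(abs(rec - n * r_expected), sd3)
})

test_that("selfing halves heterozygosity per generation", {
  p <- simulate_founders(11, 300, seed = 51)
  des_pre <- breeding_design(n_random_mating_cycles = 2,
                             n_selfing_generations = 0, n_out = 400)
  des_post <- breeding_design(n_random_mating_cycles = 2,
                              n_selfing_generations = 3, n_out = 400)
  pre <- run_magic(p, des_pre, seed = 52)
  post <- run_magic(p, des_post, seed = 52)   # same seed: same parents
  h_pre <- population_heterozygosity(pre, p)
  h_post <- population_heterozygosity(post, p)
  expected <- mean(h_pre) * (1 / 2)^3
  se3 <- 3 * stats::sd(h_post) / sqrt(length(h_post))
  expect_lt(abs(mean(h_post) - expected), se3 + 1e-9)
})

test_that("run_magic degenerate case returns the F1s, fully heterozygous", {
  p <- simulate_founders(6, 80, seed = 61)
  f1s <- run_magic(p, breeding_design(n_random_mating_cycles = 0,
                                      n_selfing_generations = 0,
                                      n_out = 100), seed = 62)
  expect_length(f1s, 15)                       # 6*5/2 families
  fams <- half_diallel(p)
  for (k in seq_along(f1s)) {
    g <- population_genotypes(f1s[k], p)[, 1]
    pa <- fams[[k]]$parents
    differs <- p$alleles[, pa[1]] != p$alleles[, pa[2]]
    expect_equal(g == 1L, differs)
  }
})

test_that("every MAGIC allele traces to a founder and segments tile", {
  p <- simulate_founders(11, 100, seed = 71)
  rils <- run_magic(p, breeding_design(n_out = 40), seed = 72)
  g <- population_genotypes(rils, p)
  expect_true(all(g %in% 0:2))
  for (ind in rils[1:5]) expect_tiles(ind, p$map)
  # determinism
  rils2 <- run_magic(p, breeding_design(n_out = 40), seed = 72)
  expect_identical(rils, rils2)
  expect_error(run_magic(p, breeding_design("biparental_f2"), seed = 1),
               "scheme")
})

test_that("run_f2 segregates 1:2:1 at the causal site", {
  p <- simulate_founders(11, 60, seed = 81)
  f2 <- run_f2(p, p$causal_founder, 2L, 800, seed = 82)
  g <- population_genotypes(f2, p)[p$causal_site, ]
  expect_lt(abs(sum(g == 2L) - 200), 3 * sqrt(800 * 0.25 * 0.75))
  expect_identical(run_f2(p, 1, 2, 1, seed = 5), run_f2(p, 1, 2, 1, seed = 5))
  expect_error(run_f2(p, 1, 2, 0, seed = 1), "n must be")
  expect_warning(run_f2(p, 2, 3, 1, seed = 1), "identical at the causal")
})

test_that("phenotypes follow the recessive-sensitivity model", {
  expect_equal(as.character(assign_phenotypes(c(2L, 1L, 0L))$phenotype),
               c("sensitive", "tolerant", "tolerant"))
  expect_true(all(assign_phenotypes(rep(2L, 50),
                                    penetrance = 0)$phenotype == "tolerant"))
  expect_error(assign_phenotypes(c(0L, 2L), model = "dominant_lethal"),
               "unknown")
  expect_error(assign_phenotypes(c(0L, NA)), "genotyped")
})

test_that("observation model behaves at its limits", {
  p <- simulate_founders(5, 80, seed = 91)
  pop <- lapply(1:5, function(i) founder_individual(p$map, i))
  gm0 <- observe_genotypes(pop, p, coverage_model(c(x = 0)), "x", seed = 92)
  expect_true(all(is.na(gm0$calls)))
  expect_true(all(gm0$depth == 0L))
  # infinite-coverage limit: calls equal truth
  gm50 <- observe_genotypes(pop, p, coverage_model(c(x = 50), error = 0),
                            "x", seed = 93)
  truth <- population_genotypes(pop, p)
  expect_equal(unname(gm50$calls[gm50$depth > 0]), truth[gm50$depth > 0])
  # e = 0: a true homozygote is never called het
  expect_false(any(gm50$calls == 1L, na.rm = TRUE))
  # determinism, byte-for-byte through the VCF writer
  gm_a <- observe_genotypes(pop, p, coverage_model(c(x = 3)), "x", seed = 94)
  gm_b <- observe_genotypes(pop, p, coverage_model(c(x = 3)), "x", seed = 94)
  expect_identical(gm_a, gm_b)
  fa <- tempfile(fileext = ".vcf"); fb <- tempfile(fileext = ".vcf")
  write_vcf(gm_a, fa, seed = 94); write_vcf(gm_b, fb, seed = 94)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("het miscall rate at low coverage matches the Poisson-binomial sum", {
  # true het, e = 0: P(called hom_ref) = sum_d Pois(d; lambda) (1/2)^d, d >= 1
  lambda <- 3
  d <- 1:30
  p_hom_one_class <- sum(stats::dpois(d, lambda) * (1 / 2)^d)
  panel <- toy_panel(matrix(c(0L, 1L), 1, 2), 50)
  f1 <- cross(founder_individual(panel$map, 1L),
              founder_individual(panel$map, 2L), panel$map)
  n <- 4000
  truth <- matrix(1L, nrow = 1, ncol = n)
  gm <- observe_genotypes(truth, panel, coverage_model(c(x = lambda), 0),
                          "x", seed = 101)
  n_hom_ref <- sum(gm$calls == 0L, na.rm = TRUE)
  sd3 <- 3 * sqrt(n * p_hom_one_class * (1 - p_hom_one_class))
  expect_lt(abs(n_hom_ref - n * p_hom_one_class), sd3)
  n_hom_alt <- sum(gm$calls == 2L, na.rm = TRUE)
  expect_lt(abs(n_hom_alt - n * p_hom_one_class), sd3)
})

test_that("coverage_model validates parameters", {
  expect_error(coverage_model(c(RIL = -1)), "lambda")
  expect_error(coverage_model(c(RIL = 3), error = 0.5), "error")
})
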