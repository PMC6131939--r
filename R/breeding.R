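#' Breeding design
#'
#' Describes either the MAGIC scheme (half-diallel F1s, cycles of random
#' mating by bulked pollen, then selfing by single-seed descent) or a
#' biparental F2.
#'
#' @param scheme "half_diallel_magic" or "biparental_f2".
#' @param n_random_mating_cycles random-mating cycles after the half-diallel
#'   (5 in the MAGIC design).
#' @param n_selfing_generations selfing generations by single-seed descent
#'   (6 in the MAGIC design).
#' @param n_out target population size (550 RILs; 1695 or 2145 F2).
#' @return object of class `breeding_design`.
#' @export
breeding_design <- function(scheme = c("half_diallel_magic", "biparental_f2"),
                            n_random_mating_cycles = 5L,
                            n_selfing_generations = 6L,
                            n_out = 550L) {
  scheme <- match.arg(scheme)
  if (n_random_mating_cycles < 0L || n_selfing_generations < 0L)
    stop("cycle/generation counts must be non-negative")
  if (n_out < 0L) stop("n_out must be non-negative")
  structure(list(scheme = scheme,
                 n_random_mating_cycles = as.integer(n_random_mating_cycles),
                 n_selfing_generations = as.integer(n_selfing_generations),
                 n_out = as.integer(n_out)),
            class = "breeding_design")
}

#' Half-diallel F1 families
#'
#' One F1 per unordered pair of founders, no selfs, no reciprocals:
#' n(n-1)/2 families (55 for 11 founders).
#'
#' @param panel a `founder_panel`.
#' @return list of families, each `list(parents = c(i, j), f1 = individual)`.
#' @export
half_diallel <- function(panel) {
  stopifnot(inherits(panel, "founder_panel"))
  n <- panel$n_founders
  if (n < 2L) stop("half-diallel needs at least 2 founders")
  fams <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    k <- k + 1L
    f1 <- structure(list(hap = list(new_haplotype(panel$map, i),
                                    new_haplotype(panel$map, j))),
                    class = "individual")
    fams[[k]] <- list(parents = c(i, j), f1 = f1)
  }
  fams
}

#' Simulate the MAGIC population
#'
#' Cycle 0 is the half-diallel F1 set. Each random-mating cycle draws, for
#' every offspring, a seed parent uniformly from the current population and a
#' pollen parent uniformly from the whole population independently of the
#' seed parent (the "bulked equal pollen" reading; selfing therefore occurs
#' at rate 1/N). After the cycles, each line is self-pollinated for
#' `n_selfing_generations` generations by single-seed descent.
#'
#' With zero cycles and zero selfing generations the raw F1 set is returned
#' (one individual per family).
#'
#' @param panel a `founder_panel`.
#' @param design a `breeding_design` with scheme "half_diallel_magic".
#' @param seed integer seed.
#' @return list of `individual` RILs, length `design$n_out` (or the F1 count
#'   in the degenerate no-cycle no-selfing case).
#' @export
run_magic <- function(panel, design = breeding_design(), seed = NULL) {
  stopifnot(inherits(panel, "founder_panel"),
            inherits(design, "breeding_design"))
  if (design$scheme != "half_diallel_magic")
    stop("run_magic requires scheme 'half_diallel_magic'")
  if (!is.null(seed)) set.seed(seed)
  pop <- lapply(half_diallel(panel), `[[`, "f1")
  if (design$n_random_mating_cycles == 0L &&
      design$n_selfing_generations == 0L)
    return(pop)
  for (cyc in seq_len(design$n_random_mating_cycles)) {
    seed_par <- sample.int(length(pop), design$n_out, replace = TRUE)
    pollen_par <- sample.int(length(pop), design$n_out, replace = TRUE)
    pop <- lapply(seq_len(design$n_out), function(m)
      cross(pop[[seed_par[m]]], pop[[pollen_par[m]]], panel$map))
  }
  if (length(pop) != design$n_out) {  # no cycles: sample seed parents from F1s
    idx <- sample.int(length(pop), design$n_out, replace = TRUE)
    pop <- pop[idx]
  }
  for (g in seq_len(design$n_selfing_generations))
    pop <- lapply(pop, function(ind) cross(ind, ind, panel$map))
  pop
}

#' Simulate a biparental F2 population
#'
#' A single F1 between the two founders is self-pollinated; each F2 is the
#' union of two independent meioses of that F1. The causal genotype
#' frequencies approach 1:2:1.
#'
#' @param panel a `founder_panel`.
#' @param founder_a,founder_b founder indices of the two parents.
#' @param n number of F2 individuals (>= 1).
#' @param seed integer seed.
#' @return list of `individual`s.
#' @export
run_f2 <- function(panel, founder_a, founder_b, n, seed = NULL) {
  stopifnot(inherits(panel, "founder_panel"))
  if (n < 1L) stop("n must be >= 1")
  if (panel$alleles[panel$causal_site, founder_a] ==
      panel$alleles[panel$causal_site, founder_b])
    warning("founders identical at the causal site: no segregation expected")
  if (!is.null(seed)) set.seed(seed)
  f1 <- structure(list(hap = list(new_haplotype(panel$map, founder_a),
                                  new_haplotype(panel$map, founder_b))),
                  class = "individual")
  lapply(seq_len(n), function(i) cross(f1, f1, panel$map))
}
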