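#' Coverage model
#'
#' Mean sequencing depth per sample class plus a per-read allele error rate.
#' The study design sequenced parents at 20x and RILs at 3x.
#'
#' @param lambda named numeric vector of mean depths per sample class, e.g.
#'   `c(parent = 20, RIL = 3)`.
#' @param error per-read probability of reporting the wrong allele
#'   (0 <= e < 0.5).
#' @return object of class `coverage_model`.
#' @export
coverage_model <- function(lambda = c(parent = 20, RIL = 3), error = 0.001) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (error < 0 || error >= 0.5) stop("error must satisfy 0 <= e < 0.5")
  structure(list(lambda = lambda, error = error), class = "coverage_model")
}

#' Genotype matrix
#'
#' Sites x samples call matrix over hom-ref (0), het (1), hom-alt (2) and
#' missing (NA), with per-cell read depth.
#'
#' @param sites data.frame with chrom, pos, ref, alt.
#' @param samples data.frame with id, class (parent/RIL/F2/cultivar).
#' @param calls integer matrix sites x samples in {0, 1, 2, NA}.
#' @param depth integer matrix sites x samples, depth >= 0.
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, calls, depth) {
  stopifnot(nrow(calls) == nrow(sites), ncol(calls) == nrow(samples),
            all(dim(calls) == dim(depth)))
  if (anyDuplicated(samples$id)) stop("duplicated sample ids")
  if (!all(unlist(tapply(sites$pos, sites$chrom, function(p) !is.unsorted(p)))))
    stop("sites must be sorted by position within chromosome")
  structure(list(sites = sites, samples = samples,
                 calls = calls, depth = depth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples (%s)\n",
              nrow(x$sites), nrow(x$samples),
              paste(sprintf("%s: %d", names(table(x$samples$class)),
                            table(x$samples$class)), collapse = ", ")))
  invisible(x)
}

#' Observe genotypes at finite coverage
#'
#' A naive pileup caller: per site and sample the read depth is
#' Poisson(lambda of the sample's class); each read reports one of the
#' individual's two true alleles and is flipped with probability `error`.
#' The call is missing at depth 0, heterozygous if both alleles are seen,
#' else the homozygote of the observed allele. At high depth and zero error
#' the calls equal the true genotypes.
#'
#' @param pop list of `individual`s, or a true-dosage matrix (sites x
#'   samples, values 0/1/2) as returned by [population_genotypes()].
#' @param panel the `founder_panel` (defines the sites).
#' @param model a `coverage_model`.
#' @param classes character vector: class of each sample (indexes into
#'   `model$lambda`).
#' @param ids sample ids.
#' @param seed integer seed.
#' @return a `genotype_matrix`.
#' @export
observe_genotypes <- function(pop, panel, model = coverage_model(),
                              classes = "RIL", ids = NULL, seed = NULL) {
  stopifnot(inherits(model, "coverage_model"))
  g <- if (is.matrix(pop)) pop else population_genotypes(pop, panel)
  n_sites <- nrow(g); n_samp <- ncol(g)
  classes <- rep_len(classes, n_samp)
  if (!all(classes %in% names(model$lambda)))
    stop("coverage model lacks lambda for class(es): ",
         paste(setdiff(classes, names(model$lambda)), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  lam <- matrix(model$lambda[classes], n_sites, n_samp, byrow = TRUE)
  d <- matrix(stats::rpois(n_sites * n_samp, lam), n_sites, n_samp)
  # P(a read reports alt) given true dosage g and error e
  p_alt <- g / 2 * (1 - model$error) + (1 - g / 2) * model$error
  n_alt <- matrix(stats::rbinom(n_sites * n_samp, as.vector(d),
                                as.vector(p_alt)), n_sites, n_samp)
  calls <- matrix(NA_integer_, n_sites, n_samp)
  calls[d > 0 & n_alt == 0] <- 0L
  calls[d > 0 & n_alt == d] <- 2L
  calls[d > 0 & n_alt > 0 & n_alt < d] <- 1L
  if (is.null(ids)) ids <- sprintf("S%04d", seq_len(n_samp))
  genotype_matrix(panel$sites,
                  data.frame(id = ids, class = classes),
                  calls, d)
}

#' Combine genotype matrices over the same sites
#' @param ... `genotype_matrix` objects sharing identical site tables.
#' @return a `genotype_matrix` with samples concatenated.
#' @export
cbind_genotypes <- function(...) {
  gs <- list(...)
  for (g in gs[-1])
    if (!identical(g$sites, gs[[1]]$sites))
      stop("genotype matrices must share identical site tables")
  genotype_matrix(gs[[1]]$sites,
                  do.call(rbind, lapply(gs, `[[`, "samples")),
                  do.call(cbind, lapply(gs, `[[`, "calls")),
                  do.call(cbind, lapply(gs, `[[`, "depth")))
}
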