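#' Summarize replicate expression measurements
#'
#' Collapses a raw replicate table (gene, genotype, dose, replicate, value)
#' to per-condition mean and sample SD. The assay design uses six biological
#' replicates; cells with fewer replicates than `expected_replicates` are
#' tolerated down to n = 2 with a warning, and below that raise an error
#' unless `allow_single = TRUE`.
#'
#' @param raw data.frame with columns `gene`, `genotype`, `dose`, `value`
#'   (one row per replicate).
#' @param expected_replicates nominal replicate count (default 6).
#' @param allow_single permit cells with a single replicate (SD becomes NA).
#' @return an `expression_table`: data.frame with `gene`, `genotype`,
#'   `dose`, `n`, `mean`, `sd`.
#' @export
summarize_replicates <- function(raw, expected_replicates = 6L,
                                 allow_single = FALSE) {
  stopifnot(all(c("gene", "genotype", "dose", "value") %in% names(raw)))
  agg <- stats::aggregate(value ~ gene + genotype + dose, data = raw,
                          FUN = function(x) c(n = length(x), mean = mean(x),
                                              sd = stats::sd(x)))
  out <- data.frame(gene = agg$gene, genotype = agg$genotype,
                    dose = agg$dose,
                    n = as.integer(agg$value[, "n"]),
                    mean = agg$value[, "mean"], sd = agg$value[, "sd"])
  if (any(out$n < 2L) && !allow_single)
    stop("cells with < 2 replicates; use allow_single = TRUE to permit")
  if (any(out$n >= 2L & out$n < expected_replicates))
    warning("some cells have fewer than ", expected_replicates,
            " replicates (minimum observed: ", min(out$n), ")")
  out <- out[order(out$gene, out$genotype, out$dose), ]
  rownames(out) <- NULL
  structure(out, class = c("expression_table", "data.frame"))
}

# per-gene profile over conditions (genotype x dose means), aligned order
.profile_matrix <- function(tab) {
  cond <- interaction(tab$genotype, tab$dose, drop = TRUE, lex.order = TRUE)
  genes <- unique(tab$gene)
  m <- matrix(NA_real_, length(levels(cond)), length(genes),
              dimnames = list(levels(cond), genes))
  m[cbind(match(cond, levels(cond)), match(tab$gene, genes))] <- tab$mean
  if (anyNA(m)) stop("every gene needs a mean for every condition")
  m
}

#' Pearson co-expression against a reference gene
#'
#' Correlates each gene's condition-mean profile (both genotypes x all
#' doses) with the reference gene's profile. A gene is classified
#' "co_induced" when r exceeds `tau` (default 0.7), optionally also
#' requiring p < `alpha`. Genes with a constant profile have undefined r and
#' are classified "constant", outside both classes.
#'
#' @param tab an `expression_table` (from [summarize_replicates()]).
#' @param reference reference gene id.
#' @param tau correlation threshold (default 0.7).
#' @param alpha significance level used when `require_significance = TRUE`.
#' @param require_significance also require the two-sided p-value below
#'   `alpha` for the co_induced class.
#' @return a `coexpression_result`: data.frame with `gene`, `r`, `p`,
#'   `class` in {co_induced, other, constant}; the reference is excluded.
#' @export
correlate_with_reference <- function(tab, reference, tau = 0.7,
                                     alpha = 0.05,
                                     require_significance = FALSE) {
  m <- .profile_matrix(tab)
  if (!reference %in% colnames(m)) stop("reference gene not in table")
  ref <- m[, reference]
  if (stats::sd(ref) == 0) stop("reference profile is constant")
  genes <- setdiff(colnames(m), reference)
  res <- lapply(genes, function(g) {
    x <- m[, g]
    if (stats::sd(x) == 0)
      return(data.frame(gene = g, r = NA_real_, p = NA_real_,
                        class = "constant"))
    ct <- stats::cor.test(x, ref, method = "pearson")
    co <- ct$estimate > tau &&
      (!require_significance || ct$p.value < alpha)
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value,
               class = if (co) "co_induced" else "other")
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("coexpression_result", "data.frame"),
            reference = reference, tau = tau)
}

#' Generate a synthetic dose-response expression experiment
#'
#' Emulates the RT-qPCR dose series: a reference gene with a step-induction
#' profile (induced at and above 50 uM in the sensitive genotype, induced
#' only at 3000 uM in the tolerant genotype), a set of co-regulated genes
#' sharing that profile up to a positive gene-specific scale, and a set of
#' independent genes that are flat. Gaussian noise is added per replicate.
#'
#' @param n_coregulated genes sharing the reference profile (default 7).
#' @param n_independent flat genes (default 13).
#' @param doses dose series in uM (default `c(0, 12.5, 50, 100, 3000)`).
#' @param n_replicates biological replicates per condition (default 6).
#' @param baseline uninduced relative-expression mean (default 1).
#' @param induced induced relative-expression mean (default 8).
#' @param noise_sd replicate-level Gaussian noise SD (default 0.5).
#' @param seed integer seed.
#' @return list with `raw` (replicate table: gene, genotype, dose,
#'   replicate, value), `truth` (gene -> co_regulated flag), `reference`
#'   (the reference gene id, "REF").
#' @export
generate_expression <- function(n_coregulated = 7L, n_independent = 13L,
                                doses = c(0, 12.5, 50, 100, 3000),
                                n_replicates = 6L, baseline = 1,
                                induced = 8, noise_sd = 0.5, seed = NULL) {
  if (noise_sd < 0) stop("noise SD must be >= 0")
  if (n_replicates < 1L) stop("need at least one replicate")
  if (!is.null(seed)) set.seed(seed)
  genotypes <- c("tolerant", "sensitive")
  step_mean <- function(genotype, dose)
    ifelse(genotype == "sensitive" & dose >= 50, induced,
           ifelse(genotype == "tolerant" & dose >= 3000, induced, baseline))
  cond <- expand.grid(genotype = genotypes, dose = doses,
                      stringsAsFactors = FALSE)
  ref_mu <- step_mean(cond$genotype, cond$dose)
  genes <- c("REF",
             if (n_coregulated) sprintf("CO%02d", seq_len(n_coregulated)),
             if (n_independent) sprintf("IND%02d", seq_len(n_independent)))
  co_flag <- stats::setNames(
    c(TRUE, rep(TRUE, n_coregulated), rep(FALSE, n_independent)), genes)
  scale <- stats::setNames(c(1, stats::runif(n_coregulated, 0.5, 2),
                             rep(NA_real_, n_independent)), genes)
  rows <- lapply(genes, function(g) {
    mu <- if (co_flag[[g]]) scale[[g]] * ref_mu
          else rep(baseline, nrow(cond))
    do.call(rbind, lapply(seq_len(n_replicates), function(rep_i)
      data.frame(gene = g, genotype = cond$genotype, dose = cond$dose,
                 replicate = rep_i,
                 value = stats::rnorm(nrow(cond), mu, noise_sd))))
  })
  raw <- do.call(rbind, rows)
  rownames(raw) <- NULL
  list(raw = raw, truth = co_flag[names(co_flag) != "REF"],
       reference = "REF")
}

#' Read/write replicate expression tables as TSV
#' @param raw replicate table data.frame.
#' @param path file path.
#' @export
write_expression <- function(raw, path) {
  utils::write.table(raw, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
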