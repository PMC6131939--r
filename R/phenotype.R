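#' Assign herbicide phenotypes
#'
#' Under the recessive-sensitivity model only individuals homozygous for the
#' causal (disrupted) allele are sensitive; heterozygotes and homozygous
#' wild-type are tolerant, i.e. tolerance behaves as a single dominant locus.
#' `penetrance` is the probability that a causal homozygote expresses
#' sensitivity (default 1).
#'
#' @param pop list of `individual`s, or an integer vector of causal-site
#'   dosages (0/1/2).
#' @param panel the `founder_panel` (needed when `pop` is a list of
#'   individuals).
#' @param causal_site site index; defaults to the panel's planted causal
#'   site.
#' @param model only "recessive_sensitive" is defined.
#' @param penetrance probability in [0, 1].
#' @param ids sample ids; default "S0001"...
#' @param seed integer seed (used only when penetrance < 1).
#' @return a `phenotype_table`: data.frame with columns `sample`,
#'   `phenotype` (factor tolerant/sensitive).
#' @export
assign_phenotypes <- function(pop, panel = NULL, causal_site = NULL,
                              model = "recessive_sensitive", penetrance = 1,
                              ids = NULL, seed = NULL) {
  if (!identical(model, "recessive_sensitive"))
    stop("unknown phenotype model: ", model)
  if (penetrance < 0 || penetrance > 1) stop("penetrance must be in [0, 1]")
  if (is.list(pop)) {
    stopifnot(inherits(panel, "founder_panel"))
    if (is.null(causal_site)) causal_site <- panel$causal_site
    g <- population_genotypes(pop, panel)[causal_site, ]
  } else {
    g <- as.integer(pop)
  }
  if (anyNA(g)) stop("causal site must be genotyped in every individual")
  if (!is.null(seed)) set.seed(seed)
  expressed <- if (penetrance >= 1) rep(TRUE, length(g))
               else stats::runif(length(g)) < penetrance
  lab <- ifelse(g == 2L & expressed, "sensitive", "tolerant")
  if (is.null(ids)) ids <- sprintf("S%04d", seq_along(g))
  structure(data.frame(sample = ids,
                       phenotype = factor(lab, c("tolerant", "sensitive"))),
            class = c("phenotype_table", "data.frame"))
}

#' Read/write phenotype tables as TSV
#' @param phen a `phenotype_table`.
#' @param path file path.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.table(phen, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  stopifnot(all(c("sample", "phenotype") %in% names(d)))
  d$phenotype <- factor(d$phenotype, c("tolerant", "sensitive"))
  structure(d, class = c("phenotype_table", "data.frame"))
}
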