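#' Filter configuration for the concordance filter
#'
#' @param mode "permissive" (missing calls never disqualify — appropriate at
#'   3x skim coverage, where ~5% of calls are missing) or "strict" (missing
#'   disqualifies — appropriate for full-coverage data).
#' @param region optional `list(chrom, start, end)` restricting the scan to
#'   the vicinity of a known locus.
#' @param require_tolerant_exclusion if TRUE (default), a tolerant RIL called
#'   hom-alt disqualifies a site ("unique to the sensitive parent").
#' @return object of class `filter_config`.
#' @export
filter_config <- function(mode = c("permissive", "strict"), region = NULL,
                          require_tolerant_exclusion = TRUE) {
  mode <- match.arg(mode)
  if (!is.null(region)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(region)))
    if (region$start > region$end) stop("malformed region: start > end")
  }
  structure(list(mode = mode, region = region,
                 require_tolerant_exclusion =
                   isTRUE(require_tolerant_exclusion)),
            class = "filter_config")
}

#' Phenotype-concordance variant filter
#'
#' Implements the discovery filter for a recessive causal variant: a site is
#' a candidate iff
#' (a) the sensitive parent is homozygous-alt;
#' (b) every other parent is homozygous-ref;
#' (c) every sensitive RIL is homozygous-alt (a heterozygous call always
#'     disqualifies: RILs are near-fully inbred and a het sensitive RIL
#'     contradicts recessiveness);
#' (d) optionally, no tolerant RIL is homozygous-alt (heterozygous tolerant
#'     samples are expected carriers under a recessive trait and never
#'     disqualify).
#' In permissive mode a missing call never disqualifies; in strict mode any
#' missing call among the samples a rule examines does.
#'
#' @param gm a `genotype_matrix` whose samples include one "parent"-class
#'   sample per founder and the RIL panel.
#' @param phenotypes a `phenotype_table` covering (at least) the non-parent
#'   samples.
#' @param sensitive_parent sample id of the sensitive parent.
#' @param config a `filter_config`.
#' @return a `candidate_set`: data.frame with site columns and evidence
#'   tallies `n_sens_hom_alt`, `n_sens_missing`, `n_other_parent_missing`,
#'   `n_tol_hom_alt`.
#' @export
concordance_filter <- function(gm, phenotypes, sensitive_parent,
                               config = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(config, "filter_config"))
  sp <- match(sensitive_parent, gm$samples$id)
  if (is.na(sp)) stop("sensitive parent not found in genotype matrix")
  is_parent <- gm$samples$class == "parent"
  other_par <- which(is_parent & seq_len(nrow(gm$samples)) != sp)
  phen <- phenotypes$phenotype[match(gm$samples$id, phenotypes$sample)]
  sens <- which(!is_parent & !is.na(phen) & phen == "sensitive")
  tol <- which(!is_parent & !is.na(phen) & phen == "tolerant")
  if (length(sens) == 0L) stop("no sensitive non-parent samples")

  keep_sites <- seq_len(nrow(gm$sites))
  if (!is.null(config$region)) {
    r <- config$region
    keep_sites <- which(gm$sites$chrom == r$chrom & gm$sites$pos >= r$start &
                          gm$sites$pos <= r$end)
  }
  calls <- gm$calls[keep_sites, , drop = FALSE]
  strict <- config$mode == "strict"

  ok_or_missing <- function(block, value) {
    # per-site TRUE iff every call in the block equals `value`,
    # missing allowed unless strict
    bad <- block != value                      # NA where missing
    n_bad <- rowSums(bad, na.rm = TRUE)
    n_na <- rowSums(is.na(block))
    n_bad == 0L & (!strict | n_na == 0L)
  }

  pass_a <- ok_or_missing(calls[, sp, drop = FALSE], 2L)
  pass_b <- if (length(other_par)) ok_or_missing(calls[, other_par, drop = FALSE], 0L)
            else TRUE
  sens_block <- calls[, sens, drop = FALSE]
  pass_c <- ok_or_missing(sens_block, 2L)
  # het sensitive RILs disqualify in every mode (covered by != 2 above)
  tol_block <- calls[, tol, drop = FALSE]
  n_tol_hom_alt <- rowSums(tol_block == 2L, na.rm = TRUE)
  pass_d <- if (config$require_tolerant_exclusion) {
    # het tolerant samples are expected carriers under recessiveness and
    # never disqualify; missing disqualifies only in strict mode
    n_tol_bad <- n_tol_hom_alt +
      if (strict) rowSums(is.na(tol_block)) else 0L
    n_tol_bad == 0L
  } else TRUE

  pass <- pass_a & pass_b & pass_c & pass_d
  idx <- keep_sites[pass]
  out <- cbind(gm$sites[idx, , drop = FALSE],
               data.frame(
                 n_sens_hom_alt = rowSums(sens_block == 2L, na.rm = TRUE)[pass],
                 n_sens_missing = rowSums(is.na(sens_block))[pass],
                 n_other_parent_missing =
                   rowSums(is.na(calls[, other_par, drop = FALSE]))[pass],
                 n_tol_hom_alt = n_tol_hom_alt[pass]))
  rownames(out) <- NULL
  structure(out, class = c("candidate_set", "data.frame"),
            site_index = idx)
}

#' Marker-phenotype concordance at one site
#'
#' Under the recessive-sensitivity model a sample is discordant if it is
#' sensitive but not homozygous-alt, or tolerant but homozygous-alt. Missing
#' genotypes are reported separately and never counted discordant.
#' "dominant_tolerant" is the same model stated from the tolerant side and is
#' accepted as a synonym.
#'
#' @param calls integer vector of calls (0/1/2/NA), one per sample.
#' @param phenotypes a `phenotype_table` (or factor/character vector aligned
#'   with `calls`).
#' @param model "recessive_sensitive" or "dominant_tolerant".
#' @return list with the 3x2 genotype-by-phenotype `table`, `n_discordant`,
#'   `n_missing`.
#' @export
marker_concordance <- function(calls, phenotypes,
                               model = "recessive_sensitive") {
  if (!model %in% c("recessive_sensitive", "dominant_tolerant"))
    stop("unknown concordance model: ", model)
  phen <- if (inherits(phenotypes, "data.frame")) phenotypes$phenotype
          else phenotypes
  stopifnot(length(calls) == length(phen))
  phen <- factor(as.character(phen), c("tolerant", "sensitive"))
  geno <- factor(calls, levels = 0:2,
                 labels = c("hom_ref", "het", "hom_alt"))
  tab <- table(genotype = geno, phenotype = phen, useNA = "no")
  n_missing <- sum(is.na(calls))
  n_disc <- sum(!is.na(calls) &
                  ((phen == "sensitive" & calls != 2L) |
                     (phen == "tolerant" & calls == 2L)))
  list(table = tab, n_discordant = n_disc, n_missing = n_missing)
}

#' Screen a cultivar diversity panel for a mutant allele
#'
#' Each cultivar is represented by one or more (possibly pooled) samples.
#' A cultivar is "mutant" if all its non-missing calls are hom-alt,
#' "wild_type" if all are hom-ref, and "heterogeneous" if calls are mixed or
#' any call is heterozygous (the pooled-DNA signal of a segregating
#' cultivar).
#'
#' @param gm a `genotype_matrix`.
#' @param site site index (row of `gm$sites`) of the allele of interest.
#' @param cultivars named character vector mapping sample id -> cultivar
#'   name; defaults to one cultivar per sample.
#' @return data.frame with `cultivar` and `status` in
#'   {mutant, wild_type, heterogeneous, missing}.
#' @export
screen_panel <- function(gm, site, cultivars = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(cultivars))
    cultivars <- stats::setNames(gm$samples$id, gm$samples$id)
  calls <- gm$calls[site, ]
  cv <- cultivars[gm$samples$id]
  if (anyNA(cv)) stop("every sample must map to a cultivar")
  groups <- split(calls, cv)
  if (any(lengths(groups) == 0L)) stop("empty cultivar pool")
  status <- vapply(groups, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return("missing")
    if (all(x == 2L)) return("mutant")
    if (all(x == 0L)) return("wild_type")
    "heterogeneous"
  }, "")
  data.frame(cultivar = names(groups), status = unname(status))
}
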