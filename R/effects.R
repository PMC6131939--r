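#' Gene model
#'
#' A protein-coding gene model: chromosome, strand, and ordered exon
#' intervals (1-based, closed) defining the CDS frame.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param exons two-column matrix or data.frame of exon `start`, `end`
#'   (1-based closed, genome coordinates, sorted, non-overlapping).
#' @param cds_phase bases to skip before the first complete codon (0/1/2).
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand = c("+", "-"), exons,
                       cds_phase = 0L) {
  strand <- match.arg(strand)
  exons <- as.matrix(exons)
  if (ncol(exons) != 2L) stop("exons must have two columns (start, end)")
  colnames(exons) <- c("start", "end")
  if (any(exons[, 2] < exons[, 1])) stop("exon end < start")
  if (is.unsorted(exons[, 1], strictly = TRUE))
    stop("exons must be sorted in genome order")
  if (nrow(exons) > 1L &&
      any(exons[-1, 1] <= exons[-nrow(exons), 2]))
    stop("exons overlap")
  if (sum(exons[, 2] - exons[, 1] + 1) < 3) stop("total CDS length < 3")
  if (!cds_phase %in% 0:2) stop("cds_phase must be 0, 1 or 2")
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds_phase = as.integer(cds_phase)),
            class = "gene_model")
}

#' Variant record
#' @param chrom chromosome; @param pos 1-based position; @param ref,alt
#'   allele strings (anchored VCF style for indels).
#' @return object of class `variant`.
#' @export
variant <- function(chrom, pos, ref, alt) {
  if (!nzchar(ref) || !nzchar(alt)) stop("ref/alt must be non-empty")
  structure(list(chrom = chrom, pos = as.integer(pos),
                 ref = toupper(ref), alt = toupper(alt)),
            class = "variant")
}

#' Normalize an indel (trim shared bases; left-align against a reference)
#'
#' Trims the common suffix, then the common prefix down to a single anchor
#' base, and — when the reference sequence is supplied — shifts the indel
#' left while the base preceding the anchor equals the last base of the
#' inserted/deleted run. Indel positions are only comparable under a fixed
#' normalization.
#'
#' @param v a `variant`.
#' @param ref_seq optional reference chromosome sequence (character), used
#'   for left alignment.
#' @return a normalized `variant`.
#' @export
normalize_variant <- function(v, ref_seq = NULL) {
  r <- strsplit(v$ref, "")[[1]]; a <- strsplit(v$alt, "")[[1]]
  # trim common suffix (keep at least one base each)
  while (length(r) > 1L && length(a) > 1L &&
         r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # trim common prefix, advancing pos, keeping one anchor for indels
  pos <- v$pos
  while (length(r) > 1L && length(a) > 1L && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1L
  }
  is_ins <- length(a) > length(r) && length(r) == 1L && r[1] == a[1]
  is_del <- length(r) > length(a) && length(a) == 1L && r[1] == a[1]
  if (!is.null(ref_seq) && (is_ins || is_del)) {
    # shift an anchored indel left while the base before the anchor equals
    # the last base of the inserted/deleted run
    run <- if (is_ins) a[-1] else r[-1]
    chars <- strsplit(toupper(ref_seq), "")[[1]]
    while (pos > 1L && chars[pos] == run[length(run)]) {
      run <- c(chars[pos], run[-length(run)])
      pos <- pos - 1L
    }
    anchor <- if (pos <= length(chars)) chars[pos] else r[1]
    r <- if (is_del) c(anchor, run) else anchor
    a <- if (is_ins) c(anchor, run) else anchor
  }
  variant(v$chrom, pos, paste(r, collapse = ""), paste(a, collapse = ""))
}

# cumulative CDS length of exons strictly 5' of exon i (transcript sense)
.cds_before <- function(g, exon_idx) {
  len <- g$exons[, 2] - g$exons[, 1] + 1
  if (g$strand == "+") {
    if (exon_idx == 1L) 0 else sum(len[seq_len(exon_idx - 1L)])
  } else {
    if (exon_idx == nrow(g$exons)) 0 else sum(len[seq(exon_idx + 1L, nrow(g$exons))])
  }
}

#' Classify a variant's coding effect against a gene model
#'
#' Maps the variant to exon or intron, counts the affected exon ordinal in
#' transcript orientation (strand-aware), computes the CDS offset and codon
#' number from cumulative exon lengths, and decides frameshift vs in-frame
#' from the indel length modulo 3. A variant whose affected bases cross an
#' exon-intron boundary gets the explicit category "boundary_spanning".
#'
#' @param v a `variant` (normalized first; pass `ref_seq` to left-align).
#' @param g a `gene_model`.
#' @param ref_seq optional chromosome sequence for indel left-alignment.
#' @return a `variant_effect`: list with `category` (one of intergenic,
#'   intronic, exonic_substitution, exonic_inframe, exonic_frameshift,
#'   boundary_spanning), `exon` (ordinal in transcript orientation or NA),
#'   `cds_offset`, `codon`, `indel_length`.
#' @examples
#' g <- gene_model("toy", "D10", "+",
#'                 cbind(c(100, 300, 500, 700, 900),
#'                       c(199, 399, 599, 799, 999)))
#' classify_variant_effect(variant("D10", 550, "A", "AA"), g)
#' @export
classify_variant_effect <- function(v, g, ref_seq = NULL) {
  stopifnot(inherits(v, "variant"), inherits(g, "gene_model"))
  v <- normalize_variant(v, ref_seq)
  indel_len <- abs(nchar(v$alt) - nchar(v$ref))
  is_indel <- indel_len > 0L
  eff <- function(category, exon = NA_integer_, cds_offset = NA_integer_,
                  codon = NA_integer_)
    structure(list(category = category, exon = exon,
                   cds_offset = cds_offset, codon = codon,
                   indel_length = indel_len, gene_id = g$gene_id),
              class = "variant_effect")
  gene_span <- range(g$exons)
  if (v$chrom != g$chrom || v$pos > gene_span[2] ||
      (v$pos + nchar(v$ref) - 1L) < gene_span[1])
    return(eff("intergenic"))

  pure_ins <- is_indel && nchar(v$ref) == 1L &&
    substr(v$alt, 1, 1) == v$ref
  # genomic interval whose bases are altered; a pure insertion lands in the
  # joint between pos and pos+1
  if (pure_ins) {
    from <- v$pos; to <- v$pos + 1L
  } else if (is_indel && nchar(v$alt) == 1L &&
             substr(v$ref, 1, 1) == v$alt) {
    from <- v$pos + 1L; to <- v$pos + nchar(v$ref) - 1L  # deleted bases
  } else {
    from <- v$pos; to <- v$pos + nchar(v$ref) - 1L       # altered bases
  }
  exon_of <- function(p) {
    e <- which(g$exons[, 1] <= p & p <= g$exons[, 2])
    if (length(e)) e else NA_integer_
  }
  e_from <- exon_of(from); e_to <- exon_of(to)
  if (is.na(e_from) || is.na(e_to) || e_from != e_to) {
    intronic <- is.na(e_from) && is.na(e_to) &&
      !any(g$exons[, 1] >= from & g$exons[, 2] <= to)  # no exon swallowed
    return(eff(if (intronic) "intronic" else "boundary_spanning"))
  }
  exon_genomic <- e_from
  n_ex <- nrow(g$exons)
  exon_ord <- if (g$strand == "+") exon_genomic else n_ex - exon_genomic + 1L
  anchor <- if (pure_ins) v$pos else from
  offset_in_exon <- if (g$strand == "+") anchor - g$exons[exon_genomic, 1] + 1L
                    else g$exons[exon_genomic, 2] - anchor + 1L
  cds_offset <- .cds_before(g, exon_genomic) + offset_in_exon
  codon <- as.integer(ceiling((cds_offset - g$cds_phase) / 3))
  category <- if (!is_indel) "exonic_substitution"
              else if (indel_len %% 3L == 0L) "exonic_inframe"
              else "exonic_frameshift"
  eff(category, exon = as.integer(exon_ord),
      cds_offset = as.integer(cds_offset), codon = codon)
}

#' @export
print.variant_effect <- function(x, ...) {
  cat(sprintf("<variant_effect> %s (gene %s)", x$category, x$gene_id))
  if (!is.na(x$exon))
    cat(sprintf(": exon %d, CDS offset %d, codon %d", x$exon, x$cds_offset,
                x$codon))
  cat("\n")
  invisible(x)
}

#' Detect a pseudogenizing frameshift between homeologous sequences
#'
#' Globally aligns a CDS query to a homeologous subject region (unit
#' match/mismatch scores, linear gap penalty) and reports every gap, plus
#' whether the net indel length is not a multiple of 3 — the signature of a
#' pseudogenizing frameshift such as a single missing adenine. If percent
#' identity falls below `min_identity` the sequences are reported as not
#' homologous and no frameshift call is made.
#'
#' @param cds_query,region_subject character or `DNAString` sequences over
#'   A/C/G/T/N.
#' @param match,mismatch,gap alignment scores (gap is the per-base penalty,
#'   positive).
#' @param min_identity homology floor as a fraction (default 0.6).
#' @return list with `homologous`, `identity`, `gaps` (data.frame: type
#'   ins/del relative to the query, position in query coordinates, length),
#'   `net_indel`, `frameshift`.
#' @export
detect_pseudogene <- function(cds_query, region_subject, match = 1,
                              mismatch = -1, gap = 2, min_identity = 0.6) {
  q <- Biostrings::DNAString(toupper(as.character(cds_query)))
  s <- Biostrings::DNAString(toupper(as.character(region_subject)))
  if (length(q) == 0L || length(s) == 0L) stop("empty sequence")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(q, s, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = gap)
  identity <- Biostrings::pid(aln) / 100
  if (identity < min_identity)
    return(list(homologous = FALSE, identity = identity,
                gaps = data.frame(type = character(0), position = integer(0),
                                  length = integer(0)),
                net_indel = NA_integer_, frameshift = NA))
  # gaps in the pattern (query) = bases present in subject only: insertions
  ins <- Biostrings::indel(Biostrings::pattern(aln))[[1]]
  del <- Biostrings::indel(Biostrings::subject(aln))[[1]]
  gaps <- rbind(
    if (length(ins)) data.frame(type = "ins",
                                position = BiocGenerics::start(ins),
                                length = BiocGenerics::width(ins)),
    if (length(del)) data.frame(type = "del",
                                position = BiocGenerics::start(del),
                                length = BiocGenerics::width(del)))
  if (is.null(gaps))
    gaps <- data.frame(type = character(0), position = integer(0),
                       length = integer(0))
  net <- length(s) - length(q)
  list(homologous = TRUE, identity = identity,
       gaps = gaps[order(gaps$position), , drop = FALSE],
       net_indel = as.integer(net),
       frameshift = (abs(net) %% 3L) != 0L)
}
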