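## File-format plumbing. VCF emission is a small bespoke writer so that the
## header can carry the run seed and the output is byte-stable under a
## fixed seed; reading goes through VariantAnnotation. GFF3 reading uses
## rtracklayer; FASTA goes through Biostrings.

.GT_STRING <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

#' Write a genotype matrix as VCF 4.2
#'
#' Emits GT:DP per sample, missing calls as "./.", and records the
#' generating seed and sample classes in the header.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @param seed seed to record in the header (optional).
#' @param source_tag value for the `##source=` header line.
#' @return the path, invisibly.
#' @export
write_vcf <- function(gm, path, seed = NULL, source_tag = "tfsmap") {
  stopifnot(inherits(gm, "genotype_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##source=", source_tag),
               if (!is.null(seed)) paste0("##tfsmap_seed=", seed),
               paste0("##tfsmap_classes=",
                      paste(gm$samples$class, collapse = ",")),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">"),
             con)
  for (ch in unique(gm$sites$chrom))
    writeLines(paste0("##contig=<ID=", ch, ">"), con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples$id), collapse = "\t"), con)
  gt <- matrix(.GT_STRING[as.character(gm$calls)],
               nrow = nrow(gm$calls))
  gt[is.na(gm$calls)] <- "./."
  cells <- matrix(paste(gt, gm$depth, sep = ":"), nrow = nrow(gt))
  lines <- paste(gm$sites$chrom, gm$sites$pos, ".", gm$sites$ref,
                 gm$sites$alt, ".", "PASS", ".", "GT:DP",
                 apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a GT:DP VCF into a genotype matrix
#'
#' @param path a VCF file (plain text or bgzipped).
#' @param classes sample classes; by default recovered from the
#'   `##tfsmap_classes=` header when present, else "unknown".
#' @return a `genotype_matrix`.
#' @export
read_vcf <- function(path, classes = NULL) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  sites <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], ""))
  gt_chr <- VariantAnnotation::geno(vcf)$GT
  calls <- matrix(NA_integer_, nrow(gt_chr), ncol(gt_chr))
  calls[gt_chr %in% c("0/0", "0|0")] <- 0L
  calls[gt_chr %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  calls[gt_chr %in% c("1/1", "1|1")] <- 2L
  depth <- VariantAnnotation::geno(vcf)$DP
  depth <- matrix(as.integer(depth), nrow(depth), ncol(depth))
  ids <- colnames(gt_chr)
  if (is.null(classes)) {
    # VariantAnnotation drops unknown ##key=value lines; scan them directly
    hdr <- readLines(path, n = 500L)
    hdr <- hdr[startsWith(hdr, "##")]
    cls_line <- grep("^##tfsmap_classes=", hdr, value = TRUE)
    classes <- if (length(cls_line))
      strsplit(sub("^##tfsmap_classes=", "", cls_line[1]), ",")[[1]]
    else "unknown"
  }
  genotype_matrix(sites, data.frame(id = ids,
                                    class = rep_len(classes, length(ids))),
                  calls, depth)
}

#' Write gene models as GFF3
#' @param genes list of `gene_model`s.
#' @param path output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    span <- range(g$exons)
    writeLines(sprintf("%s\ttfsmap\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, span[1], span[2], g$strand, g$gene_id), con)
    mrna <- paste0(g$gene_id, ".1")
    writeLines(sprintf("%s\ttfsmap\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$chrom, span[1], span[2], g$strand, mrna, g$gene_id),
               con)
    for (i in seq_len(nrow(g$exons)))
      writeLines(sprintf(
        "%s\ttfsmap\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
        g$chrom, g$exons[i, 1], g$exons[i, 2], g$strand, mrna, i, mrna), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#' @param path a GFF3 file; exon features grouped by their Parent transcript
#'   (one transcript per gene expected).
#' @return list of `gene_model`s, named by gene id.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  ex <- gr[gr$type == "exon"]
  parent <- vapply(ex$Parent, function(p) as.character(p)[1], "")
  mrna <- gr[gr$type == "mRNA"]
  gene_of <- stats::setNames(
    vapply(mrna$Parent, function(p) as.character(p)[1], ""), mrna$ID)
  out <- lapply(split(seq_along(ex), parent), function(idx) {
    e <- ex[idx]
    o <- order(BiocGenerics::start(e))
    gid <- gene_of[[parent[idx[1]]]]
    if (is.null(gid) || is.na(gid)) gid <- parent[idx[1]]
    gene_model(gid,
               as.character(GenomeInfoDb::seqnames(e))[1],
               as.character(BiocGenerics::strand(e))[1],
               cbind(BiocGenerics::start(e)[o], BiocGenerics::end(e)[o]))
  })
  stats::setNames(out, vapply(out, `[[`, "", "gene_id"))
}

#' Read/write FASTA
#' @param seqs named character vector of sequences.
#' @param path file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path, width = 60L)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a candidate set as TSV and BED
#' @param cands a `candidate_set`.
#' @param tsv,bed output paths (either may be NULL).
#' @export
write_candidates <- function(cands, tsv = NULL, bed = NULL) {
  if (!is.null(tsv))
    utils::write.table(as.data.frame(cands), tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed)) {
    bed_df <- data.frame(cands$chrom, cands$pos - 1L, cands$pos)
    utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(cands)
}

#' Write the founder allele table as TSV
#'
#' One row per site (chrom, pos, ref, alt) plus one 0/1 column per founder.
#' @param panel a `founder_panel`.
#' @param path output path.
#' @export
write_founder_table <- function(panel, path) {
  stopifnot(inherits(panel, "founder_panel"))
  utils::write.table(cbind(panel$sites, as.data.frame(panel$alleles)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
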