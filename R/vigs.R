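## VIGS target design: chop the target CDS into all overlapping k-mers
## (k = 21 mirrors the siRNA length used by silencing-specificity tools),
## count near-exact matches in every other transcript, then pick the
## window whose k-mers carry the fewest off-target hits.

.DNA_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 0L)

.encode_dna <- function(x) {
  v <- .DNA_CODE[strsplit(toupper(as.character(x)), "")[[1]]]
  if (anyNA(v)) stop("sequence contains characters outside A/C/G/T/N")
  unname(v)
}

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

# windows x k integer matrix of all k-length windows of an encoded sequence
.window_matrix <- function(enc, k) {
  n <- length(enc) - k + 1L
  matrix(enc[outer(seq_len(n), 0:(k - 1L), `+`)], nrow = n)
}

#' k-mer off-target specificity scan
#'
#' Chops the target CDS into all length-k substrings (L - k + 1 of them) and
#' counts, for each, its occurrences in every *other* transcript of the
#' database within Hamming distance `max_mismatch` (no indels). Both strands
#' are searched by default, since siRNA-mediated silencing is
#' orientation-independent. k-mers containing N are marked untestable (hit
#' count NA); database positions containing N never match.
#'
#' @param target target CDS (character or `DNAString`), or the id of a `db`
#'   entry.
#' @param db named character vector or `DNAStringSet` of coding sequences.
#' @param k k-mer length (default 21).
#' @param max_mismatch maximum Hamming distance counted as a hit (default 1).
#' @param both_strands search the reverse complement of each database
#'   sequence too (default TRUE).
#' @param target_id id under which the target itself appears in `db`
#'   (excluded from off-target counting).
#' @return a `kmer_report`: data.frame with `position`, `kmer`, `hits`,
#'   `testable`; the target sequence, k and parameters kept as attributes.
#' @export
kmer_offtarget_scan <- function(target, db, k = 21L, max_mismatch = 1L,
                                both_strands = TRUE, target_id = NULL) {
  db <- vapply(as.list(db), as.character, "")
  if (!length(db)) stop("database is empty")
  if (is.null(names(db)) || !all(nzchar(names(db))))
    stop("database sequences must be named")
  if (length(target) == 1L && !is.null(names(db)) &&
      as.character(target) %in% names(db) && is.null(target_id)) {
    target_id <- as.character(target)
    target <- db[[target_id]]
  }
  target <- toupper(as.character(target))
  L <- nchar(target)
  if (k > L) stop("k exceeds target length (", L, ")")
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
  enc_t <- .encode_dna(target)
  n_kmer <- L - k + 1L
  tmat <- .window_matrix(enc_t, k)
  testable <- rowSums(tmat == 0L) == 0L
  hits <- integer(n_kmer)

  off_db <- db[setdiff(names(db), target_id)]
  for (s in off_db) {
    strands <- if (both_strands) c(s, .revcomp(s)) else s
    for (str in strands) {
      if (nchar(str) < k) next
      enc_s <- .encode_dna(str)
      smat <- .window_matrix(enc_s, k)
      n_match <- matrix(0L, nrow(smat), n_kmer)
      for (o in seq_len(k))
        n_match <- n_match + outer(smat[, o], tmat[, o],
                                   function(a, b) (a == b) & a != 0L)
      hits <- hits + colSums(n_match >= (k - max_mismatch))
    }
  }
  hits[!testable] <- NA_integer_
  structure(
    data.frame(position = seq_len(n_kmer),
               kmer = substring(target, seq_len(n_kmer), seq_len(n_kmer) + k - 1L),
               hits = hits, testable = testable),
    class = c("kmer_report", "data.frame"),
    target = target, target_id = target_id, k = as.integer(k),
    max_mismatch = as.integer(max_mismatch), both_strands = both_strands)
}

#' Select the most specific silencing window
#'
#' Scores every window of `window_length` along the target by the number of
#' k-mers fully inside it that have at least one off-target hit, and returns
#' the window with the smallest score (leftmost on ties). Untestable k-mers
#' (containing N) do not count against a window.
#'
#' @param report a `kmer_report` from [kmer_offtarget_scan()].
#' @param window_length silencing-fragment length (default 350).
#' @return list with `start`, `end`, `length`, `score` (count of
#'   off-target-hitting k-mers inside), `sequence`.
#' @export
select_window <- function(report, window_length = 350L) {
  stopifnot(inherits(report, "kmer_report"))
  k <- attr(report, "k")
  target <- attr(report, "target")
  L <- nchar(target)
  if (L < window_length)
    stop("CDS (", L, " nt) is shorter than the requested window (",
         window_length, " nt); shorten the window")
  bad <- as.integer(!is.na(report$hits) & report$hits > 0L)
  kmers_per_window <- window_length - k + 1L
  cs <- c(0L, cumsum(bad))
  n_win <- L - window_length + 1L
  starts <- seq_len(n_win)
  scores <- cs[starts + kmers_per_window] - cs[starts]
  best <- which.min(scores)              # which.min takes the leftmost tie
  list(start = best, end = best + window_length - 1L,
       length = as.integer(window_length),
       score = as.integer(scores[best]),
       sequence = substr(target, best, best + window_length - 1L))
}

#' @export
print.kmer_report <- function(x, ...) {
  cat(sprintf("<kmer_report> %d %d-mers (max_mismatch %d, %s): %d with off-target hits, %d untestable\n",
              nrow(x), attr(x, "k"), attr(x, "max_mismatch"),
              if (attr(x, "both_strands")) "both strands" else "forward strand",
              sum(x$hits > 0, na.rm = TRUE), sum(!x$testable)))
  invisible(x)
}
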