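# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (loops, substr, full DP) so they cannot share bugs
# with the vectorized implementation paths they check.

# --- concordance filter: literal rule-by-rule evaluation per site ---------
oracle_filter <- function(calls, classes, phen, sensitive_parent_col,
                          mode = "permissive",
                          require_tolerant_exclusion = TRUE) {
  strict <- mode == "strict"
  n_samp <- ncol(calls)
  parents <- which(classes == "parent")
  other_par <- setdiff(parents, sensitive_parent_col)
  sens <- which(classes != "parent" & phen == "sensitive")
  tol <- which(classes != "parent" & phen == "tolerant")
  pass <- logical(nrow(calls))
  for (s in seq_len(nrow(calls))) {
    row <- calls[s, ]
    ok_val <- function(x, want) {
      if (is.na(x)) return(!strict)
      x == want
    }
    a <- ok_val(row[sensitive_parent_col], 2L)
    b <- all(vapply(other_par, function(j) ok_val(row[j], 0L), TRUE))
    c_ <- all(vapply(sens, function(j) ok_val(row[j], 2L), TRUE))
    d <- TRUE
    if (require_tolerant_exclusion)
      d <- all(vapply(tol, function(j) {
        if (is.na(row[j])) return(!strict)
        row[j] != 2L            # hom-alt disqualifies; het is a carrier
      }, TRUE))
    pass[s] <- a && b && c_ && d
  }
  which(pass)
}

random_genotype_matrix <- function(n_sites, n_samples, n_parents = 3L,
                                   p_missing = 0.15) {
  calls <- matrix(sample(c(0:2, NA), n_sites * n_samples, replace = TRUE,
                         prob = c((1 - p_missing) / 3, (1 - p_missing) / 3,
                                  (1 - p_missing) / 3, p_missing)),
                  n_sites, n_samples)
  classes <- c(rep("parent", n_parents),
               rep("RIL", n_samples - n_parents))
  n_ril <- n_samples - n_parents
  repeat {   # filter precondition: at least one sensitive non-parent
    ril_phen <- sample(c("sensitive", "tolerant"), n_ril, replace = TRUE)
    if (any(ril_phen == "sensitive")) break
  }
  phen <- c(rep(NA, n_parents), ril_phen)
  depth <- matrix(ifelse(is.na(calls), 0L, 3L), n_sites, n_samples)
  sites <- data.frame(chrom = "D10", pos = seq_len(n_sites) * 100L,
                      ref = "A", alt = "T")
  ids <- sprintf("X%03d", seq_len(n_samples))
  gm <- genotype_matrix(sites, data.frame(id = ids, class = classes),
                        calls, depth)
  ptab <- structure(data.frame(sample = ids[classes != "parent"],
                               phenotype = factor(phen[classes != "parent"],
                                                  c("tolerant", "sensitive"))),
                    class = c("phenotype_table", "data.frame"))
  list(gm = gm, phen = ptab, classes = classes, phen_all = phen)
}

# --- k-mer scan: all-pairs Hamming with substr -----------------------------
oracle_kmer_scan <- function(target, db, k, max_mismatch,
                             both_strands = TRUE, target_id = NULL) {
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  hamming <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    sum(x != y | x == "N" | y == "N")   # N never matches
  }
  L <- nchar(target)
  hits <- integer(L - k + 1L)
  seqs <- db[setdiff(names(db), target_id)]
  for (i in seq_len(L - k + 1L)) {
    kmer <- substr(target, i, i + k - 1L)
    if (grepl("N", kmer)) { hits[i] <- NA_integer_; next }
    for (s in seqs) {
      strands <- if (both_strands) c(s, rc(s)) else s
      for (str in strands) {
        if (nchar(str) < k) next
        for (j in seq_len(nchar(str) - k + 1L))
          if (hamming(kmer, substr(str, j, j + k - 1L)) <= max_mismatch)
            hits[i] <- hits[i] + 1L
      }
    }
  }
  hits
}

oracle_select_window <- function(hits, target_len, k, window_length) {
  bad <- !is.na(hits) & hits > 0L
  n_win <- target_len - window_length + 1L
  scores <- integer(n_win)
  for (w in seq_len(n_win)) {
    ks <- seq(w, w + window_length - k)
    scores[w] <- sum(bad[ks])
  }
  list(start = which.min(scores), score = min(scores))
}

# --- global alignment: full Needleman-Wunsch optimal score ----------------
oracle_nw_score <- function(a, b, match = 1, mismatch = -1, gap = 2) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  D <- matrix(0, n + 1L, m + 1L)
  D[, 1] <- -(0:n) * gap
  D[1, ] <- -(0:m) * gap
  for (i in seq_len(n)) for (j in seq_len(m))
    D[i + 1L, j + 1L] <- max(
      D[i, j] + if (x[i] == y[j]) match else mismatch,
      D[i, j + 1L] - gap,
      D[i + 1L, j] - gap)
  D[n + 1L, m + 1L]
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# --- small panel builder ---------------------------------------------------
# two founders, explicit allele matrix, sites at given cM spacings on one
# 100 cM / 60 Mb chromosome
toy_panel <- function(alleles, gen_pos_cM, causal_site = 1L,
                      causal_founder = 1L) {
  stopifnot(nrow(alleles) == length(gen_pos_cM))
  pos <- as.integer(round(gen_pos_cM / 100 * 60e6))
  m <- genetic_map()
  m <- map_set_sites(m, list(D10 = pos))
  n_f <- ncol(alleles)
  colnames(alleles) <- sprintf("P%02d", seq_len(n_f))
  structure(list(
    n_founders = n_f, alleles = alleles,
    sites = data.frame(chrom = "D10", pos = sort(pos), ref = "A", alt = "T"),
    map = m, causal_site = causal_site,
    causal_founder = causal_founder,
    founder_names = colnames(alleles)), class = "founder_panel")
}

# segments must tile (0, gen_len] with no gaps/overlaps
expect_tiles <- function(ind, map) {
  for (h in ind$hap) for (ch in names(h)) {
    ends <- h[[ch]]$ends
    len <- map$chromosomes$gen_len[map$chromosomes$name == ch]
    expect_true(all(diff(ends) > 0))
    expect_equal(ends[length(ends)], len)
    expect_true(all(h[[ch]]$founders >= 1L))
  }
}
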