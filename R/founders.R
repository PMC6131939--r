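#' Simulate a founder panel
#'
#' Draws biallelic variant sites for `n_founders` inbred founders and plants a
#' single causal variant — by default a 1-bp adenine insertion — carried by
#' exactly one founder (the herbicide-sensitive parent). Non-causal alleles
#' are i.i.d. Bernoulli(`maf`) per founder per site; sites that come out
#' monomorphic across the panel are redrawn so every site is segregating.
#'
#' @param n_founders number of founder lines (>= 2); 11 for the MAGIC design.
#' @param n_sites number of variant sites to simulate (>= 1), causal site
#'   included.
#' @param map a `genetic_map`; site positions are drawn uniformly along its
#'   chromosomes (proportionally to physical length) unless already attached.
#' @param causal list with `chrom`, `pos`, `founder` naming the planted
#'   causal site and its carrier founder index. Default: D10:28455988,
#'   founder 1.
#' @param maf alternate-allele frequency used for non-causal sites.
#' @param founder_names optional character vector of founder ids.
#' @param seed integer seed; the run is reproducible given the seed.
#' @return object of class `founder_panel` with fields `alleles` (sites x
#'   founders 0/1 matrix), `sites` (chrom, pos, ref, alt), `map`,
#'   `causal_site` (row index), `causal_founder`.
#' @examples
#' p <- simulate_founders(11, 50, seed = 1)
#' sum(p$alleles[p$causal_site, ]) # exactly one carrier
#' @export
simulate_founders <- function(n_founders, n_sites, map = genetic_map(),
                              causal = list(chrom = "D10", pos = 28455988L,
                                            founder = 1L),
                              maf = 0.3, founder_names = NULL, seed = NULL) {
  if (n_founders < 2L) stop("need at least 2 founders")
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (maf <= 0 || maf >= 1) stop("maf must be in (0, 1)")
  ci <- match(causal$chrom, map$chromosomes$name)
  if (is.na(ci)) stop("causal chromosome not in map")
  if (causal$pos < 1L || causal$pos > map$chromosomes$phys_len[ci])
    stop("causal site outside map")
  if (causal$founder < 1L || causal$founder > n_founders)
    stop("causal founder index out of range")
  if (!is.null(seed)) set.seed(seed)

  # spread sites over chromosomes proportionally to physical length
  w <- map$chromosomes$phys_len / sum(map$chromosomes$phys_len)
  n_per <- stats::setNames(
    as.integer(round(w * n_sites)), map$chromosomes$name)
  n_per[causal$chrom] <- max(1L, n_per[causal$chrom])
  while (sum(n_per) != n_sites) {        # rounding drift
    j <- which.max(n_per)
    n_per[j] <- n_per[j] + sign(n_sites - sum(n_per))
  }
  sites_by_chr <- lapply(seq_len(nrow(map$chromosomes)), function(i) {
    ch <- map$chromosomes$name[i]
    n <- n_per[[ch]]
    pos <- sort(sample.int(map$chromosomes$phys_len[i], n))
    if (ch == causal$chrom && !(causal$pos %in% pos)) {
      pos[which.min(abs(pos - causal$pos))] <- causal$pos
      pos <- sort(unique(pos))
      while (length(pos) < n)  # refill collisions
        pos <- sort(unique(c(pos, sample.int(map$chromosomes$phys_len[i], 1))))
    }
    pos
  })
  names(sites_by_chr) <- map$chromosomes$name
  map <- map_set_sites(map, sites_by_chr)

  sites <- do.call(rbind, lapply(names(sites_by_chr), function(ch)
    data.frame(chrom = ch, pos = map$sites[[ch]]$pos)))
  n_sites <- nrow(sites)
  causal_site <- which(sites$chrom == causal$chrom & sites$pos == causal$pos)
  stopifnot(length(causal_site) == 1L)

  alleles <- matrix(stats::rbinom(n_sites * n_founders, 1L, maf),
                    nrow = n_sites, ncol = n_founders)
  mono <- rowSums(alleles) %in% c(0L, n_founders)
  while (any(mono)) {                    # redraw monomorphic sites
    alleles[mono, ] <- stats::rbinom(sum(mono) * n_founders, 1L, maf)
    mono <- rowSums(alleles) %in% c(0L, n_founders)
  }
  alleles[causal_site, ] <- 0L
  alleles[causal_site, causal$founder] <- 1L

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  ref[causal_site] <- "A"                # 1-bp adenine insertion, anchored
  alt[causal_site] <- "AA"
  sites$ref <- ref
  sites$alt <- unname(alt)

  if (is.null(founder_names))
    founder_names <- sprintf("P%02d", seq_len(n_founders))
  colnames(alleles) <- founder_names
  structure(list(n_founders = n_founders, alleles = alleles, sites = sites,
                 map = map, causal_site = causal_site,
                 causal_founder = as.integer(causal$founder),
                 founder_names = founder_names),
            class = "founder_panel")
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("<founder_panel> %d founders x %d sites; causal %s:%d in %s\n",
              x$n_founders, nrow(x$sites),
              x$sites$chrom[x$causal_site], x$sites$pos[x$causal_site],
              x$founder_names[x$causal_founder]))
  invisible(x)
}

#' Site indices of a panel falling in a region
#' @param panel a `founder_panel`.
#' @param chrom,start,end region (1-based, closed).
#' @return integer site indices.
#' @export
panel_sites_in_region <- function(panel, chrom, start, end) {
  which(panel$sites$chrom == chrom & panel$sites$pos >= start &
          panel$sites$pos <= end)
}
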