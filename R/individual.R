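## Individuals are diploids whose haplotypes are founder mosaics: per
## chromosome a run-length list of (founder-of-origin, segment right-end in
## cM). Segments tile (0, gen_len] with no gaps or overlaps, so every allele
## an individual carries traces back to a founder allele at that site.

new_haplotype <- function(map, founder) {
  lapply(stats::setNames(seq_len(nrow(map$chromosomes)),
                         map$chromosomes$name),
         function(i) list(founders = as.integer(founder),
                          ends = map$chromosomes$gen_len[i]))
}

#' Construct a fully inbred individual from one founder
#' @param map a `genetic_map`.
#' @param founder founder index.
#' @return object of class `individual` (two identical one-segment
#'   haplotypes).
#' @export
founder_individual <- function(map, founder) {
  structure(list(hap = list(new_haplotype(map, founder),
                            new_haplotype(map, founder))),
            class = "individual")
}

# segments of (founders, ends) overlapping the genetic interval (from, to]
.hap_slice <- function(founders, ends, from, to) {
  starts <- c(0, ends[-length(ends)])
  keep <- which(ends > from & starts < to)
  list(founders = founders[keep], ends = pmin(ends[keep], to))
}

.merge_runs <- function(founders, ends) {
  if (length(founders) <= 1L) return(list(founders = founders, ends = ends))
  keep <- c(founders[-length(founders)] != founders[-1], TRUE)
  list(founders = founders[keep], ends = ends[keep])
}

#' Simulate one meiosis
#'
#' Produces a gamete haplotype from a parent: per chromosome the crossover
#' count is Poisson with mean the genetic length in Morgans, crossover
#' positions are uniform on the genetic map, and there is no interference
#' (Haldane model). The starting parental haplotype is chosen with
#' probability 1/2 per chromosome.
#'
#' @param parent an `individual`.
#' @param map a `genetic_map` (the one the parent's haplotypes tile).
#' @return a haplotype (named list per chromosome of founder mosaics).
#' @export
meiosis <- function(parent, map) {
  stopifnot(inherits(parent, "individual"))
  if (nrow(map$chromosomes) < 1L) stop("empty map")
  out <- vector("list", nrow(map$chromosomes))
  names(out) <- map$chromosomes$name
  for (i in seq_len(nrow(map$chromosomes))) {
    ch <- map$chromosomes$name[i]
    L <- map$chromosomes$gen_len[i]
    n_xo <- stats::rpois(1L, L / 100)
    cuts <- if (n_xo > 0L) sort(stats::runif(n_xo, 0, L)) else numeric(0)
    bounds <- c(cuts, L)
    which_hap <- sample.int(2L, 1L)
    f <- integer(0); e <- numeric(0); from <- 0
    for (b in bounds) {
      if (b > from) {
        src <- parent$hap[[which_hap]][[ch]]
        piece <- .hap_slice(src$founders, src$ends, from, b)
        f <- c(f, piece$founders); e <- c(e, piece$ends)
      }
      from <- b
      which_hap <- 3L - which_hap
    }
    out[[i]] <- .merge_runs(f, e)
  }
  out
}

#' Cross two individuals
#' @param mother,father `individual`s (identical for a selfing).
#' @param map a `genetic_map`.
#' @return an `individual`: one independent meiosis from each parent.
#' @export
cross <- function(mother, father, map) {
  structure(list(hap = list(meiosis(mother, map), meiosis(father, map))),
            class = "individual")
}

# founder-of-origin of each panel site on one haplotype, in panel site order
.hap_founders_at_sites <- function(hap, panel) {
  out <- integer(nrow(panel$sites))
  for (ch in names(panel$map$sites)) {
    rows <- which(panel$sites$chrom == ch)
    gen <- panel$map$sites[[ch]]$gen
    seg <- findInterval(gen, hap[[ch]]$ends, left.open = TRUE) + 1L
    out[rows] <- hap[[ch]]$founders[seg]
  }
  out
}

#' Per-site alleles of one individual
#' @param ind an `individual`.
#' @param panel the `founder_panel` it descends from.
#' @return integer matrix, sites x 2 haplotypes, values 0/1.
#' @export
individual_alleles <- function(ind, panel) {
  idx <- cbind(seq_len(nrow(panel$sites)),
               .hap_founders_at_sites(ind$hap[[1]], panel))
  a1 <- panel$alleles[idx]
  idx[, 2] <- .hap_founders_at_sites(ind$hap[[2]], panel)
  a2 <- panel$alleles[idx]
  cbind(a1, a2)
}

#' True genotype dosages of a population
#' @param pop list of `individual`s.
#' @param panel the `founder_panel`.
#' @return integer matrix sites x individuals with values 0/1/2 (alt-allele
#'   dosage).
#' @export
population_genotypes <- function(pop, panel) {
  g <- vapply(pop, function(ind) {
    a <- individual_alleles(ind, panel)
    a[, 1] + a[, 2]
  }, integer(nrow(panel$sites)))
  if (is.null(dim(g))) g <- matrix(g, nrow = nrow(panel$sites))
  g
}

#' Per-individual heterozygosity over panel sites
#' @param pop list of `individual`s.
#' @param panel the `founder_panel`.
#' @return numeric vector: fraction of sites heterozygous, per individual.
#' @export
population_heterozygosity <- function(pop, panel) {
  g <- population_genotypes(pop, panel)
  colMeans(g == 1L)
}

#' @export
print.individual <- function(x, ...) {
  nseg <- sum(vapply(x$hap, function(h)
    sum(vapply(h, function(s) length(s$founders), 1L)), 1L))
  cat(sprintf("<individual> %d chromosome(s), %d founder segments\n",
              length(x$hap[[1]]), nseg))
  invisible(x)
}
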