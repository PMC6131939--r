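#' Genetic map
#'
#' A genetic map holds one or more chromosomes, each with a physical length in
#' base pairs and a genetic length in centiMorgans, plus (optionally) a set of
#' marker/variant site positions per chromosome. Genetic positions of sites
#' are obtained by linear interpolation between the chromosome ends (uniform
#' recombination), so genetic position is non-decreasing in physical position
#' by construction.
#'
#' The default map is a single chromosome "D10" of 60 Mb / 100 cM — the scale
#' of an upland-cotton chromosome — because no empirical map is assumed.
#'
#' @param chromosomes data.frame with columns `name`, `phys_len` (bp),
#'   `gen_len` (cM). Defaults to one chromosome D10, 60 Mb / 100 cM.
#' @param sites optional named list (by chromosome name) of sorted integer
#'   physical positions.
#' @return object of class `genetic_map`.
#' @examples
#' m <- genetic_map()
#' m <- map_set_sites(m, list(D10 = c(1e6L, 28455988L, 5e7L)))
#' map_genetic_pos(m, "D10", 28455988L)
#' @export
genetic_map <- function(chromosomes = data.frame(name = "D10",
                                                 phys_len = 60e6,
                                                 gen_len = 100),
                        sites = NULL) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "phys_len", "gen_len") %in% names(chromosomes)))
  if (nrow(chromosomes) < 1L) stop("map must contain at least one chromosome")
  if (any(chromosomes$phys_len <= 0) || any(chromosomes$gen_len <= 0))
    stop("chromosome lengths must be positive")
  if (anyDuplicated(chromosomes$name)) stop("duplicated chromosome names")
  m <- structure(list(chromosomes = chromosomes, sites = NULL),
                 class = "genetic_map")
  if (!is.null(sites)) m <- map_set_sites(m, sites)
  m
}

#' Attach site positions to a map
#'
#' @param map a `genetic_map`.
#' @param sites named list of integer physical positions per chromosome.
#' @return the map with sites attached (sorted, with interpolated genetic
#'   positions).
#' @export
map_set_sites <- function(map, sites) {
  stopifnot(inherits(map, "genetic_map"), is.list(sites))
  bad <- setdiff(names(sites), map$chromosomes$name)
  if (length(bad)) stop("sites given for unknown chromosome(s): ",
                        paste(bad, collapse = ", "))
  map$sites <- lapply(stats::setNames(names(sites), names(sites)), function(ch) {
    pos <- sort(unique(as.integer(sites[[ch]])))
    len <- map$chromosomes$phys_len[map$chromosomes$name == ch]
    if (any(pos < 1L) || any(pos > len))
      stop("site position outside chromosome ", ch)
    data.frame(pos = pos, gen = map_genetic_pos(map, ch, pos))
  })
  map
}

#' Interpolated genetic position (cM) of physical coordinates
#' @param map a `genetic_map`.
#' @param chrom chromosome name.
#' @param pos integer vector of physical positions (bp).
#' @return numeric vector of genetic positions in cM.
#' @export
map_genetic_pos <- function(map, chrom, pos) {
  i <- match(chrom, map$chromosomes$name)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  pos / map$chromosomes$phys_len[i] * map$chromosomes$gen_len[i]
}

#' @export
print.genetic_map <- function(x, ...) {
  cat("<genetic_map> ", nrow(x$chromosomes), " chromosome(s)\n", sep = "")
  for (i in seq_len(nrow(x$chromosomes))) {
    ch <- x$chromosomes$name[i]
    ns <- if (is.null(x$sites[[ch]])) 0L else nrow(x$sites[[ch]])
    cat(sprintf("  %s: %.0f bp / %.1f cM, %d sites\n", ch,
                x$chromosomes$phys_len[i], x$chromosomes$gen_len[i], ns))
  }
  invisible(x)
}
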