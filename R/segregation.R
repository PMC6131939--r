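#' Chi-square goodness of fit to a Mendelian ratio
#'
#' Pearson's chi-square against an expected segregation ratio, e.g. observed
#' tolerant/sensitive counts (1255, 440) against 3:1. No continuity
#' correction by default; the classical Yates correction (2 classes only) is
#' available via `correct = TRUE`.
#'
#' @param observed non-negative integer counts per class.
#' @param ratio positive expected ratio terms, same length as `observed`
#'   (e.g. `c(3, 1)`).
#' @param correct apply the Yates continuity correction.
#' @param alpha significance level for the verdict (default 0.05).
#' @return a `segregation_result`: list with `observed`, `expected`, `ratio`,
#'   `statistic`, `df`, `p_value`, `verdict` ("ns" iff p > alpha).
#' @examples
#' chi_square_segregation(c(1255, 440), c(3, 1))
#' @export
chi_square_segregation <- function(observed, ratio, correct = FALSE,
                                   alpha = 0.05) {
  observed <- as.numeric(observed)
  if (length(observed) != length(ratio))
    stop("observed and ratio must have the same number of classes")
  if (any(observed < 0)) stop("observed counts must be >= 0")
  if (any(ratio <= 0)) stop("ratio terms must be > 0")
  total <- sum(observed)
  if (total <= 0) stop("total count must be > 0")
  expected <- total * ratio / sum(ratio)
  dev <- abs(observed - expected)
  if (correct) dev <- pmax(dev - 0.5, 0)
  statistic <- sum(dev^2 / expected)
  df <- length(observed) - 1L
  p <- stats::pchisq(statistic, df, lower.tail = FALSE)
  structure(list(observed = observed, expected = expected, ratio = ratio,
                 statistic = statistic, df = df, p_value = p,
                 alpha = alpha,
                 verdict = if (p > alpha) "ns" else "*"),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("X-squared = %.4g, df = %d, p = %.4g (%s) vs ratio %s\n",
              x$statistic, x$df, x$p_value, x$verdict,
              paste(x$ratio, collapse = ":")))
  invisible(x)
}

#' Fit a set of candidate segregation ratios
#'
#' Evaluates every candidate ratio with [chi_square_segregation()] and
#' selects the best fit: largest p-value, ties broken toward fewer classes
#' and then listed order.
#'
#' @param observed counts per class.
#' @param ratios list of ratio vectors, e.g.
#'   `list(c(3, 1), c(1, 2, 1), c(15, 1))`. Ratios whose class count differs
#'   from `length(observed)` are skipped with a note in the result.
#' @param ... passed to [chi_square_segregation()].
#' @return list with `best` (the winning ratio's `segregation_result`) and
#'   `results` (one per evaluated candidate).
#' @export
fit_ratio_set <- function(observed, ratios, ...) {
  if (!length(ratios)) stop("need at least one candidate ratio")
  usable <- vapply(ratios, function(r) length(r) == length(observed), TRUE)
  if (!any(usable)) stop("no candidate ratio matches the class count")
  res <- lapply(ratios[usable], function(r)
    chi_square_segregation(observed, r, ...))
  p <- vapply(res, `[[`, 0, "p_value")
  k <- vapply(res, function(x) length(x$ratio), 0L)
  best <- order(-p, k, seq_along(res))[1]
  list(best = res[[best]], results = res,
       skipped = ratios[!usable])
}
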