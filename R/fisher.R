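#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact conditional test of independence in the table
#' \preformatted{
#'     a  b
#'     c  d
#' }
#' The two-sided p value is computed by hypergeometric summation over all
#' tables with the observed margins, adding the probability of every table
#' whose probability does not exceed that of the observed table
#' (minimum-likelihood convention, the same rule used by
#' \code{stats::fisher.test}).  The odds ratio is the sample cross-product
#' ratio; when any cell is zero a Haldane--Anscombe corrected display value
#' (0.5 added to every cell) is also returned, but the p value always comes
#' from the uncorrected table.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list with \code{p_value}, \code{odds_ratio} (cross-product,
#'   possibly 0 or Inf) and \code{odds_ratio_display} (Haldane--Anscombe
#'   corrected only when a zero cell occurs).
#' @export
#' @examples
#' fisher_exact_2x2(10, 990, 10, 990)$p_value  # 1
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  stopifnot(length(cells) == 4, all(!is.na(cells)), all(cells >= 0),
            all(cells == round(cells)))
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) {
    # degenerate margin: only one table possible
    p <- 1
  } else {
    lo <- max(0, k - n2)
    hi <- min(k, m)
    support <- lo:hi
    probs <- stats::dhyper(support, m, n2, k)
    pobs <- stats::dhyper(a, m, n2, k)
    p <- min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
  }
  or <- (a * d) / (b * c)  # may be 0, Inf or NaN (0/0)
  if (is.nan(or)) or <- NA_real_
  or_disp <- or
  if (any(cells == 0)) {
    or_disp <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  }
  list(p_value = p, odds_ratio = or, odds_ratio_display = or_disp)
}

#' Exact conditional comparison of two Poisson rates
#'
#' Tests whether two event counts with known exposures share a common
#' rate: conditional on the total \code{x1 + x2}, the first count is
#' Binomial(n, e1 / (e1 + e2)) under the null.  The two-sided p value
#' sums all outcomes no more probable than the observed one -- the same
#' minimum-likelihood convention as \code{\link{fisher_exact_2x2}}, of
#' which this is the large-background limit.
#'
#' @param x1,x2 non-negative integer event counts.
#' @param e1,e2 positive exposures (e.g. genome counts).
#' @return two-sided p value.
#' @export
poisson_rate_test <- function(x1, x2, e1, e2) {
  stopifnot(x1 >= 0, x2 >= 0, x1 == round(x1), x2 == round(x2),
            e1 > 0, e2 > 0)
  n <- x1 + x2
  if (n == 0) return(1)
  p0 <- e1 / (e1 + e2)
  probs <- stats::dbinom(0:n, n, p0)
  min(1, sum(probs[probs <= probs[x1 + 1] * (1 + 1e-7)]))
}
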