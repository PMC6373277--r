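# Clinical sub-phenotype comparison: frequencies of the 11 binary ACR
# classification criteria in carriers of prioritised rare variants versus
# the rest of the cohort.

#' ACR sub-phenotype comparison
#'
#' Two-sided Fisher exact test per criterion comparing carriers of
#' heterozygous rare risk variants with the comparator group.  The default
#' comparison is carriers versus non-carriers (disjoint groups, a valid
#' exact-test design); \code{"carriers_vs_all"} reproduces a
#' carriers-versus-entire-cohort contrast for descriptive frequencies but
#' note the groups overlap.  Bonferroni correction multiplies each p by
#' the number of criteria tested (capped at 1).
#'
#' @param acr data.frame with sample_id and one 0/1 column per criterion.
#' @param carriers character vector of carrier sample ids.
#' @param comparison \code{"carriers_vs_noncarriers"} (default) or
#'   \code{"carriers_vs_all"}.
#' @return data.frame: criterion, carrier_n, carrier_freq, comparator_n,
#'   comparator_freq, p_value, p_corrected, zero_variance.
#' @export
acr_comparison <- function(acr, carriers,
                           comparison = c("carriers_vs_noncarriers",
                                          "carriers_vs_all")) {
  comparison <- match.arg(comparison)
  stopifnot("sample_id" %in% names(acr))
  crit <- setdiff(names(acr), "sample_id")
  is_car <- acr$sample_id %in% carriers
  if (!any(is_car) || !any(!is_car)) {
    stop("need at least one carrier and one non-carrier")
  }
  comp <- if (comparison == "carriers_vs_all") rep(TRUE, nrow(acr)) else !is_car
  m <- length(crit)
  rows <- lapply(crit, function(cr) {
    x <- acr[[cr]]
    stopifnot(all(x %in% c(0, 1)))
    a <- sum(x[is_car])          # carriers with criterion
    b <- sum(is_car) - a
    c_ <- sum(x[comp])           # comparators with criterion
    d <- sum(comp) - c_
    zero_var <- sum(x) == 0 || sum(x) == nrow(acr)
    p <- if (zero_var) 1 else fisher_exact_2x2(a, b, c_, d)$p_value
    data.frame(criterion = cr, carrier_n = sum(is_car),
               carrier_freq = a / sum(is_car), comparator_n = sum(comp),
               comparator_freq = c_ / sum(comp), p_value = p,
               p_corrected = min(1, m * p), zero_variance = zero_var,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
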