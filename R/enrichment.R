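# MAF-binned, annotation-stratified enrichment of panel variants against a
# reference cohort.
#
# Counting unit: one observation = one variant x carrier pair (a
# homozygote counts once in the default "carrier" mode, twice in "allele"
# mode).  For each stratum (annotation class group x MAF bin) the case
# cohort contributes panel and genome-wide background observation counts;
# the reference cohort contributes the same.  Because variant-calling
# sensitivity differs between pipelines (the trio design rescues private
# variants that a reference pipeline misses), the reference panel count is
# first normalised by the genome-wide per-genome rate ratio
#   factor = (case background rate) / (reference background rate).
# The corrected reference panel count c* = factor * ref_panel is then
# compared with the observed case panel count as two Poisson rates with
# genome-count exposures, via the exact conditional test: given
# n = case_panel + round(c*), the case count is Binomial(n, p0) with
# p0 = N_case / (N_case + N_ref) under no enrichment; the two-sided p
# sums all outcomes no more probable than the observed one (the same
# minimum-likelihood convention as the Fisher test, of which this is the
# large-background limit).  A 2x2 of panel-versus-background *counts*
# cannot work here: its cross-ratio is invariant to any uniform
# rescaling of the reference row, so the calling-sensitivity correction
# would cancel out of it identically; and genome-exposure odds saturate
# in common-MAF strata where genomes carry several observations each.
# The reported odds_ratio is the rate ratio observed / expected with
# expected = c* N_case / N_ref, which is exactly what the excess
# arithmetic excess = observed * (1 - 1/OR) inverts.

#' Label MAF bins
#'
#' @param bin_edges increasing numeric edges starting at 0; bins are
#'   half-open \code{(lo, hi]}, except that MAF 0 (absent from the
#'   reference) belongs to the lowest bin.
#' @return character labels like \code{"(0,0.001]"}.
#' @export
maf_bin_labels <- function(bin_edges = c(0, 0.001, 0.01, 0.05, 0.5)) {
  paste0("(", utils::head(bin_edges, -1), ",", bin_edges[-1], "]")
}

#' Assign a minor allele frequency to a bin
#'
#' Half-open binning \code{(lo, hi]} with an inclusive upper edge, so MAF
#' exactly 0.001 falls in the ultra-rare bin with the default edges.
#' Variants absent from the reference carry MAF 0 and fall in the lowest
#' bin.  A MAF above 0.5 is an error (it is not a minor allele frequency
#' and is not folded silently).
#'
#' @param ref_maf numeric MAF in [0, 0.5].
#' @param bin_edges see \code{\link{maf_bin_labels}}.
#' @return factor of bin labels.
#' @export
#' @examples
#' classify_maf_bin(c(0, 0.0005, 0.001, 0.2))
classify_maf_bin <- function(ref_maf, bin_edges = c(0, 0.001, 0.01, 0.05, 0.5)) {
  stopifnot(all(!is.na(ref_maf)))
  if (any(ref_maf < 0)) stop("negative MAF")
  if (any(ref_maf > max(bin_edges))) {
    stop("MAF above ", max(bin_edges),
         ": not a minor allele frequency (fold it explicitly upstream)")
  }
  labs <- maf_bin_labels(bin_edges)
  idx <- findInterval(ref_maf, bin_edges, left.open = TRUE,
                      rightmost.closed = FALSE) # (lo, hi] via left.open
  idx[ref_maf == 0] <- 1L # absent from reference -> lowest bin
  idx[ref_maf == max(bin_edges)] <- length(labs)
  factor(labs[idx], levels = labs)
}

.class_groups <- list(
  non_silent_coding = c("missense", "nonsense"),
  promoter = "promoter")

#' Per-stratum observation counts
#'
#' Counts variant x carrier observations in one (annotation class group x
#' MAF bin) stratum, split into panel and genome-wide background, for the
#' case cohort and the reference cohort.  Sites flagged low-quality are
#' excluded under the default policy.
#'
#' @param annotations case-variant annotation table
#'   (\code{\link{emit_annotations}} layout).
#' @param case_obs data.frame (variant_id, sample_id, dosage) of case
#'   cohort observations, restricted to the genomes that define the case
#'   cohort (e.g. patients).
#' @param ref_counts a \code{ref_counts} table.
#' @param panel a \code{gene_panel}.
#' @param class_group \code{"non_silent_coding"} or \code{"promoter"}.
#' @param maf_bin bin label (see \code{\link{maf_bin_labels}}).
#' @param n_case_genomes number of case genomes.
#' @param bin_edges MAF bin edges.
#' @param flagged character vector of LOWGP-flagged variant ids.
#' @param flag_policy \code{"exclude"} (default) or \code{"include"}.
#' @param count_mode \code{"carrier"} (homozygote = 1 observation,
#'   default) or \code{"allele"} (homozygote = 2).
#' @return one-row data.frame of class \code{stratum_counts}.
#' @export
count_stratum <- function(annotations, case_obs, ref_counts, panel,
                          class_group = c("non_silent_coding", "promoter"),
                          maf_bin, n_case_genomes,
                          bin_edges = c(0, 0.001, 0.01, 0.05, 0.5),
                          flagged = character(),
                          flag_policy = c("exclude", "include"),
                          count_mode = c("carrier", "allele")) {
  class_group <- match.arg(class_group)
  flag_policy <- match.arg(flag_policy)
  count_mode <- match.arg(count_mode)
  classes <- .class_groups[[class_group]]
  feature <- if (class_group == "promoter") "promoter" else "coding"

  ann <- annotations
  if (flag_policy == "exclude" && length(flagged)) {
    ann <- ann[!ann$variant_id %in% flagged, ]
  }
  ann <- ann[ann$class %in% classes, ]
  ann$bin <- classify_maf_bin(ann$ref_maf, bin_edges)
  ann <- ann[as.character(ann$bin) == maf_bin, ]
  in_panel <- variant_in_panel(ann$chrom, ann$pos, panel, feature)

  obs <- case_obs[case_obs$variant_id %in% ann$variant_id, ]
  obs_w <- if (count_mode == "allele") obs$dosage else rep(1L, nrow(obs))
  panel_ids <- ann$variant_id[in_panel]
  case_panel <- sum(obs_w[obs$variant_id %in% panel_ids])
  case_background <- sum(obs_w) - case_panel

  rc <- ref_counts
  if (flag_policy == "exclude" && length(flagged)) {
    rc <- rc[!rc$variant_id %in% flagged, ]
  }
  rc <- rc[rc$class %in% classes, ]
  rc$bin <- classify_maf_bin(pmin(rc$maf, max(bin_edges)), bin_edges)
  rc <- rc[as.character(rc$bin) == maf_bin, ]
  rc_panel <- variant_in_panel(rc$chrom, rc$pos, panel, feature)
  rc_w <- if (count_mode == "allele") rc$ac else rc$n_carrier
  ref_panel <- sum(rc_w[rc_panel])
  ref_background <- sum(rc_w) - ref_panel

  structure(data.frame(
    class_group = class_group, maf_bin = maf_bin,
    case_panel = case_panel, case_background = case_background,
    ref_panel = ref_panel, ref_background = ref_background,
    n_case_genomes = n_case_genomes,
    n_ref_genomes = attr(ref_counts, "n_genomes"),
    stringsAsFactors = FALSE),
    class = c("stratum_counts", "data.frame"))
}

#' Cross-cohort calling-rate normalisation factor
#'
#' Ratio of genome-wide per-genome background observation rates between
#' the case and the reference cohort in one stratum.  The reference panel
#' expectation is multiplied by this factor before testing, correcting
#' for differential variant-calling sensitivity (a trio-aware pipeline
#' recovers private variants a conventional pipeline misses).  The factor
#' is invariant to duplicating every reference sample.
#'
#' @param stratum a \code{stratum_counts} row (or any list with
#'   case_background, ref_background, n_case_genomes, n_ref_genomes).
#' @return positive scalar, or NA (with a message) when the reference
#'   background count is zero, which makes the stratum untestable.
#' @export
normalization_factor <- function(stratum) {
  if (stratum$ref_background <= 0) {
    message("stratum ", stratum$class_group, " ", stratum$maf_bin,
            ": zero reference background count; untestable")
    return(NA_real_)
  }
  (stratum$case_background / stratum$n_case_genomes) /
    (stratum$ref_background / stratum$n_ref_genomes)
}

#' Enrichment test for one stratum
#'
#' Computes the normalisation-adjusted expected number of case panel
#' observations, the enrichment odds ratio (observed / expected rate
#' ratio; Haldane--Anscombe 0.5 correction applied to the display value
#' only when a zero occurs), the two-sided Fisher exact p value by
#' hypergeometric summation on the observed-vs-expected carrier-rate
#' table, and the signed log p (negative sign = depletion).
#'
#' @param stratum a \code{stratum_counts} row.
#' @param factor normalisation factor from
#'   \code{\link{normalization_factor}}; computed from the stratum when
#'   missing.
#' @return one-row data.frame of class \code{enrichment_result}; when the
#'   stratum is untestable (no reference information) \code{testable} is
#'   FALSE and the statistics are NA.
#' @export
enrichment_test <- function(stratum, factor = NULL) {
  if (is.null(factor)) factor <- normalization_factor(stratum)
  a <- stratum$case_panel
  N <- stratum$n_case_genomes
  base <- data.frame(stratum, normalization_factor = factor,
                     stringsAsFactors = FALSE)
  if (is.na(factor) || (stratum$case_panel + stratum$ref_panel +
                        stratum$case_background + stratum$ref_background) == 0) {
    out <- cbind(base, expected_panel = NA_real_, odds_ratio = NA_real_,
                 odds_ratio_display = NA_real_, p_value = NA_real_,
                 signed_log_p = NA_real_, corrected_alpha = NA_real_,
                 significant = NA, testable = FALSE)
    class(out) <- c("enrichment_result", "data.frame")
    return(out)
  }
  Nr <- stratum$n_ref_genomes
  c_adj <- factor * stratum$ref_panel  # calling-corrected reference count
  expected <- c_adj * N / Nr           # expectation at case-cohort scale
  or <- a / expected                   # per-genome rate ratio
  if (is.nan(or)) or <- NA_real_
  or_disp <- if (isTRUE(a == 0 || expected == 0)) {
    (a + 0.5) / (expected + 0.5)
  } else or
  p <- poisson_rate_test(a, round(c_adj), N, Nr)
  s <- if (is.na(or) || or == 1) 0 else sign(or - 1)
  out <- cbind(base, expected_panel = expected, odds_ratio = or,
               odds_ratio_display = or_disp, p_value = p,
               signed_log_p = -log10(p) * s,
               corrected_alpha = NA_real_, significant = NA,
               testable = TRUE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Bonferroni correction across tested strata
#'
#' Records \code{corrected_alpha = alpha / m} (m = number of testable
#' strata) on every result and sets the significance call
#' \code{p_value <= corrected_alpha}.
#'
#' @param results data.frame of stacked \code{enrichment_result} rows.
#' @param alpha family-wise error rate (default 0.05).
#' @return the results with corrected_alpha and significant filled in.
#' @export
correct_multiple_testing <- function(results, alpha = 0.05) {
  stopifnot(nrow(results) >= 1)
  m <- sum(results$testable)
  results$corrected_alpha <- ifelse(results$testable, alpha / max(m, 1),
                                    NA_real_)
  results$significant <- ifelse(results$testable,
                                results$p_value <= results$corrected_alpha,
                                NA)
  results
}

#' Excess variants implied by an enrichment odds ratio
#'
#' excess = observed * (1 - 1/OR); the expected count observed / OR is
#' also reported.  This inversion reproduces the printed cohort arithmetic
#' (21 observed at OR 2.07 gives an excess of 10.9).
#'
#' @param observed observed panel observation count.
#' @param odds_ratio enrichment odds ratio (> 0).
#' @return list with \code{excess} and \code{expected}.
#' @export
#' @examples
#' excess_variants(21, 2.07)$excess  # 10.855 -> 10.9 at one decimal
excess_variants <- function(observed, odds_ratio) {
  stopifnot(observed >= 0)
  if (is.na(odds_ratio) || odds_ratio <= 0) {
    stop("excess_variants requires a positive odds ratio")
  }
  list(excess = observed * (1 - 1 / odds_ratio),
       expected = observed / odds_ratio)
}

#' Rounded patients-per-event summary
#'
#' "One out of N patients": the cohort size divided by an event count
#' (e.g. prioritised variants, or the excess variant count), rounded to
#' the nearest integer.
#'
#' @param n_patients cohort size.
#' @param n_events positive event count.
#' @return integer N.
#' @export
#' @examples
#' patients_per_event(71, 8)     # 9  ("one out of nine")
#' patients_per_event(71, 10.9)  # 7  ("one-seventh")
patients_per_event <- function(n_patients, n_events) {
  stopifnot(n_patients > 0, n_events > 0)
  as.integer(round(n_patients / n_events))
}

#' Full panel-enrichment analysis
#'
#' Runs \code{\link{count_stratum}}, \code{\link{normalization_factor}},
#' \code{\link{enrichment_test}} and
#' \code{\link{correct_multiple_testing}} over every (class group x MAF
#' bin) stratum.
#'
#' @param cohort a \code{trio_cohort} (patients define the case genomes),
#'   or NULL when \code{annotations}/\code{case_obs}/... are given
#'   directly.
#' @param ref_counts a \code{ref_counts} table.
#' @param panel gene panel; defaults to the cohort's.
#' @param bin_edges MAF bin edges.
#' @param flagged LOWGP-flagged variant ids to exclude.
#' @param flag_policy,count_mode see \code{\link{count_stratum}}.
#' @param alpha family-wise error rate.
#' @return \code{enrichment_result} data.frame, one row per stratum.
#' @export
panel_enrichment_analysis <- function(cohort, ref_counts, panel = NULL,
                                      bin_edges = c(0, 0.001, 0.01, 0.05, 0.5),
                                      flagged = character(),
                                      flag_policy = "exclude",
                                      count_mode = "carrier",
                                      alpha = 0.05) {
  panel <- panel %||% cohort$panel
  patients <- cohort$samples$sample_id[cohort$samples$role == "patient"]
  case_obs <- cohort$carriers[cohort$carriers$sample_id %in% patients, ]
  labs <- maf_bin_labels(bin_edges)
  rows <- list()
  for (cg in names(.class_groups)) {
    for (b in labs) {
      st <- count_stratum(cohort$annotations, case_obs, ref_counts, panel,
                          cg, b, length(patients), bin_edges, flagged,
                          flag_policy, count_mode)
      rows[[length(rows) + 1L]] <- enrichment_test(st)
    }
  }
  out <- do.call(rbind, rows)
  out <- correct_multiple_testing(out, alpha)
  class(out) <- c("enrichment_result", "data.frame")
  out
}
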