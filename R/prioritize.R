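# Candidate-variant prioritisation: reduce the refined panel variants of a
# cohort to a report of ultra-rare non-silent candidates with a
# deleteriousness call from DANN / SIFT / PolyPhen2 annotations.

#' Filter panel variants into a candidate report
#'
#' Keeps variants that are (a) inside a panel coding interval and
#' non-silent, (b) ultra-rare (\code{ref_maf <= maf_max}), and (c) not
#' excluded by the flagged-site policy.  Each kept variant receives a
#' \code{damaging_call}:
#' \itemize{
#'   \item \code{score_damaging} when SIFT < \code{sift_max} ("D"),
#'     PolyPhen2 >= \code{polyphen_min} ("D"), or DANN >=
#'     \code{dann_min}; nonsense variants are always
#'     \code{score_damaging}.
#'   \item \code{other_evidence} when the scores fail but a free-text
#'     evidence note is supplied for the variant (human judgement, e.g.
#'     structural proximity to known disease mutations); such variants
#'     stay in the report but are excluded from the headline count.
#'   \item \code{not_damaging} otherwise (excluded from the report).
#' }
#' A missing predictor score is treated as non-damaging for that
#' predictor and logged via message.
#'
#' @param cohort a \code{trio_cohort}; its annotations, carriers, panel
#'   and truth-free metadata are used.  (Scores and parent-of-origin are
#'   merged in when \code{scores}/\code{poo} are provided.)
#' @param scores optional cohort risk-score table, to report the carrier
#'   patient's risk score.
#' @param maf_max rarity ceiling (default 0.001).
#' @param sift_max,polyphen_min,dann_min predictor cutoffs.  SIFT and
#'   PolyPhen2 use the tools' published "damaging" conventions; the DANN
#'   cutoff is a calibrated configuration value.
#' @param flagged LOWGP-flagged variant ids.
#' @param evidence_notes named character vector (variant_id -> note) of
#'   manual evidence for score-negative variants.
#' @return data.frame of class \code{candidate_variants}: gene, variant_id,
#'   chrom, pos, zygosity, ref_maf, dann, sift, polyphen, damaging_call,
#'   carrier sample, risk score, parent_of_origin.
#' @export
filter_candidates <- function(cohort, scores = NULL, maf_max = 0.001,
                              sift_max = 0.05, polyphen_min = 0.85,
                              dann_min = 0.96, flagged = character(),
                              evidence_notes = NULL) {
  ann <- cohort$annotations
  patients <- cohort$samples$sample_id[cohort$samples$role == "patient"]
  obs <- cohort$carriers[cohort$carriers$sample_id %in% patients, ]

  keep <- ann$class %in% c("missense", "nonsense") &
    ann$ref_maf <= maf_max & !ann$variant_id %in% flagged &
    variant_in_panel(ann$chrom, ann$pos, cohort$panel, "coding")
  ann <- ann[keep, ]
  obs <- obs[obs$variant_id %in% ann$variant_id, ]
  if (nrow(obs) == 0) {
    out <- data.frame(gene = character(), variant_id = character(),
                      zygosity = character(), damaging_call = character(),
                      stringsAsFactors = FALSE)
    class(out) <- c("candidate_variants", "data.frame")
    return(out)
  }

  idx <- match(obs$variant_id, ann$variant_id)
  v <- ann[idx, ]
  na_scores <- is.na(v$dann) | is.na(v$sift) | is.na(v$polyphen)
  if (any(na_scores & v$class != "nonsense")) {
    message(sum(na_scores & v$class != "nonsense"),
            " variant(s) with missing predictor scores treated as ",
            "non-damaging for the missing predictor")
  }
  sift_d <- !is.na(v$sift) & v$sift < sift_max
  poly_d <- !is.na(v$polyphen) & v$polyphen >= polyphen_min
  dann_d <- !is.na(v$dann) & v$dann >= dann_min
  score_damaging <- sift_d | poly_d | dann_d | v$class == "nonsense"

  call <- ifelse(score_damaging, "score_damaging", "not_damaging")
  note <- rep("", nrow(v))
  if (!is.null(evidence_notes)) {
    has_note <- v$variant_id %in% names(evidence_notes)
    call[!score_damaging & has_note] <- "other_evidence"
    note[has_note] <- evidence_notes[v$variant_id[has_note]]
  }

  gene <- v$gene
  if (is.null(gene)) gene <- rep(NA_character_, nrow(v))
  vmap <- cohort$variants
  gene[is.na(gene)] <- vmap$gene[match(v$variant_id[is.na(gene)],
                                       vmap$variant_id)]

  # parent of origin from the trio carriers table
  fam <- cohort$samples$family_id[match(obs$sample_id,
                                        cohort$samples$sample_id)]
  car <- cohort$carriers
  dose_of <- function(ids) {
    d <- car$dosage[match(paste(obs$variant_id, ids),
                          paste(car$variant_id, car$sample_id))]
    ifelse(is.na(d), 0L, d)
  }
  poo <- parent_of_origin(obs$dosage, dose_of(paste0(fam, "_M")),
                          dose_of(paste0(fam, "_F")))

  out <- data.frame(
    gene = gene, variant_id = obs$variant_id,
    chrom = v$chrom, pos = v$pos,
    carrier_sample = obs$sample_id, family_id = fam,
    zygosity = ifelse(obs$dosage == 2L, "hom", "het"),
    ref_maf = v$ref_maf, dann = v$dann, sift = v$sift,
    polyphen = v$polyphen, damaging_call = call, evidence_note = note,
    parent_of_origin = poo, stringsAsFactors = FALSE)
  if (!is.null(scores)) {
    out$risk_score <- scores$score[match(out$carrier_sample,
                                         scores$sample_id)]
  }
  out <- out[out$damaging_call != "not_damaging", ]
  # private-variant contract: a candidate should be seen in one family only
  dup <- unique(out$variant_id[duplicated(out$variant_id)])
  if (length(dup)) {
    message("candidate variant(s) observed in more than one family ",
            "(private-variant contract violation, retained): ",
            paste(dup, collapse = ", "))
  }
  rownames(out) <- NULL
  class(out) <- c("candidate_variants", "data.frame")
  out
}

#' Zygosity summary of a candidate list
#'
#' @param candidates a \code{\link{filter_candidates}} result.
#' @return list with n_het, n_hom, n_patients (distinct carriers),
#'   n_variants.
#' @export
zygosity_summary <- function(candidates) {
  list(n_het = sum(candidates$zygosity == "het"),
       n_hom = sum(candidates$zygosity == "hom"),
       n_patients = length(unique(candidates$carrier_sample)),
       n_variants = nrow(candidates))
}
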