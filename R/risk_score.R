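# Random-forest genotype risk score.  No forest implementation ships with
# the pre-installed stack, so the package carries its own compact
# classification forest (src/forest.cpp), specialised for dosage features:
# bootstrap bagging, per-split feature subsampling (mtry), gini splits at
# the only informative thresholds 0.5 / 1.5.  The score of a sample is the
# percentage of trees voting "case", matching the convention of reporting
# genotype risk scores as percentages.

#' Train the genotype risk-score model
#'
#' @param geno samples x markers dosage matrix (0/1/2) with marker
#'   colnames and sample rownames.
#' @param labels case/control labels: logical, 0/1, or a 2-level factor
#'   where the \emph{second} level is "case".
#' @param ntree number of trees (default 500).
#' @param mtry features tried per split; default \code{floor(sqrt(p))}.
#' @param min_node minimum node size eligible for splitting.
#' @param max_depth maximum tree depth.
#' @param seed RNG seed; training is deterministic given it.
#' @return object of class \code{rf_risk_model} carrying the forest, the
#'   expected marker list and per-marker training mean dosages used to
#'   impute markers missing at scoring time.
#' @export
train_risk_model <- function(geno, labels, ntree = 500, mtry = NULL,
                             min_node = 5, max_depth = 25, seed = 1) {
  geno <- as.matrix(geno)
  if (is.null(colnames(geno))) stop("genotype matrix must have marker colnames")
  if (is.factor(labels)) {
    y <- as.integer(labels == levels(labels)[2])
  } else {
    y <- as.integer(as.numeric(labels) == max(as.numeric(labels)))
  }
  if (length(y) != nrow(geno)) stop("labels must match rows of geno")
  if (length(unique(y)) < 2) {
    stop("degenerate labels: need both cases and controls to train")
  }
  if (anyNA(geno)) stop("training genotypes may not contain missing values")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(geno))))
  set.seed(seed)
  forest <- forest_grow(geno, y, as.integer(ntree), as.integer(mtry),
                        as.integer(min_node), as.integer(max_depth))
  structure(list(forest = forest, markers = colnames(geno),
                 marker_means = colMeans(geno), ntree = ntree, mtry = mtry,
                 min_node = min_node, max_depth = max_depth, seed = seed,
                 n_train = nrow(geno), class_balance = mean(y)),
            class = "rf_risk_model")
}

#' @export
print.rf_risk_model <- function(x, ...) {
  cat("rf_risk_model:", x$ntree, "trees, mtry", x$mtry, ",",
      length(x$markers), "markers,", x$n_train, "training samples\n")
  invisible(x)
}

#' Score samples with a trained risk model
#'
#' The score is the percentage of trees voting "case" (0--100).  Markers
#' expected by the model but absent from \code{geno} -- or missing (NA)
#' in a sample -- are imputed to the training-set mean dosage and counted
#' in \code{n_imputed}.  Scoring fails when the marker overlap falls below
#' \code{min_overlap} (the analysis design assumes a near-complete overlap,
#' e.g. ~97\%), or when a sample has no observed genotype at all.
#'
#' @param model an \code{rf_risk_model}.
#' @param geno samples x markers dosage matrix.
#' @param min_overlap minimum fraction of model markers that must be
#'   present (default 0.9).
#' @return data.frame with sample_id, score, n_imputed.
#' @export
score_samples <- function(model, geno, min_overlap = 0.9) {
  stopifnot(inherits(model, "rf_risk_model"))
  geno <- as.matrix(geno)
  if (nrow(geno) == 0) {
    return(data.frame(sample_id = character(), score = numeric(),
                      n_imputed = integer(), stringsAsFactors = FALSE))
  }
  if (is.null(colnames(geno))) stop("genotype matrix must have marker colnames")
  present <- intersect(model$markers, colnames(geno))
  overlap <- length(present) / length(model$markers)
  if (overlap < min_overlap) {
    stop(sprintf(
      "marker overlap %.1f%% below the required %.0f%%: cannot score",
      100 * overlap, 100 * min_overlap))
  }
  X <- matrix(rep(model$marker_means, each = nrow(geno)),
              nrow(geno), length(model$markers),
              dimnames = list(rownames(geno), model$markers))
  n_imputed <- rep.int(length(model$markers) - length(present), nrow(geno))
  obs <- geno[, present, drop = FALSE]
  all_missing <- apply(is.na(obs), 1, all)
  if (any(all_missing)) {
    stop("sample(s) with no observed genotypes: ",
         paste(rownames(geno)[all_missing], collapse = ", "))
  }
  nas <- is.na(obs)
  n_imputed <- n_imputed + rowSums(nas)
  if (any(nas)) {
    fill <- matrix(rep(model$marker_means[present], each = nrow(obs)),
                   nrow(obs), ncol(obs))
    obs[nas] <- fill[nas]
  }
  X[, present] <- obs
  score <- 100 * forest_vote_fraction(model$forest, X)
  data.frame(sample_id = rownames(geno) %||% sprintf("s%d", seq_len(nrow(geno))),
             score = score, n_imputed = as.integer(n_imputed),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Risk-score table for a whole cohort
#'
#' Trains nothing: applies \code{model} to patients, parents and controls
#' of a simulated cohort and labels each score with the sample's role and
#' family.
#'
#' @param model an \code{rf_risk_model}.
#' @param cohort a \code{trio_cohort}.
#' @param refined optional refined child dosages (see
#'   \code{\link{refine_trios}}).
#' @return data.frame: sample_id, family_id, role, score.
#' @export
cohort_risk_scores <- function(model, cohort, refined = NULL) {
  geno <- common_genotypes(cohort,
                           roles = c("patient", "mother", "father", "control"),
                           refined = refined)
  sc <- score_samples(model, geno)
  out <- merge(sc[c("sample_id", "score")], cohort$samples, by = "sample_id")
  out[order(match(out$role, c("patient", "mother", "father", "control")),
            out$sample_id),
      c("sample_id", "family_id", "role", "score")]
}

#' Partition the two parents of each family into higher / lower risk
#'
#' The parent with the larger risk score is "higher".  An exact tie is
#' broken deterministically by lexicographic sample id and flagged.
#' Families with a missing parent score are dropped with a warning.
#'
#' @param scores data.frame with sample_id, family_id, role, score
#'   (as from \code{\link{cohort_risk_scores}}).
#' @return data.frame of class \code{parent_partition}: family_id,
#'   higher_id, lower_id, higher_score, lower_score, tie.
#' @export
partition_parents <- function(scores) {
  par <- scores[scores$role %in% c("mother", "father"), ]
  fams <- unique(par$family_id)
  rows <- lapply(fams, function(f) {
    sub <- par[par$family_id == f & !is.na(par$score), ]
    if (nrow(sub) < 2) return(NULL)
    sub <- sub[order(-sub$score, sub$sample_id), ]
    data.frame(family_id = f, higher_id = sub$sample_id[1],
               lower_id = sub$sample_id[2], higher_score = sub$score[1],
               lower_score = sub$score[2],
               tie = sub$score[1] == sub$score[2], stringsAsFactors = FALSE)
  })
  dropped <- fams[vapply(rows, is.null, TRUE)]
  if (length(dropped)) {
    warning("families excluded for missing parent scores: ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  structure(out, class = c("parent_partition", "data.frame"))
}

# Pearson correlation with exact t-distribution p value; zero variance in
# either vector yields NA with a note.
pearson_pair <- function(x, y, label) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) {
    return(data.frame(pair = label, r = NA_real_, r_squared = NA_real_,
                      p_value = NA_real_, n = n,
                      note = "fewer than 3 complete pairs",
                      stringsAsFactors = FALSE))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(data.frame(pair = label, r = NA_real_, r_squared = NA_real_,
                      p_value = NA_real_, n = n,
                      note = "zero variance: correlation undefined",
                      stringsAsFactors = FALSE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  data.frame(pair = label, r = unname(ct$estimate),
             r_squared = unname(ct$estimate)^2, p_value = ct$p.value,
             n = n, note = "", stringsAsFactors = FALSE)
}

#' Correlations between patient and parent risk scores
#'
#' Reports the Pearson correlation (r, R^2, two-sided t-distribution p, n)
#' of the patient score against the higher-risk and the lower-risk parent,
#' plus per-group mean scores (patients, higher parents, lower parents,
#' controls) for the distribution-style summary.
#'
#' @param scores cohort score table (\code{\link{cohort_risk_scores}}).
#' @param partition a \code{\link{partition_parents}} result.
#' @return list with \code{correlations} and \code{group_means}
#'   data.frames.
#' @export
correlation_report <- function(scores, partition) {
  pat <- scores[scores$role == "patient", ]
  ps <- setNames(pat$score, pat$family_id)
  hi <- setNames(partition$higher_score, partition$family_id)
  lo <- setNames(partition$lower_score, partition$family_id)
  fams <- intersect(names(ps), partition$family_id)
  correlations <- rbind(
    pearson_pair(ps[fams], hi[fams], "patient_vs_higher_parent"),
    pearson_pair(ps[fams], lo[fams], "patient_vs_lower_parent"))
  grp <- rbind(
    data.frame(group = "patients", mean_score = mean(pat$score),
               n = nrow(pat)),
    data.frame(group = "higher_parents",
               mean_score = mean(partition$higher_score),
               n = nrow(partition)),
    data.frame(group = "lower_parents",
               mean_score = mean(partition$lower_score),
               n = nrow(partition)),
    data.frame(group = "all_parents",
               mean_score = mean(scores$score[scores$role %in%
                                                c("mother", "father")]),
               n = sum(scores$role %in% c("mother", "father"))),
    data.frame(group = "controls",
               mean_score = mean(scores$score[scores$role == "control"]),
               n = sum(scores$role == "control")))
  list(correlations = correlations, group_means = grp)
}

#' Correlations split by which parent carries a rare candidate variant
#'
#' For families in which the patient carries a prioritised rare panel
#' variant, correlates the patient score with the parent carrying the
#' variant and with the parent lacking it -- the mode-of-inheritance
#' contrast: a high correlation with the variant-lacking parent together
#' with no correlation with the carrier parent indicates that the
#' polygenic burden and the rare variant come from different parents.
#'
#' @param scores cohort score table.
#' @param carrier_parents data.frame with family_id and carrier_parent_id
#'   (the parent transmitting the rare variant).
#' @return data.frame of the two correlations.
#' @export
carrier_correlation_report <- function(scores, carrier_parents) {
  pat <- scores[scores$role == "patient", ]
  ps <- setNames(pat$score, pat$family_id)
  sc <- setNames(scores$score, scores$sample_id)
  cp <- carrier_parents[!duplicated(carrier_parents$family_id), ]
  fams <- intersect(cp$family_id, names(ps))
  cp <- cp[match(fams, cp$family_id), ]
  with_v <- sc[cp$carrier_parent_id]
  other_id <- ifelse(substring(cp$carrier_parent_id,
                               nchar(cp$carrier_parent_id)) == "M",
                     paste0(cp$family_id, "_F"), paste0(cp$family_id, "_M"))
  without_v <- sc[other_id]
  rbind(pearson_pair(ps[fams], without_v, "patient_vs_parent_without_variant"),
        pearson_pair(ps[fams], with_v, "patient_vs_parent_with_variant"))
}
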