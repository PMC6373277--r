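# Figure-style summaries: score distributions by group, patient-parent
# score scatter, and the signed log-p enrichment profile.

#' Density plot of risk scores by group
#'
#' Patients, higher-risk parents, lower-risk parents and controls on one
#' panel; the expected signature of one-parent inheritance is the
#' higher-parent curve tracking the patients and the lower-parent curve
#' tracking the controls.
#'
#' @param scores cohort score table.
#' @param partition a \code{\link{partition_parents}} result.
#' @return a ggplot object.
#' @export
plot_score_distributions <- function(scores, partition) {
  grp <- rbind(
    data.frame(group = "patients",
               score = scores$score[scores$role == "patient"]),
    data.frame(group = "higher parent", score = partition$higher_score),
    data.frame(group = "lower parent", score = partition$lower_score),
    data.frame(group = "controls",
               score = scores$score[scores$role == "control"]))
  ggplot2::ggplot(grp, ggplot2::aes(x = score,
                                    colour = group)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "risk score (% trees voting case)", y = "density") +
    ggplot2::theme_minimal()
}

#' Patient versus parent score scatter with linear fits
#'
#' @inheritParams plot_score_distributions
#' @return a ggplot object.
#' @export
plot_score_correlation <- function(scores, partition) {
  pat <- scores[scores$role == "patient", ]
  ps <- setNames(pat$score, pat$family_id)
  df <- rbind(
    data.frame(parent = "higher", patient = ps[partition$family_id],
               parent_score = partition$higher_score),
    data.frame(parent = "lower", patient = ps[partition$family_id],
               parent_score = partition$lower_score))
  ggplot2::ggplot(df, ggplot2::aes(x = patient,
                                   y = parent_score,
                                   colour = parent)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "patient risk score (%)",
                  y = "parent risk score (%)") +
    ggplot2::theme_minimal()
}

#' Signed log-p enrichment profile across MAF bins
#'
#' One line per annotation class group; values below zero indicate
#' depletion.  The horizontal guides mark the Bonferroni-corrected 0.05
#' threshold.
#'
#' @param results an \code{enrichment_result} table.
#' @return a ggplot object.
#' @export
plot_enrichment_profile <- function(results) {
  df <- results[results$testable, ]
  thr <- -log10(df$corrected_alpha[1])
  ggplot2::ggplot(df, ggplot2::aes(x = maf_bin,
                                   y = signed_log_p,
                                   group = class_group,
                                   colour = class_group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(-thr, thr), colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "reference MAF bin", y = "signed -log10 p") +
    ggplot2::theme_minimal()
}
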