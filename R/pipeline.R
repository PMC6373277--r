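# Stage orchestration: simulate -> refine -> score -> enrich ->
# prioritize -> clinical -> report, with artifacts written per stage so
# each printed cohort statistic has a file analogue.  Stage chaining
# between separate invocations goes through an RDS state file in the
# output directory; all tabular artifacts are TSV with provenance
# headers (tool version, config hash, master seed -- no timestamps, so
# reruns with the same seed are byte-identical).

#' Pipeline configuration and scenario presets
#'
#' \code{"paper_like"} is the default stated world (71 trio families,
#' 1000-genome reference, 2x panel enrichment, a 0.9 reference
#' singleton-calling deflation for the normalisation step to correct).
#' \code{"null"} removes the enrichment (factor 1) at a larger cohort
#' scale used for type-I error studies, and \code{"tiny"} is a smoke-test
#' scenario.
#'
#' @param preset scenario name.
#' @param seed master seed.
#' @param out_dir artifact directory.
#' @param sim_overrides named list of \code{\link{sim_config}} arguments
#'   overriding the preset.
#' @param rf named list of risk-model hyperparameters (ntree, mtry,
#'   min_node, max_depth).
#' @param ref_deflation reference private-variant calling deflation.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(preset = c("paper_like", "null", "tiny"),
                            seed = 1, out_dir = "triorare_out",
                            sim_overrides = list(), rf = list(),
                            ref_deflation = NULL) {
  preset <- match.arg(preset)
  base <- switch(preset,
    paper_like = list(),
    null = list(n_families = 500, n_reference = 2000,
                panel_enrichment_factor = 1, n_homozygous_nonsense = 0),
    tiny = list(n_families = 8, n_controls = 60, n_reference = 60,
                n_common_markers = 40, n_causal_markers = 10))
  base$seed <- seed
  base[names(sim_overrides)] <- sim_overrides
  sim <- do.call(sim_config, base)
  rf_def <- list(ntree = if (preset == "tiny") 100 else 500, mtry = NULL,
                 min_node = 5, max_depth = 25)
  rf_def[names(rf)] <- rf
  defl <- ref_deflation %||% switch(preset, paper_like = 0.9, null = 1,
                                    tiny = 1)
  structure(list(preset = preset, seed = seed, out_dir = out_dir,
                 sim = sim, rf = rf_def, ref_deflation = defl),
            class = "pipeline_config")
}

.art <- function(cfg, name) file.path(cfg$out_dir, name)

.save_state <- function(state, cfg) {
  saveRDS(state, .art(cfg, "state.rds"))
}

.load_state <- function(cfg, needed_stage) {
  p <- .art(cfg, "state.rds")
  if (!file.exists(p)) {
    stop("missing artifact ", p, ": run the '", needed_stage,
         "' stage first", call. = FALSE)
  }
  readRDS(p)
}

.emit <- function(cfg, df, name) {
  write_tsv_provenance(df, .art(cfg, name), seed = cfg$seed,
                       extra = c(paste0("preset=", cfg$preset),
                                 paste0("config=", config_hash(cfg$sim))))
}

#' Run the analysis pipeline
#'
#' @param stages character vector drawn from \code{c("simulate",
#'   "refine", "score", "enrich", "prioritize", "clinical", "report")},
#'   or \code{"all"}.
#' @param config a \code{\link{pipeline_config}}.
#' @return the pipeline state (named list of stage outputs), invisibly.
#' @export
run_pipeline <- function(stages = "all", config = pipeline_config()) {
  all_stages <- c("simulate", "refine", "score", "enrich", "prioritize",
                  "clinical", "report")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- if (file.exists(.art(config, "state.rds")) &&
               !"simulate" %in% stages) {
    .load_state(config, "simulate")
  } else list()

  for (st in all_stages[all_stages %in% stages]) {
    state <- switch(st,
      simulate = .stage_simulate(state, config),
      refine = .stage_refine(state, config),
      score = .stage_score(state, config),
      enrich = .stage_enrich(state, config),
      prioritize = .stage_prioritize(state, config),
      clinical = .stage_clinical(state, config),
      report = .stage_report(state, config))
    .save_state(state, config)
  }
  invisible(state)
}

.stage_simulate <- function(state, cfg) {
  message("[simulate] generating cohort (", cfg$preset, ", seed ",
          cfg$seed, ")")
  cohort <- simulate_cohort(cfg$sim)
  ref <- simulate_reference(cfg$sim, deflation = cfg$ref_deflation)
  write_trio_vcf(cohort, .art(cfg, "trios.vcf"))
  write_ped(cohort$pedigree, .art(cfg, "trios.ped"))
  write_panel_bed(cohort$panel, .art(cfg, "panel.bed"))
  .emit(cfg, cohort$annotations, "annotations.tsv")
  .emit(cfg, cohort$phenotypes, "phenotypes.tsv")
  .emit(cfg, as.data.frame(ref), "reference_counts.tsv")
  message("[simulate] ", nrow(cohort$variants), " rare variants, ",
          nrow(ref), " reference variants")
  state$cohort <- cohort
  state$ref <- ref
  state
}

.require_stage <- function(state, field, stage) {
  if (is.null(state[[field]])) {
    stop("pipeline state lacks '", field, "': run the '", stage,
         "' stage first", call. = FALSE)
  }
  state[[field]]
}

.stage_refine <- function(state, cfg) {
  cohort <- .require_stage(state, "cohort", "simulate")
  refined <- refine_trios(cohort)
  message("[refine] ", refined$n_changed, " child calls changed, ",
          sum(refined$flag), " flagged LOWGP")
  write_trio_vcf(cohort, .art(cfg, "trios_refined.vcf"), refined = refined)
  flags <- data.frame(
    variant_id = rep(colnames(refined$flag), each = nrow(refined$flag)),
    sample_id = paste0(rep(rownames(refined$flag), ncol(refined$flag)), "_P"),
    flagged = as.vector(refined$flag))
  .emit(cfg, flags[flags$flagged, c("variant_id", "sample_id")],
        "lowgp_flags.tsv")
  state$refined <- refined
  state
}

.stage_score <- function(state, cfg) {
  cohort <- .require_stage(state, "cohort", "simulate")
  train <- common_genotypes(cohort, c("control_training", "case_training"))
  labels <- rep(c(0L, 1L), c(cfg$sim$n_controls, cfg$sim$n_controls))
  model <- do.call(train_risk_model,
                   c(list(geno = train, labels = labels,
                          seed = derive_seed(cfg$seed, "rf_train")),
                     cfg$rf))
  scores <- cohort_risk_scores(model, cohort, refined = state$refined$dosage)
  partition <- partition_parents(scores)
  corr <- correlation_report(scores, partition)
  message("[score] mean scores: ",
          paste(sprintf("%s %.0f%%", corr$group_means$group,
                        corr$group_means$mean_score), collapse = ", "))
  .emit(cfg, scores, "risk_scores.tsv")
  .emit(cfg, as.data.frame(partition), "parent_partition.tsv")
  .emit(cfg, corr$correlations, "score_correlations.tsv")
  .emit(cfg, corr$group_means, "score_group_means.tsv")
  state$model <- model
  state$scores <- scores
  state$partition <- partition
  state$correlations <- corr
  state
}

.stage_enrich <- function(state, cfg) {
  cohort <- .require_stage(state, "cohort", "simulate")
  ref <- .require_stage(state, "ref", "simulate")
  res <- panel_enrichment_analysis(cohort, ref)
  ultra <- res[res$class_group == "non_silent_coding" &
                 res$maf_bin == maf_bin_labels()[1], ]
  if (isTRUE(ultra$testable)) {
    message(sprintf(
      "[enrich] ultra-rare non-silent panel stratum: OR=%.2f p=%.3g",
      ultra$odds_ratio, ultra$p_value))
  }
  .emit(cfg, as.data.frame(res), "enrichment.tsv")
  state$enrichment <- res
  state
}

.stage_prioritize <- function(state, cfg) {
  cohort <- .require_stage(state, "cohort", "simulate")
  cand <- filter_candidates(cohort, scores = state$scores)
  zs <- zygosity_summary(cand)
  message("[prioritize] ", zs$n_variants, " candidate variants in ",
          zs$n_patients, " patients (", zs$n_het, " het, ", zs$n_hom,
          " hom)")
  .emit(cfg, as.data.frame(cand), "candidates.tsv")
  state$candidates <- cand
  state
}

.stage_clinical <- function(state, cfg) {
  cohort <- .require_stage(state, "cohort", "simulate")
  cand <- .require_stage(state, "candidates", "prioritize")
  carriers <- unique(cand$carrier_sample[cand$zygosity == "het"])
  if (length(carriers) == 0 ||
      length(carriers) == nrow(cohort$phenotypes)) {
    message("[clinical] no informative carrier split; skipping comparison")
    state$acr <- NULL
    return(state)
  }
  acr <- acr_comparison(cohort$phenotypes, carriers)
  .emit(cfg, acr, "acr_comparison.tsv")
  state$acr <- acr
  state
}

.stage_report <- function(state, cfg) {
  corr <- .require_stage(state, "correlations", "score")
  enr <- .require_stage(state, "enrichment", "enrich")
  cand <- .require_stage(state, "candidates", "prioritize")
  n_pat <- cfg$sim$n_families
  zs <- zygosity_summary(cand)
  ultra <- enr[enr$class_group == "non_silent_coding" &
                 enr$maf_bin == maf_bin_labels()[1], ]
  lines <- c(
    sprintf("triorare report (preset %s, seed %s)", cfg$preset, cfg$seed),
    "",
    "group mean risk scores (%):",
    sprintf("  %-15s %6.1f (n=%d)", corr$group_means$group,
            corr$group_means$mean_score, corr$group_means$n),
    "",
    "patient-parent score correlations:",
    sprintf("  %-28s r=%.3f R2=%.3f p=%.3g n=%d",
            corr$correlations$pair, corr$correlations$r,
            corr$correlations$r_squared, corr$correlations$p_value,
            corr$correlations$n),
    "",
    "panel enrichment (testable strata):")
  tst <- enr[enr$testable, ]
  lines <- c(lines, sprintf(
    "  %-18s %-14s obs=%3d exp=%6.1f OR=%5.2f p=%.3g%s",
    tst$class_group, tst$maf_bin, tst$case_panel, tst$expected_panel,
    tst$odds_ratio, tst$p_value,
    ifelse(tst$significant, " *", "")))
  if (isTRUE(ultra$testable) && !is.na(ultra$odds_ratio) &&
      ultra$odds_ratio > 0) {
    ex <- excess_variants(ultra$case_panel, ultra$odds_ratio)
    lines <- c(lines, "", sprintf(
      "  ultra-rare non-silent stratum: %d observed, %.1f expected, excess %.1f",
      ultra$case_panel, ex$expected, ex$excess))
    if (ex$excess > 0) {
      lines <- c(lines, sprintf(
        "  -> about one in %d patients carries an excess panel variant",
        patients_per_event(n_pat, ex$excess)))
    }
  }
  lines <- c(lines, "", sprintf(
    "candidates: %d variants (%d het / %d hom) in %d patients; one per %d patients",
    zs$n_variants, zs$n_het, zs$n_hom, zs$n_patients,
    if (zs$n_variants > 0) patients_per_event(n_pat, zs$n_variants) else NA))
  if (!is.null(state$acr)) {
    top <- state$acr[which.min(state$acr$p_value), ]
    lines <- c(lines, sprintf(
      "ACR: smallest p %s (carriers %.0f%% vs %.0f%%), p=%.3g corrected %.3g",
      top$criterion, 100 * top$carrier_freq, 100 * top$comparator_freq,
      top$p_value, top$p_corrected))
  }
  writeLines(lines, .art(cfg, "report.txt"))
  message(paste(lines, collapse = "\n"))
  state$report <- lines
  state
}
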