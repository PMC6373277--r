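#' Simulation configuration for synthetic trio cohorts
#'
#' The defaults describe the "paper-like" world the downstream analyses
#' assume: 71 trio families with an affected offspring, a 1000-genome
#' reference cohort, an ImmunoChip-like common-marker set carrying a
#' polygenic liability signal concentrated in one designated parent in most
#' families, and ultra-rare deleterious panel variants enriched about
#' two-fold in patients.
#'
#' The liability model is additive with Gaussian environment: liability =
#' sum(w_i g_i) - mu_G + k * rare_effect + e, with e ~ N(0,
#' environmental_sd^2).  Causal markers sit at the low-frequency end of
#' the panel (MAF <= 0.15) and carry positive half-normal weights
#' |N(0, effect_size_sd^2)|, giving a right-skewed, floor-compressed
#' population burden -- most genomes carry few risk alleles, a tail
#' carries many -- which is what concentrates the informative variance in
#' the high-burden parent.  With the defaults the genetic share of the
#' liability variance is in the vicinity of SLE's reported heritability
#' (~0.66) and the total variance is near 1, so
#' \code{liability_threshold} is read on roughly the standard-normal
#' scale; 1.645 makes crossing it a ~5\% population event.  Offspring are
#' rejection-sampled until affected (parents are redrawn after repeated
#' failures).
#'
#' @param n_families number of trio families (affected child + 2 parents).
#' @param n_controls healthy comparison controls; equally sized training
#'   control and affected training cohorts are also generated so the
#'   risk-score model never scores its own training samples.
#' @param n_reference reference-cohort genomes (SweGen stand-in).
#' @param n_common_markers common biallelic markers on the genotyping panel.
#' @param common_maf_range MAF range (0, 0.5] for common markers.
#' @param n_causal_markers markers with non-zero liability weight.
#' @param effect_size_sd SD of per-allele liability weights.
#' @param liability_threshold affection threshold, standard-normal scale.
#' @param environmental_sd SD of the environmental liability component.
#' @param one_parent_fraction fraction of families in which the polygenic
#'   burden is concentrated in one designated parent, whose causal-allele
#'   frequencies are exponentially tilted toward an elevated-liability
#'   distribution with between-family heterogeneity (see
#'   \code{\link{simulate_cohort}}).
#' @param panel_rare_rate_background expected ultra-rare non-silent panel
#'   variants per genome absent enrichment.
#' @param panel_enrichment_factor fold enrichment of ultra-rare deleterious
#'   panel variants in patients (>= 1; ~2 in paper-like scenarios).
#' @param rare_maf_max reference-MAF ceiling defining "ultra-rare"
#'   (default 0.001, i.e. MAF <= 0.1\%).
#' @param genotype_error_rate per-site probability that a child's emitted
#'   genotype is corrupted (with an ambiguous likelihood triple, so trio
#'   refinement has signal to repair it).
#' @param n_homozygous_nonsense number of injected panel variants converted
#'   to a homozygous nonsense genotype (default 1, mirroring a complement
#'   C1q-deficiency case); only applied when injections exist.
#' @param rare_effect per-allele liability increment of an injected
#'   deleterious panel variant.
#' @param carrier_nephritis_rate probability of the renal ACR criterion in
#'   patients carrying a heterozygous injected panel variant (default 0;
#'   the cohort-wide rate is 0.38).
#' @param max_resample rejection-sampling cap per family before an error
#'   naming \code{liability_threshold} is raised.
#' @param seed master seed; all stage-level seeds derive from it via
#'   \code{\link{derive_seed}}.
#' @return a validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_families = 71,
                       n_controls = 500,
                       n_reference = 1000,
                       n_common_markers = 200,
                       common_maf_range = c(0.02, 0.5),
                       n_causal_markers = 40,
                       effect_size_sd = 0.33,
                       liability_threshold = 1.645,
                       environmental_sd = 0.58,
                       one_parent_fraction = 0.8,
                       panel_rare_rate_background = 0.14,
                       panel_enrichment_factor = 2.0,
                       rare_maf_max = 0.001,
                       genotype_error_rate = 0.001,
                       n_homozygous_nonsense = 1,
                       rare_effect = 0.5,
                       carrier_nephritis_rate = 0,
                       max_resample = 2000,
                       seed = 1) {
  cfg <- list(
    n_families = n_families, n_controls = n_controls,
    n_reference = n_reference, n_common_markers = n_common_markers,
    common_maf_range = common_maf_range,
    n_causal_markers = n_causal_markers, effect_size_sd = effect_size_sd,
    liability_threshold = liability_threshold,
    environmental_sd = environmental_sd,
    one_parent_fraction = one_parent_fraction,
    panel_rare_rate_background = panel_rare_rate_background,
    panel_enrichment_factor = panel_enrichment_factor,
    rare_maf_max = rare_maf_max,
    genotype_error_rate = genotype_error_rate,
    n_homozygous_nonsense = n_homozygous_nonsense,
    rare_effect = rare_effect,
    carrier_nephritis_rate = carrier_nephritis_rate,
    max_resample = max_resample, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  counts <- c("n_families", "n_controls", "n_reference", "n_common_markers",
              "n_causal_markers")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v != round(v)) {
      stop("sim_config: ", f, " must be a positive integer count", call. = FALSE)
    }
  }
  if (cfg$n_causal_markers > cfg$n_common_markers) {
    stop("sim_config: n_causal_markers cannot exceed n_common_markers",
         call. = FALSE)
  }
  r <- cfg$common_maf_range
  if (length(r) != 2 || any(r <= 0) || any(r > 0.5) || r[1] >= r[2]) {
    stop("sim_config: common_maf_range must be an increasing pair in (0, 0.5]",
         call. = FALSE)
  }
  if (cfg$rare_maf_max <= 0 || cfg$rare_maf_max >= min(r)) {
    stop("sim_config: need 0 < rare_maf_max < min(common_maf_range)",
         call. = FALSE)
  }
  if (cfg$panel_enrichment_factor < 1) {
    stop("sim_config: panel_enrichment_factor must be >= 1", call. = FALSE)
  }
  if (cfg$one_parent_fraction < 0 || cfg$one_parent_fraction > 1) {
    stop("sim_config: one_parent_fraction must lie in [0, 1]", call. = FALSE)
  }
  for (f in c("effect_size_sd", "environmental_sd")) {
    if (cfg[[f]] <= 0) stop("sim_config: ", f, " must be positive", call. = FALSE)
  }
  if (cfg$genotype_error_rate < 0 || cfg$genotype_error_rate >= 1) {
    stop("sim_config: genotype_error_rate must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$panel_rare_rate_background <= 0) {
    stop("sim_config: panel_rare_rate_background must be positive", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_families, "trio families,",
      x$n_reference, "reference genomes,",
      x$n_common_markers, "common markers (",
      x$n_causal_markers, "causal ),",
      "panel enrichment x", x$panel_enrichment_factor,
      ", seed", x$seed, "\n")
  invisible(x)
}
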