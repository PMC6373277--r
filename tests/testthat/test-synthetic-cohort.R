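test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_families = 0), "n_families")
  expect_error(sim_config(n_families = 2.5), "n_families")
  expect_error(sim_config(rare_maf_max = 0.1,
                          common_maf_range = c(0.05, 0.5)), "rare_maf_max")
  expect_error(sim_config(panel_enrichment_factor = 0.5), "enrichment")
  expect_error(sim_config(one_parent_fraction = 1.2), "one_parent_fraction")
  expect_error(sim_config(common_maf_range = c(0.5, 0.1)), "common_maf_range")
  expect_error(sim_config(n_causal_markers = 500, n_common_markers = 100),
               "n_causal_markers")
})

test_that("an unreachable liability threshold raises a named error", {
  cfg <- tiny_cfg(seed = 1, liability_threshold = 50, max_resample = 50)
  expect_error(simulate_cohort(cfg), "liability_threshold")
})

test_that("error-free cohorts are Mendelian-consistent at every site", {
  cfg <- tiny_cfg(seed = 2, genotype_error_rate = 0)
  co <- simulate_cohort(cfg)
  ok <- mendelian_consistent(as.vector(co$geno$child_obs),
                             as.vector(co$geno$mother),
                             as.vector(co$geno$father))
  expect_true(all(ok))
  # and the rare-variant trios are consistent too: every patient
  # observation has a carrier parent
  pat <- co$samples$sample_id[co$samples$role == "patient"]
  obs <- co$carriers[co$carriers$sample_id %in% pat, ]
  fam <- sub("_P$", "", obs$sample_id)
  key <- paste(co$carriers$variant_id, co$carriers$sample_id)
  has_m <- paste(obs$variant_id, paste0(fam, "_M")) %in% key
  has_f <- paste(obs$variant_id, paste0(fam, "_F")) %in% key
  expect_true(all(has_m | has_f))
  expect_true(all((obs$dosage == 2L) <= (has_m & has_f)))
})

test_that("every affected offspring's liability exceeds the threshold", {
  co <- tiny_cohort()
  pats <- paste0(co$samples$family_id[co$samples$role == "patient"], "")
  L <- co$truth$liabilities
  child_L <- L[grepl("_P$", names(L))]
  expect_true(all(child_L > co$config$liability_threshold))
})

test_that("common-marker MAF converges to the generating frequency", {
  # estimated across parents of a cohort with no designated high-burden
  # parents, where parental genotypes are draws from the population
  cfg <- sim_config(n_families = 400, n_controls = 50, n_reference = 50,
                    n_common_markers = 80, n_causal_markers = 20,
                    one_parent_fraction = 0, seed = 31)
  co <- simulate_cohort(cfg)
  dose <- rbind(co$geno$mother, co$geno$father)
  emp <- colMeans(dose) / 2
  se <- sqrt(co$markers$maf * (1 - co$markers$maf) / (2 * nrow(dose)))
  z <- (emp - co$markers$maf) / se
  # non-causal markers are unbiased draws from the population
  neutral <- !co$markers$causal
  expect_lt(mean(abs(z[neutral]) > 3), 0.02)
  # causal risk alleles are ascertained upward in parents of affected
  # children: deviations exist but stay one-directional and bounded
  expect_gte(mean(z[co$markers$causal] >= -3), 1)
  expect_lt(max(abs(emp - co$markers$maf)), 0.08)
})

test_that("injected panel variants sit where the truth ledger says", {
  co <- tiny_cohort()
  inj <- co$truth$injected_panel_variants
  skip_if(is.null(inj), "no injections drawn in fixture")
  key <- paste(co$carriers$variant_id, co$carriers$sample_id)
  expect_true(all(paste(inj$variant_id, inj$transmitting_parent) %in% key))
  v <- co$variants[match(inj$variant_id, co$variants$variant_id), ]
  expect_true(all(v$injected))
  expect_true(all(v$dann >= 0.9 | v$class == "nonsense"))
  expect_true(all(v$ref_maf == 0))
})

test_that("patient panel variant load recovers background x enrichment", {
  tot <- 0; n <- 0
  for (s in 1:3) {
    cfg <- sim_config(n_families = 150, n_controls = 50, n_reference = 50,
                      n_common_markers = 40, n_causal_markers = 10,
                      panel_enrichment_factor = 2, seed = 200 + s)
    co <- simulate_cohort(cfg)
    ann <- co$annotations
    ultra <- ann$variant_id[ann$class %in% c("missense", "nonsense") &
                              ann$ref_maf <= 0.001 &
                              variant_in_panel(ann$chrom, ann$pos,
                                               co$panel, "coding")]
    pat <- co$samples$sample_id[co$samples$role == "patient"]
    obs <- co$carriers[co$carriers$sample_id %in% pat &
                         co$carriers$variant_id %in% ultra, ]
    tot <- tot + nrow(obs); n <- n + length(pat)
  }
  rate <- tot / n
  want <- 0.14 * 2
  se <- sqrt(want / n)
  expect_lt(abs(rate - want), 3.5 * se)
})

test_that("annotations label promoter hits and unknown classes", {
  co <- tiny_cohort()
  panel <- co$panel
  v <- data.frame(variant_id = c("x1", "x2"),
                  chrom = c("chrS1", "chrZZ"),
                  pos = c(11000L, 500L), ref = "A", alt = "C",
                  class = c("missense", NA), ref_maf = 0,
                  dann = 0.5, sift = 0.5, polyphen = 0.5)
  ann <- emit_annotations(v, panel)
  expect_equal(ann$class, c("promoter", "other"))

  # cohort-level: anything inside a promoter interval is labelled promoter
  in_prom <- variant_in_panel(co$annotations$chrom, co$annotations$pos,
                              panel, "promoter")
  expect_true(all(co$annotations$class[in_prom] == "promoter"))
})

test_that("silent panel variants exist but are excluded from non-silent counting", {
  co <- tiny_cohort()
  expect_gt(sum(co$annotations$class == "silent"), 0)
  pat <- co$samples$sample_id[co$samples$role == "patient"]
  obs <- co$carriers[co$carriers$sample_id %in% pat, ]
  st <- count_stratum(co$annotations, obs, tiny_reference(), co$panel,
                      "non_silent_coding", maf_bin_labels()[1],
                      length(pat))
  keep <- co$annotations$class %in% c("missense", "nonsense") &
    co$annotations$ref_maf <= 0.001
  manual <- sum(obs$variant_id %in% co$annotations$variant_id[keep])
  expect_equal(st$case_panel + st$case_background, manual)
})

test_that("the reference table does diploid bookkeeping and deflation", {
  ref <- tiny_reference()
  expect_true(all(ref$an == 2 * tiny_cfg()$n_reference))
  expect_true(all(ref$ac >= ref$n_carrier))
  expect_true(all(ref$ac <= 2 * ref$n_carrier))
  # deflation thins private observations: totals drop roughly by the factor
  ref80 <- simulate_reference(tiny_cfg(), deflation = 0.8)
  priv <- function(r) sum(r$n_carrier[grepl("^rv", r$variant_id)])
  expect_lt(priv(ref80), priv(ref))
})

test_that("cohort generation is reproducible from the master seed", {
  cfg <- tiny_cfg(seed = 77)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$geno$child_obs, b$geno$child_obs)
  expect_identical(a$variants, b$variants)
  expect_identical(a$truth$liabilities, b$truth$liabilities)
})
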