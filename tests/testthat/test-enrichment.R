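test_that("MAF binning conventions", {
  expect_equal(as.character(classify_maf_bin(0.0005)), "(0,0.001]")
  expect_equal(as.character(classify_maf_bin(0.001)), "(0,0.001]")
  expect_equal(as.character(classify_maf_bin(0)), "(0,0.001]")
  expect_equal(as.character(classify_maf_bin(0.0011)), "(0.001,0.01]")
  expect_equal(as.character(classify_maf_bin(0.5)), "(0.05,0.5]")
  expect_error(classify_maf_bin(0.6), "not a minor allele frequency")
})

stratum <- function(a, b, c, d, N = 71, Nr = 1000,
                    cg = "non_silent_coding", bin = "(0,0.001]") {
  structure(data.frame(class_group = cg, maf_bin = bin, case_panel = a,
                       case_background = b, ref_panel = c,
                       ref_background = d, n_case_genomes = N,
                       n_ref_genomes = Nr),
            class = c("stratum_counts", "data.frame"))
}

test_that("stratum counting on constructed cohorts", {
  co <- tiny_cohort()
  ref <- tiny_reference()
  pat <- co$samples$sample_id[co$samples$role == "patient"]

  # an empty case cohort counts zero observations everywhere
  none <- co$carriers[0, ]
  st <- count_stratum(co$annotations, none, ref, co$panel,
                      "non_silent_coding", "(0,0.001]", length(pat))
  expect_equal(st$case_panel + st$case_background, 0)

  # one heterozygous carrier of one panel missense variant
  pv <- co$variants[co$variants$injected & co$variants$class == "missense", ]
  skip_if(nrow(pv) == 0, "fixture drew no injected missense")
  one <- data.frame(variant_id = pv$variant_id[1],
                    sample_id = pat[1], dosage = 1L)
  st <- count_stratum(co$annotations, one, ref, co$panel,
                      "non_silent_coding", "(0,0.001]", length(pat))
  expect_equal(st$case_panel, 1)
  expect_equal(st$case_background, 0)

  # a patient with two distinct panel variants contributes two observations
  two <- rbind(one, data.frame(variant_id = pv$variant_id[
    min(2, nrow(pv))], sample_id = pat[1], dosage = 1L))
  two <- unique(two)
  st2 <- count_stratum(co$annotations, two, ref, co$panel,
                       "non_silent_coding", "(0,0.001]", length(pat))
  expect_equal(st2$case_panel, nrow(two))

  # allele mode counts a homozygote twice, carrier mode once
  hom <- data.frame(variant_id = pv$variant_id[1], sample_id = pat[1],
                    dosage = 2L)
  expect_equal(count_stratum(co$annotations, hom, ref, co$panel,
                             "non_silent_coding", "(0,0.001]",
                             length(pat))$case_panel, 1)
  expect_equal(count_stratum(co$annotations, hom, ref, co$panel,
                             "non_silent_coding", "(0,0.001]", length(pat),
                             count_mode = "allele")$case_panel, 2)

  # LOWGP-flagged sites are excluded under the default policy
  st3 <- count_stratum(co$annotations, one, ref, co$panel,
                       "non_silent_coding", "(0,0.001]", length(pat),
                       flagged = pv$variant_id[1])
  expect_equal(st3$case_panel, 0)
})

test_that("normalisation factor is a per-genome background rate ratio", {
  expect_equal(normalization_factor(stratum(5, 100, 50, 1000, N = 100,
                                            Nr = 1000)), 1)
  # invariant to duplicating every reference sample
  f1 <- normalization_factor(stratum(5, 120, 50, 1000, N = 100, Nr = 1000))
  f2 <- normalization_factor(stratum(5, 120, 100, 2000, N = 100, Nr = 2000))
  expect_equal(f1, f2)
  # a 0.8 calling deflation of the reference inflates the factor to 1.25
  expect_equal(normalization_factor(stratum(5, 100, 40, 800, N = 100,
                                            Nr = 1000)), 1.25)
  expect_message(
    expect_true(is.na(normalization_factor(stratum(5, 100, 5, 0)))),
    "untestable")
})

test_that("enrichment test: identity, monotonicity, signs", {
  # identical per-genome rates: OR 1, p 1
  r <- enrichment_test(stratum(10, 990, 10, 990, N = 100, Nr = 100))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  expect_equal(r$signed_log_p, 0)

  # increasing the case panel count never decreases the OR
  ors <- sapply(0:30, function(a) {
    enrichment_test(stratum(a, 1000, 10, 1000, N = 100, Nr = 100))$odds_ratio
  })
  expect_true(all(diff(ors) >= 0))

  # depletion carries a negative signed log p; enrichment a positive one
  lo <- enrichment_test(stratum(2, 1000, 20, 1000, N = 100, Nr = 100))
  hi <- enrichment_test(stratum(40, 1000, 20, 1000, N = 100, Nr = 100))
  expect_lt(lo$signed_log_p, 0)
  expect_gt(hi$signed_log_p, 0)
  expect_equal(sign(lo$odds_ratio - 1), -1)

  # swapping the case and reference roles inverts the OR
  sw <- enrichment_test(stratum(20, 1000, 40, 1000, N = 100, Nr = 100))
  expect_equal(sw$odds_ratio, 1 / hi$odds_ratio, tolerance = 1e-12)
  expect_equal(sw$p_value, hi$p_value, tolerance = 1e-9)
  expect_equal(sw$signed_log_p, -hi$signed_log_p, tolerance = 1e-9)

  # an untestable stratum is reported as such
  u <- enrichment_test(stratum(5, 100, 0, 0))
  expect_false(u$testable)
  expect_true(is.na(u$p_value))
})

test_that("Bonferroni correction across strata", {
  one <- enrichment_test(stratum(10, 990, 10, 990, N = 100, Nr = 100))
  expect_equal(correct_multiple_testing(one)$corrected_alpha, 0.05)

  eight <- do.call(rbind, lapply(1:8, function(i) {
    enrichment_test(stratum(10 + i, 990, 10, 990, N = 100, Nr = 100))
  }))
  cm <- correct_multiple_testing(eight)
  expect_equal(unique(cm$corrected_alpha), 0.00625)
  expect_identical(cm$significant, cm$p_value <= cm$corrected_alpha)
  # a p of 0.00182 stays significant for any m <= 27
  expect_true(0.00182 <= 0.05 / 27)
})

test_that("excess-variant arithmetic", {
  ex <- excess_variants(21, 2.07)
  expect_equal(round(ex$excess, 1), 10.9)
  expect_equal(ex$expected, 21 / 2.07)
  expect_equal(excess_variants(21, 1)$excess, 0)
  expect_equal(excess_variants(0, 2)$excess, 0)
  expect_error(excess_variants(21, 0), "positive odds ratio")
  expect_equal(patients_per_event(71, 8), 9L)
  expect_equal(patients_per_event(71, 10.9), 7L)
})

test_that("full-cohort analysis recovers the generator's enrichment", {
  co <- fixture("enrich_cohort", function() {
    simulate_cohort(sim_config(n_families = 200, n_controls = 50,
                               n_reference = 600, n_common_markers = 40,
                               n_causal_markers = 10,
                               panel_enrichment_factor = 2, seed = 88))
  })
  ref <- fixture("enrich_ref", function() {
    simulate_reference(sim_config(n_families = 200, n_controls = 50,
                                  n_reference = 600, n_common_markers = 40,
                                  n_causal_markers = 10,
                                  panel_enrichment_factor = 2, seed = 88))
  })
  res <- panel_enrichment_analysis(co, ref)
  expect_equal(nrow(res), 8)
  ultra <- res[res$class_group == "non_silent_coding" &
                 res$maf_bin == "(0,0.001]", ]
  expect_true(ultra$testable)
  expect_gt(ultra$odds_ratio, 1.3)
  expect_lt(ultra$odds_ratio, 3.2)
  # non-enriched strata stay near 1
  others <- res[res$testable & !(res$class_group == "non_silent_coding" &
                                   res$maf_bin == "(0,0.001]"), ]
  expect_true(all(others$odds_ratio > 0.4 & others$odds_ratio < 2.5))
})
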