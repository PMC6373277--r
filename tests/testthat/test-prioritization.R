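test_that("deleteriousness calls follow the predictor conventions", {
  co <- tiny_cohort()
  # graft three synthetic annotation rows onto the cohort: one clearly
  # damaging by all predictors, one benign-by-scores, one silent
  panel_pos <- GenomicRanges::start(co$panel[co$panel$feature == "coding"])[1]
  panel_chr <- as.character(
    GenomicRanges::seqnames(co$panel[co$panel$feature == "coding"]))[1]
  extra <- data.frame(
    variant_id = c("t_dmg", "t_ben", "t_sil"),
    chrom = panel_chr, pos = panel_pos + 0:2, ref = "G", alt = "A",
    gene = co$panel$gene[co$panel$feature == "coding"][1],
    class = c("missense", "missense", "silent"), ref_maf = 0,
    dann = c(0.999, 0.362, 0.999), sift = c(0.0, 0.699, 0.0),
    polyphen = c(1.0, 0.001, 1.0), injected = FALSE)
  pat <- co$samples$sample_id[co$samples$role == "patient"][1:3]
  co$variants <- rbind(co$variants, extra)
  co$carriers <- rbind(co$carriers, data.frame(
    variant_id = extra$variant_id, sample_id = pat, dosage = 1L))
  co$annotations <- emit_annotations(co$variants, co$panel)

  cand <- filter_candidates(co)
  expect_true("t_dmg" %in% cand$variant_id)
  expect_equal(cand$damaging_call[cand$variant_id == "t_dmg"],
               "score_damaging")
  # benign-by-scores is dropped without an evidence note...
  expect_false("t_ben" %in% cand$variant_id)
  # ...but retained as other_evidence with one
  cand2 <- filter_candidates(co, evidence_notes = c(
    t_ben = "structurally adjacent to known disease mutations"))
  expect_equal(cand2$damaging_call[cand2$variant_id == "t_ben"],
               "other_evidence")
  # the silent variant never passes, whatever its scores
  expect_false("t_sil" %in% cand2$variant_id)
})

test_that("nonsense variants are always score_damaging, missing scores logged", {
  co <- tiny_cohort()
  inj <- co$variants[co$variants$injected, ]
  skip_if(nrow(inj) == 0, "fixture drew no injections")
  cand <- filter_candidates(co)
  # every injected deleterious panel variant is recovered (sensitivity 1)
  expect_true(all(inj$variant_id %in% cand$variant_id))
  non <- cand[cand$variant_id %in%
                inj$variant_id[inj$class == "nonsense"], ]
  if (nrow(non)) expect_true(all(non$damaging_call == "score_damaging"))
})

test_that("candidate counts shrink as thresholds tighten", {
  co <- tiny_cohort()
  base <- nrow(filter_candidates(co))
  stricter <- nrow(filter_candidates(co, sift_max = 0.01,
                                     polyphen_min = 0.99, dann_min = 0.999))
  loose <- nrow(filter_candidates(co, sift_max = 0.2, polyphen_min = 0.5,
                                  dann_min = 0.8))
  expect_lte(stricter, base)
  expect_gte(loose, base)
  tighter_maf <- nrow(filter_candidates(co, maf_max = 0))
  expect_lte(tighter_maf, base)
})

test_that("zygosity summary reflects the injected homozygote", {
  expect_equal(zygosity_summary(filter_candidates(tiny_cohort())[0, ]),
               list(n_het = 0L, n_hom = 0L, n_patients = 0L,
                    n_variants = 0L))
  # a larger cohort reliably carries the single injected homozygous
  # nonsense among otherwise heterozygous candidates
  co <- fixture("zyg_cohort", function() {
    simulate_cohort(sim_config(n_families = 120, n_controls = 50,
                               n_reference = 50, n_common_markers = 40,
                               n_causal_markers = 10, seed = 99))
  })
  cand <- filter_candidates(co)
  zs <- zygosity_summary(cand)
  expect_equal(zs$n_hom, 1L)
  expect_equal(zs$n_het, zs$n_variants - 1L)
  expect_lte(zs$n_patients, zs$n_variants)
  # every injected variant is a candidate; naturally arising nonsense
  # variants may legitimately join them
  inj <- co$truth$injected_panel_variants
  expect_true(all(inj$variant_id %in% cand$variant_id))
  expect_gte(zs$n_variants, nrow(inj))
  # candidate report carries parent-of-origin calls for het candidates
  expect_true(all(cand$parent_of_origin[cand$zygosity == "het"] %in%
                    c("maternal", "paternal")))
})

test_that("risk scores are attached to carrier patients when provided", {
  co <- tiny_cohort()
  sc <- cohort_risk_scores(tiny_model(), co)
  cand <- filter_candidates(co, scores = sc)
  skip_if(nrow(cand) == 0, "no candidates in fixture")
  expect_true(all(!is.na(cand$risk_score)))
  expect_equal(cand$risk_score,
               sc$score[match(cand$carrier_sample, sc$sample_id)])
})
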