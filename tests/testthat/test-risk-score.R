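make_sep_data <- function(n = 120, p = 8, seed = 3) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 2, 0.3), n, p,
              dimnames = list(sprintf("s%03d", 1:n), paste0("m", 1:p)))
  y <- as.integer(X[, 1] >= 1)  # one fully predictive marker
  list(X = X, y = y)
}

test_that("degenerate single-class labels refuse to train", {
  d <- make_sep_data()
  expect_error(train_risk_model(d$X, rep(1, nrow(d$X))), "degenerate")
})

test_that("a fully predictive marker yields a wide training score gap", {
  d <- make_sep_data()
  m <- train_risk_model(d$X, d$y, ntree = 100, seed = 5)
  sc <- score_samples(m, d$X)
  gap <- mean(sc$score[d$y == 1]) - mean(sc$score[d$y == 0])
  expect_gte(gap, 50)
})

test_that("training and scoring are deterministic given the seed", {
  d <- make_sep_data()
  m1 <- train_risk_model(d$X, d$y, ntree = 60, seed = 11)
  m2 <- train_risk_model(d$X, d$y, ntree = 60, seed = 11)
  s1 <- score_samples(m1, d$X)
  s2 <- score_samples(m2, d$X)
  expect_identical(s1$score, s2$score)
  # scoring the same sample twice gives the identical score
  s3 <- score_samples(m1, d$X[c(1, 1), ])
  expect_identical(s3$score[1], s3$score[2])
})

test_that("scoring handles empty input, imputation and overlap failures", {
  d <- make_sep_data()
  m <- train_risk_model(d$X, d$y, ntree = 50, seed = 2)
  expect_equal(nrow(score_samples(m, d$X[0, ])), 0)

  # dropping one of eight markers (87.5% overlap) falls below the default
  expect_error(score_samples(m, d$X[, -1]), "overlap")
  sc <- score_samples(m, d$X[, -1], min_overlap = 0.8)
  expect_true(all(sc$n_imputed == 1))

  # per-sample NAs are imputed and counted; an all-missing sample errors
  Xna <- d$X
  Xna[1, 1:3] <- NA
  sc <- score_samples(m, Xna)
  expect_equal(sc$n_imputed[1], 3L)
  Xna[2, ] <- NA
  expect_error(score_samples(m, Xna), "no observed genotypes")
})

test_that("parents partition into higher/lower with deterministic ties", {
  scores <- data.frame(
    sample_id = c("F1_P", "F1_M", "F1_F", "F2_P", "F2_M", "F2_F"),
    family_id = rep(c("F1", "F2"), each = 3),
    role = rep(c("patient", "mother", "father"), 2),
    score = c(50, 40, 20, 50, 30, 30))
  pp <- partition_parents(scores)
  expect_equal(pp$higher_id, c("F1_M", "F2_F"))
  expect_equal(pp$lower_id, c("F1_F", "F2_M"))
  expect_identical(pp$tie, c(FALSE, TRUE))

  scores$score[2] <- NA
  expect_warning(pp2 <- partition_parents(scores), "F1")
  expect_equal(pp2$family_id, "F2")
})

test_that("correlation report matches a direct-formula oracle", {
  expect_equal(triorare:::pearson_pair(1:5, 1:5, "x")$r, 1)
  expect_equal(triorare:::pearson_pair(c(1, 2, 3), c(3, 2, 1), "x")$r, -1)
  expect_match(triorare:::pearson_pair(c(1, 1, 1), c(1, 2, 3), "x")$note,
               "zero variance")
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.3 * x
    got <- triorare:::pearson_pair(x, y, "pair")
    want <- oracle_pearson(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
    expect_equal(got$r_squared, want$r^2, tolerance = 1e-12)
  }
})

test_that("cohort scores recover the designated high-burden parent", {
  co <- tiny_cohort()
  sc <- cohort_risk_scores(tiny_model(), co)
  expect_true(all(sc$score >= 0 & sc$score <= 100))
  expect_setequal(unique(sc$role),
                  c("patient", "mother", "father", "control"))
  pp <- partition_parents(sc)
  expect_true(all(pp$higher_score >= pp$lower_score))
  cr <- correlation_report(sc, pp)
  expect_equal(nrow(cr$correlations), 2)
  expect_equal(cr$group_means$n[1], co$config$n_families)
  # patients should outscore controls even in a small cohort
  gm <- setNames(cr$group_means$mean_score, cr$group_means$group)
  expect_gt(gm["patients"], gm["controls"])
})

test_that("no polygenic signal means no cross-family score correlation", {
  # any genotype-based score correlates between true parent-offspring
  # pairs through allele sharing, signal or not; the meaningful null is a
  # permuted pairing, where correlations must vanish
  rs <- sapply(1:3, function(s) {
    cfg <- sim_config(n_families = 60, n_controls = 80, n_reference = 50,
                      n_common_markers = 60, n_causal_markers = 15,
                      effect_size_sd = 1e-6, environmental_sd = 1,
                      one_parent_fraction = 0, seed = 400 + s)
    co <- simulate_cohort(cfg)
    m <- train_risk_model(common_genotypes(co, c("control_training",
                                                 "case_training")),
                          rep(0:1, each = 80), ntree = 120,
                          seed = derive_seed(s, "null_rf"))
    sc <- cohort_risk_scores(m, co)
    pp <- partition_parents(sc)
    pat_sc <- sc[sc$role == "patient", ]
    pat <- pat_sc$score[match(pp$family_id, pat_sc$family_id)]
    set.seed(derive_seed(s, "perm"))
    perm <- sample(length(pat))
    c(abs(cor(pat[perm], pp$higher_score)),
      abs(cor(pat[perm], pp$lower_score)))
  })
  expect_lt(mean(rs), 2 / sqrt(60))
})

test_that("mother and father mean scores do not differ systematically", {
  ps <- sapply(1:6, function(s) {
    cfg <- tiny_cfg(seed = 500 + s, n_families = 30)
    co <- simulate_cohort(cfg)
    m <- train_risk_model(common_genotypes(co, c("control_training",
                                                 "case_training")),
                          rep(0:1, each = 80), ntree = 120,
                          seed = derive_seed(s, "mf_rf"))
    sc <- cohort_risk_scores(m, co)
    stats::t.test(sc$score[sc$role == "mother"],
                  sc$score[sc$role == "father"])$p.value
  })
  expect_gte(sum(ps > 0.05), 5)
})
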