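test_that("exactly 15 of the 27 trio genotype combinations are consistent", {
  combos <- expand.grid(child = 0:2, mother = 0:2, father = 0:2)
  got <- mendelian_consistent(combos$child, combos$mother, combos$father)
  want <- mapply(oracle_mendel, combos$child, combos$mother, combos$father)
  expect_identical(got, unname(want))
  expect_identical(sum(got), 15L)

  # spot checks
  expect_false(mendelian_consistent(trio_genotype("het", "hom_ref", "hom_ref")))
  expect_true(mendelian_consistent(trio_genotype("het", "het", "hom_ref")))
})

test_that("missing genotypes are indeterminate, never silently consistent", {
  expect_true(is.na(mendelian_consistent(NA, 1, 1)))
  expect_true(is.na(mendelian_consistent(1, NA, 1)))
  tg <- trio_genotype("het", "missing", "hom_alt")
  expect_true(is.na(mendelian_consistent(tg)))
})

test_that("parent of origin covers the enumerated domain", {
  expect_equal(parent_of_origin(1, 1, 0), "maternal")
  expect_equal(parent_of_origin(1, 0, 1), "paternal")
  expect_equal(parent_of_origin(1, 1, 1), "ambiguous")
  expect_equal(parent_of_origin(1, 0, 0), "de_novo")
  expect_equal(parent_of_origin(1, NA, 1), "indeterminate")
  expect_equal(parent_of_origin(2, 1, 1), "ambiguous")
  expect_equal(parent_of_origin(2, 0, 1), "de_novo")
  expect_equal(parent_of_origin(0, 1, 1), "indeterminate")
})

test_that("ambiguity fraction on a cohort matches enumeration from truth", {
  co <- tiny_cohort()
  # rare variants: child het, exactly one carrier parent by construction,
  # so no rare call can be ambiguous or de novo
  pat <- co$samples$sample_id[co$samples$role == "patient"]
  obs <- co$carriers[co$carriers$sample_id %in% pat, ]
  fam <- sub("_P$", "", obs$sample_id)
  car <- co$carriers
  d_of <- function(ids) {
    d <- car$dosage[match(paste(obs$variant_id, ids),
                          paste(car$variant_id, car$sample_id))]
    ifelse(is.na(d), 0L, d)
  }
  poo <- parent_of_origin(obs$dosage, d_of(paste0(fam, "_M")),
                          d_of(paste0(fam, "_F")))
  het <- obs$dosage == 1L
  expect_true(all(poo[het] %in% c("maternal", "paternal")))
  expect_true(all(poo[!het] == "ambiguous"))
})

test_that("refinement reproduces the hand-computed Bayes posterior", {
  # flat likelihoods, both parents hom_ref: the call is hom_ref with
  # posterior 1 - O(eps), unflagged
  pc <- refine_genotype(trio_genotype(1, 0, 0, child_pl = c(0, 0, 0)),
                        epsilon = 1e-8)
  expect_equal(pc$genotype, "hom_ref")
  expect_gt(pc$posterior[1], 1 - 1e-7)
  expect_false(pc$low_quality_flag)
  expect_equal(sum(pc$posterior), 1, tolerance = 1e-12)

  # PL favouring het with hom_ref x het parents: het retained, posterior
  # matching the closed-form oracle
  pl <- c(40, 0, 40)
  pc <- refine_genotype(trio_genotype(1, 0, 1, child_pl = pl),
                        epsilon = 1e-8)
  expect_equal(pc$genotype, "het")
  expect_equal(pc$posterior, oracle_refine_posterior(pl, 0, 1, 1e-8),
               tolerance = 1e-12)
})

test_that("refinement equals the enumeration oracle across a PL grid", {
  pls <- list(c(0, 0, 0), c(0, 10, 20), c(20, 0, 10), c(50, 20, 0),
              c(0, 5, 60), c(30, 0, 30), c(60, 30, 0), c(6, 0, 40))
  eps <- 1e-6
  for (gm in 0:2) for (gf in 0:2) for (pl in pls) {
    pc <- refine_genotype(trio_genotype(1, gm, gf, child_pl = pl),
                          epsilon = eps)
    want <- oracle_refine_posterior(pl, gm, gf, eps)
    expect_lt(max(abs(pc$posterior - want)), 1e-9)
    expect_equal(sum(pc$posterior), 1, tolerance = 1e-12)
  }
})

test_that("with a vanishing de novo leak the refined call is Mendelian-consistent", {
  set.seed(5)
  for (i in 1:100) {
    gm <- sample(0:2, 1); gf <- sample(0:2, 1)
    pl <- sample(0:60, 3); pl <- pl - min(pl)
    pc <- refine_genotype(trio_genotype(1, gm, gf, child_pl = pl),
                          epsilon = 1e-12)
    expect_true(mendelian_consistent(pc$dosage, gm, gf))
  }
})

test_that("Q20 flagging is strict: the boundary posterior passes", {
  expect_equal(phred_from_posterior(0.99), 20)
  expect_false(is_low_quality(phred_from_posterior(0.99)))
  expect_true(is_low_quality(phred_from_posterior(0.9899)))
})

test_that("missing parents fall back to the Hardy-Weinberg prior", {
  tg <- trio_genotype(1, NA, 1, child_pl = c(0, 0, 0))
  expect_error(refine_genotype(tg), "population_af")
  pc <- refine_genotype(tg, population_af = 0.2)
  expect_equal(pc$prior_source, "population")
  expect_equal(pc$posterior, c(0.64, 0.32, 0.04), tolerance = 1e-12)
})

test_that("vectorised cohort refinement agrees with the scalar operation", {
  co <- tiny_cohort()
  ref <- refine_trios(co, epsilon = 1e-8)
  set.seed(31)
  fams <- sample(nrow(co$geno$mother), 6)
  mks <- sample(ncol(co$geno$mother), 8)
  for (i in fams) for (j in mks) {
    pc <- refine_genotype(
      trio_genotype(co$geno$child_obs[i, j], co$geno$mother[i, j],
                    co$geno$father[i, j],
                    child_pl = co$geno$child_pl[i, j, ]),
      epsilon = 1e-8)
    expect_equal(ref$dosage[i, j], pc$dosage)
    expect_equal(ref$phred[i, j], pc$posterior_phred, tolerance = 1e-9)
  }
})

test_that("refinement repairs most injected genotype errors", {
  cfg <- tiny_cfg(seed = 9, genotype_error_rate = 0.02,
                  n_families = 25)
  co <- simulate_cohort(cfg)
  before <- mean(co$geno$child_obs != co$geno$child_true)
  ref <- refine_trios(co)
  after <- mean(ref$dosage != co$geno$child_true)
  expect_gt(before, 0)
  expect_lt(after, before / 2)
})
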