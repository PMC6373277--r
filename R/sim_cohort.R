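# Synthetic trio-cohort generator.
#
# The generator states a scaled-down genomic world: a common-marker panel
# carrying an additive liability signal, a 22-gene monogenic-SLE panel in
# which ultra-rare deleterious variants are injected into patients at
# background * enrichment rate, and a genome-wide "background" variant
# space represented at per-genome rates rather than full genomic realism.
# All per-stratum rates below are observations (variant x carrier) per
# genome and are deliberately fixed constants of the stated world.

.maf_bin_default_edges <- c(0, 0.001, 0.01, 0.05, 0.5)

# elevation of the designated high-burden parent (see draw_parent in
# simulate_cohort): mean tilt and between-family heterogeneity, chosen so
# that designated parents score like patients while non-designated
# parents score like population controls
.designated_tilt <- list(theta0 = 2.5, tau = 1.25)

# causal markers are sampled from panel markers at or below this MAF
.causal_maf_max <- 0.15

.acr_criteria <- c("malar_rash", "discoid_rash", "photosensitivity",
                   "oral_ulcers", "arthritis", "serositis", "renal",
                   "neurologic", "hematologic", "immunologic", "ana")
.acr_rates <- c(0.55, 0.15, 0.45, 0.30, 0.75, 0.30, 0.38, 0.08, 0.55,
                0.70, 0.95)

# per-genome observation rates by (class group x MAF bin); bin 1 variants
# are private to their cohort, bins 2-4 come from a shared segregating-site
# pool.  Panel rates for bins 2-4 are ~1% of background, panel bin 1 for
# the non-silent group is the configurable panel_rare_rate_background.
.stratum_rate_table <- function(cfg) {
  labs <- maf_bin_labels(.maf_bin_default_edges)
  data.frame(
    class_group = rep(c("non_silent_coding", "promoter"), each = 4),
    maf_bin = rep(labs, 2),
    bin_index = rep(1:4, 2),
    background = c(30, 25, 20, 25, 8, 7, 6, 8),
    panel = c(cfg$panel_rare_rate_background, 0.30, 0.25, 0.30,
              0.05, 0.08, 0.07, 0.08),
    stringsAsFactors = FALSE)
}

.rand_ref_alt <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  list(ref = ref, alt = unname(alt))
}

# uniform positions inside panel intervals of the requested feature;
# returns chrom/pos/gene
.panel_positions <- function(n, panel, feature) {
  sub <- panel[panel$feature == feature]
  k <- sample(length(sub), n, replace = TRUE,
              prob = GenomicRanges::width(sub))
  pos <- GenomicRanges::start(sub)[k] +
    floor(runif(n) * GenomicRanges::width(sub)[k])
  list(chrom = as.character(GenomicRanges::seqnames(sub))[k], pos = pos,
       gene = sub$gene[k])
}

.background_positions <- function(n, promoter = FALSE) {
  contigs <- if (promoter) paste0("chrSBp", 1:4) else paste0("chrSB", 1:8)
  list(chrom = sample(contigs, n, replace = TRUE),
       pos = 1L + floor(runif(n) * 1e7), gene = rep(NA_character_, n))
}

# Deterministic (per config seed) table of shared segregating sites for the
# non-private MAF bins, used identically by the case cohort and the
# reference cohort so that both sample from the same site space.
shared_site_table <- function(cfg, panel) {
  set.seed(derive_seed(cfg$seed, "shared_sites"))
  rt <- .stratum_rate_table(cfg)
  edges <- .maf_bin_default_edges
  out <- list()
  counter <- 0L
  for (i in seq_len(nrow(rt))) {
    if (rt$bin_index[i] == 1) next
    lo <- edges[rt$bin_index[i]]
    hi <- edges[rt$bin_index[i] + 1]
    for (loc in c("panel", "background")) {
      rate <- rt[[loc]][i]
      mean_maf <- (lo + hi) / 2
      n_sites <- max(3L, ceiling(rate / (2 * mean_maf)))
      maf <- runif(n_sites, lo, hi)
      is_prom <- rt$class_group[i] == "promoter"
      posn <- if (loc == "panel") {
        .panel_positions(n_sites, panel, if (is_prom) "promoter" else "coding")
      } else {
        .background_positions(n_sites, promoter = is_prom)
      }
      cls <- if (is_prom) {
        rep("promoter", n_sites)
      } else {
        sample(c("missense", "nonsense"), n_sites, replace = TRUE,
               prob = c(0.95, 0.05))
      }
      ra <- .rand_ref_alt(n_sites)
      out[[length(out) + 1L]] <- data.frame(
        variant_id = sprintf("sv%06d", counter + seq_len(n_sites)),
        chrom = posn$chrom, pos = posn$pos, ref = ra$ref, alt = ra$alt,
        gene = posn$gene, class = cls, ref_maf = maf,
        class_group = rt$class_group[i], bin_index = rt$bin_index[i],
        in_panel = loc == "panel", stringsAsFactors = FALSE)
      counter <- counter + n_sites
    }
  }
  do.call(rbind, out)
}

# Poisson-multinomial sampling of shared-site observations for one cohort:
# each genome draws Pois(sum 2*maf) observations assigned to sites with
# probability proportional to maf; carriers are homozygous with the
# conditional probability maf / (2 - maf).
.sample_shared_obs <- function(sites, sample_ids) {
  if (nrow(sites) == 0 || length(sample_ids) == 0) {
    return(data.frame(variant_id = character(), sample_id = character(),
                      dosage = integer(), stringsAsFactors = FALSE))
  }
  lambda <- sum(2 * sites$ref_maf)
  counts <- rpois(length(sample_ids), lambda)
  tot <- sum(counts)
  if (tot == 0) {
    return(data.frame(variant_id = character(), sample_id = character(),
                      dosage = integer(), stringsAsFactors = FALSE))
  }
  site <- sample.int(nrow(sites), tot, replace = TRUE, prob = sites$ref_maf)
  obs <- data.frame(variant_id = sites$variant_id[site],
                    sample_id = rep(sample_ids, counts),
                    stringsAsFactors = FALSE)
  p_hom <- sites$ref_maf[site] / (2 - sites$ref_maf[site])
  obs$dosage <- 1L + rbinom(tot, 1L, p_hom)
  # a genome cannot observe the same site twice
  obs <- obs[!duplicated(obs[c("variant_id", "sample_id")]), ]
  rownames(obs) <- NULL
  obs
}

# Private (cohort-specific) ultra-rare variants: one new variant record per
# observation, heterozygous, absent from the reference population.
.sample_private_obs <- function(rate, sample_ids, id_prefix, id_offset,
                                panel, location = c("background_coding",
                                                    "background_promoter",
                                                    "panel_coding",
                                                    "panel_promoter"),
                                classes, class_probs, scores = "benign") {
  location <- match.arg(location)
  counts <- rpois(length(sample_ids), rate)
  n <- sum(counts)
  empty <- list(variants = data.frame(), carriers = data.frame())
  if (n == 0) return(empty)
  posn <- switch(location,
    background_coding = .background_positions(n, promoter = FALSE),
    background_promoter = .background_positions(n, promoter = TRUE),
    panel_coding = .panel_positions(n, panel, "coding"),
    panel_promoter = .panel_positions(n, panel, "promoter"))
  cls <- if (length(classes) == 1) rep(classes, n) else {
    sample(classes, n, replace = TRUE, prob = class_probs)
  }
  ra <- .rand_ref_alt(n)
  sc <- if (scores == "benign") {
    data.frame(dann = runif(n, 0, 0.9), sift = runif(n, 0.06, 1),
               polyphen = runif(n, 0, 0.8))
  } else { # damaging by construction
    data.frame(dann = runif(n, 0.96, 1), sift = runif(n, 0, 0.045),
               polyphen = runif(n, 0.85, 1))
  }
  variants <- data.frame(
    variant_id = sprintf("%s%06d", id_prefix, id_offset + seq_len(n)),
    chrom = posn$chrom, pos = posn$pos, ref = ra$ref, alt = ra$alt,
    gene = posn$gene, class = cls, ref_maf = 0,
    dann = sc$dann, sift = sc$sift, polyphen = sc$polyphen,
    injected = FALSE, stringsAsFactors = FALSE)
  carriers <- data.frame(variant_id = variants$variant_id,
                         sample_id = rep(sample_ids, counts),
                         dosage = 1L, stringsAsFactors = FALSE)
  list(variants = variants, carriers = carriers)
}

#' Simulate a trio cohort with ground truth
#'
#' Generates \code{n_families} parent-offspring trios with an affected
#' child under an additive liability-threshold model, a healthy control
#' cohort and an affected training cohort for the risk-score model, rare
#' panel and background variants, ACR sub-phenotypes, and a
#' \code{truth} ledger (causal weights, designated high-burden parent,
#' injected panel variants, liabilities) for parameter-recovery tests.
#'
#' In \code{one_parent_fraction} of families one designated parent's
#' causal-allele dosage is rejection-sampled from the top 20\% of the
#' population genetic-score distribution; the other parent is drawn from
#' the population.  Children are resampled (transmissions and environment,
#' parents held fixed) until affected.  Injected ultra-rare deleterious
#' panel variants are transmitted from the non-designated parent when a
#' designated parent exists.
#'
#' @param config a \code{\link{sim_config}}.
#' @param panel a \code{gene_panel}; defaults to the bundled 22-gene panel.
#' @return an object of class \code{trio_cohort}; see Details.
#' @export
simulate_cohort <- function(config, panel = example_gene_panel()) {
  validate_sim_config(config)
  cfg <- config
  master <- cfg$seed
  nf <- cfg$n_families
  nm <- cfg$n_common_markers

  ## common markers and liability weights ------------------------------
  # Risk architecture: causal markers are drawn from the low-frequency end
  # of the panel and carry positive (risk-increasing) half-normal weights.
  # The resulting population burden is right-skewed and floor-compressed:
  # most genomes carry few risk alleles while a high-burden tail carries
  # many.  A symmetric Gaussian burden cannot reproduce the observed
  # family structure -- with parents of equal burden variance the patient
  # correlates equally with the higher- and the lower-scoring parent --
  # whereas a sparse risk-allele burden concentrates the informative
  # variance in the high-burden parent.
  set.seed(derive_seed(master, "markers"))
  maf <- runif(nm, cfg$common_maf_range[1], cfg$common_maf_range[2])
  marker_id <- sprintf("m%04d", seq_len(nm))
  low <- which(maf <= .causal_maf_max)
  if (length(low) < cfg$n_causal_markers) {
    low <- order(maf)[seq_len(min(nm, cfg$n_causal_markers * 2L))]
  }
  causal_idx <- sort(sample(low, cfg$n_causal_markers,
                            replace = length(low) < cfg$n_causal_markers))
  w <- numeric(nm)
  w[causal_idx] <- abs(rnorm(cfg$n_causal_markers, 0, cfg$effect_size_sd))
  muG <- sum(2 * maf * w)
  sdG <- sqrt(sum(w^2 * 2 * maf * (1 - maf)))

  ## family structure ---------------------------------------------------
  fam <- sprintf("F%03d", seq_len(nf))
  set.seed(derive_seed(master, "family_structure"))
  designated <- sample(c("mother", "father"), nf, replace = TRUE)
  designated[runif(nf) >= cfg$one_parent_fraction] <- "none"
  lambda_inj <- cfg$panel_rare_rate_background *
    (cfg$panel_enrichment_factor - 1)
  n_inj <- rpois(nf, lambda_inj)
  hom_fams <- utils::head(which(n_inj > 0), cfg$n_homozygous_nonsense)

  # The designated high-burden parent is drawn from an elevated-liability
  # distribution produced by exponentially tilting the causal allele
  # frequencies: p_i' = p_i e^(theta w_i) / (p_i e^(theta w_i) + 1 - p_i),
  # with a per-family tilt theta ~ N(theta0, tau^2).  Tilting shifts the
  # mean genetic score by about theta * varG while *adding* between-family
  # variance (tau), instead of truncating it away as quantile conditioning
  # would -- truncation makes the high-burden parent nearly constant and
  # hands the patient correlation to the other parent, the opposite of the
  # structure being modelled.
  draw_parent <- function(elevated) {
    if (!elevated) return(rbinom(nm, 2L, maf))
    theta <- max(0, rnorm(1, .designated_tilt$theta0, .designated_tilt$tau))
    ew <- exp(theta * w)
    p_tilt <- maf * ew / (maf * ew + 1 - maf)
    rbinom(nm, 2L, p_tilt)
  }

  gm <- gf <- gc_true <- matrix(0L, nf, nm,
                                dimnames = list(fam, marker_id))
  liab_child <- numeric(nf)
  liab_mother <- liab_father <- numeric(nf)

  for (i in seq_len(nf)) {
    set.seed(derive_seed(master, "family", i))
    rare_l <- cfg$rare_effect * (n_inj[i] + as.integer(i %in% hom_fams))
    # resample the whole family until the child is affected: parents are
    # redrawn after a run of failed transmissions, so families whose
    # parents cannot plausibly produce an affected child do not stall
    ok <- FALSE
    tries <- 0L
    while (!ok) {
      m_g <- draw_parent(designated[i] == "mother")
      f_g <- draw_parent(designated[i] == "father")
      for (k in seq_len(40L)) {
        tries <- tries + 1L
        if (tries > cfg$max_resample) {
          stop("family ", fam[i], ": no affected offspring after ",
               cfg$max_resample, " resamples; liability_threshold (",
               cfg$liability_threshold, ") appears unreachable",
               call. = FALSE)
        }
        child <- rbinom(nm, 1L, m_g / 2) + rbinom(nm, 1L, f_g / 2)
        L <- sum(w * child) - muG + rare_l + rnorm(1, 0, cfg$environmental_sd)
        if (L > cfg$liability_threshold) { ok <- TRUE; break }
      }
    }
    gm[i, ] <- m_g
    gf[i, ] <- f_g
    liab_mother[i] <- sum(w * m_g) - muG
    liab_father[i] <- sum(w * f_g) - muG
    gc_true[i, ] <- child
    liab_child[i] <- L
  }

  ## genotype errors and likelihood triples for the children ------------
  set.seed(derive_seed(master, "genotype_errors"))
  gc_obs <- gc_true
  err <- matrix(runif(nf * nm) < cfg$genotype_error_rate, nf, nm)
  if (any(err)) {
    idx <- which(err)
    shift <- sample(1:2, length(idx), replace = TRUE)
    gc_obs[idx] <- (gc_true[idx] + shift) %% 3L
  }
  # PL triples: confident (0/30/60 by distance) at clean sites; at error
  # sites the observed (wrong) genotype is only weakly preferred over the
  # true one so that trio refinement has signal to repair the call
  pl <- array(0L, dim = c(nf, nm, 3))
  for (g in 0:2) pl[, , g + 1] <- 30L * abs(gc_obs - g)
  if (any(err)) {
    idx <- which(err)
    for (g in 0:2) {
      layer <- pl[, , g + 1]
      weak <- idx[gc_true[idx] == g]
      other <- idx[gc_true[idx] != g & gc_obs[idx] != g]
      layer[weak] <- 6L
      layer[other] <- 40L
      pl[, , g + 1] <- layer
    }
  }

  ## control and training cohorts ---------------------------------------
  # two disjoint control draws: the model is trained on one and the
  # score-distribution comparison uses the other, so that control scores
  # are out-of-sample exactly like the parents they are compared with
  nc <- cfg$n_controls
  set.seed(derive_seed(master, "controls"))
  ctrl <- matrix(rbinom(nc * nm, 2L, rep(maf, each = nc)), nc, nm,
                 dimnames = list(sprintf("C%04d", seq_len(nc)), marker_id))
  set.seed(derive_seed(master, "controls_training"))
  ctrl_train <- matrix(rbinom(nc * nm, 2L, rep(maf, each = nc)), nc, nm,
                       dimnames = list(sprintf("CT%04d", seq_len(nc)),
                                       marker_id))
  set.seed(derive_seed(master, "training_cases"))
  p_aff <- stats::pnorm(cfg$liability_threshold,
                        sd = sqrt(sdG^2 + cfg$environmental_sd^2),
                        lower.tail = FALSE)
  kept <- matrix(0L, 0, nm)
  guard <- 0L
  while (nrow(kept) < nc) {
    guard <- guard + 1L
    if (guard > 200L) {
      stop("training-case rejection sampling failed; liability_threshold (",
           cfg$liability_threshold, ") appears unreachable", call. = FALSE)
    }
    B <- max(200L, ceiling((nc - nrow(kept)) / max(p_aff, 1e-6) * 1.3))
    X <- matrix(rbinom(B * nm, 2L, rep(maf, each = B)), B, nm)
    L <- as.vector(X %*% w) - muG + rnorm(B, 0, cfg$environmental_sd)
    kept <- rbind(kept, X[L > cfg$liability_threshold, , drop = FALSE])
  }
  train_cases <- kept[seq_len(nc), , drop = FALSE]
  dimnames(train_cases) <- list(sprintf("T%04d", seq_len(nc)), marker_id)

  ## rare variants -------------------------------------------------------
  patients <- paste0(fam, "_P")
  mothers <- paste0(fam, "_M")
  fathers <- paste0(fam, "_F")
  sites <- shared_site_table(cfg, panel)
  rt <- .stratum_rate_table(cfg)

  set.seed(derive_seed(master, "rare_variants"))
  vparts <- list(); cparts <- list()
  add <- function(part) {
    if (nrow(part$variants)) vparts[[length(vparts) + 1L]] <<- part$variants
    if (nrow(part$carriers)) cparts[[length(cparts) + 1L]] <<- part$carriers
  }
  off <- function() sum(vapply(vparts, nrow, 0L))
  # natural (benign-scored) private panel variants at background rate
  add(.sample_private_obs(cfg$panel_rare_rate_background, patients, "pv",
                          off(), panel, "panel_coding",
                          c("missense", "nonsense"), c(0.95, 0.05)))
  add(.sample_private_obs(rt$panel[rt$class_group == "promoter" &
                                     rt$bin_index == 1],
                          patients, "pv", off(), panel, "panel_promoter",
                          "promoter", 1))
  add(.sample_private_obs(0.05, patients, "pv", off(), panel,
                          "panel_coding", "silent", 1))
  # private background variants
  add(.sample_private_obs(rt$background[rt$class_group == "non_silent_coding" &
                                          rt$bin_index == 1],
                          patients, "pv", off(), panel, "background_coding",
                          c("missense", "nonsense"), c(0.95, 0.05)))
  add(.sample_private_obs(rt$background[rt$class_group == "promoter" &
                                          rt$bin_index == 1],
                          patients, "pv", off(), panel, "background_promoter",
                          "promoter", 1))
  add(.sample_private_obs(10, patients, "pv", off(), panel,
                          "background_coding", "silent", 1))
  # injected deleterious panel variants (the enrichment signal)
  inj_records <- NULL
  if (sum(n_inj) + length(hom_fams) > 0) {
    fam_idx <- rep(seq_len(nf), n_inj)
    n <- length(fam_idx)
    posn <- .panel_positions(max(n, 1L), panel, "coding")
    ra <- .rand_ref_alt(max(n, 1L))
    if (n > 0) {
      iv <- data.frame(
        variant_id = sprintf("iv%06d", seq_len(n)),
        chrom = posn$chrom[seq_len(n)], pos = posn$pos[seq_len(n)],
        ref = ra$ref[seq_len(n)], alt = ra$alt[seq_len(n)],
        gene = posn$gene[seq_len(n)], class = "missense", ref_maf = 0,
        dann = runif(n, 0.96, 1), sift = runif(n, 0, 0.045),
        polyphen = runif(n, 0.85, 1), injected = TRUE,
        stringsAsFactors = FALSE)
      zyg <- rep("het", n)
      first_of_fam <- !duplicated(fam_idx)
      is_hom <- first_of_fam & fam_idx %in% hom_fams
      zyg[is_hom] <- "hom"
      iv$class[is_hom] <- "nonsense"
      iv$dann[is_hom] <- NA_real_
      iv$sift[is_hom] <- NA_real_
      iv$polyphen[is_hom] <- NA_real_
      transmit <- ifelse(designated[fam_idx] == "mother", fathers[fam_idx],
                  ifelse(designated[fam_idx] == "father", mothers[fam_idx],
                         ifelse(runif(n) < 0.5, mothers[fam_idx],
                                fathers[fam_idx])))
      iv_car <- data.frame(variant_id = iv$variant_id,
                           sample_id = patients[fam_idx],
                           dosage = ifelse(zyg == "hom", 2L, 1L),
                           stringsAsFactors = FALSE)
      add(list(variants = iv, carriers = iv_car))
      inj_records <- data.frame(family_id = fam[fam_idx],
                                variant_id = iv$variant_id,
                                transmitting_parent = transmit,
                                zygosity = zyg, stringsAsFactors = FALSE)
    }
  }
  # shared segregating sites, patients
  shared_case <- .sample_shared_obs(sites, patients)
  variants <- do.call(rbind, vparts)
  carriers <- do.call(rbind, c(cparts, list(shared_case)))

  ## transmit every patient rare observation from a parent ---------------
  set.seed(derive_seed(master, "transmission"))
  pat_car <- carriers[carriers$sample_id %in% patients, ]
  fam_of <- setNames(fam, patients)
  parent_rows <- NULL
  if (nrow(pat_car)) {
    f <- fam_of[pat_car$sample_id]
    vmap <- if (is.null(inj_records)) character(0) else
      setNames(inj_records$transmitting_parent, inj_records$variant_id)
    tp <- vmap[pat_car$variant_id]
    random_parent <- ifelse(runif(nrow(pat_car)) < 0.5,
                            paste0(f, "_M"), paste0(f, "_F"))
    tp[is.na(tp)] <- random_parent[is.na(tp)]
    parent_rows <- data.frame(variant_id = pat_car$variant_id,
                              sample_id = unname(tp), dosage = 1L,
                              stringsAsFactors = FALSE)
    # homozygous child: both parents are heterozygous carriers
    hom <- pat_car$dosage == 2L
    if (any(hom)) {
      other <- ifelse(substring(tp[hom], nchar(tp[hom])) == "M",
                      paste0(f[hom], "_F"), paste0(f[hom], "_M"))
      parent_rows <- rbind(parent_rows,
                           data.frame(variant_id = pat_car$variant_id[hom],
                                      sample_id = other, dosage = 1L,
                                      stringsAsFactors = FALSE))
    }
  }
  carriers <- rbind(carriers, parent_rows)
  carriers <- carriers[!duplicated(carriers[c("variant_id", "sample_id")]), ]
  rownames(carriers) <- NULL

  # shared-site records enter the variant table once observed in the cohort
  obs_shared <- sites[sites$variant_id %in% carriers$variant_id,
                      c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                        "class", "ref_maf")]
  if (nrow(obs_shared)) {
    set.seed(derive_seed(master, "shared_scores"))
    obs_shared$dann <- runif(nrow(obs_shared), 0, 0.9)
    obs_shared$sift <- runif(nrow(obs_shared), 0.06, 1)
    obs_shared$polyphen <- runif(nrow(obs_shared), 0, 0.8)
    obs_shared$injected <- FALSE
    variants <- rbind(variants, obs_shared)
  }
  rownames(variants) <- NULL

  ## phenotypes -----------------------------------------------------------
  set.seed(derive_seed(master, "phenotypes"))
  acr <- matrix(rbinom(nf * length(.acr_criteria), 1L,
                       rep(.acr_rates, each = nf)),
                nf, length(.acr_criteria),
                dimnames = list(patients, .acr_criteria))
  het_carrier_fams <- if (is.null(inj_records)) character(0) else
    unique(inj_records$family_id[inj_records$zygosity == "het"])
  if (length(het_carrier_fams)) {
    acr[paste0(het_carrier_fams, "_P"), "renal"] <-
      rbinom(length(het_carrier_fams), 1L, cfg$carrier_nephritis_rate)
  }
  phenotypes <- data.frame(sample_id = patients, acr, check.names = FALSE,
                           stringsAsFactors = FALSE)

  ## pedigree and samples -------------------------------------------------
  set.seed(derive_seed(master, "sex"))
  child_sex <- ifelse(runif(nf) < 0.85, 2L, 1L)  # 85% female patients
  pedigree <- rbind(
    data.frame(family_id = fam, individual_id = patients,
               father_id = fathers, mother_id = mothers,
               sex = child_sex, phenotype = 2L, stringsAsFactors = FALSE),
    data.frame(family_id = fam, individual_id = mothers, father_id = "0",
               mother_id = "0", sex = 2L, phenotype = 1L,
               stringsAsFactors = FALSE),
    data.frame(family_id = fam, individual_id = fathers, father_id = "0",
               mother_id = "0", sex = 1L, phenotype = 1L,
               stringsAsFactors = FALSE))
  samples <- rbind(
    data.frame(sample_id = patients, family_id = fam, role = "patient",
               stringsAsFactors = FALSE),
    data.frame(sample_id = mothers, family_id = fam, role = "mother",
               stringsAsFactors = FALSE),
    data.frame(sample_id = fathers, family_id = fam, role = "father",
               stringsAsFactors = FALSE),
    data.frame(sample_id = rownames(ctrl), family_id = NA, role = "control",
               stringsAsFactors = FALSE),
    data.frame(sample_id = rownames(ctrl_train), family_id = NA,
               role = "control_training", stringsAsFactors = FALSE),
    data.frame(sample_id = rownames(train_cases), family_id = NA,
               role = "case_training", stringsAsFactors = FALSE))

  truth <- structure(list(
    causal_weights = setNames(w[causal_idx], marker_id[causal_idx]),
    high_burden_parent = setNames(designated, fam),
    injected_panel_variants = inj_records,
    liabilities = c(setNames(liab_child, patients),
                    setNames(liab_mother, mothers),
                    setNames(liab_father, fathers))),
    class = "synthetic_truth")

  markers <- data.frame(variant_id = marker_id, chrom = "chrSM1",
                        pos = 10000L * seq_len(nm), maf = maf,
                        causal = seq_len(nm) %in% causal_idx,
                        stringsAsFactors = FALSE)
  ra <- { set.seed(derive_seed(master, "marker_alleles")); .rand_ref_alt(nm) }
  markers$ref <- ra$ref
  markers$alt <- ra$alt

  cohort <- structure(list(
    config = cfg, panel = panel, samples = samples, pedigree = pedigree,
    markers = markers,
    geno = list(mother = gm, father = gf, child_true = gc_true,
                child_obs = gc_obs, child_pl = pl, controls = ctrl,
                controls_training = ctrl_train,
                training_cases = train_cases),
    variants = variants, carriers = carriers,
    annotations = NULL, phenotypes = phenotypes, truth = truth),
    class = "trio_cohort")
  cohort$annotations <- emit_annotations(variants, panel)
  cohort
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat("trio_cohort:", x$config$n_families, "families,",
      nrow(x$markers), "common markers,", nrow(x$variants),
      "rare variants (", sum(x$variants$injected), "injected ),",
      x$config$n_controls, "controls + training cases, seed",
      x$config$seed, "\n")
  invisible(x)
}

#' Simulate a reference cohort allele-count table
#'
#' Draws \code{n_reference} diploid genomes from the same background
#' variant process as the case cohort (identical shared-site pool, same
#' per-genome rates, no patient-specific enrichment) and aggregates to
#' per-variant allele counts.  An optional calling-efficiency
#' \code{deflation} factor thins private (cohort-singleton) observations,
#' emulating a reference pipeline that misses a fraction of singletons;
#' the enrichment normalisation step is designed to correct exactly this.
#'
#' @param config a \code{\link{sim_config}}.
#' @param deflation probability in (0, 1] that a private reference
#'   observation is retained (1 = no deflation).
#' @param panel gene panel (must match the case cohort's).
#' @return data.frame of class \code{ref_counts} with columns variant_id,
#'   chrom, pos, ref, alt, gene, class, maf, ac, an, n_het, n_hom,
#'   n_carrier; attribute \code{n_genomes}.
#' @export
simulate_reference <- function(config, deflation = 1,
                               panel = example_gene_panel()) {
  validate_sim_config(config)
  stopifnot(deflation > 0, deflation <= 1)
  cfg <- config
  nr <- cfg$n_reference
  ids <- sprintf("R%05d", seq_len(nr))
  sites <- shared_site_table(cfg, panel)
  rt <- .stratum_rate_table(cfg)
  set.seed(derive_seed(cfg$seed, "reference"))
  vparts <- list(); cparts <- list()
  add <- function(part) {
    if (nrow(part$variants)) vparts[[length(vparts) + 1L]] <<- part$variants
    if (nrow(part$carriers)) cparts[[length(cparts) + 1L]] <<- part$carriers
  }
  off <- function() sum(vapply(vparts, nrow, 0L))
  # private observations, thinned by the deflation factor
  d <- deflation
  add(.sample_private_obs(cfg$panel_rare_rate_background * d, ids, "rv",
                          off(), panel, "panel_coding",
                          c("missense", "nonsense"), c(0.95, 0.05)))
  add(.sample_private_obs(rt$panel[rt$class_group == "promoter" &
                                     rt$bin_index == 1] * d,
                          ids, "rv", off(), panel, "panel_promoter",
                          "promoter", 1))
  add(.sample_private_obs(0.05 * d, ids, "rv", off(), panel, "panel_coding",
                          "silent", 1))
  add(.sample_private_obs(rt$background[rt$class_group == "non_silent_coding" &
                                          rt$bin_index == 1] * d,
                          ids, "rv", off(), panel, "background_coding",
                          c("missense", "nonsense"), c(0.95, 0.05)))
  add(.sample_private_obs(rt$background[rt$class_group == "promoter" &
                                          rt$bin_index == 1] * d,
                          ids, "rv", off(), panel, "background_promoter",
                          "promoter", 1))
  add(.sample_private_obs(10 * d, ids, "rv", off(), panel,
                          "background_coding", "silent", 1))
  shared <- .sample_shared_obs(sites, ids)

  priv_var <- do.call(rbind, vparts)
  priv_car <- do.call(rbind, cparts)
  an <- 2L * nr

  agg_counts <- function(car) {
    if (is.null(car) || nrow(car) == 0) {
      return(data.frame(variant_id = character(), ac = integer(),
                        n_het = integer(), n_hom = integer(),
                        n_carrier = integer(), stringsAsFactors = FALSE))
    }
    ac <- tapply(car$dosage, car$variant_id, sum)
    nhet <- tapply(car$dosage == 1L, car$variant_id, sum)
    nhom <- tapply(car$dosage == 2L, car$variant_id, sum)
    data.frame(variant_id = names(ac), ac = as.integer(ac),
               n_het = as.integer(nhet), n_hom = as.integer(nhom),
               n_carrier = as.integer(nhet + nhom),
               stringsAsFactors = FALSE)
  }

  out <- NULL
  if (!is.null(priv_var) && nrow(priv_var)) {
    cc <- agg_counts(priv_car)
    m <- merge(priv_var[c("variant_id", "chrom", "pos", "ref", "alt",
                          "gene", "class")], cc, by = "variant_id")
    m$maf <- m$ac / an
    out <- m
  }
  if (nrow(shared)) {
    cc <- agg_counts(shared)
    m <- merge(sites[c("variant_id", "chrom", "pos", "ref", "alt", "gene",
                       "class", "ref_maf")], cc, by = "variant_id")
    names(m)[names(m) == "ref_maf"] <- "maf"
    out <- rbind(out, m[names(out)])
  }
  out$an <- an
  rownames(out) <- NULL
  structure(out, class = c("ref_counts", "data.frame"),
            n_genomes = nr, deflation = deflation)
}

#' Annotation table for a variant set
#'
#' Produces the per-variant annotation TSV contract: functional class,
#' reference-population MAF and the deleteriousness triple.  Variants whose
#' position falls inside a panel promoter interval are labelled
#' \code{promoter}; variants without a recognised class are labelled
#' \code{other}.
#'
#' @param variants data.frame with variant_id, chrom, pos, ref, alt, class,
#'   ref_maf, dann, sift, polyphen.
#' @param panel a \code{gene_panel}.
#' @return annotation data.frame (one row per variant).
#' @export
emit_annotations <- function(variants, panel) {
  stopifnot(nrow(variants) > 0)
  cls <- variants$class
  in_prom <- variant_in_panel(variants$chrom, variants$pos, panel, "promoter")
  cls[in_prom] <- "promoter"
  known <- c("missense", "nonsense", "silent", "promoter")
  cls[is.na(cls) | !cls %in% known] <- "other"
  data.frame(variant_id = variants$variant_id, chrom = variants$chrom,
             pos = variants$pos, ref = variants$ref, alt = variants$alt,
             class = cls, ref_maf = variants$ref_maf,
             dann = variants$dann, sift = variants$sift,
             polyphen = variants$polyphen, stringsAsFactors = FALSE)
}

#' Simulate per-stratum counts under the null
#'
#' Draws Poisson stratum counts (case/reference x panel/background) from
#' the generator's per-genome rate table with no enrichment, for type-I
#' error studies of the enrichment test at a given cohort scale.
#'
#' @param n_strata number of strata to draw (cycling over the 2 annotation
#'   groups x 4 MAF bins of the rate table).
#' @param n_case_genomes,n_ref_genomes cohort sizes.
#' @param config sim_config supplying the panel background rate.
#' @param seed RNG seed.
#' @return data.frame with one row per stratum: class_group, maf_bin,
#'   case_panel, case_background, ref_panel, ref_background,
#'   n_case_genomes, n_ref_genomes.
#' @export
simulate_null_strata <- function(n_strata, n_case_genomes = 500,
                                 n_ref_genomes = 2000,
                                 config = sim_config(), seed = 1) {
  rt <- .stratum_rate_table(config)
  set.seed(derive_seed(seed, "null_strata"))
  k <- rep_len(seq_len(nrow(rt)), n_strata)
  data.frame(
    class_group = rt$class_group[k], maf_bin = rt$maf_bin[k],
    case_panel = rpois(n_strata, rt$panel[k] * n_case_genomes),
    case_background = rpois(n_strata, rt$background[k] * n_case_genomes),
    ref_panel = rpois(n_strata, rt$panel[k] * n_ref_genomes),
    ref_background = rpois(n_strata, rt$background[k] * n_ref_genomes),
    n_case_genomes = n_case_genomes, n_ref_genomes = n_ref_genomes,
    stringsAsFactors = FALSE)
}

#' Extract the common-marker dosage matrix for a set of roles
#'
#' @param cohort a \code{trio_cohort}.
#' @param roles which cohort members to include.
#' @param refined optional refined child dosage matrix replacing the
#'   observed child genotypes (as returned by \code{\link{refine_trios}}).
#' @return samples x markers integer dosage matrix.
#' @export
common_genotypes <- function(cohort,
                             roles = c("patient", "mother", "father"),
                             refined = NULL) {
  g <- cohort$geno
  child <- if (is.null(refined)) g$child_obs else refined
  rownames(child) <- paste0(rownames(g$mother), "_P")
  mm <- g$mother; rownames(mm) <- paste0(rownames(g$mother), "_M")
  ff <- g$father; rownames(ff) <- paste0(rownames(g$father), "_F")
  pick <- list(patient = child, mother = mm, father = ff,
               control = g$controls, control_training = g$controls_training,
               case_training = g$training_cases)
  do.call(rbind, pick[roles])
}
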