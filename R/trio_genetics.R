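# Trio genotype operations: Mendelian consistency, parent-of-origin
# assignment, and simplified trio-aware genotype posterior refinement.
# Genotypes are alt-allele dosages 0/1/2 ("hom_ref"/"het"/"hom_alt") with
# NA for missing.

.geno_levels <- c("hom_ref", "het", "hom_alt")

as_dosage <- function(g) {
  if (is.character(g)) {
    out <- match(g, .geno_levels) - 1L
    out[g == "missing"] <- NA_integer_
    if (any(!g %in% c(.geno_levels, "missing"))) {
      stop("unknown genotype label: ",
           paste(setdiff(g, c(.geno_levels, "missing")), collapse = ", "))
    }
    return(out)
  }
  g <- as.integer(g)
  if (any(!is.na(g) & (g < 0 | g > 2))) stop("dosage must be 0, 1, 2 or NA")
  g
}

#' A trio genotype at one biallelic site
#'
#' @param child,mother,father genotype as dosage (0/1/2), label
#'   (\code{"hom_ref"}, \code{"het"}, \code{"hom_alt"}, \code{"missing"}),
#'   or NA.
#' @param child_pl optional phred-scaled genotype likelihood triple
#'   (hom_ref, het, hom_alt) for the child; normalised so its minimum is 0.
#' @return list of class \code{trio_genotype}.
#' @export
trio_genotype <- function(child, mother, father, child_pl = NULL) {
  tg <- list(child = as_dosage(child), mother = as_dosage(mother),
             father = as_dosage(father), child_pl = child_pl)
  if (!is.null(child_pl)) {
    stopifnot(length(child_pl) == 3, all(child_pl >= 0))
    tg$child_pl <- child_pl - min(child_pl)
  }
  structure(tg, class = "trio_genotype")
}

#' Mendelian consistency of a trio genotype
#'
#' TRUE iff the child genotype can be formed by one allele transmitted
#' from each parent.  Any missing genotype yields NA (indeterminate) --
#' never silently TRUE.
#'
#' @param tg a \code{\link{trio_genotype}}, or a child dosage when
#'   \code{mother}/\code{father} are given (vectorised).
#' @param mother,father parental dosages for the vectorised form.
#' @return logical (NA = indeterminate).
#' @export
#' @examples
#' mendelian_consistent(trio_genotype("het", "hom_ref", "hom_ref")) # FALSE
mendelian_consistent <- function(tg, mother = NULL, father = NULL) {
  if (inherits(tg, "trio_genotype")) {
    child <- tg$child; mother <- tg$mother; father <- tg$father
  } else {
    child <- as_dosage(tg); mother <- as_dosage(mother)
    father <- as_dosage(father)
  }
  # transmissible alt-allele counts: parent dosage g can transmit alt with
  # multiplicity in {floor(g/2) .. ceiling(g/2)}
  lo <- floor(mother / 2) + floor(father / 2)
  hi <- ceiling(mother / 2) + ceiling(father / 2)
  ok <- child >= lo & child <= hi
  ok[is.na(child) | is.na(mother) | is.na(father)] <- NA
  ok
}

#' Parent of origin of a child's variant allele
#'
#' For a heterozygous child: the single carrier parent when exactly one
#' parent carries the alternate allele; \code{ambiguous} when both carry;
#' \code{de_novo} when neither does.  A homozygous-alt child requires one
#' allele from each parent, so both-carriers is reported \code{ambiguous}
#' (no single origin) and a non-carrier parent implies \code{de_novo}.
#' Missing genotypes, or a child without the allele, are
#' \code{indeterminate}.
#'
#' @inheritParams mendelian_consistent
#' @return character vector over \{maternal, paternal, ambiguous, de_novo,
#'   indeterminate\}.
#' @export
parent_of_origin <- function(tg, mother = NULL, father = NULL) {
  if (inherits(tg, "trio_genotype")) {
    child <- tg$child; mother <- tg$mother; father <- tg$father
  } else {
    child <- as_dosage(tg); mother <- as_dosage(mother)
    father <- as_dosage(father)
  }
  n <- length(child)
  out <- rep("indeterminate", n)
  known <- !is.na(child) & !is.na(mother) & !is.na(father)
  m_car <- mother >= 1
  f_car <- father >= 1
  het <- known & child == 1
  out[het & m_car & !f_car] <- "maternal"
  out[het & !m_car & f_car] <- "paternal"
  out[het & m_car & f_car] <- "ambiguous"
  out[het & !m_car & !f_car] <- "de_novo"
  hom <- known & child == 2
  out[hom & m_car & f_car] <- "ambiguous"
  out[hom & !(m_car & f_car)] <- "de_novo"
  out
}

# Mendelian transmission prior over the child genotype given parental
# dosages, with a per-allele de novo leak epsilon: an allele transmitted
# from a parent with dosage g is alt with probability
# (g/2)(1 - eps) + (1 - g/2) eps.
transmission_prior <- function(mother, father, epsilon) {
  pm <- (mother / 2) * (1 - epsilon) + (1 - mother / 2) * epsilon
  pf <- (father / 2) * (1 - epsilon) + (1 - father / 2) * epsilon
  c((1 - pm) * (1 - pf), pm * (1 - pf) + (1 - pm) * pf, pm * pf)
}

hwe_prior <- function(af) {
  stopifnot(af >= 0, af <= 1)
  c((1 - af)^2, 2 * af * (1 - af), af^2)
}

#' Trio-aware genotype posterior refinement
#'
#' Combines the child's genotype likelihoods (from the phred-scaled PL
#' triple) with a Mendelian transmission prior given the parental
#' genotypes (with a small per-allele de novo leak \code{epsilon}).  The
#' refined call is the maximum-posterior genotype; its quality is
#' \code{-10 log10(1 - max posterior)} and calls below Q20 (strictly) are
#' flagged.  When either parent is missing the prior falls back to
#' Hardy--Weinberg from \code{population_af} and the output records the
#' fallback.
#'
#' @param tg a \code{\link{trio_genotype}} with \code{child_pl} present.
#' @param epsilon per-allele de novo leak (default 1e-8).
#' @param population_af population alternate-allele frequency for the
#'   Hardy--Weinberg fallback when a parent is missing.
#' @return object of class \code{posterior_call}: \code{genotype} (label),
#'   \code{dosage}, \code{posterior} (3-vector summing to 1),
#'   \code{posterior_phred}, \code{low_quality_flag}, \code{prior_source}.
#' @export
refine_genotype <- function(tg, epsilon = 1e-8, population_af = NULL) {
  stopifnot(inherits(tg, "trio_genotype"))
  if (is.null(tg$child_pl)) stop("refine_genotype requires the child PL triple")
  if (is.na(tg$mother) || is.na(tg$father)) {
    if (is.null(population_af)) {
      stop("parents missing and no population_af given for the ",
           "Hardy-Weinberg fallback")
    }
    prior <- hwe_prior(population_af)
    src <- "population"
  } else {
    prior <- transmission_prior(tg$mother, tg$father, epsilon)
    src <- "trio"
  }
  lik <- 10^(-tg$child_pl / 10)
  post <- prior * lik
  post <- post / sum(post)
  g <- which.max(post) - 1L
  phred <- phred_from_posterior(max(post))
  structure(list(genotype = .geno_levels[g + 1L], dosage = g,
                 posterior = post, posterior_phred = phred,
                 low_quality_flag = is_low_quality(phred),
                 prior_source = src),
            class = "posterior_call")
}

#' @export
print.posterior_call <- function(x, ...) {
  cat("posterior_call:", x$genotype,
      sprintf("(Q%.1f%s, prior=%s)\n", x$posterior_phred,
              if (x$low_quality_flag) ", LOWGP" else "", x$prior_source))
  invisible(x)
}

#' Refine all child genotypes of a cohort at the common markers
#'
#' Vectorised application of the trio posterior refinement across every
#' (family x marker) cell, using the stored child PL triples and the
#' parental dosages.
#'
#' @param cohort a \code{trio_cohort}.
#' @param epsilon per-allele de novo leak.
#' @return list with \code{dosage} (families x markers refined calls),
#'   \code{phred} (posterior phred), \code{flag} (LOWGP logical matrix),
#'   and \code{n_changed}, the number of calls altered by refinement.
#' @export
refine_trios <- function(cohort, epsilon = 1e-8) {
  gm <- cohort$geno$mother
  gf <- cohort$geno$father
  pl <- cohort$geno$child_pl
  pm <- (gm / 2) * (1 - epsilon) + (1 - gm / 2) * epsilon
  pf <- (gf / 2) * (1 - epsilon) + (1 - gf / 2) * epsilon
  prior0 <- (1 - pm) * (1 - pf)
  prior1 <- pm * (1 - pf) + (1 - pm) * pf
  prior2 <- pm * pf
  l0 <- 10^(-pl[, , 1] / 10) * prior0
  l1 <- 10^(-pl[, , 2] / 10) * prior1
  l2 <- 10^(-pl[, , 3] / 10) * prior2
  tot <- l0 + l1 + l2
  p0 <- l0 / tot; p1 <- l1 / tot; p2 <- l2 / tot
  pmax_ <- pmax(p0, p1, p2)
  # argmax with deterministic tie-break toward the lower dosage
  dosage <- ifelse(p0 >= p1 & p0 >= p2, 0L, ifelse(p1 >= p2, 1L, 2L))
  mode(dosage) <- "integer"
  phred <- matrix(phred_from_posterior(pmax_), nrow(pmax_), ncol(pmax_))
  dimnames(dosage) <- dimnames(cohort$geno$child_obs)
  dimnames(phred) <- dimnames(dosage)
  list(dosage = dosage, phred = phred, flag = is_low_quality(phred),
       n_changed = sum(dosage != cohort$geno$child_obs))
}
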