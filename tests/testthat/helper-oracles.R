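# Independent brute-force oracles used to pin down expected values.

# Two-sided Fisher exact p by explicit enumeration of all tables with the
# observed margins, probabilities from choose() products (no dhyper).
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || (b + d) == 0) return(1)
  xs <- max(0, k - n2):min(k, m)
  tot <- choose(m + n2, k)
  probs <- choose(m, xs) * choose(n2, k - xs) / tot
  pobs <- choose(m, a) * choose(n2, k - a) / tot
  min(1, sum(probs[probs <= pobs * (1 + 1e-7)]))
}

# Mendelian consistency by enumeration of transmissible allele pairs.
oracle_mendel <- function(child, mother, father) {
  trans <- function(g) unique(c(floor(g / 2), ceiling(g / 2)))
  child %in% outer(trans(mother), trans(father), "+")
}

# Trio genotype posterior by enumeration over transmitted alleles and
# per-allele de novo flips (independent of the closed-form prior in the
# implementation).
oracle_refine_posterior <- function(pl, gm, gf, eps) {
  post <- numeric(3)
  for (am in 0:1) for (af in 0:1) {
    pm <- c(1 - gm / 2, gm / 2)[am + 1]
    pf <- c(1 - gf / 2, gf / 2)[af + 1]
    for (fm in 0:1) for (ff in 0:1) {
      pflip <- eps^(fm + ff) * (1 - eps)^(2 - fm - ff)
      g <- xor(am, fm) + xor(af, ff)
      post[g + 1] <- post[g + 1] + pm * pf * pflip
    }
  }
  post <- post * 10^(-pl / 10)
  post / sum(post)
}

# Direct-formula Pearson r and t-distribution p value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}
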