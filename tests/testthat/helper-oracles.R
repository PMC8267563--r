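# Independent oracles used to derive expected values. These stay
# deliberately naive and separate from the package implementation.

# Symmetric-difference size by explicit set operations.
oracle_symdiff <- function(a, b) {
  length(setdiff(a, b)) + length(setdiff(b, a))
}

# Connected components of the threshold graph (breadth-first search).
oracle_threshold_components <- function(m, cutoff) {
  n <- nrow(m)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(m[v, ] <= cutoff & is.na(comp))
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}

# Probability two independent HWE genotypes at alt frequency q agree.
hwe_match_prob <- function(q) {
  p <- 1 - q
  (p^2)^2 + (2 * p * q)^2 + (q^2)^2
}

# Monte-Carlo concordance oracle for parent-child and unrelated pairs,
# simulated directly from allele dosages (never through the package).
mc_relative_concordance <- function(mafs, n_rep = 20, seed = 1,
                                    relation = c("parent_child", "unrelated")) {
  relation <- match.arg(relation)
  set.seed(seed)
  out <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    q <- mafs
    d_parent <- rbinom(length(q), 2, q)
    if (relation == "unrelated") {
      d_other <- rbinom(length(q), 2, q)
    } else {
      # transmitted allele: Bernoulli(dosage/2); other parent independent
      transmitted <- rbinom(length(q), 1, d_parent / 2)
      d_other <- transmitted + rbinom(length(q), 1, q)
    }
    out[r] <- mean(d_parent == d_other)
  }
  out
}

# Exact two-sided tail of the binomial z test at threshold zc, averaged
# over a MAF vector (the null blacklist rate for a finite cohort).
oracle_null_blacklist_rate <- function(mafs, n_genomes, zc) {
  n2 <- 2 * n_genomes
  mean(vapply(mafs, function(q) {
    ks <- 0:n2
    z <- (ks / n2 - q) / sqrt(q * (1 - q) / n2)
    sum(stats::dbinom(ks[abs(z) > zc], n2, q))
  }, numeric(1)))
}
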