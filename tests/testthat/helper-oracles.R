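# Independent brute-force oracles used to check the statistical routines.
# These deliberately avoid the code paths they verify.

# exact two-sided binomial p by pmf enumeration: doubled smaller tail,
# observed value included, capped at 1
oracle_binom_p <- function(m, c) {
  n <- m + c
  pmf <- vapply(0:n, function(k) choose(n, k) * 0.5^n, 0)
  lower <- sum(pmf[seq_len(m + 1L)])          # P(X <= m)
  upper <- sum(pmf[seq(m + 1L, n + 1L)])      # P(X >= m)
  min(1, 2 * min(lower, upper))
}

# Benjamini-Hochberg step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(1, q)
  out
}

# upper-tail hypergeometric by pmf summation (overlap >= k)
oracle_hyper <- function(k, n_ref, n_universe, n_skew) {
  ks <- k:min(n_ref, n_skew)
  sum(choose(n_ref, ks) * choose(n_universe - n_ref, n_skew - ks)) /
    choose(n_universe, n_skew)
}

# quadratic all-pairs interval overlap tally (0-based half-open)
oracle_count <- function(fragments, regions) {
  out <- list()
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    hit <- fragments$chrom == r$chrom &
      fragments$start < r$end & fragments$end > r$start
    f <- fragments[hit, ]
    for (a in unique(fragments$assay)) {
      fa <- f[f$assay == a, ]
      out[[paste(r$gene_id, r$region_type, a)]] <- data.frame(
        gene_id = r$gene_id, region_type = r$region_type, assay = a,
        n_composite = nrow(fa),
        n_mus = sum(fa$allele == "mus"),
        n_cas = sum(fa$allele == "cas"))
    }
  }
  do.call(rbind, out)
}
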