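# Shared fixture builders for the suite. All randomness is seeded at the
# call sites; helpers themselves are deterministic given the RNG state.

# Small genome: m variants spread over n_chrom chromosomes.
make_spec <- function(m, n_chrom = 22L, freq = NULL) {
  if (is.null(freq)) freq <- runif(m, 0.1, 0.9)
  variant_spec(rep_len(seq_len(n_chrom), m), freq)
}

# Dosage-scale weights equivalent to a standardized-scale architecture,
# so compute_pgs(pop, weights, set) reproduces the chromosome-set part of
# the true genetic value (up to an additive constant).
true_weights <- function(arch, variants) {
  w <- rep(0, nrow(variants))
  p <- variants$freq[arch$causal_index]
  w[arch$causal_index] <- arch$beta / sqrt(2 * p * (1 - p))
  w
}

# Chromosome-set halves of the true genetic value for a population.
true_half_scores <- function(pop, arch, scheme = "odd_even") {
  w <- true_weights(arch, pop$variants)
  grp <- chromosome_groups(scheme)
  list(odd = compute_pgs(pop, w, grp$set1),
       even = compute_pgs(pop, w, grp$set2))
}

# Population with dosages set directly from a matrix (no phase).
pop_from_dosages <- function(G, chrom = NULL, freq = NULL) {
  m <- ncol(G)
  if (is.null(chrom)) chrom <- rep_len(1:22, m)
  if (is.null(freq)) freq <- pmin(pmax(colMeans(G, na.rm = TRUE) / 2, 0.01), 0.99)
  new_population(G, variant_spec(chrom, freq))
}

# Independent brute-force oracle for the exact HWE test: conditional
# probability of each heterozygote count from log-factorials, summed over
# outcomes no more probable than the observed one.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- n_Aa + 2 * n_aa
  nA <- 2 * n - na
  rare <- min(nA, na)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    hr <- (rare - h) / 2
    hc <- n - h - hr
    lfactorial(n) - lfactorial(hr) - lfactorial(h) - lfactorial(hc) +
      h * log(2) + lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(lp)
  sum(p[p <= p[match(n_Aa, hets)] * (1 + 1e-9)]) / sum(p)
}
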