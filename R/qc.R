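#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on the genotype counts of a biallelic variant:
#' given the allele counts, the P value is the summed probability of all
#' heterozygote counts (of the same parity) whose conditional probability
#' does not exceed that of the observed count. Probabilities follow the
#' standard recurrence over heterozygote counts.
#'
#' @param n_AA,n_Aa,n_aa non-negative integer genotype counts.
#' @return exact P value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0L, n_Aa >= 0L, n_aa >= 0L)
  n <- n_AA + n_Aa + n_aa
  if (n < 1L) stop("at least one genotype required")
  n_a <- n_Aa + 2L * n_aa          # minor-agnostic: use rarer allele count
  n_A <- n_Aa + 2L * n_AA
  rare <- min(n_A, n_a)
  if (rare == 0L) return(1)
  # heterozygote counts share the parity of the rare allele count;
  # upward recurrence P(h+2)/P(h) = 4 hom_r(h) hom_c(h) / ((h+2)(h+1))
  # with hom_r = (rare - h)/2 rare homozygotes, hom_c = n - h - hom_r,
  # accumulated in log space to stay finite at large n
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  h <- hets[-length(hets)]
  hom_r <- (rare - h) / 2
  hom_c <- n - h - hom_r
  lp <- c(0, cumsum(log(4 * hom_r * hom_c) - log(h + 2) - log(h + 1)))
  lp <- lp - max(lp)
  probs <- exp(lp) / sum(exp(lp))
  p_obs <- probs[match(n_Aa, hets)]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

#' Per-variant inbreeding coefficient
#'
#' `F = 1 - observed heterozygosity / expected heterozygosity`, with the
#' expectation `2 p (1 - p)` at the sample allele frequency. Positive `F`
#' indicates excess homozygosity (as accumulates under assortative
#' mating); `F = -1` is maximal heterozygote excess.
#'
#' @param dosages dosage vector (0/1/2, `NA` allowed) at one variant.
#' @return scalar F in \[-1, 1\].
#' @export
inbreeding_coefficient <- function(dosages) {
  x <- dosages[!is.na(dosages)]
  if (length(x) < 2L) stop("need >= 2 non-missing dosages")
  p <- mean(x) / 2
  if (p <= 0 || p >= 1) stop("monomorphic variant: F undefined")
  1 - mean(x == 1L) / (2 * p * (1 - p))
}

#' Composite linkage disequilibrium between two variants
#'
#' Squared Pearson correlation of the dosage vectors.
#'
#' @param dosages_a,dosages_b equal-length dosage vectors.
#' @return r-squared in \[0, 1\].
#' @export
ld_r2 <- function(dosages_a, dosages_b) {
  stopifnot(length(dosages_a) == length(dosages_b))
  ok <- !is.na(dosages_a) & !is.na(dosages_b)
  a <- dosages_a[ok]; b <- dosages_b[ok]
  if (sd(a) == 0 || sd(b) == 0) stop("constant dosage vector: LD undefined")
  cor(a, b)^2
}

#' Variant quality control
#'
#' Applies the exclusion rules with strict inequalities: call rate below
#' `call_rate`, minor allele frequency below `maf`, or exact
#' Hardy-Weinberg P below `hwe_p`. A variant failing any rule is removed;
#' the per-variant report (call rate, MAF, HWE P, inbreeding coefficient
#' F, pass flags) is retained for all variants.
#'
#' @param pop a `population`.
#' @param call_rate minimum call rate (default 0.99; excluded if below).
#' @param maf minimum minor allele frequency (default 0.01).
#' @param hwe_p minimum HWE exact-test P (default 1e-6).
#' @return list with `keep` (integer indices of surviving variants) and
#'   `report` (data.frame, one row per variant).
#' @export
qc_variants <- function(pop, call_rate = 0.99, maf = 0.01, hwe_p = 1e-6) {
  stopifnot(call_rate >= 0, call_rate <= 1, maf >= 0, maf <= 0.5,
            hwe_p >= 0, hwe_p <= 1)
  G <- pop$genotypes
  n <- nrow(G)
  cr <- 1 - colSums(is.na(G)) / n
  af <- colMeans(G, na.rm = TRUE) / 2
  mafs <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    hwe_exact_test(sum(x == 0L, na.rm = TRUE), sum(x == 1L, na.rm = TRUE),
                   sum(x == 2L, na.rm = TRUE))
  }, numeric(1))
  f <- vapply(seq_len(ncol(G)), function(j) {
    x <- G[, j]
    if (length(unique(x[!is.na(x)])) < 2L) return(NA_real_)
    inbreeding_coefficient(x)
  }, numeric(1))
  report <- data.frame(id = pop$variants$id, call_rate = cr, maf = mafs,
                       hwe_p = hwe, f = f,
                       pass_call_rate = !(cr < call_rate),
                       pass_maf = !(mafs < maf),
                       pass_hwe = !(hwe < hwe_p))
  report$pass <- report$pass_call_rate & report$pass_maf & report$pass_hwe
  keep <- which(report$pass)
  if (length(keep) == 0L) stop("no variants survive QC")
  list(keep = keep, report = report)
}
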