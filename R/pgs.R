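#' Chromosome grouping schemes
#'
#' Partitions of the 22 autosomes into two disjoint sets used for
#' chromosome-set polygenic scores: odd vs even numbered chromosomes
#' (default), first half vs second half (1-8 vs 9-22, balancing variant
#' counts), and a fixed pseudo-random split (1, 3, 5, 6, 9, 10, 13, 14,
#' 17, 18 vs the rest).
#'
#' @param scheme one of `"odd_even"`, `"halves"`, `"pseudo_random"`.
#' @return named list of two integer vectors (`set1`, `set2`).
#' @export
chromosome_groups <- function(scheme = c("odd_even", "halves", "pseudo_random")) {
  scheme <- match.arg(scheme)
  switch(scheme,
    odd_even = list(set1 = seq(1L, 21L, 2L), set2 = seq(2L, 22L, 2L)),
    halves = list(set1 = 1:8, set2 = 9:22),
    pseudo_random = list(
      set1 = c(1L, 3L, 5L, 6L, 9L, 10L, 13L, 14L, 17L, 18L),
      set2 = c(2L, 4L, 7L, 8L, 11L, 12L, 15L, 16L, 19L, 20L, 21L, 22L)))
}

#' Compute a chromosome-set polygenic score
#'
#' Weighted allele-dosage sum restricted to variants on the given
#' chromosome set, z-standardized within the scored sample. Missing
#' dosages are mean-imputed per variant. Dosages outside the chromosome
#' set are never read.
#'
#' @param pop a `population`.
#' @param betas per-variant weights: either a numeric vector aligned with
#'   the variant table (zero or `NA` entries contribute nothing), or a
#'   `summary_stats` data.frame whose `BETA_POST` (else `BETA`) column is
#'   matched to the variant table by `SNP` id.
#' @param chromosome_set integer vector of chromosome numbers.
#' @return numeric score vector with mean 0, variance 1; the raw
#'   (unstandardized) score is kept in the `"raw"` attribute.
#' @export
compute_pgs <- function(pop, betas, chromosome_set) {
  stopifnot(length(chromosome_set) > 0L)
  if (inherits(betas, "data.frame")) {
    w <- rep(0, n_variants(pop))
    col <- if ("BETA_POST" %in% names(betas)) "BETA_POST" else "BETA"
    idx <- match(betas$SNP, pop$variants$id)
    if (anyNA(idx)) stop("summary statistics contain variants absent from the population")
    w[idx] <- betas[[col]]
  } else {
    stopifnot(length(betas) == n_variants(pop))
    w <- ifelse(is.na(betas), 0, betas)
  }
  in_set <- pop$variants$chrom %in% chromosome_set
  if (!any(in_set)) stop("no scored variants on the requested chromosome set")
  X <- pop$genotypes[, in_set, drop = FALSE]
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2L]]
  }
  raw <- drop(X %*% w[in_set])
  s <- sd(raw)
  if (s == 0) stop("degenerate polygenic score: zero variance")
  out <- (raw - mean(raw)) / s
  attr(out, "raw") <- raw
  out
}
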