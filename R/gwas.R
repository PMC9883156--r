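#' Per-variant association scan
#'
#' Regresses the phenotype on each variant's dosage with an intercept and
#' optional covariates, by ordinary least squares. The covariates are
#' projected out of both phenotype and dosages once (a single QR
#' decomposition), after which each variant reduces to a simple
#' regression on residualized dosage; this is algebraically identical to
#' the full multiple regression coefficient for the dosage term. Binary
#' traits are fitted on the same linear scale (a linear probability
#' model). Missing dosages are mean-imputed per variant.
#'
#' @param pop a `population`.
#' @param phenotype numeric vector (quantitative or 0/1).
#' @param covariates optional numeric matrix (no intercept column needed).
#' @param variant_subset optional integer indices restricting the scan
#'   (e.g. the QC-passing set).
#' @return data.frame of class `summary_stats` with columns `CHR`, `POS`,
#'   `SNP`, `A1`, `A2`, `FREQ`, `BETA`, `SE`, `P`, `N` (effect allele
#'   `A1` is the alt allele).
#' @export
run_gwas <- function(pop, phenotype, covariates = NULL, variant_subset = NULL) {
  n <- n_individuals(pop)
  stopifnot(length(phenotype) == n)
  if (is.null(variant_subset)) variant_subset <- seq_len(n_variants(pop))
  X <- pop$genotypes[, variant_subset, drop = FALSE]
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2L]]
  }
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    drop_cols <- colnames(C)[qrC$pivot[(qrC$rank + 1L):ncol(C)]]
    stop("collinear covariates: ", paste(drop_cols, collapse = ", "))
  }
  # residualize against the covariate span through the thin Q factor:
  # sxx and sxy only need Q'X (k x m), never the full residual matrix
  Qc <- qr.Q(qrC)
  yr <- phenotype - drop(Qc %*% crossprod(Qc, phenotype))
  QtX <- crossprod(Qc, X)
  sxx <- pmax(colSums(X^2) - colSums(QtX^2), 0)
  sxy <- drop(crossprod(X, yr))
  beta <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  df <- n - ncol(C) - 1L
  rss <- sum(yr^2) - ifelse(sxx > 0, beta^2 * sxx, 0)
  se <- sqrt(pmax(rss, 0) / df / sxx)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  v <- pop$variants[variant_subset, ]
  out <- data.frame(CHR = v$chrom, POS = v$pos, SNP = v$id,
                    A1 = v$alt, A2 = v$ref, FREQ = colMeans(X) / 2,
                    BETA = beta, SE = se, P = pval, N = n,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Shrink per-variant effect estimates
#'
#' A pluggable stand-in for Bayesian continuous-shrinkage posterior
#' effects. Methods: `"empirical_bayes"` (default) shrinks each estimate
#' by `tau2 / (tau2 + se_i^2)` with the prior variance `tau2` estimated
#' by moment matching, `mean(beta^2) - mean(se^2)` truncated at zero;
#' `"pt"` zeroes out variants with association P above `p_threshold`;
#' `"none"` returns the estimates unchanged. Empirical-Bayes shrinkage is
#' always a contraction (`|posterior| <= |estimate|`).
#'
#' @param stats a `summary_stats` data.frame from [run_gwas()].
#' @param method one of `"empirical_bayes"`, `"pt"`, `"none"`.
#' @param p_threshold P-value cutoff for `method = "pt"`.
#' @param tau2 optional fixed prior variance overriding the moment estimate.
#' @return `stats` with a `BETA_POST` column appended.
#' @export
shrink_effects <- function(stats, method = c("empirical_bayes", "pt", "none"),
                           p_threshold = 0.05, tau2 = NULL) {
  method <- match.arg(method)
  post <- switch(method,
    none = stats$BETA,
    pt = ifelse(stats$P <= p_threshold, stats$BETA, 0),
    empirical_bayes = {
      if (is.null(tau2)) tau2 <- max(mean(stats$BETA^2) - mean(stats$SE^2), 0)
      stats$BETA * tau2 / (tau2 + stats$SE^2)
    })
  stats$BETA_POST <- post
  stats
}
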