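#' Principal components of a chromosome-set genotype submatrix
#'
#' PCA of the column-standardized dosages restricted to one chromosome
#' set, used to control population stratification on the predictor side
#' of the GPD regression. Monomorphic variants are dropped, missing
#' dosages mean-imputed. PC signs follow a deterministic convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param pop a `population`.
#' @param chromosome_set integer vector of chromosome numbers.
#' @param k number of components (default 20); `k = 0` yields an empty
#'   PC matrix (no adjustment downstream).
#' @param variant_subset optional indices (e.g. QC-passing variants); the
#'   chromosome-set restriction is applied on top.
#' @return object of class `chromosome_set_pcs`: list with `scores`
#'   (individuals x k), `explained` (variance fractions), `set`, `k`.
#' @export
pca_chromosome_set <- function(pop, chromosome_set, k = 20L,
                               variant_subset = NULL) {
  n <- n_individuals(pop)
  if (is.null(variant_subset)) variant_subset <- seq_len(n_variants(pop))
  idx <- variant_subset[pop$variants$chrom[variant_subset] %in% chromosome_set]
  if (k > 0L && (n <= k || length(idx) < k))
    stop("need more than k individuals and at least k variants in the set")
  if (k == 0L)
    return(structure(list(scores = matrix(0, n, 0L), explained = numeric(0),
                          set = chromosome_set, k = 0L),
                     class = "chromosome_set_pcs"))
  X <- pop$genotypes[, idx, drop = FALSE]
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    nas <- which(is.na(X), arr.ind = TRUE)
    X[nas] <- mu[nas[, 2L]]
  }
  v <- apply(X, 2L, sd)
  X <- X[, v > 0, drop = FALSE]
  v <- v[v > 0]
  if (ncol(X) < k) stop("fewer than k polymorphic variants in the set")
  pc <- prcomp(X, center = TRUE, scale. = v, rank. = k)
  if (pc$sdev[k] < .Machine$double.eps * 1e3)
    stop("k exceeds the rank of the chromosome-set matrix")
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    lead <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[lead, j] < 0) pc$x[, j] <- -pc$x[, j]
  }
  structure(list(scores = pc$x[, seq_len(k), drop = FALSE],
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 set = chromosome_set, k = as.integer(k)),
            class = "chromosome_set_pcs")
}

#' Estimate gametic phase disequilibrium between chromosome-set scores
#'
#' The core fit: least squares of the target chromosome-set polygenic
#' score on the predictor-set score, an intercept, and the predictor-set
#' principal components. The coefficient on the predictor score is the
#' GPD estimate (theta); under random mating and well-controlled
#' stratification it is null, while assortative mating induces a positive
#' cross-chromosome correlation. The two-sided P value uses the normal
#' (Wald) approximation. A variance-inflation factor of the score term
#' against the PCs is reported, and estimates with `vif` above
#' `vif_warn` carry a collinearity flag (strong score-stratification
#' correlation destabilizes the fit).
#'
#' @param target_pgs standardized score of the target chromosome set.
#' @param predictor_pgs standardized score of the predictor set.
#' @param predictor_pcs a [pca_chromosome_set()] result for the predictor
#'   set (or `NULL` / `k = 0` for an unadjusted fit).
#' @param direction label recording which set predicts which, e.g.
#'   `"even_to_odd"` for target = odd, predictor = even.
#' @param vif_warn collinearity flag threshold on the VIF.
#' @param keep_fit keep residuals and full coefficients on the object.
#' @return object of class `gpd_estimate` with fields `theta`, `se`, `p`,
#'   `direction`, `n`, `n_pcs`, `vif`, `collinear`.
#' @seealso [select_conservative()], [sweep_pc_adjustment()], [run_logo()]
#' @export
estimate_gpd <- function(target_pgs, predictor_pgs, predictor_pcs = NULL,
                         direction = "even_to_odd", vif_warn = 10,
                         keep_fit = FALSE) {
  n <- length(target_pgs)
  stopifnot(length(predictor_pgs) == n)
  P <- if (is.null(predictor_pcs)) matrix(0, n, 0L) else predictor_pcs$scores
  stopifnot(nrow(P) == n)
  X <- cbind(`(Intercept)` = rep(1, n), pgs = as.numeric(predictor_pgs), P)
  fit <- lm.fit(X, as.numeric(target_pgs))
  if (any(is.na(fit$coefficients)))
    stop("rank-deficient design in GPD regression")
  rss <- sum(fit$residuals^2)
  df <- n - ncol(X)
  XtXinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(rss / df * XtXinv[2L, 2L])
  theta <- unname(fit$coefficients["pgs"])
  p <- if (se > 0) 2 * pnorm(-abs(theta / se)) else as.numeric(theta == 0)
  vif <- if (ncol(P) > 0L) {
    r2 <- summary(stats::lm(predictor_pgs ~ P))$r.squared
    1 / max(1 - r2, .Machine$double.eps)
  } else 1
  structure(list(theta = theta, se = se, p = p, direction = direction,
                 n = n, n_pcs = ncol(P), vif = vif,
                 collinear = vif > vif_warn,
                 coefficients = if (keep_fit) fit$coefficients else NULL,
                 residuals = if (keep_fit) fit$residuals else NULL),
            class = "gpd_estimate")
}

#' @export
print.gpd_estimate <- function(x, ...) {
  cat(sprintf("GPD estimate (%s): theta = %.4g, s.e. = %.4g, P = %.3g\n",
              x$direction, x$theta, x$se, x$p))
  cat(sprintf("  n = %d, PCs adjusted = %d, VIF = %.2f%s\n", x$n, x$n_pcs,
              x$vif, if (x$collinear) "  [collinearity flag]" else ""))
  invisible(x)
}

#' @export
coef.gpd_estimate <- function(object, ...) c(theta = object$theta)

#' @export
confint.gpd_estimate <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  m <- matrix(object$theta + c(-1, 1) * z * object$se, 1L)
  dimnames(m) <- list("theta", sprintf("%.1f %%", c((1 - level) / 2,
                                                    1 - (1 - level) / 2) * 100))
  m
}

#' @export
summary.gpd_estimate <- function(object, ...) {
  out <- data.frame(direction = object$direction, theta = object$theta,
                    se = object$se, p = object$p, n = object$n,
                    n_pcs = object$n_pcs, vif = object$vif,
                    collinear = object$collinear)
  class(out) <- c("summary.gpd_estimate", "data.frame")
  out
}

#' Conservative direction selection
#'
#' Of the two directional GPD estimates (even-to-odd and odd-to-even),
#' adopt the one with the larger variance (larger standard error); ties
#' go to the even-to-odd direction.
#'
#' @param est_eo,est_oe `gpd_estimate` objects for the two directions.
#' @return the selected `gpd_estimate`.
#' @export
select_conservative <- function(est_eo, est_oe) {
  if (est_oe$se > est_eo$se) est_oe else est_eo
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs statistic `G = max |d_i - mean(d)| / sd(d)` with the
#' P value from the closed-form t-distribution relation, used to flag
#' transchromosomal imbalance in the per-trait differences between the
#' two directional GPD estimates.
#'
#' @param differences numeric vector, length >= 3.
#' @return list with `G`, `p`, and `outlier` (index of the extreme value).
#' @export
grubbs_test <- function(differences) {
  d <- differences[!is.na(differences)]
  N <- length(d)
  if (N < 3L) stop("Grubbs test needs at least 3 values")
  s <- sd(d)
  if (s == 0) stop("zero standard deviation: Grubbs statistic undefined")
  dev <- abs(d - mean(d))
  G <- max(dev) / s
  q <- N * G^2 / (N - 1)^2
  p <- if (q >= 1) 0 else {
    tt <- sqrt((N - 2) * q / (1 - q))
    min(1, 2 * N * pt(tt, df = N - 2, lower.tail = FALSE))
  }
  list(G = G, p = p, outlier = which.max(abs(differences - mean(d))))
}

#' Sensitivity of the GPD estimate to the number of adjusting PCs
#'
#' Re-fits the GPD regression for each PC count in `k_grid`. A signal
#' driven by assortative mating is stable across the grid, whereas a
#' stratification artifact collapses as PCs are added.
#'
#' @param target_pgs,predictor_pgs standardized chromosome-set scores.
#' @param predictor_pcs a [pca_chromosome_set()] result holding at least
#'   `max(k_grid)` components.
#' @param k_grid integer vector of PC counts (default 0:30).
#' @return data.frame with one row per `k`: `k`, `theta`, `se`, `p`, `vif`.
#' @export
sweep_pc_adjustment <- function(target_pgs, predictor_pgs, predictor_pcs,
                                k_grid = 0:30) {
  stopifnot(max(k_grid) <= predictor_pcs$k)
  rows <- lapply(k_grid, function(k) {
    pcs_k <- if (k == 0L) NULL else
      structure(list(scores = predictor_pcs$scores[, seq_len(k), drop = FALSE],
                     k = k), class = "chromosome_set_pcs")
    e <- estimate_gpd(target_pgs, predictor_pgs, pcs_k)
    data.frame(k = k, theta = e$theta, se = e$se, p = e$p, vif = e$vif)
  })
  do.call(rbind, rows)
}

#' One-cohort GPD analysis from per-variant weights
#'
#' Convenience wrapper running the full per-cohort estimation: computes
#' both chromosome-set scores, both chromosome-set PCAs, fits the GPD
#' regression in both directions (each adjusted for the predictor-side
#' PCs), and applies the conservative direction selection.
#'
#' @param pop the target `population` (scored sample).
#' @param betas per-variant weights or `summary_stats` (see [compute_pgs()]).
#' @param scheme chromosome grouping scheme, see [chromosome_groups()].
#' @param n_pcs number of adjusting PCs per chromosome set.
#' @param variant_subset optional QC-passing variant indices for the PCA.
#' @return list with `eo`, `oe` (both directional `gpd_estimate`s) and
#'   `selected` (the conservative choice).
#' @export
estimate_gpd_cohort <- function(pop, betas, scheme = "odd_even", n_pcs = 20L,
                                variant_subset = NULL) {
  grp <- chromosome_groups(scheme)
  pgs1 <- compute_pgs(pop, betas, grp$set1) # odd-like set
  pgs2 <- compute_pgs(pop, betas, grp$set2) # even-like set
  pcs1 <- pca_chromosome_set(pop, grp$set1, n_pcs, variant_subset)
  pcs2 <- pca_chromosome_set(pop, grp$set2, n_pcs, variant_subset)
  eo <- estimate_gpd(pgs1, pgs2, pcs2, direction = "even_to_odd")
  oe <- estimate_gpd(pgs2, pgs1, pcs1, direction = "odd_to_even")
  list(eo = eo, oe = oe, selected = select_conservative(eo, oe))
}
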