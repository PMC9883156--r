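#' Two-sided Wald P value
#'
#' `p = 2 * pnorm(-|theta / se|)`.
#'
#' @param theta estimate.
#' @param se standard error (> 0).
#' @return P value in (0, 1].
#' @export
wald_p <- function(theta, se) {
  stopifnot(all(se > 0))
  2 * pnorm(-abs(theta / se))
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_traits number of traits tested.
#' @return per-test threshold `alpha / n_traits`.
#' @export
bonferroni_threshold <- function(alpha, n_traits) {
  stopifnot(alpha > 0, alpha < 1, n_traits >= 1)
  alpha / n_traits
}

#' Inverse-variance fixed-effect meta-analysis
#'
#' Combines GPD estimates with weights `w_i = 1 / se_i^2`: the pooled
#' estimate is the weighted mean, its standard error `(sum w_i)^{-1/2}`,
#' and Cochran's `Q = sum w_i (theta_i - theta)^2` tests homogeneity
#' against a chi-square with `k - 1` degrees of freedom.
#'
#' @param estimates list of `gpd_estimate` objects (k >= 1), or a
#'   data.frame with columns `theta` and `se`.
#' @param trait optional trait label carried on the result.
#' @return object of class `gpd_meta`: `theta`, `se`, `p` (two-sided
#'   Wald), `Q`, `p_het` (`NA` when k = 1), `k`, `trait`, plus the
#'   component table.
#' @export
fixed_effect_meta <- function(estimates, trait = NA_character_) {
  comp <- if (is.data.frame(estimates)) estimates else
    do.call(rbind, lapply(estimates, function(e)
      data.frame(theta = e$theta, se = e$se, direction = e$direction,
                 n = e$n, stringsAsFactors = FALSE)))
  k <- nrow(comp)
  stopifnot(k >= 1L)
  if (any(comp$se <= 0)) stop("all component standard errors must be > 0")
  w <- 1 / comp$se^2
  theta <- sum(w * comp$theta) / sum(w)
  se <- 1 / sqrt(sum(w))
  Q <- sum(w * (comp$theta - theta)^2)
  p_het <- if (k >= 2L) pchisq(Q, df = k - 1L, lower.tail = FALSE) else NA_real_
  structure(list(theta = theta, se = se, p = wald_p(theta, se),
                 Q = if (k >= 2L) Q else NA_real_, p_het = p_het,
                 k = k, trait = trait, components = comp),
            class = "gpd_meta")
}

#' @export
print.gpd_meta <- function(x, ...) {
  cat(sprintf("Fixed-effect meta-analysis of %d GPD estimates%s\n", x$k,
              if (is.na(x$trait)) "" else paste0(" [", x$trait, "]")))
  cat(sprintf("  theta = %.4g, s.e. = %.4g, P = %.3g\n", x$theta, x$se, x$p))
  if (x$k >= 2L)
    cat(sprintf("  heterogeneity: Q = %.3g (df = %d), P_het = %.3g\n",
                x$Q, x$k - 1L, x$p_het))
  invisible(x)
}

#' @export
coef.gpd_meta <- function(object, ...) c(theta = object$theta)

#' Assign individuals to folds
#'
#' Seeded uniform random permutation into `folds` groups whose sizes
#' differ by at most one.
#'
#' @param n number of individuals.
#' @param folds number of folds.
#' @param seed optional integer seed.
#' @return integer fold label per individual.
#' @export
assign_folds <- function(n, folds, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(folds >= 2L, n >= folds)
  sample(rep_len(seq_len(folds), n))
}

#' Leave-one-group-out GPD meta-analysis
#'
#' The full pipeline on one cohort: individuals are split into random
#' folds; for each fold, per-variant effects are estimated by [run_gwas()]
#' on the other folds and shrunk by [shrink_effects()]; both
#' chromosome-set scores, chromosome-set PCs and the two directional GPD
#' regressions are computed within the held-out fold; the conservative
#' direction is selected per fold; and the per-fold estimates are pooled
#' by [fixed_effect_meta()]. Both per-direction meta-analyses are also
#' returned for transparency.
#'
#' @param pop a `population`.
#' @param phenotype numeric phenotype vector.
#' @param folds number of folds (default 10).
#' @param covariates optional covariate matrix for the GWAS.
#' @param scheme chromosome grouping scheme.
#' @param n_pcs adjusting PCs per chromosome set (default 20).
#' @param shrinkage shrinkage method passed to [shrink_effects()].
#' @param qc apply [qc_variants()] before analysis (default TRUE).
#' @param trait trait label.
#' @param seed optional integer seed (fold assignment).
#' @return object of class `gpd_logo`: `meta` (conservative-selection
#'   meta), `meta_eo`, `meta_oe`, `folds` (per-fold estimate pairs),
#'   `fold_id`, `trait`.
#' @export
run_logo <- function(pop, phenotype, folds = 10L, covariates = NULL,
                     scheme = "odd_even", n_pcs = 20L,
                     shrinkage = "empirical_bayes", qc = TRUE,
                     trait = NA_character_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_individuals(pop)
  stopifnot(length(phenotype) == n, folds >= 2L)
  keep <- if (qc) qc_variants(pop)$keep else seq_len(n_variants(pop))
  fold_id <- assign_folds(n, folds)
  per_fold <- vector("list", folds)
  for (f in seq_len(folds)) {
    test <- fold_id == f
    train_pop <- subset_population(pop, which(!test), keep_phase = FALSE)
    cv <- if (is.null(covariates)) NULL else covariates[!test, , drop = FALSE]
    ss <- run_gwas(train_pop, phenotype[!test], covariates = cv,
                   variant_subset = keep)
    ss <- shrink_effects(ss, shrinkage)
    test_pop <- subset_population(pop, which(test), keep_phase = FALSE)
    per_fold[[f]] <- estimate_gpd_cohort(test_pop, ss, scheme, n_pcs,
                                         variant_subset = keep)
  }
  sel <- lapply(per_fold, `[[`, "selected")
  structure(list(meta = fixed_effect_meta(sel, trait),
                 meta_eo = fixed_effect_meta(lapply(per_fold, `[[`, "eo"), trait),
                 meta_oe = fixed_effect_meta(lapply(per_fold, `[[`, "oe"), trait),
                 folds = per_fold, fold_id = fold_id, trait = trait,
                 scheme = scheme, n_pcs = n_pcs),
            class = "gpd_logo")
}

#' @export
print.gpd_logo <- function(x, ...) {
  cat(sprintf("Leave-one-group-out GPD analysis (%d folds, scheme %s, %d PCs)\n",
              length(x$folds), x$scheme, x$n_pcs))
  print(x$meta)
  invisible(x)
}

#' @export
coef.gpd_logo <- function(object, ...) coef(object$meta)

#' @export
summary.gpd_logo <- function(object, ...) {
  comp <- object$meta$components
  comp$unit <- sprintf("fold%d", seq_len(nrow(comp)))
  meta_row <- data.frame(theta = object$meta$theta, se = object$meta$se,
                         direction = "selected", n = sum(comp$n),
                         unit = "meta")
  out <- rbind(comp[, c("unit", "theta", "se", "direction", "n")],
               meta_row[, c("unit", "theta", "se", "direction", "n")])
  out$p <- wald_p(out$theta, out$se)
  class(out) <- c("summary.gpd_logo", "data.frame")
  out
}

#' Forest plot of per-fold and pooled GPD estimates
#'
#' @param x a `gpd_logo` (or `gpd_loro`) object.
#' @param level confidence level for the interval bars.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gpd_logo <- function(x, level = 0.95, ...) {
  s <- summary(x)
  z <- qnorm(1 - (1 - level) / 2)
  k <- nrow(s)
  ylim <- rev(seq_len(k))
  plot(s$theta, ylim, xlim = range(s$theta - z * s$se, s$theta + z * s$se),
       yaxt = "n", ylab = "", xlab = expression(theta),
       pch = ifelse(s$unit == "meta", 18, 16), ...)
  segments(s$theta - z * s$se, ylim, s$theta + z * s$se, ylim)
  axis(2, at = ylim, labels = s$unit, las = 1)
  abline(v = 0, lty = 2)
  invisible(x)
}

#' @export
plot.gpd_loro <- plot.gpd_logo

#' Leave-one-region-out GPD meta-analysis
#'
#' For each region, per-variant effects are trained on all other regions,
#' scores and the GPD regression are evaluated within the held-out
#' region, and region estimates are pooled by fixed-effect
#' meta-analysis. Geography-driven homogamy that a random fold split
#' cannot separate from assortative mating is absorbed by the regional
#' hold-out. Regions smaller than `min_region` individuals are excluded
#' with a warning.
#'
#' @inheritParams run_logo
#' @param min_region minimum region size retained.
#' @return object of class `gpd_loro` (same layout as `gpd_logo`, with
#'   regions in place of folds).
#' @export
run_loro <- function(pop, phenotype, covariates = NULL, scheme = "odd_even",
                     n_pcs = 20L, shrinkage = "empirical_bayes", qc = TRUE,
                     trait = NA_character_, min_region = 100L) {
  if (is.null(pop$region)) stop("population carries no region labels")
  regions <- unique(pop$region)
  if (length(regions) < 2L) stop("need at least 2 distinct regions")
  sizes <- table(pop$region)
  small <- names(sizes)[sizes < min_region]
  if (length(small)) {
    warning("excluding regions below minimum size: ", paste(small, collapse = ", "))
    regions <- setdiff(regions, small)
    if (length(regions) < 2L) stop("fewer than 2 regions of sufficient size")
  }
  keep <- if (qc) qc_variants(pop)$keep else seq_len(n_variants(pop))
  per_region <- vector("list", length(regions))
  names(per_region) <- regions
  for (rg in regions) {
    test <- pop$region == rg
    train_pop <- subset_population(pop, which(!test), keep_phase = FALSE)
    cv <- if (is.null(covariates)) NULL else covariates[!test, , drop = FALSE]
    ss <- run_gwas(train_pop, phenotype[!test], covariates = cv,
                   variant_subset = keep)
    ss <- shrink_effects(ss, shrinkage)
    test_pop <- subset_population(pop, which(test), keep_phase = FALSE)
    per_region[[rg]] <- estimate_gpd_cohort(test_pop, ss, scheme, n_pcs,
                                            variant_subset = keep)
  }
  sel <- lapply(per_region, `[[`, "selected")
  structure(list(meta = fixed_effect_meta(sel, trait),
                 meta_eo = fixed_effect_meta(lapply(per_region, `[[`, "eo"), trait),
                 meta_oe = fixed_effect_meta(lapply(per_region, `[[`, "oe"), trait),
                 folds = per_region, regions = regions, trait = trait,
                 scheme = scheme, n_pcs = n_pcs),
            class = c("gpd_loro", "gpd_logo"))
}

#' Subset a population by individual index
#'
#' @param pop a `population`.
#' @param idx integer indices of individuals to keep.
#' @param keep_phase retain the haplotype matrices (set `FALSE` when only
#'   dosages are needed downstream, e.g. inside fold loops).
#' @return a `population` restricted to those individuals.
#' @export
subset_population <- function(pop, idx, keep_phase = TRUE) {
  keep_phase <- keep_phase && !is.null(pop$hap1)
  new_population(pop$genotypes[idx, , drop = FALSE], pop$variants,
                 hap1 = if (keep_phase) pop$hap1[idx, , drop = FALSE],
                 hap2 = if (keep_phase) pop$hap2[idx, , drop = FALSE],
                 sex = pop$sex[idx], subpop = pop$subpop[idx],
                 region = pop$region[idx], generation = pop$generation,
                 pheno_offset = pop$pheno_offset[idx])
}
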