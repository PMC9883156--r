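#' Theory parameters for the expected GPD
#'
#' Bundles the parameters of the closed-form expected gametic phase
#' disequilibrium under equilibrium assortative mating, and their derived
#' quantities: `rho = r * h_eq2` (the genetic spousal correlation),
#' `f_eq = h_snp2 / h_eq2` (the fraction of equilibrium heritability
#' captured by genotyped variants) and `f0 = f_eq / (1 - rho)` (its
#' base-generation counterpart, the printed first-order approximation).
#'
#' @param r spousal phenotype correlation.
#' @param h_eq2 equilibrium heritability, in (0, 1].
#' @param h_snp2 SNP-based heritability, `0 <= h_snp2 <= h_eq2`.
#' @param M number of causal variants (>= 1).
#' @param n GWAS training sample size (>= 1; `Inf` allowed for the
#'   large-sample limit).
#' @return object of class `theory_params`.
#' @export
theory_params <- function(r, h_eq2, h_snp2, M, n) {
  stopifnot(h_snp2 >= 0, h_snp2 <= h_eq2, h_eq2 <= 1, M >= 1, n >= 1)
  rho <- r * h_eq2
  if (rho >= 1) stop("rho = r * h_eq2 must be < 1")
  f_eq <- if (h_eq2 > 0) h_snp2 / h_eq2 else 0
  structure(list(r = r, h_eq2 = h_eq2, h_snp2 = h_snp2, M = M, n = n,
                 rho = rho, f_eq = f_eq, f0 = f_eq / (1 - rho)),
            class = "theory_params")
}

#' Closed-form expected GPD under equilibrium assortative mating
#'
#' Evaluates
#' \deqn{\theta = \frac{\rho f_0}{2 - \rho(2 - f_0)}
#'   \left[1 + \frac{M(1-\rho)}{n h_{eq}^2}
#'   \left\{1 + \frac{\rho f_0}{2(1-\rho)}\right\}^{-3}\right]^{-1}}
#' with \eqn{\rho = r h_{eq}^2}, \eqn{f_0 \approx f_{eq}/(1-\rho)},
#' \eqn{f_{eq} = h_{snp}^2 / h_{eq}^2}. The first factor is the
#' infinite-sample limit (returned as the `"limit"` attribute); the
#' second attenuates it for the finite GWAS sample size through the
#' noise in estimated per-variant effects, so the expected value is
#' always at or below the limit and shrinks as the causal-variant count
#' `M` grows at fixed `n`.
#'
#' @param params a [theory_params()] object (or arguments to build one,
#'   passed through `...`).
#' @param ... alternative to `params`: `r`, `h_eq2`, `h_snp2`, `M`, `n`.
#' @return expected theta, with the infinite-n limit in `attr(, "limit")`.
#' @export
expected_gpd <- function(params = NULL, ...) {
  if (is.null(params)) params <- theory_params(...)
  rho <- params$rho; f0 <- params$f0
  denom <- 2 - rho * (2 - f0)
  if (denom <= 0) stop("nonpositive denominator: parameters outside the model's domain")
  lim <- rho * f0 / denom
  finite <- if (is.infinite(params$n)) 1 else
    1 / (1 + params$M * (1 - rho) / (params$n * params$h_eq2) *
           (1 + rho * f0 / (2 * (1 - rho)))^-3)
  structure(lim * finite, limit = lim)
}

#' Expected GPD for a table of trait parameters
#'
#' @param table data.frame with columns `r`, `h_eq2`, `h_snp2`, `M`, `n`
#'   (and optionally `trait`), one row per trait.
#' @return the table with `theta_theory` and `theta_limit` columns added.
#' @export
expected_gpd_table <- function(table) {
  stopifnot(all(c("r", "h_eq2", "h_snp2", "M", "n") %in% names(table)))
  res <- lapply(seq_len(nrow(table)), function(i)
    expected_gpd(theory_params(table$r[i], table$h_eq2[i], table$h_snp2[i],
                               table$M[i], table$n[i])))
  table$theta_theory <- vapply(res, as.numeric, numeric(1))
  table$theta_limit <- vapply(res, attr, numeric(1), "limit")
  table
}

#' Exact equilibrium GPD for a complete causal score
#'
#' For a score built from the complete causal-variant set with true
#' effects, the equilibrium cross-half-genome correlation has an exact
#' infinitesimal-model form, \eqn{\theta_\infty = \rho / (2 - \rho)} with
#' \eqn{\rho = r h_{eq}^2}, obtained from the gametic variance-component
#' recursions (equilibrium cross-set covariance \eqn{\rho\sigma^2/4},
#' per-set variance \eqn{V/2 + \rho\sigma^2/4},
#' \eqn{\sigma^2 = V/(1-\rho)}). This equals [expected_gpd()] at
#' \eqn{f_0 = 1}: the approximation \eqn{f_0 \approx f_{eq}/(1-\rho)}
#' used there is a first-order conversion suited to sparse tagging
#' scores and overstates the complete-score limit as \eqn{\rho} grows.
#' Used to validate the forward simulator.
#'
#' @param r spousal phenotype correlation.
#' @param h_eq2 equilibrium heritability.
#' @return the exact limit `rho / (2 - rho)`.
#' @export
equilibrium_gpd_exact <- function(r, h_eq2) {
  rho <- r * h_eq2
  if (rho >= 1) stop("rho = r * h_eq2 must be < 1")
  rho / (2 - rho)
}
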