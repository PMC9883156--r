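test_that("chromosome-set PCA separates diverged subpopulations", {
  set.seed(1)
  pop <- suppressWarnings(
    simulate_stratified(300, K = 2, divergence = 0.1, trait_shift = 0))
  pcs <- pca_chromosome_set(pop, chromosome_groups("odd_even")$set2, k = 5)
  lab <- as.integer(factor(pop$subpop))
  expect_gt(abs(cor(pcs$scores[, 1], lab)), 0.9)
  expect_identical(dim(pcs$scores), c(600L, 5L))
})

test_that("chromosome-set PCA honors k = 0 and is functionally deterministic", {
  set.seed(2)
  pop <- simulate_founders(100, make_spec(60))
  p0 <- pca_chromosome_set(pop, 1:22, k = 0)
  expect_identical(ncol(p0$scores), 0L)
  # duplicated individuals receive identical PC rows
  pop2 <- subset_population(pop, c(1:100, 1:10))
  pcs <- pca_chromosome_set(pop2, 1:22, k = 3)
  expect_equal(pcs$scores[101:110, ], pcs$scores[1:10, ], tolerance = 1e-9)
  # deterministic sign convention: two runs agree exactly
  pcs_b <- pca_chromosome_set(pop2, 1:22, k = 3)
  expect_identical(pcs$scores, pcs_b$scores)
  expect_error(pca_chromosome_set(pop, 1:22, k = 200), "k")
})

test_that("GPD regression reduces to identity and orthogonal cases", {
  set.seed(3)
  x <- rnorm(500); x <- (x - mean(x)) / sd(x)
  fit <- estimate_gpd(x, x, NULL)
  expect_equal(fit$theta, 1, tolerance = 1e-12)
  expect_lt(fit$se, 1e-12)
  # predictor constructed exactly orthogonal to target (after centering)
  y <- rnorm(500)
  y <- y - mean(y)
  xo <- x - sum(x * y) / sum(y^2) * y
  fit0 <- estimate_gpd(y, xo, NULL)
  expect_lt(abs(fit0$theta), 1e-12)
})

test_that("GPD regression matches the normal-equations oracle on a fixture", {
  target <- c(0.3, -1.2, 0.7, 2.1, -0.4, -1.0, 0.9, -0.5)
  predictor <- c(0.1, -0.9, 1.1, 1.8, 0.2, -1.3, 0.4, -0.6)
  pcs <- structure(list(scores = cbind(c(1, 2, 0, -1, 1, 0, -2, 1),
                                       c(0.5, -0.5, 1, 0, -1, 0.3, 0.2, -0.1)),
                        k = 2L), class = "chromosome_set_pcs")
  fit <- estimate_gpd(target, predictor, pcs)
  X <- cbind(1, predictor, pcs$scores)
  bh <- solve(t(X) %*% X, t(X) %*% target)
  res <- target - X %*% bh
  s2 <- sum(res^2) / (8 - ncol(X))
  se <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(fit$theta, bh[2], tolerance = 1e-10)
  expect_equal(fit$se, se, tolerance = 1e-10)
  expect_equal(fit$p, 2 * pnorm(-abs(bh[2] / se)), tolerance = 1e-10)
  expect_identical(fit$n_pcs, 2L)
})

test_that("GPD estimate is invariant to PC sign flips", {
  set.seed(4)
  pop <- simulate_founders(300, make_spec(80))
  w <- rnorm(80)
  grp <- chromosome_groups("odd_even")
  p1 <- compute_pgs(pop, w, grp$set1)
  p2 <- compute_pgs(pop, w, grp$set2)
  pcs <- pca_chromosome_set(pop, grp$set2, k = 4)
  f1 <- estimate_gpd(p1, p2, pcs)
  pcs$scores <- pcs$scores %*% diag(c(-1, 1, -1, 1))
  f2 <- estimate_gpd(p1, p2, pcs)
  expect_equal(f1$theta, f2$theta, tolerance = 1e-12)
  expect_equal(f1$se, f2$se, tolerance = 1e-12)
})

test_that("collinearity between score and PCs raises the VIF flag", {
  set.seed(5)
  x <- rnorm(200)
  pcs <- structure(list(scores = cbind(x + rnorm(200, 0, 0.01), rnorm(200)),
                        k = 2L), class = "chromosome_set_pcs")
  fit <- estimate_gpd(rnorm(200), x, pcs)
  expect_true(fit$collinear)
  expect_gt(fit$vif, 10)
})

test_that("conservative selection returns the larger-variance direction", {
  eo <- structure(list(theta = 0.02, se = 0.0030, p = 0.1,
                       direction = "even_to_odd", n = 10L, n_pcs = 0L,
                       vif = 1, collinear = FALSE), class = "gpd_estimate")
  oe <- structure(list(theta = 0.01, se = 0.0025, p = 0.1,
                       direction = "odd_to_even", n = 10L, n_pcs = 0L,
                       vif = 1, collinear = FALSE), class = "gpd_estimate")
  expect_identical(select_conservative(eo, oe)$direction, "even_to_odd")
  # tie goes to even_to_odd
  oe$se <- 0.0030
  expect_identical(select_conservative(eo, oe)$direction, "even_to_odd")
  # property: never the smaller s.e.
  set.seed(6)
  for (i in 1:100) {
    eo$se <- runif(1); oe$se <- runif(1)
    sel <- select_conservative(eo, oe)
    expect_gte(sel$se, max(eo$se, oe$se) - 1e-15)
  }
})

test_that("Grubbs statistic and P value follow the closed form", {
  d <- c(0.1, -0.2, 0.05, 0.15, 2.5)
  g <- grubbs_test(d)
  N <- 5
  expect_equal(g$G, max(abs(d - mean(d))) / sd(d), tolerance = 1e-12)
  expect_identical(g$outlier, 5L)
  # invert the textbook t-quantile critical-value relation at alpha = p
  tcrit <- qt(g$p / (2 * N), df = N - 2, lower.tail = FALSE)
  G_from_p <- (N - 1) / sqrt(N) * sqrt(tcrit^2 / (N - 2 + tcrit^2))
  expect_equal(g$G, G_from_p, tolerance = 1e-9)
  # a single deviant among many zeros is flagged
  x <- c(rep(0, 80), 1)
  gz <- grubbs_test(x)
  expect_identical(gz$outlier, 81L)
  expect_lt(gz$p, 1e-10)
  expect_error(grubbs_test(c(1, 2)), "at least 3")
  expect_error(grubbs_test(rep(1, 5)), "zero")
})

test_that("Grubbs test is calibrated under the normal null", {
  set.seed(7)
  rej <- mean(replicate(1000, grubbs_test(rnorm(10))$p < 0.05))
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lt(abs(rej - 0.05), 3 * se + 0.005)
})

test_that("PC sweep reproduces the unadjusted fit at k = 0", {
  set.seed(8)
  pop <- simulate_founders(400, make_spec(120))
  w <- rnorm(120)
  grp <- chromosome_groups("odd_even")
  p1 <- compute_pgs(pop, w, grp$set1)
  p2 <- compute_pgs(pop, w, grp$set2)
  pcs <- pca_chromosome_set(pop, grp$set2, k = 10)
  sw <- sweep_pc_adjustment(p1, p2, pcs, k_grid = 0:10)
  expect_identical(nrow(sw), 11L)
  un <- estimate_gpd(p1, p2, NULL)
  expect_equal(sw$theta[1], un$theta, tolerance = 1e-12)
  expect_equal(sw$se[1], un$se, tolerance = 1e-12)
  k5 <- estimate_gpd(p1, p2, structure(list(
    scores = pcs$scores[, 1:5], k = 5L), class = "chromosome_set_pcs"))
  expect_equal(sw$theta[6], k5$theta, tolerance = 1e-12)
})

test_that("gpd_estimate methods expose the fit", {
  set.seed(9)
  x <- rnorm(100); y <- 0.3 * x + rnorm(100)
  fit <- estimate_gpd(y, x, NULL)
  expect_named(coef(fit), "theta")
  ci <- confint(fit)
  expect_true(ci[1] < fit$theta && fit$theta < ci[2])
  expect_output(print(fit), "GPD estimate")
  s <- summary(fit)
  expect_identical(s$n, 100L)
})
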