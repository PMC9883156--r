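test_that("founders are drawn under Hardy-Weinberg at the nominal frequencies", {
  pop <- simulate_founders(10000, variant_spec(1L, 0.5), seed = 1)
  expect_equal(mean(pop$genotypes), 1.0, tolerance = 0.03)
  # heterozygote fraction 2pq = 0.5 within 5 s.e.
  het <- mean(pop$genotypes == 1L)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(het - 0.5), 5 * se)
  # phase consistency
  expect_identical(pop$hap1 + pop$hap2, pop$genotypes)
})

test_that("founder simulation is deterministic under a fixed seed", {
  spec <- variant_spec(rep_len(1:22, 200), 0.3)
  a <- simulate_founders(5000, spec, seed = 42)
  b <- simulate_founders(5000, spec, seed = 42)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$hap1, b$hap1)
})

test_that("invalid allele frequencies are rejected", {
  spec <- variant_spec(1:2, c(0.5, 1.0))
  expect_error(simulate_founders(10, spec), "frequencies")
})

test_that("architecture sampling matches its contract", {
  set.seed(3)
  pop <- simulate_founders(50, make_spec(300))
  arch <- sample_architecture(pop, 300, 0.5, seed = 4)
  expect_identical(arch$causal_index, 1:300)       # exhaustive sampling
  expect_error(sample_architecture(pop, 301, 0.5), "exceeds")
  # the study's dummy-trait configuration: 10,000 standard-normal effects
  pop2 <- simulate_founders(10, make_spec(10000), seed = 5)
  arch2 <- sample_architecture(pop2, 10000, 0.5, seed = 6)
  expect_identical(arch2$M, 10000L)
  expect_identical(arch2$h2, 0.5)
  expect_lt(abs(mean(arch2$beta)), 3 / sqrt(10000))
})

test_that("phenotype model y = g + e realizes the requested heritability", {
  set.seed(7)
  pop <- simulate_founders(20000, make_spec(500))
  arch <- sample_architecture(pop, 500, 0.5)
  ph <- simulate_phenotype(pop, arch)
  expect_equal(ph$y, ph$g + ph$e)
  expect_equal(var(ph$g) / var(ph$y), 0.5, tolerance = 0.03)
  # h2 = 1: no residual
  arch1 <- arch; arch1$h2 <- 1
  ph1 <- simulate_phenotype(pop, arch1)
  expect_identical(ph1$e, numeric(20000))
  expect_equal(ph1$y, ph1$g)
  # null architecture: zero genetic values
  arch0 <- arch; arch0$beta <- rep(0, 500)
  expect_identical(simulate_phenotype(pop, arch0)$g, numeric(20000))
})

test_that("mate pairing hits the target spousal correlation", {
  set.seed(8)
  y <- rnorm(10000)
  # r = 1: rank-adjacent partners
  p1 <- pair_mates(y, 1)
  o <- order(y)
  expect_true(all(abs(match(p1[, 1], o) - match(p1[, 2], o)) == 1L))
  # r = 0: near-zero correlation
  p0 <- pair_mates(y, 0)
  expect_lt(abs(cor(y[p0[, 1]], y[p0[, 2]])), 0.05)
  # r = 0.5 calibration over 20 replicates
  r_hat <- replicate(20, {
    p <- pair_mates(y, 0.5)
    cor(y[p[, 1]], y[p[, 2]])
  })
  expect_equal(mean(r_hat), 0.5, tolerance = 0.03)
  # negative r
  rn <- replicate(20, {
    p <- pair_mates(y, -0.5)
    cor(y[p[, 1]], y[p[, 2]])
  })
  expect_equal(mean(rn), -0.5, tolerance = 0.05)
  expect_error(pair_mates(rnorm(11), 0.5), "even")
})

test_that("pairs are disjoint and cover each individual at most once", {
  set.seed(9)
  y <- rnorm(1000)
  for (r in c(0, 0.5, 1)) {
    p <- pair_mates(y, r)
    expect_false(any(duplicated(c(p))))
  }
  p <- pair_mates(y, 0.5, sex = rep_len(c("M", "F"), 1000))
  expect_false(any(duplicated(c(p))))
})

test_that("reproduction follows Mendelian transmission", {
  set.seed(10)
  spec <- make_spec(60, n_chrom = 3L)
  pop <- simulate_founders(200, spec)
  # force two parents homozygous alt at variant 1
  pop$hap1[1:2, 1] <- 1L; pop$hap2[1:2, 1] <- 1L
  pop$genotypes <- pop$hap1 + pop$hap2
  off <- reproduce(pop, cbind(c(1, 3), c(2, 4)), offspring_per_pair = 2)
  expect_true(all(off$genotypes[1:2, 1] == 2L))
  expect_identical(off$generation, 1L)
  expect_error(reproduce(pop, cbind(1, 999)), "outside")
})

test_that("zero crossover rate transmits intact parental chromosomes", {
  set.seed(11)
  pop <- simulate_founders(20, make_spec(40, n_chrom = 2L))
  off <- reproduce(pop, cbind(1:5, 6:10), offspring_per_pair = 1,
                   crossover_rate = 0)
  for (ch in 1:2) {
    idx <- which(pop$variants$chrom == ch)
    for (i in 1:5) {
      gam <- off$hap1[i, idx]  # gamete from parent i
      expect_true(identical(gam, pop$hap1[i, idx]) ||
                    identical(gam, pop$hap2[i, idx]))
    }
  }
})

test_that("allele frequencies are conserved in expectation across generations", {
  set.seed(12)
  spec <- make_spec(100, freq = rep(0.5, 100))
  pop <- simulate_founders(2000, spec)
  off <- reproduce(pop, pair_mates(rnorm(2000), 0), offspring_per_pair = 2)
  af <- colMeans(off$genotypes) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 2000))
  expect_true(all(abs(af - 0.5) < 5 * se))
})

test_that("evolve_under_am with zero generations returns the founders", {
  set.seed(13)
  pop <- simulate_founders(100, make_spec(50))
  arch <- sample_architecture(pop, 50, 0.8)
  out <- evolve_under_am(pop, arch, mating_design(0.5, 0))
  expect_identical(out$genotypes, pop$genotypes)
  expect_identical(out$generation, 0L)
})

test_that("random mating leaves cross-chromosome genetic values uncorrelated", {
  set.seed(14)
  pop <- simulate_founders(4000, make_spec(200))
  arch <- sample_architecture(pop, 200, 0.8)
  fin <- evolve_under_am(pop, arch, mating_design(0, 3))
  sc <- true_half_scores(fin, arch)
  expect_lt(abs(cor(sc$odd, sc$even)), 4 / sqrt(4000))
})

test_that("assortative mating induces a detectable positive GPD", {
  set.seed(15)
  pop <- simulate_founders(2000, make_spec(300))
  arch <- sample_architecture(pop, 300, 0.8)
  fin <- evolve_under_am(pop, arch, mating_design(0.6, 5))
  sc <- true_half_scores(fin, arch)
  est <- estimate_gpd(sc$odd, sc$even, NULL)
  expect_gt(est$theta, 3 * est$se)
  h <- attr(fin, "history")
  expect_equal(nrow(h), 5L)
  expect_equal(mean(h$spousal_r), 0.6, tolerance = 0.08)
})

test_that("stratified simulation separates subpopulations on PC1", {
  set.seed(16)
  pop <- suppressWarnings(
    simulate_stratified(400, K = 2, divergence = 0.1, trait_shift = 0))
  pcs <- pca_chromosome_set(pop, 1:22, k = 2)
  lab <- as.integer(factor(pop$subpop))
  expect_gt(abs(cor(pcs$scores[, 1], lab)), 0.9)
  # near-zero divergence: PC1 does not separate the labels
  pop0 <- suppressWarnings(
    simulate_stratified(400, K = 2, divergence = 1e-4, trait_shift = 0))
  pcs0 <- pca_chromosome_set(pop0, 1:22, k = 2)
  lab0 <- as.integer(factor(pop0$subpop))
  expect_lt(abs(cor(pcs0$scores[, 1], lab0)), 0.3)
  # trait shift is recorded as a phenotype offset
  pop2 <- suppressWarnings(
    simulate_stratified(100, K = 2, divergence = 0.01, trait_shift = 0.5))
  expect_identical(unique(pop2$pheno_offset), c(0, 0.5))
})

test_that("assortative mating builds excess homozygosity at causal variants", {
  set.seed(17)
  spec <- make_spec(50, freq = runif(50, 0.2, 0.8))
  pop <- simulate_founders(2000, spec)
  arch <- sample_architecture(pop, 50, 0.9)
  fin <- evolve_under_am(pop, arch, mating_design(0.9, 4))
  f <- vapply(arch$causal_index, function(j)
    inbreeding_coefficient(fin$genotypes[, j]), numeric(1))
  expect_gt(mean(f), 0)
})
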