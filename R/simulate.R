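#' Simulate a randomly mating founder population
#'
#' Draws phased diploid genotypes under Hardy-Weinberg equilibrium: each
#' haplotype allele is an independent Bernoulli draw at the variant's
#' nominal alt-allele frequency. Haplotype phase is retained so the
#' population can be transmitted through [reproduce()]. Sexes are assigned
#' alternately (M, F, M, F, ...).
#'
#' @param n number of individuals (>= 2).
#' @param variants variant table as produced by [variant_spec()]; the
#'   `freq` column gives per-variant alt-allele frequencies, all in (0, 1).
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return a [new_population()] object at generation 0.
#' @examples
#' pop <- simulate_founders(100, variant_spec(rep(1:2, each = 5), 0.5), seed = 1)
#' @export
simulate_founders <- function(n, variants, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 2)
  p <- variants$freq
  if (any(p <= 0 | p >= 1)) stop("allele frequencies must lie strictly in (0, 1)")
  m <- length(p)
  hap1 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
  hap2 <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
  new_population(hap1 + hap2, variants, hap1 = hap1, hap2 = hap2,
                 sex = rep_len(c("M", "F"), n), generation = 0L)
}

#' Sample a polygenic trait architecture
#'
#' Chooses `M` causal variants uniformly without replacement and draws
#' their effect sizes (on the standardized-genotype scale) from a standard
#' normal distribution.
#'
#' @param pop a `population`.
#' @param M number of causal variants (`M <= n_variants(pop)`).
#' @param h2 narrow-sense heritability in (0, 1].
#' @param seed optional integer seed.
#' @return an object of class `trait_architecture` with fields
#'   `causal_index`, `beta`, `h2`, `M`.
#' @export
sample_architecture <- function(pop, M, h2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (M > n_variants(pop)) stop("M exceeds the number of variants")
  stopifnot(h2 > 0, h2 <= 1)
  structure(list(causal_index = sort(sample.int(n_variants(pop), M)),
                 beta = rnorm(M), h2 = h2, M = as.integer(M)),
            class = "trait_architecture")
}

#' Simulate an additive phenotype
#'
#' Phenotypes follow `y = g + e` with genetic values
#' `g_j = sum_i W_ij beta_i`, where `W_ij = (x_ij - 2 p_i) / sqrt(2 p_i (1
#' - p_i))` standardizes dosages at the nominal (founder) allele
#' frequencies, and residuals are drawn `e ~ N(0, Var(g) (1 - h2) / h2)` so
#' the realized heritability matches `h2`. Frequencies are frozen at
#' founder values so genetic values are comparable across generations.
#'
#' With `arch = NULL` the trait is purely environmental: `y = offset +
#' N(0, 1)`; this is the construction used for stratification-confounded
#' null traits, where a subpopulation trait shift but no causal variant
#' drives the phenotype.
#'
#' @param pop a `population`.
#' @param arch a `trait_architecture`, or `NULL` for a purely
#'   environmental trait.
#' @param seed optional integer seed.
#' @param offset per-individual phenotype offset; defaults to the
#'   population's `pheno_offset` when present.
#' @return object of class `simulated_phenotype`: list with `y`, `g`, `e`.
#' @export
simulate_phenotype <- function(pop, arch, seed = NULL, offset = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_individuals(pop)
  if (is.null(offset)) offset <- pop$pheno_offset
  if (is.null(offset)) offset <- 0
  if (is.null(arch)) {
    e <- rnorm(n)
    g <- numeric(n)
  } else {
    p <- pop$variants$freq[arch$causal_index]
    if (any(p <= 0 | p >= 1))
      stop("causal variant with frequency 0 or 1 cannot be standardized")
    sdv <- sqrt(2 * p * (1 - p))
    X <- pop$genotypes[, arch$causal_index, drop = FALSE]
    if (anyNA(X)) { # mean-impute at nominal frequency
      for (j in which(colSums(is.na(X)) > 0L))
        X[is.na(X[, j]), j] <- 2 * p[j]
    }
    w <- arch$beta / sdv
    g <- drop(X %*% w) - sum(2 * p * w)
    vg <- var(g)
    ve <- vg * (1 - arch$h2) / arch$h2
    e <- if (ve > 0) rnorm(n, 0, sqrt(ve)) else numeric(n)
  }
  structure(list(y = g + e + offset, g = g, e = e),
            class = "simulated_phenotype")
}

#' Pair individuals into couples with a target phenotype correlation
#'
#' Mate matching uses a calibrated noisy-rank mechanism: each individual
#' receives a matching score `s = a z + sqrt(1 - a^2) eps` with `z` the
#' standardized phenotype, `eps` standard normal, and `a(r) = sqrt(|r|)`.
#' Rank-adjacent pairing on `s` then yields a spousal phenotype
#' correlation of `a^2 = r` in expectation (under rank matching the two
#' partners share essentially the same score `s`, and `E[z | s] = a s`, so
#' `Cov(z, z') = a^2`). `r = 0` is uniform random pairing and `r = 1`
#' exact rank matching. Negative `r` pairs opposite-sorted groups.
#'
#' @param pheno numeric phenotype vector; length must be even.
#' @param r target spousal phenotype correlation in \[-1, 1\].
#' @param seed optional integer seed.
#' @param sex optional labels; when given, couples are formed
#'   male-female by matching ranks between the two sexes.
#' @return integer matrix with two columns, one row per disjoint couple.
#' @export
pair_mates <- function(pheno, r, seed = NULL, sex = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(pheno)
  if (n %% 2L != 0L) stop("number of individuals must be even")
  if (abs(r) > 1) stop("|r| must be <= 1")
  z <- as.numeric(scale(pheno))
  if (!all(is.finite(z))) z <- numeric(n) # constant phenotype: random pairing
  a <- sqrt(abs(r))
  s <- a * z + sqrt(1 - a^2) * rnorm(n)
  if (is.null(sex)) {
    if (r >= 0) {
      ord <- order(s)
      return(cbind(ord[seq(1L, n, 2L)], ord[seq(2L, n, 2L)]))
    }
    grp <- sample.int(n) # random halves, opposite sort order
    g1 <- grp[seq_len(n / 2L)]; g2 <- grp[(n / 2L + 1L):n]
    return(cbind(g1[order(s[g1])], g2[order(s[g2], decreasing = TRUE)]))
  }
  males <- which(sex == "M"); females <- which(sex != "M")
  k <- min(length(males), length(females))
  if (length(males) != length(females))
    warning("unequal sex counts; pairing the first ", k, " ranks of each")
  mo <- males[order(s[males])][seq_len(k)]
  fo <- females[order(s[females], decreasing = r < 0)][seq_len(k)]
  cbind(mo, fo, deparse.level = 0)
}

#' Produce offspring by Mendelian transmission
#'
#' Each offspring receives one recombinant gamete from each parent.
#' Chromosomes assort independently; within a chromosome, crossovers
#' follow a Poisson process along the physical map with a configurable
#' expected number of crossovers per chromosome (default 1), placed
#' uniformly. Sexes are assigned alternately at birth.
#'
#' @param pop a phased `population` (must carry `hap1`/`hap2`).
#' @param pairs two-column index matrix from [pair_mates()].
#' @param offspring_per_pair offspring per couple (default 2, which keeps
#'   the census size constant).
#' @param seed optional integer seed.
#' @param crossover_rate expected crossovers per chromosome per meiosis.
#' @return a new phased `population` with `generation` incremented.
#' @export
reproduce <- function(pop, pairs, offspring_per_pair = 2L, seed = NULL,
                      crossover_rate = 1) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pop$hap1)) stop("population has no haplotype phase; cannot transmit")
  pairs <- as.matrix(pairs)
  if (any(pairs < 1L) || any(pairs > n_individuals(pop)))
    stop("pairs reference individuals outside the population")
  if (nrow(pairs) < 2L) stop("fewer than 2 mating pairs; population collapsed")
  stopifnot(offspring_per_pair >= 1L)
  n_off <- nrow(pairs) * offspring_per_pair
  par_a <- rep(pairs[, 1L], each = offspring_per_pair)
  par_b <- rep(pairs[, 2L], each = offspring_per_pair)
  m <- n_variants(pop)
  off1 <- matrix(0L, n_off, m)
  off2 <- matrix(0L, n_off, m)
  chrom <- pop$variants$chrom
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos <- pop$variants$pos[idx]
    off1[, idx] <- .gamete(pop$hap1, pop$hap2, idx, pos, par_a, crossover_rate)
    off2[, idx] <- .gamete(pop$hap1, pop$hap2, idx, pos, par_b, crossover_rate)
  }
  subpop <- if (!is.null(pop$subpop)) pop$subpop[par_a] else NULL
  region <- if (!is.null(pop$region)) pop$region[par_a] else NULL
  off_shift <- if (!is.null(pop$pheno_offset)) pop$pheno_offset[par_a] else NULL
  new_population(off1 + off2, pop$variants, hap1 = off1, hap2 = off2,
                 sex = rep_len(c("M", "F"), n_off), subpop = subpop,
                 region = region, generation = pop$generation + 1L,
                 pheno_offset = off_shift)
}

# One recombinant gamete per entry of parent_idx, restricted to the
# variant columns `idx` of a single chromosome. Crossover counts between
# adjacent variants are independent Poisson increments of the process, so
# the parental-haplotype source at each variant is (start + cumulative
# count) mod 2, computed fully vectorized.
.gamete <- function(hap1, hap2, idx, pos, parent_idx, rate) {
  g <- length(parent_idx)
  k <- length(idx)
  start <- rbinom(g, 1L, 0.5)
  if (k > 1L && rate > 0) {
    d <- diff(pos)
    L <- sum(d)
    P <- matrix(rpois(g * (k - 1L), rep(rate * d / L, each = g)), g, k - 1L)
    cum <- P %*% upper.tri(diag(k - 1L), diag = TRUE)
    src <- (start + cbind(0L, cum)) %% 2L
  } else {
    src <- matrix(start, g, k)
  }
  H1 <- hap1[parent_idx, idx, drop = FALSE]
  H2 <- hap2[parent_idx, idx, drop = FALSE]
  out <- H1 * (1L - src) + H2 * src
  storage.mode(out) <- "integer"
  out
}

#' Mating design parameters
#'
#' @param r target spousal phenotype correlation in \[-1, 1\].
#' @param generations number of generations of mating (>= 0).
#' @param offspring_per_pair offspring per couple.
#' @return object of class `mating_design`.
#' @export
mating_design <- function(r, generations, offspring_per_pair = 2L) {
  if (abs(r) > 1) stop("|r| must be <= 1")
  stopifnot(generations >= 0L, offspring_per_pair >= 1L)
  structure(list(r = r, generations = as.integer(generations),
                 offspring_per_pair = as.integer(offspring_per_pair)),
            class = "mating_design")
}

#' Evolve a population under assortative mating
#'
#' Iterates phenotype simulation, phenotype-correlated mate pairing and
#' Mendelian reproduction for `design$generations` generations. When the
#' population carries subpopulation labels, mating is endogamous (couples
#' form within subpopulations). Per-generation diagnostics (realized
#' spousal correlation, Var(g), realized heritability) are recorded in the
#' `history` attribute, and the final generation's phenotype is attached
#' as `$phenotype`.
#'
#' @param founders a phased `population`.
#' @param arch a `trait_architecture` (or `NULL` for an environmental trait).
#' @param design a [mating_design()].
#' @param seed optional integer seed.
#' @param crossover_rate expected crossovers per chromosome per meiosis.
#' @return the final-generation `population`.
#' @export
evolve_under_am <- function(founders, arch, design, seed = NULL,
                            crossover_rate = 1) {
  if (!is.null(seed)) set.seed(seed)
  pop <- founders
  hist <- vector("list", design$generations)
  for (gen in seq_len(design$generations)) {
    ph <- simulate_phenotype(pop, arch)
    pairs <- .pair_within_groups(ph$y, design$r, pop$sex, pop$subpop)
    if (nrow(pairs) < 2L) stop("population collapsed below 2 mating pairs")
    sp_r <- suppressWarnings(cor(ph$y[pairs[, 1L]], ph$y[pairs[, 2L]]))
    hist[[gen]] <- data.frame(generation = pop$generation,
                              spousal_r = sp_r, var_g = var(ph$g),
                              h2_realized = var(ph$g) / var(ph$y))
    pop <- reproduce(pop, pairs, design$offspring_per_pair,
                     crossover_rate = crossover_rate)
  }
  pop$phenotype <- simulate_phenotype(pop, arch)
  attr(pop, "history") <- do.call(rbind, hist)
  pop
}

.pair_within_groups <- function(y, r, sex, subpop) {
  if (is.null(subpop)) return(pair_mates(y, r, sex = sex))
  out <- lapply(unique(subpop), function(sp) {
    idx <- which(subpop == sp)
    idx[pair_mates(y[idx], r, sex = sex[idx])]
  })
  do.call(rbind, lapply(out, function(m) matrix(m, ncol = 2L)))
}

#' Simulate a discretely stratified population
#'
#' Draws `K` subpopulations whose allele frequencies diverge from shared
#' ancestral frequencies under a Balding-Nichols model: subpopulation
#' frequencies are Beta-distributed around the ancestral frequency with
#' between-subpopulation variance `divergence * p * (1 - p)` (the
#' `divergence` parameter plays the role of Fst). Drawn frequencies are
#' truncated to (0.01, 0.99), matching a MAF >= 1\% variant universe.
#' Each subpopulation receives a phenotype offset (`trait_shift`), stored
#' as the population's `pheno_offset`, and subpopulation labels double as
#' region labels for leave-one-region-out analyses. Mating downstream is
#' endogamous within subpopulations.
#'
#' @param n_per_subpop individuals per subpopulation.
#' @param K number of subpopulations (>= 2).
#' @param divergence Balding-Nichols divergence (Fst-like), > 0.
#' @param trait_shift per-subpopulation phenotype offset in phenotypic
#'   s.d. units: either a length-`K` vector, or a scalar step so that
#'   subpopulation k is shifted by `trait_shift * (k - 1)`.
#' @param variants variant table giving the ancestral frequencies; by
#'   default 1000 variants spread over 22 chromosomes with ancestral
#'   frequencies drawn uniformly on (0.1, 0.9).
#' @param seed optional integer seed.
#' @return a phased `population` with `subpop`, `region` and
#'   `pheno_offset` set; the variant table's `freq` column keeps the
#'   ancestral frequencies (used for score standardization).
#' @export
simulate_stratified <- function(n_per_subpop, K, divergence, trait_shift = 0,
                                variants = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(K >= 2L, divergence > 0)
  if (is.null(variants))
    variants <- variant_spec(rep_len(1:22, 1000L), runif(1000L, 0.1, 0.9))
  if (length(trait_shift) == 1L) trait_shift <- trait_shift * (seq_len(K) - 1L)
  stopifnot(length(trait_shift) == K)
  p <- variants$freq
  shape <- (1 - divergence) / divergence
  pops <- vector("list", K)
  n_trunc <- 0L
  for (k in seq_len(K)) {
    pk <- rbeta(length(p), p * shape, (1 - p) * shape)
    out_of_range <- pk < 0.01 | pk > 0.99
    n_trunc <- n_trunc + sum(out_of_range)
    pk <- pmin(pmax(pk, 0.01), 0.99)
    vk <- variants; vk$freq <- pk
    pops[[k]] <- simulate_founders(n_per_subpop, vk)
  }
  if (n_trunc > 0L)
    warning(n_trunc, " subpopulation frequencies truncated to (0.01, 0.99)")
  lab <- rep(sprintf("pop%d", seq_len(K)), each = n_per_subpop)
  new_population(do.call(rbind, lapply(pops, `[[`, "genotypes")), variants,
                 hap1 = do.call(rbind, lapply(pops, `[[`, "hap1")),
                 hap2 = do.call(rbind, lapply(pops, `[[`, "hap2")),
                 sex = rep_len(c("M", "F"), n_per_subpop * K),
                 subpop = lab, region = lab, generation = 0L,
                 pheno_offset = rep(trait_shift, each = n_per_subpop))
}
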