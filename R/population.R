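#' Construct a population object
#'
#' A `population` bundles a dosage matrix (individuals x variants, values
#' 0/1/2 or `NA`), a variant table, and optional per-individual labels.
#' Populations produced by the simulator additionally carry the two phased
#' haplotype matrices (`hap1`, `hap2`, 0/1 alleles), which Mendelian
#' transmission requires; populations read from unphased sources carry only
#' dosages.
#'
#' @param genotypes integer matrix, individuals x variants, dosages in
#'   \{0, 1, 2, NA\}.
#' @param variants data.frame with columns `chrom` (integer 1-22), `pos`
#'   (1-based, strictly increasing within chromosome), `id`, `ref`, `alt`,
#'   `freq` (nominal alt-allele frequency).
#' @param hap1,hap2 optional 0/1 haplotype matrices with `hap1 + hap2 ==
#'   genotypes`.
#' @param sex optional character vector (`"M"`/`"F"`) per individual.
#' @param subpop,region optional per-individual labels.
#' @param generation integer generation index (founders are 0).
#' @param pheno_offset optional per-individual phenotype offset (used by
#'   stratified simulations to encode subpopulation trait shifts).
#' @return an object of class `population`.
#' @export
new_population <- function(genotypes, variants, hap1 = NULL, hap2 = NULL,
                           sex = NULL, subpop = NULL, region = NULL,
                           generation = 0L, pheno_offset = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "id", "ref", "alt", "freq") %in% names(variants)),
            ncol(genotypes) == nrow(variants))
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA")
  if (any(variants$chrom < 1L | variants$chrom > 22L))
    stop("chromosomes must be autosomes 1-22")
  for (ch in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == ch]
    if (any(diff(p) <= 0)) stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (!is.null(hap1)) {
    storage.mode(hap1) <- "integer"
    storage.mode(hap2) <- "integer"
    stopifnot(identical(dim(hap1), dim(genotypes)),
              identical(dim(hap2), dim(genotypes)))
  }
  structure(list(genotypes = genotypes, variants = variants,
                 hap1 = hap1, hap2 = hap2,
                 sex = sex, subpop = subpop, region = region,
                 generation = as.integer(generation),
                 pheno_offset = pheno_offset),
            class = "population")
}

#' @export
print.population <- function(x, ...) {
  cat("<population> generation", x$generation, "\n")
  cat("  individuals:", nrow(x$genotypes),
      " variants:", ncol(x$genotypes),
      " chromosomes:", length(unique(x$variants$chrom)), "\n")
  cat("  phased haplotypes:", if (is.null(x$hap1)) "no" else "yes", "\n")
  if (!is.null(x$subpop)) cat("  subpopulations:", length(unique(x$subpop)), "\n")
  if (!is.null(x$region)) cat("  regions:", length(unique(x$region)), "\n")
  invisible(x)
}

#' Number of individuals / variants in a population
#' @param pop a `population`.
#' @return integer count.
#' @export
n_individuals <- function(pop) nrow(pop$genotypes)

#' @rdname n_individuals
#' @export
n_variants <- function(pop) ncol(pop$genotypes)

#' Build a variant specification table
#'
#' Convenience constructor for the per-variant (chromosome, frequency)
#' table consumed by [simulate_founders()]. Positions are laid out on an
#' even grid within each chromosome and ids are generated.
#'
#' @param chrom integer vector of chromosome assignments (1-22).
#' @param freq alt-allele frequencies in (0, 1), recycled to match.
#' @param spacing base-pair spacing between adjacent variants.
#' @return data.frame usable as the `variants` slot of a population.
#' @export
variant_spec <- function(chrom, freq, spacing = 1e5L) {
  chrom <- as.integer(chrom)
  freq <- rep_len(freq, length(chrom))
  ord <- order(chrom)
  chrom <- chrom[ord]; freq <- freq[ord]
  pos <- integer(length(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    pos[idx] <- seq_along(idx) * spacing
  }
  data.frame(chrom = chrom, pos = pos,
             id = sprintf("v%d_%d", chrom, pos),
             ref = "A", alt = "G", freq = freq,
             stringsAsFactors = FALSE)
}
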