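#' Read genotypes into a population
#'
#' Supported formats: VCF (v4.x, `GT`-based; dosage is the alt-allele
#' count, phased `|` genotypes also populate the haplotype matrices) and
#' the package's dosage TSV dialect (variants as rows: `chrom`, `pos`,
#' `id`, `ref`, `alt`, `freq`, then one column per individual). Only
#' autosomes 1-22 are accepted; records on other chromosomes are dropped
#' with a warning. Writing a simulated population with
#' [write_population()] and reading it back is lossless for dosages and
#' variant metadata.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage_tsv"` (guessed from the extension
#'   by default).
#' @return a `population`.
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage_tsv"
  if (format == "dosage_tsv") return(.read_dosage_tsv(path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  chrom_raw <- v@fix[, "CHROM"]
  chrom <- suppressWarnings(as.integer(sub("^chr", "", chrom_raw)))
  ok <- !is.na(chrom) & chrom >= 1L & chrom <= 22L
  if (any(!ok)) {
    warning(sum(!ok), " non-autosomal record(s) rejected (",
            paste(unique(chrom_raw[!ok]), collapse = ", "), ")")
    if (!any(ok)) stop("no autosomal records in ", path)
    v <- v[ok, ]
    chrom <- chrom[ok]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("^[0-9.]+$", gt[!is.na(gt)])))
    stop("mixed or non-diploid ploidy in GT field")
  a1 <- substr(gt, 1L, 1L)
  sep <- substr(gt, 2L, 2L)
  a2 <- substr(gt, 3L, 3L)
  num <- function(a) { out <- suppressWarnings(as.integer(a)); out }
  dos <- num(a1) + num(a2)
  dosages <- t(matrix(dos, nrow(gt), ncol(gt), dimnames = dimnames(gt)))
  info <- v@fix[, "INFO"]
  af <- suppressWarnings(as.numeric(sub("^.*AF=([0-9.eE+-]+).*$", "\\1",
                                        ifelse(grepl("AF=", info), info, NA))))
  emp <- colMeans(dosages, na.rm = TRUE) / 2
  variants <- data.frame(chrom = chrom,
                         pos = as.integer(v@fix[, "POS"]),
                         id = v@fix[, "ID"],
                         ref = v@fix[, "REF"], alt = v@fix[, "ALT"],
                         freq = ifelse(is.na(af), emp, af),
                         stringsAsFactors = FALSE)
  phased <- all(sep[!is.na(gt)] == "|")
  h1 <- h2 <- NULL
  if (phased && !anyNA(gt)) {
    h1 <- t(matrix(num(a1), nrow(gt), ncol(gt)))
    h2 <- t(matrix(num(a2), nrow(gt), ncol(gt)))
  }
  ord <- order(variants$chrom, variants$pos)
  new_population(dosages[, ord, drop = FALSE], variants[ord, ],
                 hap1 = if (!is.null(h1)) h1[, ord, drop = FALSE],
                 hap2 = if (!is.null(h2)) h2[, ord, drop = FALSE])
}

.read_dosage_tsv <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                  stringsAsFactors = FALSE)
  meta <- c("chrom", "pos", "id", "ref", "alt", "freq")
  if (!all(meta %in% names(d)))
    stop("dosage TSV must start with columns: ", paste(meta, collapse = ", "))
  G <- t(as.matrix(d[, setdiff(names(d), meta), drop = FALSE]))
  variants <- d[, meta]
  ord <- order(variants$chrom, variants$pos)
  new_population(G[, ord, drop = FALSE], variants[ord, ])
}

#' Write a population to disk
#'
#' Writes the genotypes as a VCF (phased `GT` with `|` separators when
#' haplotypes are available, with the nominal alt-allele frequency in the
#' INFO `AF` field) or as the compact dosage TSV dialect, plus a
#' phenotype/label TSV (`iid`, optional phenotype columns, `sex`,
#' `subpop`, `region`). Output is byte-deterministic.
#'
#' @param pop a `population`.
#' @param dir output directory (created if needed).
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @param phenotypes optional named list or data.frame of per-individual
#'   phenotype columns.
#' @return invisibly, the paths written.
#' @export
write_population <- function(pop, dir, format = c("vcf", "dosage_tsv"),
                             phenotypes = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- n_individuals(pop)
  iid <- sprintf("I%05d", seq_len(n))
  geno_path <- file.path(dir, if (format == "vcf") "genotypes.vcf" else "genotypes.tsv")
  if (format == "vcf") .write_vcf(pop, geno_path, iid) else
    .write_dosage_tsv(pop, geno_path, iid)
  ph <- data.frame(iid = iid, stringsAsFactors = FALSE)
  if (!is.null(phenotypes)) ph <- cbind(ph, as.data.frame(phenotypes))
  if (!is.null(pop$sex)) ph$sex <- pop$sex
  if (!is.null(pop$subpop)) ph$subpop <- pop$subpop
  if (!is.null(pop$region)) ph$region <- pop$region
  ph_path <- file.path(dir, "phenotypes.tsv")
  write.table(ph, ph_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genotypes = geno_path, phenotypes = ph_path))
}

.write_vcf <- function(pop, path, iid) {
  v <- pop$variants
  header <- c("##fileformat=VCFv4.2",
              "##source=gpdscan",
              '##INFO=<ID=AF,Number=A,Type=Float,Description="Nominal alt allele frequency">',
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", iid), collapse = "\t"))
  if (!is.null(pop$hap1)) {
    gt <- matrix(paste0(t(pop$hap1), "|", t(pop$hap2)),
                 n_variants(pop), length(iid))
  } else {
    g <- t(pop$genotypes)
    gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
    gt[is.na(g)] <- "./."
  }
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS",
                sprintf("AF=%.6g", v$freq), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
}

.write_dosage_tsv <- function(pop, path, iid) {
  d <- cbind(pop$variants[, c("chrom", "pos", "id", "ref", "alt", "freq")],
             as.data.frame(t(pop$genotypes)))
  names(d)[-(1:6)] <- iid
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write GPD results with a run manifest
#'
#' Writes a results table with deterministic column order and float
#' formatting (theta and s.e. at 4 significant digits, P in scientific
#' notation), plus a JSON manifest recording the configuration, seed and
#' package version.
#'
#' @param results data.frame with at least `trait`, `direction`, `theta`,
#'   `se`, `p`, `n`, `n_pcs` columns (missing ones are filled with `NA`).
#' @param path output TSV path; the manifest is written alongside with
#'   extension `.manifest.json`.
#' @param config optional configuration list recorded in the manifest.
#' @return invisibly, the manifest path.
#' @export
write_results <- function(results, path, config = NULL) {
  cols <- c("trait", "direction", "theta", "se", "p", "n", "n_pcs", "vif")
  for (cl in setdiff(cols, names(results))) results[[cl]] <- NA
  out <- results[, cols]
  out$theta <- signif(out$theta, 4)
  out$se <- signif(out$se, 4)
  out$p <- ifelse(is.na(out$p), NA, sprintf("%.3e", as.numeric(out$p)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(config = config,
                   seed = config$seed,
                   n_rows = nrow(out),
                   package = "gpdscan",
                   version = as.character(utils::packageVersion("gpdscan")))
  mpath <- sub("\\.tsv$", "", path)
  mpath <- paste0(mpath, ".manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(mpath)
}

#' Default run configuration
#'
#' Returns (or reads / merges) the flat configuration driving the
#' pipeline. Defaults follow the study design: 10 folds, 20 PCs per
#' chromosome set, odd/even grouping, MAF >= 1\%, HWE P >= 1e-6, call
#' rate >= 99\%, empirical-Bayes shrinkage.
#'
#' @param path optional YAML file whose entries override the defaults.
#' @param ... named overrides applied last.
#' @return named list of configuration values.
#' @export
default_config <- function(path = NULL, ...) {
  cfg <- list(seed = 1L, folds = 10L, pc_count = 20L, scheme = "odd_even",
              call_rate = 0.99, maf = 0.01, hwe_p = 1e-6,
              shrinkage = "empirical_bayes", crossover_rate = 1,
              offspring_per_pair = 2L)
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  cfg
}

#' Read a phenotype table
#'
#' @param path TSV with an `iid` column and one column per phenotype/label.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Read / write GWAS-style summary statistics
#'
#' TSV dialect with columns `CHR`, `POS`, `SNP`, `A1`, `A2`, `FREQ`,
#' `BETA`, `SE`, `P`, `N` (plus `BETA_POST` when shrinkage has been
#' applied).
#'
#' @param stats a `summary_stats` data.frame.
#' @param path file path.
#' @return `read_summary_stats` returns a `summary_stats` data.frame.
#' @export
write_summary_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  out <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("SNP", "BETA", "SE", "P") %in% names(out)))
  class(out) <- c("summary_stats", "data.frame")
  out
}
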