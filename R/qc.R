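#' Apply SNP quality filters
#'
#' Removes SNPs failing the array-QC rules used for inbred diversity
#' panels: unplaced markers (no genome position), missing-call fraction
#' above `miss_max`, heterozygote fraction above `het_max` (a high het rate
#' on a selfing species flags paralogous or badly clustered assays), and
#' minor allele frequency below `maf_min`. MAF is computed on raw
#' non-missing calls, before any imputation. Each removed SNP is attributed
#' to the first filter it fails, in the fixed order
#' unplaced -> missing -> heterozygosity -> MAF, so report counts are
#' reproducible.
#'
#' @param G a [geno_matrix()].
#' @param maf_min minimum minor-allele frequency (default 0.03).
#' @param het_max maximum per-SNP heterozygote fraction (default 0.05).
#' @param miss_max maximum per-SNP missing fraction (default 0.10).
#' @return list with `genotypes` (filtered [geno_matrix()]) and `report`,
#'   a `qc_report` with per-filter removal counts and the thresholds used.
#' @export
apply_qc_filters <- function(G, maf_min = 0.03, het_max = 0.05,
                             miss_max = 0.10) {
  stopifnot(inherits(G, "geno_matrix"))
  n <- ncol(G$dosage)
  unplaced <- is.na(G$map$pos) | is.na(G$map$chrom)
  miss <- missing_fraction(G) > miss_max & !unplaced
  het <- het_fraction(G) > het_max & !unplaced & !miss
  maf <- minor_allele_freq(G) < maf_min & !unplaced & !miss & !het
  keep <- !(unplaced | miss | het | maf)
  if (!any(keep))
    stop("empty panel: all ", n, " SNPs removed by QC filters")
  report <- structure(list(
    n_input = n,
    n_removed_unplaced = sum(unplaced),
    n_removed_missing = sum(miss),
    n_removed_het = sum(het),
    n_removed_maf = sum(maf),
    n_retained = sum(keep),
    thresholds = list(maf_min = maf_min, het_max = het_max,
                      miss_max = miss_max)), class = "qc_report")
  list(genotypes = G[, keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC report\n")
  cat(sprintf("  input SNPs:              %d\n", x$n_input))
  cat(sprintf("  removed, unplaced:       %d\n", x$n_removed_unplaced))
  cat(sprintf("  removed, missing > %g%%:  %d\n",
              100 * x$thresholds$miss_max, x$n_removed_missing))
  cat(sprintf("  removed, het > %g%%:      %d\n",
              100 * x$thresholds$het_max, x$n_removed_het))
  cat(sprintf("  removed, MAF < %g%%:      %d\n",
              100 * x$thresholds$maf_min, x$n_removed_maf))
  cat(sprintf("  retained:                %d\n", x$n_retained))
  invisible(x)
}

#' Serialise a QC report to JSON
#' @param x a `qc_report`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
qc_report_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "qc_report"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Impute missing calls with the per-SNP modal dosage
#'
#' For a highly inbred panel with low missingness the per-SNP mode is an
#' adequate single imputation; ties between equally frequent dosages are
#' broken towards the lower dosage. The method is exposed as an argument so
#' an LD-aware imputer can be slotted in later.
#'
#' @param G a [geno_matrix()].
#' @param method imputation method; only `"mode"` is implemented.
#' @return a [geno_matrix()] with no missing values.
#' @export
impute_missing <- function(G, method = c("mode")) {
  method <- match.arg(method)
  d <- G$dosage
  nmiss <- colSums(is.na(d))
  if (!any(nmiss > 0)) return(G)
  all_missing <- nmiss == nrow(d)
  if (any(all_missing))
    stop("SNP(s) with all calls missing (should have been QC-filtered): ",
         paste(utils::head(G$map$id[all_missing], 5), collapse = ", "))
  for (j in which(nmiss > 0)) {
    tab <- tabulate(d[, j] + 1L, nbins = 3L)
    mode <- which.max(tab) - 1L   # which.max takes the first max: low dosage
    d[is.na(d[, j]), j] <- mode
  }
  geno_matrix(d, G$map)
}
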