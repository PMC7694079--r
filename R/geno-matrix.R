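#' Genotype matrix with SNP map
#'
#' The central container of the package: an accessions x SNPs dosage matrix
#' counting copies of the alternative allele (0, 1, 2; `NA` = missing call)
#' together with a SNP map (marker id, chromosome, 1-based bp position).
#' Chromosome labels are normalised to the "Pv01".."Pv11" convention of the
#' common-bean reference genome; plain integers are accepted and converted.
#'
#' @param dosage numeric matrix, accessions in rows (rownames = accession
#'   ids), SNPs in columns (colnames = marker ids); values in {0, 1, 2, NA}.
#' @param map data.frame with columns `id`, `chrom`, `pos`; one row per SNP,
#'   in the same order as the columns of `dosage`. `pos` may be `NA` for
#'   unplaced markers (scaffolds), which the QC step removes.
#' @return an object of class `geno_matrix`: a list with elements `dosage`
#'   and `map`.
#' @export
geno_matrix <- function(dosage, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (nrow(dosage) < 1L) stop("genotype matrix has no accessions")
  if (ncol(dosage) < 1L) stop("genotype matrix has no SNPs")
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("acc", seq_len(nrow(dosage)))
  stopifnot(is.data.frame(map), all(c("id", "chrom", "pos") %in% names(map)))
  if (nrow(map) != ncol(dosage))
    stop("map has ", nrow(map), " SNPs but dosage has ", ncol(dosage),
         " columns")
  map$id <- as.character(map$id)
  map$chrom <- normalise_chrom(map$chrom)
  map$pos <- as.numeric(map$pos)
  if (anyDuplicated(map$id)) stop("duplicated SNP ids in map")
  bad <- !is.na(dosage) & !(dosage %in% c(0, 1, 2))
  if (any(bad))
    stop("dosage values outside {0, 1, 2, NA} at ", sum(bad), " cells")
  placed <- !is.na(map$pos)
  if (any(map$pos[placed] < 1)) stop("SNP positions must be >= 1")
  key <- paste(map$chrom, map$pos)
  if (anyDuplicated(key[placed]))
    stop("duplicated (chrom, pos) in map")
  colnames(dosage) <- map$id
  structure(list(dosage = dosage, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", nrow(x$dosage), "accessions x", ncol(x$dosage),
      "SNPs\n")
  cat("  chromosomes:", paste(unique(x$map$chrom), collapse = " "), "\n")
  nm <- sum(is.na(x$dosage))
  cat("  missing calls:", nm,
      sprintf("(%.2f%%)", 100 * nm / length(x$dosage)), "\n")
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' @param x a [geno_matrix()].
#' @param i accession selector (indices, names or logical).
#' @param j SNP selector (indices, marker ids or logical).
#' @param ... ignored.
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(j)) j <- match(j, x$map$id)
  if (anyNA(j)) stop("unknown SNP id in subset")
  geno_matrix(x$dosage[i, j, drop = FALSE], x$map[j, , drop = FALSE])
}

#' Normalise chromosome labels to Pv01..Pv11
#'
#' @param chrom character or integer vector of chromosome labels.
#' @return character vector of "Pv01"-style labels; labels that are neither
#'   integers nor already Pv-prefixed (e.g. scaffold names) are kept
#'   verbatim.
#' @export
normalise_chrom <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.integer(chrom))
  out <- chrom
  out[!is.na(num)] <- sprintf("Pv%02d", num[!is.na(num)])
  pv <- grepl("^[Pp][Vv][0-9]+$", chrom)
  out[pv] <- sprintf("Pv%02d", as.integer(sub("^[Pp][Vv]", "", chrom[pv])))
  out
}

#' Per-SNP alternative-allele frequency
#'
#' Computed on non-missing dosages; heterozygotes contribute one copy of
#' each allele.
#'
#' @param G a [geno_matrix()].
#' @return numeric vector, one frequency per SNP.
#' @export
alt_allele_freq <- function(G) {
  colMeans(G$dosage, na.rm = TRUE) / 2
}

#' Per-SNP minor-allele frequency
#' @param G a [geno_matrix()].
#' @export
minor_allele_freq <- function(G) {
  p <- alt_allele_freq(G)
  pmin(p, 1 - p)
}

#' Per-SNP heterozygote fraction (among non-missing calls)
#' @param G a [geno_matrix()].
#' @export
het_fraction <- function(G) {
  colMeans(G$dosage == 1, na.rm = TRUE)
}

#' Per-SNP missing-call fraction
#' @param G a [geno_matrix()].
#' @export
missing_fraction <- function(G) {
  colMeans(is.na(G$dosage))
}
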