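#' Read genotypes from a VCF file
#'
#' Reads a VCF (v4.x) with biallelic SNP records into a [geno_matrix()].
#' GT fields are converted to alternative-allele dosage: `0/0` -> 0,
#' `0/1` -> 1, `1/1` -> 2, `./.` -> `NA`; phased separators (`|`) are
#' treated identically to unphased ones.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param multiallelic `"reject"` (default) errors on records with more
#'   than one ALT allele; `"drop"` silently removes them.
#' @return a [geno_matrix()].
#' @export
read_vcf <- function(path, multiallelic = c("reject", "drop")) {
  multiallelic <- match.arg(multiallelic)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    if (multiallelic == "reject")
      stop("multiallelic site(s) in VCF: ",
           paste(fix[multi, "ID"], collapse = ", "),
           " (use multiallelic = \"drop\" to remove them)")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  allele1 <- substr(gt, 1, 1)
  allele2 <- substr(gt, 3, 3)
  num <- function(a) ifelse(a == ".", NA_real_, as.numeric(a))
  dosage <- num(allele1) + num(allele2)
  dim(dosage) <- dim(gt)
  id <- fix[, "ID"]
  blank <- is.na(id) | id == "."
  id[blank] <- paste0(fix[blank, "CHROM"], "_", fix[blank, "POS"])
  map <- data.frame(id = id, chrom = fix[, "CHROM"],
                    pos = as.numeric(fix[, "POS"]), stringsAsFactors = FALSE)
  dosage <- t(dosage)
  rownames(dosage) <- colnames(gt)
  geno_matrix(dosage, map)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits an uncompressed VCF v4.2 with GT-only FORMAT; REF/ALT are written
#' as the placeholder alleles A/G to mirror the array's reference/alternative
#' coding. Inverse of [read_vcf()] at the dosage level.
#'
#' @param G a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(G$dosage)), collapse = "\t")),
             con)
  gtsym <- c("0/0", "0/1", "1/1")
  d <- t(G$dosage)                       # SNPs x accessions
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gtsym[d[ok] + 1L]
  rows <- cbind(G$map$chrom,
                format(G$map$pos, scientific = FALSE, trim = TRUE),
                G$map$id, "A", "G", ".", "PASS", ".", "GT", gt)
  writeLines(apply(rows, 1, paste, collapse = "\t"), con)
  invisible(path)
}
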