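#' Read a HapMap genotype file
#'
#' Reads the tab-separated HapMap dialect produced by TASSEL for a biallelic
#' SNP array: 11 standard leading columns (`rs#`, `alleles`, `chrom`, `pos`,
#' `strand`, `assembly#`, `center`, `protLSID`, `assayLSID`, `panelLSID`,
#' `QCcode`) followed by one column per accession. Genotype cells use the
#' single-letter IUPAC-style coding in which "A" is the reference homozygote,
#' "G" the alternative homozygote, "R" the heterozygote and "N" a missing
#' call; these map to dosages 0, 2, 1 and `NA` respectively.
#'
#' @param path path to a HapMap file.
#' @return a [geno_matrix()].
#' @export
read_hapmap <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    stop("HapMap parse error: empty file: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (length(header) < 12L)
    stop("HapMap parse error at line 1: expected 11 header columns plus ",
         "at least one accession, found ", length(header), " columns")
  if (!identical(tolower(header[[1]]), "rs#") &&
      !identical(tolower(header[[1]]), "rs"))
    stop("HapMap parse error at line 1: first column must be 'rs#', found '",
         header[[1]], "'")
  accessions <- header[-(1:11)]
  n_acc <- length(accessions)
  if (length(lines) < 2L)
    stop("HapMap parse error: file has a header but no data rows: ", path)

  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 11L + n_acc)
  if (length(bad))
    stop("HapMap parse error at line ", bad[[1]] + 1L, ": expected ",
         11L + n_acc, " columns, found ", nf[[bad[[1]]]])
  m <- matrix(unlist(fields), nrow = length(fields), byrow = TRUE)
  map <- data.frame(id = m[, 1], chrom = m[, 3], pos = m[, 4],
                    stringsAsFactors = FALSE)
  map$pos <- suppressWarnings(as.numeric(map$pos))

  calls <- m[, -(1:11), drop = FALSE]
  lut <- c(A = 0, R = 1, G = 2, N = NA_real_)
  dosage <- matrix(lut[calls], nrow = nrow(calls))
  unknown <- is.na(dosage) & !(calls %in% c("N", names(lut)))
  if (any(unknown)) {
    w <- which(unknown, arr.ind = TRUE)[1, ]
    stop("HapMap parse error: unknown genotype symbol '",
         calls[w[1], w[2]], "' at SNP ", map$id[w[1]], ", accession ",
         accessions[w[2]])
  }
  dosage <- t(dosage)
  rownames(dosage) <- accessions
  geno_matrix(dosage, map)
}

#' Write a genotype matrix in HapMap format
#'
#' Inverse of [read_hapmap()]: dosages 0/1/2/`NA` become "A"/"R"/"G"/"N".
#'
#' @param G a [geno_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_hapmap <- function(G, path) {
  header <- c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
              "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
              rownames(G$dosage))
  sym <- c("A", "R", "G")
  calls <- matrix("N", nrow = ncol(G$dosage), ncol = nrow(G$dosage))
  d <- t(G$dosage)
  ok <- !is.na(d)
  calls[ok] <- sym[d[ok] + 1L]
  rows <- cbind(G$map$id, "A/G", G$map$chrom,
                ifelse(is.na(G$map$pos), "NA", format(G$map$pos,
                                                      scientific = FALSE,
                                                      trim = TRUE)),
                "+", "NA", "NA", "NA", "NA", "NA", "NA", calls)
  writeLines(c(paste(header, collapse = "\t"),
               apply(rows, 1, paste, collapse = "\t")), path)
  invisible(path)
}
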