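#' Select accessions pure for a gene pool on every chromosome
#'
#' An accession is "pure" for a pool when its membership coefficient for
#' that pool is at least `pure_tol` on every analysed chromosome. Because a
#' finite-likelihood admixture model never returns exactly 1, purity is
#' operationalised with a tolerance (default 0.999).
#'
#' @param chrom_ancestry named list of per-chromosome `ancestry_result`
#'   objects with aligned cluster labels (see [per_chromosome_ancestry()]).
#' @param pool cluster index (column of `Q`) identifying the pool.
#' @param pure_tol minimum per-chromosome membership coefficient.
#' @return character vector of pure accession ids.
#' @export
identify_pure_accessions <- function(chrom_ancestry, pool,
                                     pure_tol = 0.999) {
  qs <- sapply(chrom_ancestry, function(r) r$Q[, pool])
  pure <- rowSums(qs >= pure_tol) == ncol(qs)
  ids <- rownames(chrom_ancestry[[1]]$Q)[pure]
  if (!length(ids))
    stop("no accession is pure at pure_tol = ", pure_tol,
         "; consider lowering pure_tol")
  ids
}

#' Diagnostic-SNP discovery by genotype contrast
#'
#' A SNP is diagnostic between two panels when every call in the recipient
#' panel is one homozygote and every call in the donor panel the opposite
#' homozygote; a heterozygous call in either panel disqualifies the SNP,
#' and missing calls are tolerated only up to `max_missing` per panel.
#' The result keeps the two orientations apart: SNPs where the donor
#' (Andean) panel carries the alternative homozygote, and the mirrored set.
#'
#' @param G a [geno_matrix()] (raw or imputed).
#' @param pure_recipient_ids accession ids of the pure recipient
#'   (Mesoamerican) contrast panel.
#' @param donor_ids accession ids of the donor (Andean) contrast panel.
#' @param max_missing maximum missing-call fraction per panel at a SNP
#'   (default 0: complete data required).
#' @return a `diagnostic_snp_set` (see [diagnostic_snp_set()]) with
#'   provenance attributes recording the contrast panels.
#' @export
find_diagnostic_snps <- function(G, pure_recipient_ids, donor_ids,
                                 max_missing = 0) {
  if (length(intersect(pure_recipient_ids, donor_ids)))
    stop("recipient and donor panels overlap")
  miss <- setdiff(c(pure_recipient_ids, donor_ids), rownames(G$dosage))
  if (length(miss))
    stop("accession id(s) not in genotype matrix: ",
         paste(miss, collapse = ", "))
  dr <- G$dosage[pure_recipient_ids, , drop = FALSE]
  dd <- G$dosage[donor_ids, , drop = FALSE]
  ok_miss <- colMeans(is.na(dr)) <= max_missing &
    colMeans(is.na(dd)) <= max_missing
  no_het <- colSums(dr == 1, na.rm = TRUE) == 0 &
    colSums(dd == 1, na.rm = TRUE) == 0
  all0 <- function(m) colSums(m != 0, na.rm = TRUE) == 0 &
    colSums(!is.na(m)) > 0
  all2 <- function(m) colSums(m != 2, na.rm = TRUE) == 0 &
    colSums(!is.na(m)) > 0
  alt_in_andean <- ok_miss & no_het & all0(dr) & all2(dd)
  alt_in_meso <- ok_miss & no_het & all2(dr) & all0(dd)
  diagnostic_snp_set(G$map$id[alt_in_andean], G$map$id[alt_in_meso],
                     provenance = list(recipients = pure_recipient_ids,
                                       donors = donor_ids))
}

#' Construct a diagnostic-SNP set
#'
#' Container for the two orientations of fixed-contrast loci; enforces
#' their disjointness.
#'
#' @param set_alt_in_andean SNP ids with the alternative homozygote fixed
#'   in the donor (Andean) panel and the reference homozygote in the
#'   recipient panel.
#' @param set_alt_in_meso the mirrored set.
#' @param provenance optional list recording the contrast panels.
#' @return a `diagnostic_snp_set` list with elements `set_alt_in_andean`,
#'   `set_alt_in_meso`, `provenance`.
#' @export
diagnostic_snp_set <- function(set_alt_in_andean, set_alt_in_meso,
                               provenance = NULL) {
  a <- unique(as.character(set_alt_in_andean))
  b <- unique(as.character(set_alt_in_meso))
  if (length(intersect(a, b)))
    stop("diagnostic orientations overlap: ",
         paste(utils::head(intersect(a, b), 5), collapse = ", "))
  structure(list(set_alt_in_andean = a, set_alt_in_meso = b,
                 provenance = provenance), class = "diagnostic_snp_set")
}

#' @export
print.diagnostic_snp_set <- function(x, ...) {
  cat("diagnostic_snp_set:", length(x$set_alt_in_andean),
      "alt-in-donor +", length(x$set_alt_in_meso), "alt-in-recipient =",
      length(x$set_alt_in_andean) + length(x$set_alt_in_meso),
      "diagnostic SNPs\n")
  invisible(x)
}

#' Donor-allele frequency scan at diagnostic SNPs
#'
#' For each diagnostic SNP, the frequency of the donor-pool allele among
#' all recipient-pool accessions (not only the pure ones used for
#' discovery): `(2 * donor homozygotes + heterozygotes) / (2 * non-missing
#' calls)`, i.e. heterozygotes count as half a dosage. Frequencies are
#' binned as (0, 10%], (10%, 15%], (15%, 20%), [20%, 1]; the paper-style
#' bin labels are `<=10%`, `11-15%`, `16-19%`, `>=20%`.
#'
#' @param G a [geno_matrix()].
#' @param recipient_ids all recipient-pool accession ids to scan.
#' @param diag a `diagnostic_snp_set`.
#' @return data.frame per diagnostic SNP: `snp`, `chrom`, `pos`,
#'   `donor_freq`, `bin`.
#' @export
introgression_scan <- function(G, recipient_ids, diag) {
  stopifnot(inherits(diag, "diagnostic_snp_set"))
  ids <- c(diag$set_alt_in_andean, diag$set_alt_in_meso)
  if (!length(ids)) stop("diagnostic set is empty")
  missing_snp <- setdiff(ids, G$map$id)
  if (length(missing_snp))
    stop("diagnostic SNP(s) absent from genotype matrix: ",
         paste(utils::head(missing_snp, 5), collapse = ", "))
  d <- G$dosage[recipient_ids, ids, drop = FALSE]
  mean_d <- colMeans(d, na.rm = TRUE)
  donor_is_alt <- ids %in% diag$set_alt_in_andean
  freq <- ifelse(donor_is_alt, mean_d / 2, 1 - mean_d / 2)
  j <- match(ids, G$map$id)
  out <- data.frame(snp = ids, chrom = G$map$chrom[j], pos = G$map$pos[j],
                    donor_freq = freq, stringsAsFactors = FALSE)
  out$bin <- introgression_bin(out$donor_freq)
  out[order(out$chrom, out$pos), ]
}

introgression_bin <- function(freq) {
  cut(freq, breaks = c(-Inf, 0.10, 0.15, 0.20 - 1e-12, Inf),
      labels = c("<=10%", "11-15%", "16-19%", ">=20%"), right = TRUE)
}

#' Call introgression segments from a frequency scan and LD
#'
#' SNPs whose donor-allele frequency reaches `freq_min` are grouped
#' greedily along the map, per chromosome: a SNP joins the open segment if
#' its r-squared with every current member is at least `r2_min` and the
#' segment span stays within `max_span_bp`; otherwise it opens a new
#' segment. Singleton segments are allowed.
#'
#' @param scan result of [introgression_scan()].
#' @param ld_pairs data.frame with columns `snp_a`, `snp_b`, `r2` covering
#'   the scanned SNPs (see [pairwise_r2()]).
#' @param freq_min minimum donor-allele frequency (default 0.20).
#' @param r2_min minimum pairwise r-squared within a segment (default 0.8).
#' @param max_span_bp maximum segment span (default 5 Mb).
#' @return data.frame, one row per segment: `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `snps` (comma-separated ids), `min_r2`, `max_donor_freq`.
#' @export
detect_segments <- function(scan, ld_pairs, freq_min = 0.20, r2_min = 0.8,
                            max_span_bp = 5e6) {
  hits <- scan[scan$donor_freq >= freq_min, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(chrom = character(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer(),
                      snps = character(), min_r2 = numeric(),
                      max_donor_freq = numeric(), stringsAsFactors = FALSE))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  r2 <- stats::setNames(ld_pairs$r2, key(ld_pairs$snp_a, ld_pairs$snp_b))
  lookup <- function(a, b) {
    v <- r2[key(a, b)]
    if (is.na(v)) 0 else v
  }
  segs <- list()
  for (ch in unique(hits$chrom)) {
    h <- hits[hits$chrom == ch, , drop = FALSE]
    h <- h[order(h$pos), , drop = FALSE]
    cur <- 1L
    for (i in seq_len(nrow(h))[-1]) {
      ok_ld <- all(vapply(cur, function(m)
        lookup(h$snp[m], h$snp[i]), numeric(1)) >= r2_min)
      ok_span <- h$pos[i] - h$pos[cur[1]] <= max_span_bp
      if (ok_ld && ok_span) cur <- c(cur, i)
      else {
        segs[[length(segs) + 1L]] <- h[cur, , drop = FALSE]
        cur <- i
      }
    }
    segs[[length(segs) + 1L]] <- h[cur, , drop = FALSE]
  }
  do.call(rbind, lapply(segs, function(s) {
    pr <- if (nrow(s) > 1) {
      cmb <- utils::combn(nrow(s), 2)
      min(mapply(function(a, b) lookup(s$snp[a], s$snp[b]),
                 cmb[1, ], cmb[2, ]))
    } else NA_real_
    data.frame(chrom = s$chrom[1], start_bp = min(s$pos),
               end_bp = max(s$pos), n_snps = nrow(s),
               snps = paste(s$snp, collapse = ","), min_r2 = pr,
               max_donor_freq = max(s$donor_freq),
               stringsAsFactors = FALSE)
  }))
}

#' Export segments as BED
#'
#' Converts the 1-based inclusive map coordinates to BED's 0-based
#' half-open convention.
#'
#' @param segments result of [detect_segments()].
#' @param path output path.
#' @export
write_segments_bed <- function(segments, path) {
  rows <- sprintf("%s\t%d\t%d\tsegment_%d\t%d", segments$chrom,
                  as.integer(segments$start_bp) - 1L,
                  as.integer(segments$end_bp), seq_len(nrow(segments)),
                  segments$n_snps)
  writeLines(rows, path)
  invisible(path)
}

#' Genes within a window around a SNP
#'
#' Looks up gene models in a GFF3 file whose span intersects a window
#' centred on the SNP (`window_bp / 2` on each side, clipped at position
#' 1). Each gene is returned with its signed distance from the SNP:
#' 0 when the SNP falls inside the gene, negative when the gene lies
#' upstream (before) the SNP, positive when downstream.
#'
#' @param gff_path path to a GFF3 file.
#' @param snp one-row data.frame (or list) with `id`, `chrom`, `pos`.
#' @param window_bp total window width (default 2 Mb).
#' @param feature_type GFF3 feature type to report (default `"gene"`).
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`, `distance_bp`.
#' @export
genes_in_window <- function(gff_path, snp, window_bp = 2e6,
                            feature_type = "gene") {
  gff <- ape::read.gff(gff_path)
  chrom <- normalise_chrom(snp$chrom)
  gff$seqid_norm <- normalise_chrom(as.character(gff$seqid))
  if (!chrom %in% gff$seqid_norm)
    stop("chromosome ", chrom, " not present in GFF3 (seqids: ",
         paste(unique(gff$seqid_norm), collapse = ", "), ")")
  g <- gff[gff$type == feature_type & gff$seqid_norm == chrom, ,
           drop = FALSE]
  lo <- max(1, snp$pos - window_bp / 2)
  hi <- snp$pos + window_bp / 2
  g <- g[g$end >= lo & g$start <= hi, , drop = FALSE]
  if (!nrow(g))
    return(data.frame(gene_id = character(), chrom = character(),
                      start = numeric(), end = numeric(),
                      distance_bp = numeric(), stringsAsFactors = FALSE))
  id <- sub('.*(?:ID|Name)=([^;]+).*', "\\1", g$attributes)
  dist <- ifelse(snp$pos >= g$start & snp$pos <= g$end, 0,
                 ifelse(g$end < snp$pos, -(snp$pos - g$end),
                        g$start - snp$pos))
  out <- data.frame(gene_id = id, chrom = chrom, start = g$start,
                    end = g$end, distance_bp = dist,
                    stringsAsFactors = FALSE)
  out[order(abs(out$distance_bp)), ]
}
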