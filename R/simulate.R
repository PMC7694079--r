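#' Parameters for the synthetic two-gene-pool panel generator
#'
#' Defaults describe the panel the analyses are designed for: 175
#' Mesoamerican and 10 Andean highly inbred accessions typed at ~2827 SNPs
#' on 11 chromosomes of a ~587 Mb genome, with roughly 1060 loci fixed for
#' opposite homozygotes between the pools (the diagnostic fraction),
#' residual heterozygosity ~2%, a Carioca/Black/Special commercial-class
#' split of 131/29/25 and the Carioca era split 36 old / 53 modern / 42
#' lines. Within-pool allele frequencies are drawn from pool-specific Beta
#' distributions tuned so realised mean expected heterozygosity is ~0.12
#' (Mesoamerican) and ~0.10 (Andean). Linkage disequilibrium arises from
#' block-wise copying out of a small founder-haplotype pool.
#'
#' @param n_meso,n_andean accession counts per gene pool.
#' @param n_chrom number of chromosomes.
#' @param snps_per_chrom SNPs simulated per chromosome.
#' @param chrom_length_bp chromosome length in bp.
#' @param frac_diagnostic fraction of loci fixed for opposite alleles
#'   between the pools (before any introgression).
#' @param freq_beta_meso,freq_beta_andean `c(shape1, shape2)` of the Beta
#'   distribution of within-pool alternative-allele frequencies at
#'   non-diagnostic loci.
#' @param residual_het_rate probability that a non-diagnostic call is
#'   rendered heterozygous (residual outcrossing/assay noise); must be
#'   <= 0.05.
#' @param n_founders founder haplotypes per pool (per commercial class for
#'   the Mesoamerican pool, which induces class-level differentiation).
#' @param ld_block_len_bp length of the founder-copying blocks; haplotype
#'   correlation, and hence r-squared, decays on this scale.
#' @param class_counts named integer vector of Mesoamerican class sizes.
#' @param carioca_era_counts named integer vector `c(old, modern, lines)`
#'   partitioning the Carioca class by release era.
#' @param introgressions list of planted Andean segments, each a list with
#'   `n_recipients` (or explicit `recipients` ids), `chrom`, `start_bp`,
#'   `end_bp`.
#' @param seed integer seed for the genotype stream.
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_meso = 175, n_andean = 10, n_chrom = 11,
                       snps_per_chrom = 257, chrom_length_bp = 53.4e6,
                       frac_diagnostic = 0.375,
                       freq_beta_meso = c(0.25, 2),
                       freq_beta_andean = c(0.20, 2),
                       residual_het_rate = 0.02,
                       n_founders = 8, ld_block_len_bp = 2e6,
                       class_counts = c(Carioca = 131, Black = 29,
                                        Special = 15),
                       carioca_era_counts = c(old = 36, modern = 53,
                                              lines = 42),
                       introgressions = list(), seed = 1L) {
  p <- list(n_meso = n_meso, n_andean = n_andean, n_chrom = n_chrom,
            snps_per_chrom = snps_per_chrom,
            chrom_length_bp = chrom_length_bp,
            frac_diagnostic = frac_diagnostic,
            freq_beta_meso = freq_beta_meso,
            freq_beta_andean = freq_beta_andean,
            residual_het_rate = residual_het_rate,
            n_founders = n_founders, ld_block_len_bp = ld_block_len_bp,
            class_counts = class_counts,
            carioca_era_counts = carioca_era_counts,
            introgressions = introgressions, seed = as.integer(seed))
  stopifnot(n_meso >= 1, n_andean >= 1, n_chrom >= 1, snps_per_chrom >= 1,
            n_founders >= 2,
            frac_diagnostic >= 0, frac_diagnostic <= 1,
            residual_het_rate >= 0, residual_het_rate <= 0.05)
  if (sum(class_counts) != n_meso) {
    # scale the default split to the requested pool size
    cc <- round(class_counts * n_meso / sum(class_counts))
    cc[1] <- cc[1] + n_meso - sum(cc)
    p$class_counts <- cc
  }
  nc <- p$class_counts["Carioca"]
  if (is.na(nc)) nc <- 0
  if (sum(carioca_era_counts) != nc && nc > 0) {
    ce <- round(carioca_era_counts * as.numeric(nc) /
                  sum(carioca_era_counts))
    ce[1] <- ce[1] + as.numeric(nc) - sum(ce)
    p$carioca_era_counts <- ce
  }
  class(p) <- "sim_params"
  p
}

#' Simulate a two-gene-pool SNP panel
#'
#' Builds the genotype matrix, accession metadata and a ground-truth record
#' used by the recovery tests. Diagnostic loci are fixed at dosage 0 in one
#' pool and 2 in the other (orientation randomised per locus); all other
#' loci segregate at pool-specific Beta-distributed frequencies. Accessions
#' are assembled chromosome by chromosome by copying founder haplotypes in
#' blocks of `ld_block_len_bp`, which induces block-wise LD; Mesoamerican
#' founders are drawn per commercial class so classes differentiate.
#' Residual heterozygotes are injected at `residual_het_rate` at
#' non-diagnostic loci only (ancestry-informative assays on a selfing crop
#' are curated to be cleanly homozygous, and keeping planted diagnostic
#' loci strictly fixed makes the generator usable as an exact oracle).
#' Planted introgression segments then overwrite recipient dosages inside
#' the segment with alleles copied from an Andean founder.
#'
#' @param params a [sim_params()] object.
#' @return list with `genotypes` (a [geno_matrix()]), `metadata` (data.frame
#'   with `accession`, `pool`, `class`, `era`) and `truth` (list with pool /
#'   class / era labels, the planted diagnostic loci split by orientation,
#'   planted segments, and the target founder allele frequencies per pool).
#' @export
simulate_panel <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  set.seed(p$seed)
  n_snps <- p$n_chrom * p$snps_per_chrom

  # map: sorted unique positions per chromosome
  chroms <- sprintf("Pv%02d", seq_len(p$n_chrom))
  map <- do.call(rbind, lapply(seq_len(p$n_chrom), function(ci) {
    pos <- sort(sample.int(p$chrom_length_bp, p$snps_per_chrom))
    data.frame(id = sprintf("ss%02d%04d", ci, seq_len(p$snps_per_chrom)),
               chrom = chroms[ci], pos = pos, stringsAsFactors = FALSE)
  }))

  # diagnostic loci and their orientation
  n_diag <- round(p$frac_diagnostic * n_snps)
  diag_idx <- sort(sample.int(n_snps, n_diag))
  alt_in_andean <- rep(FALSE, n_snps)
  alt_in_andean[diag_idx] <- stats::runif(n_diag) < 0.5

  # founder-level target allele frequencies (alternative allele)
  freq_meso <- stats::rbeta(n_snps, p$freq_beta_meso[1], p$freq_beta_meso[2])
  freq_andean <- stats::rbeta(n_snps, p$freq_beta_andean[1],
                              p$freq_beta_andean[2])
  freq_meso[diag_idx] <- ifelse(alt_in_andean[diag_idx], 0, 1)
  freq_andean[diag_idx] <- ifelse(alt_in_andean[diag_idx], 1, 0)

  # founder haplotypes: one founder set per Mesoamerican class, one Andean
  classes <- rep(names(p$class_counts), p$class_counts)
  founder_sets <- lapply(names(p$class_counts), function(cl) {
    matrix(stats::rbinom(p$n_founders * n_snps, 1, rep(freq_meso,
                                                       each = p$n_founders)),
           nrow = p$n_founders)
  })
  names(founder_sets) <- names(p$class_counts)
  founders_andean <- matrix(
    stats::rbinom(p$n_founders * n_snps, 1,
                  rep(freq_andean, each = p$n_founders)),
    nrow = p$n_founders)

  # block index per SNP (blocks restart on each chromosome)
  block_of <- paste(map$chrom, (map$pos - 1) %/% p$ld_block_len_bp)
  block_ids <- unique(block_of)
  block_no <- match(block_of, block_ids)
  n_blocks <- length(block_ids)

  build_acc <- function(founders) {
    pick <- sample.int(nrow(founders), n_blocks, replace = TRUE)
    founders[cbind(pick[block_no], seq_len(n_snps))]
  }

  n_total <- p$n_meso + p$n_andean
  dosage <- matrix(NA_real_, n_total, n_snps)
  pool <- c(rep("Mesoamerican", p$n_meso), rep("Andean", p$n_andean))
  class_lab <- c(classes, rep("Special", p$n_andean))
  for (i in seq_len(p$n_meso))
    dosage[i, ] <- 2 * build_acc(founder_sets[[classes[i]]])
  for (i in seq_len(p$n_andean))
    dosage[p$n_meso + i, ] <- 2 * build_acc(founders_andean)

  # the effective diagnostic set is the realised fixed-contrast set: besides
  # the planted loci, a locus can drift to opposite fixation between the
  # pools through the finite founder draw, and the truth record must
  # describe the panel as built
  meso_rows <- seq_len(p$n_meso)
  and_rows <- p$n_meso + seq_len(p$n_andean)
  meso_all0 <- colSums(dosage[meso_rows, , drop = FALSE]) == 0
  meso_all2 <- colSums(dosage[meso_rows, , drop = FALSE]) == 2 * p$n_meso
  and_all0 <- colSums(dosage[and_rows, , drop = FALSE]) == 0
  and_all2 <- colSums(dosage[and_rows, , drop = FALSE]) == 2 * p$n_andean
  alt_in_andean <- meso_all0 & and_all2
  diag_idx <- which(alt_in_andean | (meso_all2 & and_all0))

  # residual heterozygosity at non-diagnostic loci
  if (p$residual_het_rate > 0) {
    nondiag <- setdiff(seq_len(n_snps), diag_idx)
    het <- matrix(stats::runif(n_total * length(nondiag)) <
                    p$residual_het_rate, n_total)
    dosage[, nondiag][het] <- 1
  }

  # era groups within Carioca
  era <- rep(NA_character_, n_total)
  cario <- which(class_lab == "Carioca")
  if (length(cario))
    era[cario] <- rep(names(p$carioca_era_counts), p$carioca_era_counts)

  accession <- sprintf("%s-%03d", ifelse(pool == "Andean", "AND", "BRS"),
                       seq_len(n_total))
  rownames(dosage) <- accession

  # planted introgression: copy an Andean founder inside each segment
  segments <- data.frame(accession = character(), chrom = character(),
                         start_bp = numeric(), end_bp = numeric(),
                         stringsAsFactors = FALSE)
  meso_ids <- accession[pool == "Mesoamerican"]
  for (sp in p$introgressions) {
    chrom <- normalise_chrom(sp$chrom)
    if (sp$start_bp < 1 || sp$end_bp > p$chrom_length_bp ||
        sp$start_bp > sp$end_bp)
      stop("introgression segment [", sp$start_bp, ", ", sp$end_bp,
           "] outside chromosome bounds (1..", p$chrom_length_bp, ")")
    rec <- if (!is.null(sp$recipients)) sp$recipients else
      sample(meso_ids, sp$n_recipients)
    in_seg <- map$chrom == chrom & map$pos >= sp$start_bp &
      map$pos <= sp$end_bp
    for (a in rec) {
      donor <- founders_andean[sample.int(p$n_founders, 1), ]
      dosage[a, in_seg] <- 2 * donor[in_seg]
      segments <- rbind(segments, data.frame(
        accession = a, chrom = chrom, start_bp = sp$start_bp,
        end_bp = sp$end_bp, stringsAsFactors = FALSE))
    }
  }

  G <- geno_matrix(dosage, map)
  metadata <- data.frame(accession = accession, pool = pool,
                         class = class_lab, era = era,
                         stringsAsFactors = FALSE)
  truth <- list(
    pool = stats::setNames(pool, accession),
    class = stats::setNames(class_lab, accession),
    era = stats::setNames(era, accession),
    diagnostic_ids = map$id[diag_idx],
    diag_alt_in_andean = map$id[diag_idx][alt_in_andean[diag_idx]],
    diag_alt_in_meso = map$id[diag_idx][!alt_in_andean[diag_idx]],
    segments = segments,
    target_freq_meso = freq_meso,
    target_freq_andean = freq_andean,
    params = p)
  list(genotypes = G, metadata = metadata, truth = truth)
}

#' Simulate RCBD phenotypes on a simulated panel
#'
#' Plot-level phenotypes under a randomized complete block design:
#' `value = trait mean + genetic value + block effect + residual`, where the
#' genetic value is the sum of planted QTL effects on centred dosages plus
#' a polygenic term. DTF and DTM share their first QTL, making their
#' correlation positive. HAB is generated on a latent scale and discretised
#' to ordinal classes 1-3 (type 4, climbing habit, is absent from elite
#' panels). The residual variance is set from the target line-mean
#' broad-sense heritability `h2_target`:
#' `var(e) = n_blocks * var(g) * (1 - h2) / h2`.
#'
#' The phenotype stream is seeded independently of the genotype stream, so
#' replicate phenotype sets can be drawn on a fixed panel.
#'
#' @param G a [geno_matrix()] (imputed; QTL dosages must be complete).
#' @param truth the `truth` list from [simulate_panel()].
#' @param design list with `n_blocks` (default 4) and `traits`
#'   (default DTF, DTM, HAB).
#' @param qtl_spec data.frame with columns `trait` and `effect` (and
#'   optionally `snp`); by default two QTLs per quantitative trait are
#'   sampled from SNPs with MAF >= 0.15, with the first DTF QTL shared by
#'   DTM.
#' @param h2_target target line-mean broad-sense heritability.
#' @param seed integer seed for the phenotype stream.
#' @return list with `phenotypes` (long data.frame: `accession`, `block`,
#'   `trait`, `value`) and `truth` augmented with `qtls` and
#'   `realised_h2`.
#' @export
simulate_phenotypes <- function(G, truth,
                                design = list(n_blocks = 4,
                                              traits = c("DTF", "DTM",
                                                         "HAB")),
                                qtl_spec = NULL, h2_target = 0.8,
                                seed = 1L) {
  n_blocks <- design$n_blocks
  if (is.null(n_blocks) || n_blocks < 1)
    stop("design$n_blocks must be a positive integer")
  traits <- design$traits
  set.seed(as.integer(seed) + 1000003L)
  acc <- rownames(G$dosage)
  n <- length(acc)

  maf <- minor_allele_freq(G)
  candidates <- G$map$id[maf >= 0.15]
  if (is.null(qtl_spec)) {
    qtl_spec <- data.frame(
      trait = c("DTF", "DTF", "DTM", "DTM", "HAB", "HAB"),
      effect = c(2.0, 1.5, 2.0, 1.5, 0.6, 0.4),
      stringsAsFactors = FALSE)
    picked <- sample(candidates, 5)
    # DTF and DTM share the first QTL -> positive DTF/DTM correlation
    qtl_spec$snp <- picked[c(1, 2, 1, 3, 4, 5)]
  }
  if (!all(qtl_spec$snp %in% G$map$id))
    stop("QTL snp id(s) absent from the genotype map: ",
         paste(setdiff(qtl_spec$snp, G$map$id), collapse = ", "))
  qtl_spec <- qtl_spec[qtl_spec$trait %in% traits, , drop = FALSE]

  trait_mean <- c(DTF = 65, DTM = 90, HAB = 2)
  records <- list()
  realised_h2 <- stats::setNames(numeric(0), character(0))
  for (tr in traits) {
    qs <- qtl_spec[qtl_spec$trait == tr, , drop = FALSE]
    g <- rep(0, n)
    for (k in seq_len(nrow(qs))) {
      d <- G$dosage[, qs$snp[k]]
      g <- g + qs$effect[k] * (d - mean(d))
    }
    poly_sd <- if (nrow(qs)) 0.3 * stats::sd(g) else 1
    g <- g + stats::rnorm(n, 0, poly_sd)
    vg <- stats::var(g)
    ve <- if (vg > 0) n_blocks * vg * (1 - h2_target) / h2_target else 1
    sde <- sqrt(ve)
    block_eff <- stats::rnorm(n_blocks, 0, sde)
    val <- outer(g, block_eff, "+") + trait_mean[tr] +
      matrix(stats::rnorm(n * n_blocks, 0, sde), n)
    if (tr == "HAB") {
      lat <- as.vector(val)
      cuts <- stats::quantile(lat, c(0.35, 0.75))
      val[] <- cut(lat, c(-Inf, cuts, Inf), labels = FALSE)
    }
    realised_h2[tr] <- if (vg > 0) vg / (vg + ve / n_blocks) else 0
    records[[tr]] <- data.frame(
      accession = rep(acc, n_blocks),
      block = rep(seq_len(n_blocks), each = n),
      trait = tr, value = as.vector(val), stringsAsFactors = FALSE)
  }
  truth$qtls <- qtl_spec
  truth$realised_h2 <- realised_h2
  list(phenotypes = do.call(rbind, records), truth = truth)
}
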