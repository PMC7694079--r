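# shared fixtures, built in code and cached for the session

make_geno <- function(dosage, chrom = NULL, pos = NULL, ids = NULL) {
  dosage <- as.matrix(dosage)
  L <- ncol(dosage)
  map <- data.frame(
    id = if (is.null(ids)) paste0("s", seq_len(L)) else ids,
    chrom = if (is.null(chrom)) rep("Pv01", L) else chrom,
    pos = if (is.null(pos)) seq_len(L) * 1000 else pos,
    stringsAsFactors = FALSE)
  geno_matrix(dosage, map)
}

.panel_cache <- new.env(parent = emptyenv())

# a mid-sized two-pool panel with planted segments, shared across tests
shared_sim <- function() {
  if (is.null(.panel_cache$sim)) {
    p <- sim_params(
      n_meso = 50, n_andean = 10, n_chrom = 3, snps_per_chrom = 120,
      chrom_length_bp = 2e7, frac_diagnostic = 0.375,
      introgressions = list(
        list(n_recipients = 8, chrom = 1, start_bp = 2e6, end_bp = 6e6),
        list(n_recipients = 10, chrom = 2, start_bp = 5e6, end_bp = 9e6)),
      seed = 7)
    sim <- simulate_panel(p)
    sim$imputed <- impute_missing(sim$genotypes)
    .panel_cache$sim <- sim
  }
  .panel_cache$sim
}

# same panel structure with no residual heterozygosity and no introgression
shared_sim_clean <- function() {
  if (is.null(.panel_cache$clean)) {
    p <- sim_params(
      n_meso = 50, n_andean = 10, n_chrom = 3, snps_per_chrom = 120,
      chrom_length_bp = 2e7, frac_diagnostic = 0.375,
      residual_het_rate = 0, seed = 11)
    .panel_cache$clean <- simulate_panel(p)
  }
  .panel_cache$clean
}
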