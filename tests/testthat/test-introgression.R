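fake_ancestry <- function(Q) {
  structure(list(Q = Q, K = ncol(Q)), class = "ancestry_result")
}

test_that("purity requires the tolerance on every chromosome", {
  q1 <- matrix(c(1, 0.90, 0, 0.10), 2, 2,
               dimnames = list(c("accA", "accB"), NULL))
  q2 <- matrix(c(1, 1, 1, 1), 2, 2, dimnames = dimnames(q1))
  ca <- list(Pv01 = fake_ancestry(q1), Pv02 = fake_ancestry(q2))
  expect_equal(identify_pure_accessions(ca, pool = 1), "accA")
  # accB fails on one chromosome only
  q1b <- q1; q1b["accB", 1] <- 1
  ca$Pv01 <- fake_ancestry(q1b)
  expect_setequal(identify_pure_accessions(ca, pool = 1),
                  c("accA", "accB"))
  q0 <- matrix(0.5, 2, 2, dimnames = dimnames(q1))
  expect_error(identify_pure_accessions(list(Pv01 = fake_ancestry(q0)),
                                        pool = 1), "pure_tol")
})

test_that("exactly the planted zero-introgression cultivars are pure", {
  p <- sim_params(n_meso = 50, n_andean = 10, n_chrom = 3,
                  snps_per_chrom = 120, chrom_length_bp = 2e7,
                  frac_diagnostic = 0.375, seed = 19)
  sim0 <- simulate_panel(p)
  meso <- names(sim0$truth$pool)[sim0$truth$pool == "Mesoamerican"]
  pure_true <- meso[1:22]
  cr <- setdiff(meso, pure_true)     # 28 carriers
  # many rare segments (2-4 recipients each), the regime the scan targets:
  # a segment shared by a large recipient fraction would instead be
  # absorbed into the recipient cluster's allele frequencies
  seg <- function(r, ch, s, e) list(recipients = r, chrom = ch,
                                    start_bp = s, end_bp = e)
  p$introgressions <- list(
    seg(cr[1:3], 1, 2e6, 6e6), seg(cr[4:6], 1, 9e6, 13e6),
    seg(cr[7:9], 1, 15e6, 19e6), seg(cr[10:12], 2, 1e6, 5e6),
    seg(cr[13:15], 2, 8e6, 12e6), seg(cr[16:18], 2, 14e6, 18e6),
    seg(cr[19:21], 3, 2e6, 6e6), seg(cr[22:24], 3, 8e6, 12e6),
    seg(cr[25:28], 3, 14e6, 18e6))
  sim <- simulate_panel(p)
  G <- impute_missing(sim$genotypes)
  gw <- em_admixture(G, K = 2, seed = 1, n_restarts = 2, max_iter = 2000)
  ca <- per_chromosome_ancestry(G, K = 2, seed = 1, n_restarts = 2,
                                max_iter = 2000, genome_result = gw)
  k_meso <- which.max(colMeans(gw$Q[meso, ]))
  pure <- identify_pure_accessions(ca, pool = k_meso)
  expect_setequal(intersect(pure, meso), pure_true)
})

test_that("genotype contrast finds exactly the fixed-contrast SNPs", {
  # hand-built cases
  d <- rbind(matrix(0, 4, 4), matrix(2, 3, 4))
  d[, 2] <- 0                 # monomorphic in both panels
  d[7, 3] <- 1                # het in donor panel
  d[, 4] <- 2 - d[, 4]        # mirrored orientation
  rownames(d) <- c(paste0("m", 1:4), paste0("a", 1:3))
  G <- make_geno(d)
  ds <- find_diagnostic_snps(G, paste0("m", 1:4), paste0("a", 1:3))
  expect_equal(ds$set_alt_in_andean, "s1")
  expect_equal(ds$set_alt_in_meso, "s4")
  expect_error(find_diagnostic_snps(G, c("m1", "a1"), c("a1", "a2")),
               "overlap")
  expect_error(find_diagnostic_snps(G, "m1", "zz"), "not in genotype")
})

test_that("diagnostic recovery on simulation is exact and matches brute force", {
  sim <- shared_sim_clean()
  meso <- names(sim$truth$pool)[sim$truth$pool == "Mesoamerican"]
  andean <- names(sim$truth$pool)[sim$truth$pool == "Andean"]
  ds <- find_diagnostic_snps(sim$genotypes, meso, andean)
  found <- c(ds$set_alt_in_andean, ds$set_alt_in_meso)
  expect_setequal(found, sim$truth$diagnostic_ids)
  expect_setequal(ds$set_alt_in_andean, sim$truth$diag_alt_in_andean)
  bf <- diagnostic_bruteforce(sim$genotypes, meso, andean)
  expect_setequal(ds$set_alt_in_andean, bf$alt_in_andean)
  expect_setequal(ds$set_alt_in_meso, bf$alt_in_meso)
})

test_that("diagnostic orientations must be disjoint", {
  expect_error(diagnostic_snp_set(c("a", "b"), c("b", "c")), "overlap")
  ds <- diagnostic_snp_set(c("a", "b"), c("c"))
  expect_equal(length(ds$set_alt_in_andean) + length(ds$set_alt_in_meso), 3)
})

test_that("scan frequencies count heterozygotes as half-dosage", {
  d <- rbind(matrix(0, 10, 2), matrix(2, 3, 2))
  rownames(d) <- c(paste0("m", 1:10), paste0("a", 1:3))
  d[1:2, 1] <- 2        # two donor homozygotes among 10 recipients
  d[1, 2] <- 1          # one heterozygote
  G <- make_geno(d, pos = c(1e6, 2e6))
  ds <- diagnostic_snp_set(c("s1", "s2"), character(0))
  scan <- introgression_scan(G, paste0("m", 1:10), ds)
  expect_equal(scan$donor_freq[scan$snp == "s1"], 0.20)
  expect_equal(as.character(scan$bin[scan$snp == "s1"]), ">=20%")
  expect_equal(scan$donor_freq[scan$snp == "s2"], 0.05)
  expect_equal(as.character(scan$bin[scan$snp == "s2"]), "<=10%")
  expect_error(introgression_scan(G, paste0("m", 1:10),
                                  diagnostic_snp_set("zz", character(0))),
               "absent")
})

test_that("a segment planted in 29% of recipients scans at 0.29", {
  p <- sim_params(n_meso = 100, n_andean = 10, n_chrom = 2,
                  snps_per_chrom = 80, chrom_length_bp = 2e7,
                  frac_diagnostic = 0.375, residual_het_rate = 0,
                  seed = 23)
  sim0 <- simulate_panel(p)
  meso <- names(sim0$truth$pool)[sim0$truth$pool == "Mesoamerican"]
  p$introgressions <- list(list(recipients = meso[1:29], chrom = 2,
                                start_bp = 5e6, end_bp = 9e6))
  sim <- simulate_panel(p)
  ds <- diagnostic_snp_set(sim$truth$diag_alt_in_andean,
                           sim$truth$diag_alt_in_meso)
  scan <- introgression_scan(sim$genotypes, meso, ds)
  covered <- with(sim$genotypes$map,
                  id[chrom == "Pv02" & pos >= 5e6 & pos <= 9e6])
  covered <- intersect(covered, sim$truth$diagnostic_ids)
  expect_gt(length(covered), 0)
  expect_equal(scan$donor_freq[match(covered, scan$snp)],
               rep(0.29, length(covered)))
  # outside all planted segments the donor frequency is exactly zero
  outside <- setdiff(scan$snp, covered)
  expect_equal(max(scan$donor_freq[match(outside, scan$snp)]), 0)
})

test_that("segment calling groups by LD and span with documented bins", {
  scan <- data.frame(
    snp = paste0("s", 1:7), chrom = "Pv05",
    pos = c(1e6, 1.5e6, 2e6, 2.5e6, 3e6, 9e6, 9.5e6),
    donor_freq = c(rep(0.25, 5), 0.30, 0.30),
    stringsAsFactors = FALSE)
  full <- expand.grid(a = scan$snp, b = scan$snp,
                      stringsAsFactors = FALSE)
  full <- full[full$a < full$b, ]
  ld <- data.frame(snp_a = full$a, snp_b = full$b, r2 = 1)
  segs <- detect_segments(scan, ld, max_span_bp = 2.7e6)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$n_snps, c(5, 2))
  expect_equal(segs$min_r2[1], 1)
  # weak LD splits into singletons
  ld$r2 <- 0.3
  segs2 <- detect_segments(scan, ld)
  expect_equal(segs2$n_snps, rep(1, 7))
  # no SNP above the frequency floor -> empty result
  expect_equal(nrow(detect_segments(scan, ld, freq_min = 0.5)), 0)
})

test_that("planted segments are recovered with high member overlap", {
  sim <- shared_sim_clean()
  p <- sim$truth$params
  meso <- names(sim$truth$pool)[sim$truth$pool == "Mesoamerican"]
  p$introgressions <- list(list(recipients = meso[1:15], chrom = 2,
                                start_bp = 6e6, end_bp = 8e6))
  sim2 <- simulate_panel(p)
  ds <- diagnostic_snp_set(sim2$truth$diag_alt_in_andean,
                           sim2$truth$diag_alt_in_meso)
  scan <- introgression_scan(sim2$genotypes, meso, ds)
  G <- impute_missing(sim2$genotypes)
  ld <- pairwise_r2(G[meso, ])
  segs <- detect_segments(scan, ld, freq_min = 0.20, r2_min = 0.8)
  truth_members <- with(sim2$genotypes$map,
                        id[chrom == "Pv02" & pos >= 6e6 & pos <= 8e6])
  truth_members <- intersect(truth_members, sim2$truth$diagnostic_ids)
  called <- unlist(strsplit(segs$snps, ","))
  jaccard <- length(intersect(called, truth_members)) /
    length(union(called, truth_members))
  expect_gte(jaccard, 0.9)
  # segment invariants: members inside [start, end], no SNP in two segments
  expect_false(any(duplicated(called)))
  for (i in seq_len(nrow(segs))) {
    mem <- strsplit(segs$snps[i], ",")[[1]]
    pos <- sim2$genotypes$map$pos[match(mem, sim2$genotypes$map$id)]
    expect_true(all(pos >= segs$start_bp[i] & pos <= segs$end_bp[i]))
  }
})

test_that("gene-window lookup returns signed distances", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "Pv01\tsrc\tgene\t900000\t950000\t.\t+\t.\tID=geneA",
    "Pv01\tsrc\tgene\t995000\t1005000\t.\t+\t.\tID=geneB",
    "Pv01\tsrc\tgene\t1800000\t1900000\t.\t+\t.\tID=geneC",
    "Pv01\tsrc\tgene\t5000000\t5100000\t.\t+\t.\tID=geneD",
    "Pv02\tsrc\tgene\t1000000\t1100000\t.\t+\t.\tID=geneE"), gff)
  snp <- list(id = "s1", chrom = "Pv01", pos = 1e6)
  hits <- genes_in_window(gff, snp, window_bp = 2e6)
  expect_equal(hits$gene_id, c("geneB", "geneA", "geneC"))
  expect_equal(hits$distance_bp, c(0, -(1e6 - 950000), 1800000 - 1e6))
  # empty region
  none <- genes_in_window(gff, list(id = "s2", chrom = "Pv02", pos = 9e6),
                          window_bp = 1e6)
  expect_equal(nrow(none), 0)
  expect_error(genes_in_window(gff, list(id = "s3", chrom = "Pv07",
                                         pos = 1e6)), "Pv07")
})
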