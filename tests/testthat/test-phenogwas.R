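make_rcbd <- function(n_acc, n_blocks, gen_sd = 2, res_sd = 1,
                      block_sd = 1, seed = 1, trait = "T") {
  set.seed(seed)
  g <- stats::rnorm(n_acc, 0, gen_sd)
  b <- stats::rnorm(n_blocks, 0, block_sd)
  data.frame(
    accession = rep(paste0("a", seq_len(n_acc)), n_blocks),
    block = rep(seq_len(n_blocks), each = n_acc),
    trait = trait,
    value = 50 + rep(g, n_blocks) + rep(b, each = n_acc) +
      stats::rnorm(n_acc * n_blocks, 0, res_sd))
}

test_that("balanced RCBD decomposition is exact and h2 follows from MS", {
  ph <- make_rcbd(40, 4, seed = 11)
  an <- rcbd_anova(ph, "T")
  expect_equal(unname(an$df), c(39, 3, 117))
  expect_equal(an$h2, (an$ms_cultivar - an$ms_residual) / an$ms_cultivar)
  # sequential SS add up to the total under balance
  ss_tot <- sum((ph$value - mean(ph$value))^2)
  ss_parts <- an$ms_cultivar * an$df["cultivar"] +
    an$ms_block * an$df["block"] + an$ms_residual * an$df["residual"]
  expect_equal(unname(ss_parts), ss_tot, tolerance = 1e-8)
  expect_equal(an$cv_percent, 100 * sqrt(an$ms_residual) / mean(ph$value))
  # pure noise: h2 near zero, flagged when negative
  ph0 <- make_rcbd(40, 4, gen_sd = 0, seed = 12)
  an0 <- rcbd_anova(ph0, "T")
  expect_lt(an0$h2, 0.3)
  expect_identical(an0$h2_flag, an0$h2 < 0)
  expect_error(rcbd_anova(ph, "missing_trait"), "no records")
})

test_that("simulated heritability is recovered from the ANOVA", {
  sim <- shared_sim()
  ph <- simulate_phenotypes(sim$imputed, sim$truth,
                            design = list(n_blocks = 4, traits = "DTM"),
                            h2_target = 0.8, seed = 31)
  an <- rcbd_anova(ph$phenotypes, "DTM")
  expect_false(an$balanced == FALSE)
  expect_lt(abs(an$h2 - ph$truth$realised_h2[["DTM"]]), 0.05)
  expect_lt(abs(an$h2 - 0.8), 0.1)
})

test_that("least-squares means equal raw means only under balance", {
  ph <- make_rcbd(12, 3, seed = 21)
  lsm <- ls_means(ph, "T")
  raw <- tapply(ph$value, ph$accession, mean)[names(lsm)]
  expect_equal(unname(lsm), as.numeric(raw), tolerance = 1e-12)
  # drop one plot from a high block: adjusted mean moves the right way
  drop_row <- which(ph$accession == "a1" & ph$block == 1)
  ph2 <- ph[-drop_row, ]
  lsm2 <- suppressWarnings(ls_means(ph2, "T"))
  raw2 <- tapply(ph2$value, ph2$accession, mean)["a1"]
  # normal-equations oracle: solve the two-way model directly
  X <- stats::model.matrix(~ 0 + accession + block,
                           transform(ph2, accession = factor(accession),
                                     block = factor(block)))
  beta <- solve(crossprod(X), crossprod(X, ph2$value))
  blocks <- grep("^block", rownames(beta))
  oracle <- beta["accessiona1", 1] +
    sum(c(0, beta[blocks, 1])) / (length(blocks) + 1)
  expect_equal(unname(lsm2["a1"]), unname(oracle), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(lsm2[["a1"]], raw2[[1]])))
  # constant trait maps to the constant
  phc <- make_rcbd(6, 2, gen_sd = 0, res_sd = 0, block_sd = 0, seed = 3)
  expect_equal(unname(ls_means(phc, "T")), rep(50, 6))
})

test_that("trait correlations respond to a shared QTL and flag degeneracy", {
  sim <- shared_sim()
  ph <- simulate_phenotypes(sim$imputed, sim$truth, seed = 41)
  means <- sapply(c("DTF", "DTM"), function(tr)
    ls_means(ph$phenotypes, tr))
  tc <- trait_correlations(as.data.frame(means))
  expect_gt(tc$r[1], 0.2)
  expect_lt(tc$p_value[1], 0.01)
  # independent traits stay near zero on average
  set.seed(42)
  indep <- data.frame(x = stats::rnorm(60), y = stats::rnorm(60))
  tci <- trait_correlations(indep)
  expect_lt(abs(tci$r[1]), 0.35)
  degen <- trait_correlations(data.frame(x = stats::rnorm(10),
                                         y = rep(1, 10)))
  expect_true(degen$degenerate[1])
  expect_true(is.na(degen$r[1]))
  expect_error(trait_correlations(data.frame(x = 1:2, y = 2:3)), ">= 3")
})

test_that("BIC covariate selection tracks structure in the phenotype", {
  sim <- shared_sim()
  G <- sim$imputed
  pc <- geno_pca(G, n_components = 5)
  set.seed(51)
  y_null <- stats::rnorm(nrow(G$dosage))
  names(y_null) <- rownames(G$dosage)
  expect_equal(bic_select_pcs(G, y_null, max_pcs = 5), 0)
  y_pc1 <- pc$scores[, 1] + stats::rnorm(nrow(G$dosage), 0,
                                         0.1 * stats::sd(pc$scores[, 1]))
  names(y_pc1) <- rownames(G$dosage)
  expect_gte(bic_select_pcs(G, y_pc1, max_pcs = 5), 1)
  expect_equal(bic_select_pcs(G, y_null, max_pcs = 0), 0)
  expect_error(bic_select_pcs(G, y_null, max_pcs = 60), "max_pcs")
})

test_that("the scan matches per-SNP linear models and finds planted QTLs", {
  sim <- shared_sim()
  G <- sim$imputed[1:40, 1:60]
  set.seed(61)
  y <- stats::rnorm(40)
  names(y) <- rownames(G$dosage)
  scan <- gwas_scan(G, y)
  # dual route: lm() per SNP as the independent oracle
  for (j in sample(60, 12)) {
    if (scan$monomorphic[j]) next
    fit <- summary(stats::lm(y ~ G$dosage[, j]))$coefficients
    expect_equal(scan$p[j], fit[2, 4], tolerance = 1e-10)
    expect_equal(scan$effect[j], fit[2, 1], tolerance = 1e-10)
  }
  # planted large-effect QTL is the top hit (or a proxy in strong LD)
  ph <- simulate_phenotypes(sim$imputed, sim$truth,
                            design = list(n_blocks = 4, traits = "DTF"),
                            qtl_spec = data.frame(
                              trait = "DTF", effect = 4,
                              snp = sim$truth$diagnostic_ids[10]),
                            seed = 62)
  lsm <- ls_means(ph$phenotypes, "DTF")
  full <- gwas_scan(sim$imputed, lsm)
  top <- full$snp[which.min(full$p)]
  if (top != sim$truth$diagnostic_ids[10]) {
    ld <- pairwise_r2(sim$imputed)
    r2 <- ld$r2[(ld$snp_a == top & ld$snp_b == sim$truth$diagnostic_ids[10]) |
                  (ld$snp_b == top & ld$snp_a == sim$truth$diagnostic_ids[10])]
    expect_gte(r2, 0.8)
  } else succeed()
  # constant phenotype: everything flagged to p = 1
  yc <- stats::setNames(rep(1, 40), rownames(G$dosage))
  expect_true(all(gwas_scan(G, yc)$p == 1))
})

test_that("scan p-values are uniform under a permuted phenotype", {
  sim <- shared_sim()
  # one class, non-diagnostic SNPs, one SNP per founder block: the
  # retained dosage columns are close to mutually independent
  acc <- names(sim$truth$class)[sim$truth$class == "Carioca"]
  G <- sim$imputed[acc, ]
  ph <- simulate_phenotypes(sim$imputed, sim$truth,
                            design = list(n_blocks = 4, traits = "DTF"),
                            seed = 71)
  lsm <- ls_means(ph$phenotypes, "DTF")[acc]
  set.seed(72)
  yperm <- stats::setNames(sample(lsm), names(lsm))
  scan <- gwas_scan(G, yperm)
  keep <- !scan$monomorphic &
    !(scan$snp %in% sim$truth$diagnostic_ids) &
    !duplicated(paste(scan$chrom, (scan$pos - 1) %/% 2e6))
  ks <- suppressWarnings(stats::ks.test(scan$p[keep], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("permutation threshold: analytic limit, determinism, warnings", {
  sim <- shared_sim()
  G1 <- sim$imputed[, 1]
  set.seed(81)
  y <- stats::rnorm(60)
  names(y) <- rownames(sim$imputed$dosage)
  thr <- permutation_threshold(G1, y, n_perm = 400, seed = 2)
  expect_lt(abs(thr - 0.05), 0.03)   # min-p over one SNP is uniform
  thr2 <- permutation_threshold(G1, y, n_perm = 400, seed = 2)
  expect_equal(as.numeric(thr), as.numeric(thr2))
  expect_warning(permutation_threshold(G1, y, n_perm = 10, seed = 1),
                 "unstable")
  # the permissive literal reading is available by configuration
  thr95 <- permutation_threshold(G1, y, n_perm = 400,
                                 quantile_level = 0.95, seed = 2)
  expect_gt(as.numeric(thr95), as.numeric(thr))
})

test_that("Bonferroni threshold arithmetic", {
  expect_equal(bonferroni_threshold(1927, 0.01), 0.01 / 1927)
  expect_equal(bonferroni_threshold(1), 0.01)
  expect_equal(bonferroni_threshold(10, 0), 0)
})

test_that("QTL detection power at the Bonferroni threshold is high", {
  sim <- shared_sim()
  G <- sim$imputed
  thr <- bonferroni_threshold(ncol(G$dosage), 0.01)
  hits <- 0
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    qtl <- data.frame(trait = "DTF", effect = 1.2,
                      snp = sample(sim$truth$diagnostic_ids, 1))
    ph <- simulate_phenotypes(G, sim$truth,
                              design = list(n_blocks = 4, traits = "DTF"),
                              qtl_spec = qtl, h2_target = 0.7,
                              seed = 500 + r)
    lsm <- ls_means(ph$phenotypes, "DTF")
    scan <- gwas_scan(G, lsm)
    if (min(scan$p) < thr) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})
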