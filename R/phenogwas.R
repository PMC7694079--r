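#' RCBD analysis of variance for one trait
#'
#' Two-way decomposition `value = mean + cultivar + block + residual`.
#' Under a balanced design the standard sequential ANOVA is exact; an
#' unbalanced design falls back to the same least-squares decomposition
#' and is flagged. Reports mean squares, the coefficient of variation
#' `CV = 100 * sqrt(MS_residual) / grand mean`, line-mean broad-sense
#' heritability `h2 = (MS_cultivar - MS_residual) / MS_cultivar` (flagged
#' when `MS_cultivar < MS_residual`), and a Shapiro-Wilk normality test on
#' the model residuals.
#'
#' @param phenotypes long data.frame with columns `accession`, `block`,
#'   `trait`, `value`.
#' @param trait trait name to analyse.
#' @return an `anova_summary`: list of mean squares, dfs, CV, h2,
#'   normality p, flags.
#' @export
rcbd_anova <- function(phenotypes, trait) {
  p <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  if (!nrow(p)) stop("no records for trait ", trait)
  p$accession <- factor(p$accession)
  p$block <- factor(p$block)
  if (nlevels(p$accession) < 2 || nlevels(p$block) < 2)
    stop("RCBD ANOVA needs >= 2 accessions and >= 2 blocks")
  balanced <- all(table(p$accession, p$block) == 1)
  if (!balanced)
    warning("unbalanced design: least-squares (sequential) decomposition ",
            "used")
  fit <- stats::lm(value ~ block + accession, data = p)
  an <- stats::anova(fit)
  ms <- an[["Mean Sq"]]
  names(ms) <- rownames(an)
  ms_block <- ms[["block"]]
  ms_cult <- ms[["accession"]]
  ms_res <- ms[["Residuals"]]
  h2 <- (ms_cult - ms_res) / ms_cult
  res <- stats::resid(fit)
  sw <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 0)
    stats::shapiro.test(res)$p.value else NA_real_
  structure(list(
    trait = trait,
    ms_cultivar = ms_cult, ms_block = ms_block, ms_residual = ms_res,
    df = c(cultivar = an["accession", "Df"], block = an["block", "Df"],
           residual = an["Residuals", "Df"]),
    f_cultivar_p = an["accession", "Pr(>F)"],
    f_block_p = an["block", "Pr(>F)"],
    cv_percent = 100 * sqrt(ms_res) / mean(p$value),
    h2 = h2, h2_flag = h2 < 0,
    shapiro_p = sw, balanced = balanced, fit = fit),
    class = "anova_summary")
}

#' @export
print.anova_summary <- function(x, ...) {
  cat(sprintf("RCBD ANOVA, trait %s%s\n", x$trait,
              if (x$balanced) "" else " (unbalanced)"))
  cat(sprintf("  MS cultivar %.4g (df %d, p %.3g) | MS block %.4g | MS residual %.4g\n",
              x$ms_cultivar, x$df["cultivar"], x$f_cultivar_p, x$ms_block,
              x$ms_residual))
  cat(sprintf("  CV %.2f%% | h2 %.3f%s | Shapiro-Wilk p %.3g\n",
              x$cv_percent, x$h2, if (x$h2_flag) " (negative, flagged)"
              else "", x$shapiro_p))
  invisible(x)
}

#' Least-squares (adjusted) accession means
#'
#' Accession effects plus grand mean from the two-way RCBD model; equal to
#' arithmetic accession means under a balanced design, and adjusted for
#' block membership otherwise. Accessions absent from every block are
#' dropped with a warning.
#'
#' @param phenotypes long phenotype data.frame.
#' @param trait trait name.
#' @return named numeric vector of adjusted means per accession.
#' @export
ls_means <- function(phenotypes, trait) {
  p <- phenotypes[phenotypes$trait == trait & !is.na(phenotypes$value), ,
                  drop = FALSE]
  if (!nrow(p)) stop("no records for trait ", trait)
  all_acc <- unique(phenotypes$accession[phenotypes$trait == trait])
  dropped <- setdiff(all_acc, p$accession)
  if (length(dropped))
    warning("accession(s) with no observations dropped: ",
            paste(dropped, collapse = ", "))
  p$accession <- factor(p$accession)
  p$block <- factor(p$block)
  if (nlevels(p$block) < 2) {
    m <- tapply(p$value, p$accession, mean)
    return(stats::setNames(as.numeric(m[levels(p$accession)]),
                           levels(p$accession)))
  }
  fit <- stats::lm(value ~ accession + block, data = p)
  grid <- expand.grid(accession = levels(p$accession),
                      block = levels(p$block))
  pred <- stats::predict(fit, newdata = grid)
  out <- tapply(pred, grid$accession, mean)
  stats::setNames(as.numeric(out[levels(p$accession)]),
                  levels(p$accession))
}

#' Pairwise trait correlations on accession means
#'
#' Pearson correlation with two-sided p-values between every trait pair.
#' Zero-variance traits give `NA` and are flagged.
#'
#' @param means_table data.frame of least-squares means, accessions in
#'   rows, one column per trait.
#' @return data.frame per pair: `trait_a`, `trait_b`, `r`, `p_value`,
#'   `degenerate` flag.
#' @export
trait_correlations <- function(means_table) {
  tr <- colnames(means_table)
  if (nrow(means_table) < 3) stop("need >= 3 accessions")
  out <- list()
  for (i in seq_along(tr)) for (j in seq_along(tr)) {
    if (j <= i) next
    x <- means_table[[i]]
    y <- means_table[[j]]
    degenerate <- stats::sd(x) == 0 || stats::sd(y) == 0
    if (degenerate) {
      r <- NA_real_; pv <- NA_real_
    } else {
      ct <- stats::cor.test(x, y)
      r <- unname(ct$estimate); pv <- ct$p.value
    }
    out[[length(out) + 1L]] <- data.frame(
      trait_a = tr[i], trait_b = tr[j], r = r, p_value = pv,
      degenerate = degenerate, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' BIC selection of the number of PC covariates
#'
#' Fits the covariate-only model `y ~ 1 + PC1..PCk` for `k = 0..max_pcs`
#' and returns the `k` with the highest BIC in the
#' higher-is-better convention `logLik - (k_params / 2) * ln n`.
#'
#' @param G an imputed [geno_matrix()].
#' @param y named numeric phenotype vector (accession means).
#' @param max_pcs largest number of leading PCs considered (default 5).
#' @return integer: selected number of PCs.
#' @export
bic_select_pcs <- function(G, y, max_pcs = 5L) {
  y <- y[rownames(G$dosage)]
  if (anyNA(y)) stop("phenotype missing for some accessions")
  n <- length(y)
  if (max_pcs >= n) stop("max_pcs must be < number of accessions")
  if (max_pcs == 0L) return(0L)
  pc <- geno_pca(G, n_components = max_pcs)
  bic <- vapply(0:max_pcs, function(k) {
    X <- if (k == 0) matrix(1, n, 1) else cbind(1, pc$scores[, 1:k])
    res <- stats::lm.fit(X, y)$residuals
    ll <- -n / 2 * (log(2 * pi * sum(res^2) / n) + 1)
    k_params <- k + 2   # intercept + k slopes + error variance
    ll - (k_params / 2) * log(n)
  }, numeric(1))
  (0:max_pcs)[which.max(bic)]
}

#' Single-marker association scan
#'
#' Per SNP, the linear model `y ~ intercept + PCs + dosage`; the reported
#' p-value is the two-sided t-test on the dosage coefficient. Monomorphic
#' SNPs get `p = 1` and are flagged. The scan is computed in closed form
#' on covariate-residualised phenotype and dosages, which makes the
#' permutation-threshold machinery cheap.
#'
#' @param G an imputed [geno_matrix()].
#' @param y named numeric phenotype vector.
#' @param n_pcs number of leading PC covariates (e.g. from
#'   [bic_select_pcs()]).
#' @return a `gwas_result`: data.frame per SNP (`snp`, `chrom`, `pos`,
#'   `effect`, `t`, `p`, `monomorphic`) with `n_pcs` attribute.
#' @export
gwas_scan <- function(G, y, n_pcs = 0L) {
  y <- y[rownames(G$dosage)]
  if (anyNA(y)) stop("phenotype missing for some accessions")
  n <- length(y)
  if (stats::sd(y) < 1e-12) {
    out <- data.frame(snp = G$map$id, chrom = G$map$chrom,
                      pos = G$map$pos, effect = 0, t = NA_real_, p = 1,
                      monomorphic = FALSE, stringsAsFactors = FALSE)
    attr(out, "n_pcs") <- n_pcs
    attr(out, "degenerate_phenotype") <- TRUE
    class(out) <- c("gwas_result", class(out))
    return(out)
  }
  X <- matrix(1, n, 1)
  if (n_pcs > 0)
    X <- cbind(X, geno_pca(G, n_components = n_pcs)$scores)
  q <- ncol(X)
  M <- diag(n) - X %*% solve(crossprod(X), t(X))
  ry <- as.vector(M %*% y)
  rd <- M %*% G$dosage
  sxx <- colSums(rd^2)
  mono <- sxx < 1e-12
  sxy <- as.vector(crossprod(rd, ry))
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  df <- n - q - 1
  syy <- sum(ry^2)
  sse <- pmax(syy - ifelse(mono, 0, beta^2 * sxx), 0)
  tstat <- ifelse(mono | sse <= 1e-300, NA_real_,
                  beta / sqrt(sse / df / sxx))
  p <- ifelse(is.na(tstat), 1, 2 * stats::pt(-abs(tstat), df))
  p <- pmin(pmax(p, 1e-300), 1)
  out <- data.frame(snp = G$map$id, chrom = G$map$chrom, pos = G$map$pos,
                    effect = beta, t = tstat, p = p, monomorphic = mono,
                    stringsAsFactors = FALSE)
  attr(out, "n_pcs") <- n_pcs
  class(out) <- c("gwas_result", class(out))
  out
}

#' Permutation-calibrated scan threshold
#'
#' The trait is permuted `n_perm` times to break genotype-phenotype
#' association; each permutation is fully re-scanned and its minimum
#' p-value recorded. The threshold is the `quantile_level` quantile of the
#' minimum-p distribution (default 0.05, which controls the family-wise
#' error rate at ~5%; the permissive 0.95 reading is available by setting
#' `quantile_level = 0.95`).
#'
#' @param G an imputed [geno_matrix()].
#' @param y named numeric phenotype vector.
#' @param n_perm number of permutations (default 300).
#' @param quantile_level quantile of the min-p null distribution.
#' @param n_pcs PC covariates, as in [gwas_scan()].
#' @param seed integer seed.
#' @return the p-value threshold, with the permutation minima as
#'   attribute `min_p`.
#' @export
permutation_threshold <- function(G, y, n_perm = 300L,
                                  quantile_level = 0.05, n_pcs = 0L,
                                  seed = 1L) {
  if (n_perm < 20)
    warning("n_perm < 20 gives an unstable quantile estimate")
  y <- y[rownames(G$dosage)]
  n <- length(y)
  X <- matrix(1, n, 1)
  if (n_pcs > 0)
    X <- cbind(X, geno_pca(G, n_components = n_pcs)$scores)
  q <- ncol(X)
  M <- diag(n) - X %*% solve(crossprod(X), t(X))
  rd <- M %*% G$dosage
  sxx <- colSums(rd^2)
  poly <- sxx > 1e-12
  rd <- rd[, poly, drop = FALSE]
  sxx <- sxx[poly]
  df <- n - q - 1
  set.seed(as.integer(seed))
  min_p <- vapply(seq_len(n_perm), function(b) {
    ry <- as.vector(M %*% sample(y))
    sxy <- as.vector(crossprod(rd, ry))
    beta <- sxy / sxx
    sse <- pmax(sum(ry^2) - beta^2 * sxx, 1e-300)
    tstat <- beta / sqrt(sse / df / sxx)
    min(2 * stats::pt(-abs(tstat), df))
  }, numeric(1))
  # order-statistic (type 1) quantile: a resampling threshold should be an
  # attained permutation minimum, and interpolation is anticonservative
  thr <- unname(stats::quantile(min_p, quantile_level, type = 1))
  attr(thr, "min_p") <- min_p
  thr
}

#' Bonferroni scan threshold
#'
#' @param n_snps number of tests.
#' @param alpha family-wise error level (default 0.01).
#' @return `alpha / n_snps`.
#' @export
bonferroni_threshold <- function(n_snps, alpha = 0.01) {
  stopifnot(n_snps >= 1, alpha >= 0)
  alpha / n_snps
}
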