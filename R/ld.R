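#' Pairwise intrachromosomal r-squared
#'
#' Squared Pearson correlation of dosage vectors for every pair of SNPs on
#' the same chromosome (optionally within `max_dist_bp`). On an almost
#' fully inbred panel this coincides with the haplotype-based r-squared.
#' Pairs involving a monomorphic SNP are skipped; their count is attached
#' as attribute `n_skipped_monomorphic`.
#'
#' @param G an imputed [geno_matrix()].
#' @param max_dist_bp optional maximum pair distance.
#' @return data.frame: `snp_a`, `snp_b`, `chrom`, `dist_bp`, `r2`, plus the
#'   skip-count attribute.
#' @export
pairwise_r2 <- function(G, max_dist_bp = NULL) {
  corrected_r2(G, covariates = NULL, max_dist_bp = max_dist_bp)
}

#' Structure- or kinship-corrected pairwise r-squared
#'
#' Pairwise LD with confounding removed. In structure mode (`covariates` a
#' matrix of membership/PC columns) each dosage vector is projected off the
#' covariate column space (plus intercept) and r-squared is computed on the
#' residuals. In kinship mode (`kinship` an accessions x accessions
#' relationship matrix) dosage vectors are whitened by the inverse square
#' root of the kinship matrix before correlation. With no covariates the
#' raw r-squared is returned.
#'
#' @param G an imputed [geno_matrix()].
#' @param covariates numeric matrix (accessions x q) of structure
#'   covariates, or `NULL`.
#' @param kinship accessions x accessions kinship matrix, or `NULL`
#'   (mutually exclusive with `covariates`).
#' @param max_dist_bp optional maximum pair distance.
#' @param ridge ridge term added to the kinship diagonal before the inverse
#'   square root when it is near-singular.
#' @return as [pairwise_r2()], with a `correction` attribute
#'   (`"none"`, `"structure"` or `"kinship"`).
#' @export
corrected_r2 <- function(G, covariates = NULL, kinship = NULL,
                         max_dist_bp = NULL, ridge = 1e-8) {
  if (!is.null(covariates) && !is.null(kinship))
    stop("give either covariates (structure mode) or kinship, not both")
  d <- G$dosage
  if (anyNA(d)) stop("missing dosages: run impute_missing() first")
  mode <- "none"
  if (!is.null(covariates)) {
    mode <- "structure"
    X <- cbind(1, as.matrix(covariates))
    d <- stats::resid(stats::lm.fit(X, d))
  } else if (!is.null(kinship)) {
    mode <- "kinship"
    ek <- eigen(kinship, symmetric = TRUE)
    vals <- ek$values
    if (min(vals) < ridge * max(vals)) vals <- vals + ridge * max(vals)
    if (min(vals) <= 0)
      stop("kinship matrix not positive definite even after ridge ",
           ridge, "; increase the ridge term")
    W <- ek$vectors %*% (t(ek$vectors) / sqrt(vals))
    d <- W %*% scale(d, center = TRUE, scale = FALSE)
  }
  sds <- apply(d, 2, stats::sd)
  poly <- sds > 1e-12
  n_skip <- 0L
  out <- list()
  for (ch in unique(G$map$chrom)) {
    j <- which(G$map$chrom == ch)
    if (length(j) < 2) next
    cmb <- utils::combn(j, 2)
    dist <- G$map$pos[cmb[2, ]] - G$map$pos[cmb[1, ]]
    keep <- rep(TRUE, ncol(cmb))
    if (!is.null(max_dist_bp)) keep <- dist <= max_dist_bp
    mono <- !(poly[cmb[1, ]] & poly[cmb[2, ]])
    n_skip <- n_skip + sum(mono & keep)
    keep <- keep & !mono
    if (!any(keep)) next
    jp <- j[poly[j]]
    cc <- stats::cor(d[, jp, drop = FALSE])
    ia <- match(cmb[1, keep], jp)
    ib <- match(cmb[2, keep], jp)
    out[[ch]] <- data.frame(
      snp_a = G$map$id[cmb[1, keep]], snp_b = G$map$id[cmb[2, keep]],
      chrom = ch, dist_bp = dist[keep],
      r2 = pmin(cc[cbind(ia, ib)]^2, 1), stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no polymorphic intrachromosomal SNP pair found")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_skipped_monomorphic") <- n_skip
  attr(res, "correction") <- mode
  res
}

#' VanRaden kinship matrix
#'
#' Centred cross-product of the dosage matrix scaled by
#' `sum over loci of 2 p (1 - p)`; symmetric and positive semidefinite.
#'
#' @param G an imputed [geno_matrix()].
#' @return accessions x accessions kinship matrix.
#' @export
kinship_matrix <- function(G) {
  d <- G$dosage
  if (anyNA(d)) stop("missing dosages: run impute_missing() first")
  p <- colMeans(d) / 2
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("kinship undefined: all SNPs monomorphic")
  Z <- sweep(d, 2, 2 * p)
  K <- Z %*% t(Z) / denom
  (K + t(K)) / 2
}

# Hill-Weir expected r2 at recombination scale C = rho * distance, for
# sample size n
hill_weir_expectation <- function(C, n) {
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir LD-decay model
#'
#' Nonlinear least squares of observed pairwise r-squared against distance
#' under the drift-recombination expectation
#' `E(r2) = [(10+C)/((2+C)(11+C))] * [1 + ((3+C)(12+12C+C^2)) /
#' (n (2+C)(11+C))]` with `C = rho * d`; `rho` (per bp) is constrained
#' non-negative.
#'
#' @param pairs data.frame with `dist_bp` and `r2` (see [pairwise_r2()]).
#' @param n number of accessions the pairs were computed from.
#' @return a `hill_weir_fit`: list with `rho`, `n`, `rss`, `n_pairs` and
#'   `curve(d)`, the fitted-expectation evaluator.
#' @export
fit_hill_weir <- function(pairs, n) {
  stopifnot(nrow(pairs) >= 10, n >= 2)
  d <- pairs$dist_bp
  r2 <- pairs$r2
  start_rho <- 1 / stats::median(d)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      r2 ~ hill_weir_expectation(rho * d, n),
      start = list(rho = start_rho), lower = 0,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Hill-Weir optimisation failed: ", conditionMessage(e),
           " (n_pairs = ", length(d), ", start rho = ", start_rho, ")"))
  rho <- stats::coef(fit)[["rho"]]
  structure(list(rho = rho, n = n, rss = sum(stats::resid(fit)^2),
                 n_pairs = length(d),
                 curve = function(d) hill_weir_expectation(rho * d, n)),
            class = "hill_weir_fit")
}

#' @export
print.hill_weir_fit <- function(x, ...) {
  cat("hill_weir_fit: rho =", format(x$rho), "per bp | n =", x$n,
      "| pairs =", x$n_pairs, "\n")
  invisible(x)
}

#' Distance at which fitted LD decays to a threshold
#'
#' Root-brackets the (strictly decreasing) fitted Hill-Weir curve. Returns
#' `NA` ("never") when the curve already starts below the threshold, or
#' when rho = 0 (no decay).
#'
#' @param fit a `hill_weir_fit`.
#' @param threshold r-squared threshold (default 0.2, the field's standard
#'   decay criterion).
#' @return decay distance in bp, or `NA_real_`.
#' @export
decay_distance <- function(fit, threshold = 0.2) {
  stopifnot(inherits(fit, "hill_weir_fit"))
  at0 <- fit$curve(0)
  if (threshold <= 0 || at0 <= threshold || fit$rho <= 0)
    return(NA_real_)
  hi <- 1
  while (fit$curve(hi) > threshold && hi < 1e15) hi <- hi * 10
  stats::uniroot(function(d) fit$curve(d) - threshold, c(0, hi),
                 tol = 1e-6)$root
}

#' Minimum SNP count for genome-wide coverage
#'
#' Number of markers needed so that adjacent markers sit within the LD
#' decay distance: `round(genome_size_mb / decay_distance_mb)`
#' (round-half-to-even, R's default rounding).
#'
#' @param genome_size_mb genome size in Mb.
#' @param decay_distance_mb LD decay distance in Mb.
#' @return integer SNP count.
#' @export
min_snp_count <- function(genome_size_mb, decay_distance_mb) {
  stopifnot(genome_size_mb > 0)
  if (decay_distance_mb <= 0)
    stop("decay distance must be > 0")
  as.integer(round(genome_size_mb / decay_distance_mb))
}
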