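#' Maximum-likelihood admixture estimation by EM
#'
#' Estimates per-accession membership coefficients `Q` (n x K) and
#' per-cluster allele frequencies `P` (K x SNPs) under the binomial
#' admixture likelihood: dosage `g_il ~ Binomial(2, f_il)` with
#' `f_il = sum_k q_ik p_kl`. Alternating EM updates of `Q` and `P` increase
#' the log-likelihood monotonically; the best of `n_restarts` random starts
#' is returned. In supervised mode the `Q` rows of labelled reference
#' accessions are held fixed at their label's unit vector while `P` and
#' the remaining rows are estimated.
#'
#' @param G an imputed [geno_matrix()].
#' @param K number of ancestral clusters (>= 1).
#' @param seed integer seed for the random restarts.
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence tolerance on the log-likelihood gain.
#' @param supervised_labels optional named vector mapping accession id to a
#'   cluster index in `1..K`; those rows of `Q` are fixed.
#' @param n_restarts number of random restarts.
#' @return an `ancestry_result`: list with `Q`, `P`, `loglik`, `K`, `seed`,
#'   `converged`, `n_iter`, `scope`.
#' @export
em_admixture <- function(G, K, seed = 1L, max_iter = 500L, tol = 1e-6,
                         supervised_labels = NULL, n_restarts = 5L) {
  stopifnot(inherits(G, "geno_matrix"), K >= 1)
  d <- G$dosage
  if (anyNA(d)) stop("missing dosages: run impute_missing() first")
  n <- nrow(d)
  L <- ncol(d)
  if (K > n) stop("K = ", K, " exceeds the number of accessions (", n, ")")
  if (K == 1L) {
    p <- colMeans(d) / 2
    pc <- pmin(pmax(p, 1e-9), 1 - 1e-9)
    ll <- sum(stats::dbinom(d, 2, rep(pc, each = n), log = TRUE))
    return(structure(list(
      Q = matrix(1, n, 1, dimnames = list(rownames(d), "k1")),
      P = matrix(p, 1, L, dimnames = list("k1", colnames(d))),
      loglik = ll, K = 1L, seed = seed, converged = TRUE, n_iter = 0L,
      scope = "genome-wide"), class = "ancestry_result"))
  }
  fixed <- NULL
  if (!is.null(supervised_labels)) {
    ix <- match(names(supervised_labels), rownames(d))
    if (anyNA(ix)) stop("supervised label(s) for unknown accession(s)")
    fixed <- list(rows = ix, Qfix = diag(K)[as.integer(supervised_labels), ,
                                           drop = FALSE])
  }
  set.seed(as.integer(seed))
  eps <- 1e-6
  best <- NULL
  for (r in seq_len(n_restarts)) {
    Q <- matrix(stats::rgamma(n * K, 1), n, K)
    Q <- Q / rowSums(Q)
    P <- matrix(stats::runif(K * L, 0.05, 0.95), K, L)
    if (!is.null(fixed)) Q[fixed$rows, ] <- fixed$Qfix
    ll_prev <- -Inf
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      P <- pmin(pmax(P, eps), 1 - eps)
      f <- Q %*% P
      f <- pmin(pmax(f, eps), 1 - eps)
      Anum <- d / f          # n x L, expected alt-allele weight / (q p)
      Bnum <- (2 - d) / (1 - f)
      Qnew <- matrix(0, n, K)
      Pnew <- matrix(0, K, L)
      for (k in seq_len(K)) {
        a_k <- Anum * (Q[, k] %o% P[k, ])        # expected alt copies from k
        b_k <- Bnum * (Q[, k] %o% (1 - P[k, ]))  # expected ref copies from k
        Qnew[, k] <- rowSums(a_k) + rowSums(b_k)
        Pnew[k, ] <- colSums(a_k) / pmax(colSums(a_k) + colSums(b_k), 1e-12)
      }
      Qnew <- Qnew / (2 * L)
      if (!is.null(fixed)) Qnew[fixed$rows, ] <- fixed$Qfix
      Q <- Qnew
      P <- Pnew
      fc <- pmin(pmax(Q %*% pmin(pmax(P, eps), 1 - eps), eps), 1 - eps)
      ll <- sum(d * log(fc) + (2 - d) * log(1 - fc)) +
        sum(lchoose(2, d))
      if (ll < ll_prev - 1e-6 * abs(ll_prev))
        stop("EM log-likelihood decreased (", ll_prev, " -> ", ll,
             "); this indicates a numerical fault")
      if (ll - ll_prev < tol) { converged <- TRUE; ll_prev <- ll; break }
      ll_prev <- ll
    }
    if (is.null(best) || ll_prev > best$loglik)
      best <- list(Q = Q, P = P, loglik = ll_prev, converged = converged,
                   n_iter = it)
  }
  if (!best$converged)
    warning("EM did not converge in ", max_iter, " iterations")
  dimnames(best$Q) <- list(rownames(d), paste0("k", seq_len(K)))
  dimnames(best$P) <- list(paste0("k", seq_len(K)), colnames(d))
  structure(list(Q = best$Q, P = best$P, loglik = best$loglik, K = K,
                 seed = seed, converged = best$converged,
                 n_iter = best$n_iter, scope = "genome-wide"),
            class = "ancestry_result")
}

#' @export
print.ancestry_result <- function(x, ...) {
  cat("ancestry_result: K =", x$K, "| scope:", x$scope,
      "| loglik:", format(x$loglik), "\n")
  invisible(x)
}

#' Per-chromosome ancestry estimation
#'
#' Runs [em_admixture()] on each chromosome's SNPs separately (the scan used
#' to localise inter-pool introgression) and aligns cluster labels across
#' chromosomes by correlating each chromosome's cluster allele frequencies
#' with the genome-wide ones, which removes EM label switching.
#'
#' @param G an imputed [geno_matrix()].
#' @param K number of clusters (default 2, the two gene pools).
#' @param seed integer seed.
#' @param min_snps chromosomes with fewer SNPs are skipped with a warning.
#' @param genome_result optional genome-wide `ancestry_result` to align
#'   against; computed when absent.
#' @param ... passed on to [em_admixture()].
#' @return named list of `ancestry_result`, one per analysed chromosome,
#'   labels aligned to the genome-wide clustering.
#' @export
per_chromosome_ancestry <- function(G, K = 2L, seed = 1L, min_snps = 20L,
                                    genome_result = NULL, ...) {
  if (is.null(genome_result))
    genome_result <- em_admixture(G, K = K, seed = seed, ...)
  chroms <- unique(G$map$chrom)
  out <- list()
  for (ch in chroms) {
    snps <- which(G$map$chrom == ch)
    if (length(snps) < min_snps) {
      warning("chromosome ", ch, " has ", length(snps), " SNPs (< ",
              min_snps, "); skipped")
      next
    }
    res <- em_admixture(G[, snps], K = K, seed = seed, ...)
    perm <- align_clusters(res$P, genome_result$P[, snps, drop = FALSE])
    res$Q <- res$Q[, perm, drop = FALSE]
    res$P <- res$P[perm, , drop = FALSE]
    dimnames(res$Q)[[2]] <- paste0("k", seq_len(K))
    dimnames(res$P)[[1]] <- paste0("k", seq_len(K))
    res$scope <- ch
    out[[ch]] <- res
  }
  if (!length(out)) stop("no chromosome reached min_snps = ", min_snps)
  out
}

# permutation of rows of P maximising agreement with Pref (same loci)
align_clusters <- function(P, Pref) {
  K <- nrow(P)
  if (K == 1L) return(1L)
  perms <- all_permutations(K)
  score <- vapply(perms, function(pm)
    -sum((P[pm, , drop = FALSE] - Pref)^2), numeric(1))
  perms[[which.max(score)]]
}

all_permutations <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- all_permutations(K - 1L)
  out <- list()
  for (s in sub) for (pos in 0:(K - 1L))
    out[[length(out) + 1L]] <- append(s, K, after = pos)
  out
}

#' Evanno delta-K from replicate clustering runs
#'
#' Second-order rate of change of the model log-likelihood across K,
#' scaled by the between-run standard deviation:
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`.
#' Defined only for interior K; where `sd = 0` the value is `NA` and
#' flagged.
#'
#' @param runs data.frame with columns `K`, `run`, `loglik`; >= 2 runs per
#'   K over consecutive K values.
#' @return data.frame per K: `K`, `n_runs`, `mean_loglik`, `sd_loglik`,
#'   `abs_l2` (|second difference|), `delta_k`, `sd_zero` flag.
#' @export
evanno_delta_k <- function(runs) {
  stopifnot(all(c("K", "run", "loglik") %in% names(runs)))
  ks <- sort(unique(runs$K))
  if (length(ks) >= 2 && any(diff(ks) != 1))
    stop("K values must be consecutive")
  agg <- do.call(rbind, lapply(ks, function(k) {
    l <- runs$loglik[runs$K == k]
    if (length(l) < 2) stop("need >= 2 runs per K (K = ", k, ")")
    data.frame(K = k, n_runs = length(l), mean_loglik = mean(l),
               sd_loglik = stats::sd(l))
  }))
  m <- agg$mean_loglik
  nk <- nrow(agg)
  agg$abs_l2 <- NA_real_
  if (nk >= 3)
    agg$abs_l2[2:(nk - 1)] <- abs(m[3:nk] - 2 * m[2:(nk - 1)] +
                                    m[1:(nk - 2)])
  agg$sd_zero <- agg$sd_loglik == 0
  agg$delta_k <- ifelse(agg$sd_zero, NA_real_, agg$abs_l2 / agg$sd_loglik)
  agg
}

#' Principal component analysis of the dosage matrix
#'
#' @param G an imputed [geno_matrix()].
#' @param n_components number of components to return.
#' @param scale centre-and-scale columns (default: centre only).
#' @return list with `scores` (accessions x components), `variance_fraction`
#'   and the `rotation` matrix (SNPs x components).
#' @export
geno_pca <- function(G, n_components = 10L, scale = FALSE) {
  d <- G$dosage
  if (anyNA(d)) stop("missing dosages: run impute_missing() first")
  if (nrow(d) < 2) stop("PCA needs >= 2 accessions")
  keep <- apply(d, 2, stats::sd) > 0 | !scale
  pr <- stats::prcomp(d[, keep, drop = FALSE], center = TRUE, scale. = scale)
  rank <- sum(pr$sdev > 1e-10)
  if (n_components > rank) {
    warning("n_components = ", n_components, " exceeds rank ", rank,
            "; truncated")
    n_components <- rank
  }
  varfrac <- pr$sdev^2 / sum(pr$sdev^2)
  list(scores = pr$x[, seq_len(n_components), drop = FALSE],
       variance_fraction = varfrac[seq_len(n_components)],
       rotation = pr$rotation[, seq_len(n_components), drop = FALSE])
}

#' Discriminant analysis of principal components
#'
#' Linear discriminant analysis on the leading PCA scores of the dosage
#' matrix: within-class variance is minimised and between-class variance
#' maximised. Per-accession memberships are LDA posterior class
#' probabilities; per-SNP loadings are the squared discriminant
#' contributions mapped back through the PCA rotation and normalised to
#' sum to 1 (the loading-plot statistic used to rank class-separating
#' markers).
#'
#' @param G an imputed [geno_matrix()].
#' @param classes named vector mapping accession id to class (>= 2 classes,
#'   each >= 2 accessions).
#' @param n_pcs number of leading PCs retained; must be
#'   `< n accessions - n classes`.
#' @return list with `membership` (accessions x classes posterior matrix),
#'   `assigned` (factor), `loadings` (per-SNP, sums to 1) and `lda` (the
#'   underlying fit).
#' @export
dapc <- function(G, classes, n_pcs = 10L) {
  cl <- classes[rownames(G$dosage)]
  if (anyNA(cl)) stop("class label missing for some accessions")
  cl <- factor(cl)
  if (nlevels(cl) < 2) stop("need >= 2 classes")
  if (any(table(cl) < 2)) stop("each class needs >= 2 accessions")
  n <- nrow(G$dosage)
  if (n_pcs >= n - nlevels(cl))
    stop("n_pcs must be < accessions - classes (", n - nlevels(cl), ")")
  pc <- geno_pca(G, n_components = n_pcs)
  fit <- tryCatch(
    MASS::lda(pc$scores, grouping = cl),
    error = function(e)
      stop("within-class scatter is singular; retry with fewer PCs (",
           conditionMessage(e), ")"))
  pred <- stats::predict(fit, pc$scores)
  snp_load <- pc$rotation %*% fit$scaling      # SNPs x discriminants
  loadings <- rowSums(snp_load^2)
  loadings <- loadings / sum(loadings)
  list(membership = pred$posterior, assigned = pred$class,
       loadings = stats::setNames(loadings, G$map$id), lda = fit)
}
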