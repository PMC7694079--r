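# independent brute-force oracles used to validate the implementations

# expected distinct-allele count in a draw of g copies, by exhaustive
# enumeration over all C(2N, g) subsets of the gene copies at one locus
enumerate_rarefaction <- function(copies, g) {
  idx <- utils::combn(length(copies), g)
  mean(apply(idx, 2, function(j) length(unique(copies[j]))))
}

# Nei (1972) distance by an explicit per-locus loop
nei_distance_loop <- function(freq_x, freq_y) {
  jxy <- 0; jx <- 0; jy <- 0
  for (l in seq_along(freq_x)) {
    px <- freq_x[l]; py <- freq_y[l]
    jxy <- jxy + px * py + (1 - px) * (1 - py)
    jx <- jx + px^2 + (1 - px)^2
    jy <- jy + py^2 + (1 - py)^2
  }
  -log(jxy / sqrt(jx * jy))
}

# naive UPGMA returning the cophenetic (ultrametric) distance matrix
upgma_cophenetic_bruteforce <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  labels <- rownames(D)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  Dc <- D
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  repeat {
    act <- which(active)
    if (length(act) < 2) break
    best <- c(NA, NA); bestd <- Inf
    for (i in act) for (j in act) if (i < j && Dc[i, j] < bestd) {
      bestd <- Dc[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- bestd; coph[b, a] <- bestd
    }
    # average linkage: distance of merged cluster to others, size-weighted
    ni <- length(members[[i]]); nj <- length(members[[j]])
    for (k in act) if (k != i && k != j)
      Dc[i, k] <- Dc[k, i] <- (ni * Dc[i, k] + nj * Dc[j, k]) / (ni + nj)
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
  }
  coph
}

# diagnostic-SNP discovery by direct enumeration over SNPs
diagnostic_bruteforce <- function(G, rec_ids, donor_ids) {
  a <- character(); b <- character()
  for (j in seq_len(ncol(G$dosage))) {
    dr <- G$dosage[rec_ids, j]
    dd <- G$dosage[donor_ids, j]
    if (anyNA(dr) || anyNA(dd)) next
    if (all(dr == 0) && all(dd == 2)) a <- c(a, G$map$id[j])
    if (all(dr == 2) && all(dd == 0)) b <- c(b, G$map$id[j])
  }
  list(alt_in_andean = a, alt_in_meso = b)
}

# AMOVA from the definitional pairwise squared-distance sums over allele
# copies (Excoffier): an implementation independent of the package's
amova_bruteforce <- function(G, classes) {
  d <- G$dosage
  cl <- factor(classes[rownames(d)])
  n <- nrow(d)
  copies <- matrix(0, 2 * n, ncol(d))
  copies[seq(1, 2 * n, 2), ] <- (d >= 1) * 1
  copies[seq(2, 2 * n, 2), ] <- (d >= 2) * 1
  acc <- rep(seq_len(n), each = 2)
  grp <- cl[acc]
  d2 <- as.matrix(stats::dist(copies))^2
  ss_pairs <- function(rows) sum(d2[rows, rows][upper.tri(d2[rows, rows])]) /
    length(rows)
  ss_tot <- ss_pairs(seq_len(2 * n))
  ss_wc <- sum(vapply(levels(cl), function(g)
    ss_pairs(which(grp == g)), numeric(1)))
  ss_wi <- sum(vapply(seq_len(n), function(i)
    ss_pairs(c(2 * i - 1, 2 * i)), numeric(1)))
  G_ <- nlevels(cl)
  ss_a <- ss_tot - ss_wc
  ss_b <- ss_wc - ss_wi
  ms_a <- ss_a / (G_ - 1); ms_b <- ss_b / (n - G_); ms_c <- ss_wi / n
  n_g <- as.numeric(table(cl))
  s2_c <- ms_c
  s2_b <- (ms_b - s2_c) / 2
  n_pp <- (2 * n - sum((2 * n_g)^2) / (2 * n)) / (G_ - 1)
  s2_a <- (ms_a - s2_c - 2 * s2_b) / n_pp
  list(ss = c(ss_a, ss_b, ss_wi), comps = c(s2_a, s2_b, s2_c))
}

# haplotype-based r2 for fully inbred (0/2) genotypes
haplotype_r2 <- function(x, y) {
  hx <- x / 2; hy <- y / 2
  pa <- mean(hx); pb <- mean(hy)
  pab <- mean(hx * hy)
  D <- pab - pa * pb
  D^2 / (pa * (1 - pa) * pb * (1 - pb))
}
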