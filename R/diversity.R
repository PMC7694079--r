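#' Per-group diversity statistics
#'
#' For each group of accessions, per-locus statistics are computed from the
#' alternative-allele frequency `p` (heterozygotes contribute one copy of
#' each allele) and averaged over loci: observed heterozygosity `Ho` (het
#' fraction), expected heterozygosity `He = 2p(1-p)`, unbiased expected
#' heterozygosity `uHe = He * 2N / (2N - 1)`, Shannon's information index
#' `I = -p ln p - q ln q` (0 at fixed loci, natural log), and polymorphic
#' information content `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`. `Npa` counts
#' alleles present in the group and absent from every other group, summed
#' over loci; `Rs` is rarefied allelic richness at gene-copy size `g`
#' (see [rarefied_allelic_richness()]).
#'
#' @param G an imputed [geno_matrix()] (no missing calls).
#' @param groups named character vector or factor mapping accession id to
#'   group; accessions absent from `groups` are ignored.
#' @param rarefaction_g gene-copy sample size for `Rs`; defaults to twice
#'   the smallest group size.
#' @return data.frame, one row per group: `group`, `N`, `Npa`, `I`, `Rs`,
#'   `Ho`, `He`, `uHe`, `PIC` (the column order of the field's standard
#'   diversity tables).
#' @export
group_diversity <- function(G, groups, rarefaction_g = NULL) {
  groups <- split_groups(G, groups)
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 2))
    stop("group(s) with a single accession: ",
         paste(names(groups)[sizes < 2], collapse = ", "),
         " (unbiased heterozygosity needs N >= 2)")
  if (anyNA(G$dosage)) stop("missing dosages: run impute_missing() first")
  if (is.null(rarefaction_g)) rarefaction_g <- 2L * min(sizes)
  rs <- rarefied_allelic_richness(G, groups, g = rarefaction_g)

  # allele presence per group (for private alleles)
  pres_ref <- sapply(groups, function(ix)
    colSums(G$dosage[ix, , drop = FALSE] < 2) > 0)
  pres_alt <- sapply(groups, function(ix)
    colSums(G$dosage[ix, , drop = FALSE] > 0) > 0)

  out <- lapply(names(groups), function(gname) {
    ix <- groups[[gname]]
    d <- G$dosage[ix, , drop = FALSE]
    n <- length(ix)
    p <- colMeans(d) / 2
    q <- 1 - p
    ho <- mean(colMeans(d == 1))
    he <- 2 * p * q
    i_shan <- ifelse(p == 0 | p == 1, 0,
                     -p * log(p) - q * log(q))
    pic <- 1 - (p^2 + q^2) - 2 * p^2 * q^2
    others <- setdiff(names(groups), gname)
    priv <- sum(pres_ref[, gname] &
                  rowSums(pres_ref[, others, drop = FALSE]) == 0) +
      sum(pres_alt[, gname] &
            rowSums(pres_alt[, others, drop = FALSE]) == 0)
    data.frame(group = gname, N = n, Npa = priv, I = mean(i_shan),
               Rs = rs[[gname]], Ho = ho, He = mean(he),
               uHe = mean(he) * 2 * n / (2 * n - 1), PIC = mean(pic),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

split_groups <- function(G, groups) {
  if (is.factor(groups)) groups <- stats::setNames(as.character(groups),
                                                   names(groups))
  if (is.null(names(groups)))
    stop("`groups` must be named by accession id")
  known <- intersect(names(groups), rownames(G$dosage))
  groups <- groups[known]
  groups <- groups[!is.na(groups)]
  split(match(names(groups), rownames(G$dosage)), groups)
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random draw of `g` gene copies
#' from each group, the population-size-corrected allele count. Per locus,
#' `Rs = sum_a [1 - C(2N - n_a, g) / C(2N, g)]` with `n_a` the copies of
#' allele `a` among the group's `2N` gene copies; group values are means
#' over loci, so for biallelic SNPs `1 <= Rs <= 2`.
#'
#' @param G an imputed [geno_matrix()].
#' @param groups named vector mapping accession to group, or a list of
#'   per-group accession row indices.
#' @param g gene-copy sample size; must be <= `2 * min(group size)`.
#' @return named numeric vector of per-group Rs.
#' @export
rarefied_allelic_richness <- function(G, groups, g) {
  gl <- if (is.list(groups)) groups else split_groups(G, groups)
  sizes <- vapply(gl, length, 1L)
  if (g > 2 * min(sizes))
    stop("rarefaction size g = ", g, " exceeds 2N of the smallest group (",
         2 * min(sizes), ")")
  vapply(gl, function(ix) {
    d <- G$dosage[ix, , drop = FALSE]
    n2 <- 2 * nrow(d)
    n_alt <- colSums(d)
    n_ref <- n2 - n_alt
    term <- function(n_a)
      1 - exp(lchoose(n2 - n_a, g) - lchoose(n2, g))
    mean(term(n_alt) + term(n_ref))
  }, numeric(1))
}

#' Relative diversity change between two groups
#'
#' `delta = 1 - v_modern / v_old`; negative values indicate a diversity
#' gain in the modern group (the sign convention of Vigouroux-style
#' temporal comparisons).
#'
#' @param v_old diversity statistic of the older group (> 0).
#' @param v_modern diversity statistic of the modern group.
#' @return the relative change.
#' @export
diversity_delta <- function(v_old, v_modern) {
  if (any(v_old <= 0))
    stop("diversity_delta: v_old must be > 0")
  1 - v_modern / v_old
}

#' Nei (1972) standard genetic distance
#'
#' `D = -ln( Jxy / sqrt(Jx * Jy) )` with `Jxy = sum over loci and alleles of
#' x*y`, aggregated over loci before the log. Units may be individual
#' accessions or groups of accessions; frequencies are allele frequencies
#' within the unit. Pairs with zero shared polymorphism have identity 0 and
#' are flagged with an infinite distance (attribute `infinite_pairs`).
#'
#' @param G an imputed [geno_matrix()].
#' @param units optional named vector mapping accession to unit (group
#'   mode); by default every accession is its own unit.
#' @return symmetric distance matrix with zero diagonal; attribute
#'   `infinite_pairs` is a two-column matrix of unit labels with D = Inf
#'   (absent when all distances are finite).
#' @export
nei_distance_matrix <- function(G, units = NULL) {
  if (is.null(units)) {
    freq <- G$dosage / 2
    labels <- rownames(G$dosage)
  } else {
    gl <- split_groups(G, units)
    freq <- t(sapply(gl, function(ix)
      colMeans(G$dosage[ix, , drop = FALSE]) / 2))
    labels <- names(gl)
  }
  # Jxy over both alleles: sum_l [p_x p_y + (1-p_x)(1-p_y)]
  p <- freq
  q <- 1 - freq
  jxy <- p %*% t(p) + q %*% t(q)
  jx <- diag(jxy)
  denom <- sqrt(outer(jx, jx))
  ident <- jxy / denom
  d <- -log(pmin(ident, 1))
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  inf <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(inf)) {
    attr(d, "infinite_pairs") <- cbind(labels[inf[, 1]], labels[inf[, 2]])
    warning(nrow(inf), " unit pair(s) share no polymorphism; ",
            "their Nei distance is infinite")
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomeration returning a rooted ultrametric tree with
#' node heights at half the merge distance (so two units at distance d sit
#' at height d/2).
#'
#' @param D symmetric distance matrix with finite entries.
#' @return an [ape::phylo] object (serialisable with [ape::write.tree()]).
#' @export
upgma <- function(D) {
  if (any(!is.finite(as.matrix(D))))
    stop("UPGMA needs finite distances; flag or drop infinite pairs first")
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::as.phylo(hc)   # as.phylo places nodes at half the merge distance
}

#' Gene-pool composition of a panel
#'
#' Percentage of accessions assigned to each gene pool (or any other
#' grouping), on the 0-100 scale.
#'
#' @param metadata data.frame with an `accession` column and the grouping
#'   column.
#' @param column grouping column name (default `"pool"`).
#' @return named numeric vector of percentages, rounded to one decimal.
#' @export
pool_composition <- function(metadata, column = "pool") {
  tab <- table(metadata[[column]])
  round(100 * as.numeric(tab) / sum(tab), 1) |>
    stats::setNames(names(tab))
}
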