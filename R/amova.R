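#' Two-level hierarchical AMOVA
#'
#' Molecular variance decomposition across commercial classes, cultivars
#' within classes, and allele copies within cultivars. Each accession
#' contributes two allele copies per locus (dosage 1 splits into one copy
#' of each allele); sums of squares are allele-difference sums of squared
#' deviations accumulated over loci (the Excoffier decomposition), and
#' variance components come from the expected mean squares with
#' unequal-class-size coefficients. Degrees of freedom are
#' `classes - 1`, `cultivars - classes`, and `cultivars` (one per
#' accession's copy pair), summing to `2 N - 1`.
#'
#' Phi statistics: `Phi_CT = s2_a / s2_tot` (among classes),
#' `Phi_SC = s2_b / (s2_b + s2_c)` (among cultivars within classes),
#' `Phi_ST = (s2_a + s2_b) / s2_tot`.
#'
#' @param G an imputed [geno_matrix()].
#' @param classes named vector mapping accession id to class; >= 2 classes,
#'   each with >= 2 accessions.
#' @param truncate_negative truncate negative variance components to zero
#'   (default `FALSE`: they are reported and flagged instead).
#' @return an `amova_result`: list with `table` (data.frame: stratum, df,
#'   SS, variance component, percent of total), `phi` (named vector
#'   Phi_CT, Phi_SC, Phi_ST), `negative_components` flag.
#' @export
amova_two_level <- function(G, classes, truncate_negative = FALSE) {
  d <- G$dosage
  if (anyNA(d)) stop("missing dosages: run impute_missing() first")
  cl <- classes[rownames(d)]
  if (anyNA(cl)) stop("class label missing for some accessions")
  cl <- factor(cl)
  if (nlevels(cl) < 2) stop("need >= 2 classes")
  if (any(table(cl) < 2))
    stop("class(es) with a single accession: ",
         paste(names(which(table(cl) < 2)), collapse = ", "))
  res <- amova_components(d, cl, truncate_negative)
  structure(res, class = "amova_result")
}

# core decomposition on a dosage matrix + class factor; copies of each
# accession may be permuted externally via the `copies` matrix interface
amova_components <- function(d, cl, truncate_negative = FALSE,
                             copies = NULL) {
  n <- nrow(d)
  G_ <- nlevels(cl)
  # allele-copy representation: 2n x L matrix of 0/1, rows 2i-1, 2i = acc i
  if (is.null(copies)) {
    copies <- matrix(0, 2 * n, ncol(d))
    copies[seq(1, 2 * n, 2), ] <- (d >= 1) * 1    # dosage 1 -> (1, 0)
    copies[seq(2, 2 * n, 2), ] <- (d >= 2) * 1
  }
  acc_of_copy <- rep(seq_len(n), each = 2)
  cl_of_copy <- cl[acc_of_copy]

  # sums of squared deviations of 0/1 allele copies, accumulated over loci:
  # for m copies with cs ones, SSD = cs (m - cs) / m
  cs_tot <- colSums(copies)
  ss_total <- sum(cs_tot * (2 * n - cs_tot) / (2 * n))
  cs_class <- rowsum(copies, group = as.integer(cl_of_copy))
  m_class <- 2 * as.numeric(table(cl))
  ss_within_class <- rowSums(cs_class * (m_class - cs_class) / m_class)
  odd <- copies[seq(1, 2 * n, 2), , drop = FALSE]
  even <- copies[seq(2, 2 * n, 2), , drop = FALSE]
  ss_within_cult <- sum((odd - even)^2) / 2
  ss_a <- ss_total - sum(ss_within_class)
  ss_b <- sum(ss_within_class) - ss_within_cult
  ss_c <- ss_within_cult

  df_a <- G_ - 1
  df_b <- n - G_
  df_c <- n
  ms_a <- ss_a / df_a
  ms_b <- ss_b / df_b
  ms_c <- ss_c / df_c
  n_g <- as.numeric(table(cl))      # accessions per class
  copies_g <- 2 * n_g
  n_tot <- 2 * n
  # copies per cultivar are exactly 2 -> balanced at the lowest level
  s2_c <- ms_c
  s2_b <- (ms_b - s2_c) / 2
  n_pp <- (n_tot - sum(copies_g^2) / n_tot) / df_a
  s2_a <- (ms_a - s2_c - 2 * s2_b) / n_pp
  comps <- c(s2_a, s2_b, s2_c)
  negative <- any(comps < 0)
  if (truncate_negative) comps <- pmax(comps, 0)
  tot <- sum(comps)
  phi <- c(Phi_CT = comps[1] / tot,
           Phi_SC = comps[2] / (comps[2] + comps[3]),
           Phi_ST = (comps[1] + comps[2]) / tot)
  if (tot == 0) phi[] <- NA_real_
  list(table = data.frame(
    stratum = c("Between commercial classes", "Between cultivars",
                "Within cultivars", "Total"),
    df = c(df_a, df_b, df_c, df_a + df_b + df_c),
    SS = c(ss_a, ss_b, ss_c, ss_total),
    variance_component = c(comps, tot),
    percent = if (tot > 0) c(100 * comps / tot, 100) else rep(NA_real_, 4),
    stringsAsFactors = FALSE),
    phi = phi, negative_components = negative)
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("Phi_CT =", format(x$phi["Phi_CT"], digits = 4),
      "| Phi_SC =", format(x$phi["Phi_SC"], digits = 4),
      "| Phi_ST =", format(x$phi["Phi_ST"], digits = 4), "\n")
  if (x$negative_components)
    cat("note: negative variance component(s) present\n")
  invisible(x)
}

#' Permutation significance for the AMOVA Phi statistics
#'
#' Each Phi statistic is tested against its own null: `Phi_CT` by permuting
#' whole accessions among classes; `Phi_SC` by permuting allele copies
#' among accessions within each class (the cultivar level is the accession
#' here); `Phi_ST` by permuting allele copies among all accessions.
#' p-values use the add-one rule `p = (count >= observed + 1) /
#' (n_perm + 1)`.
#'
#' @param G an imputed [geno_matrix()].
#' @param classes named accession-to-class vector.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return list with `observed` (the `amova_result`) and `p_values` (named
#'   vector for Phi_CT, Phi_SC, Phi_ST).
#' @export
amova_permutation_test <- function(G, classes, n_perm = 9999, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  d <- G$dosage
  cl <- factor(classes[rownames(d)])
  obs <- amova_components(d, cl)
  set.seed(as.integer(seed))
  n <- nrow(d)
  copies <- matrix(0, 2 * n, ncol(d))
  copies[seq(1, 2 * n, 2), ] <- (d >= 1) * 1
  copies[seq(2, 2 * n, 2), ] <- (d >= 2) * 1
  acc_of_copy <- rep(seq_len(n), each = 2)

  count <- c(Phi_CT = 0, Phi_SC = 0, Phi_ST = 0)
  for (b in seq_len(n_perm)) {
    # Phi_CT: permute accessions among classes
    phi_ct <- amova_components(d, sample(cl))$phi["Phi_CT"]
    # Phi_SC: permute copies among accessions within class
    ord <- seq_len(2 * n)
    for (g in levels(cl)) {
      rows <- which(cl[acc_of_copy] == g)
      ord[rows] <- rows[sample.int(length(rows))]
    }
    phi_sc <- amova_components(d, cl,
                               copies = copies[ord, , drop = FALSE]
                               )$phi["Phi_SC"]
    # Phi_ST: permute copies among all accessions
    phi_st <- amova_components(d, cl,
                               copies = copies[sample.int(2 * n), ,
                                               drop = FALSE]
                               )$phi["Phi_ST"]
    count["Phi_CT"] <- count["Phi_CT"] +
      (!is.na(phi_ct) && phi_ct >= obs$phi["Phi_CT"])
    count["Phi_SC"] <- count["Phi_SC"] +
      (!is.na(phi_sc) && phi_sc >= obs$phi["Phi_SC"])
    count["Phi_ST"] <- count["Phi_ST"] +
      (!is.na(phi_st) && phi_st >= obs$phi["Phi_ST"])
  }
  list(observed = structure(obs, class = "amova_result"),
       p_values = (count + 1) / (n_perm + 1),
       n_permutations = n_perm)
}
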