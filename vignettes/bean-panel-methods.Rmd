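---
title: "Methods: gene-pool structure, introgression and diversity in common bean panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-pool structure, introgression and diversity in common bean panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`beanpanel` implements the analysis chain used to characterise SNP
diversity panels of common bean (*Phaseolus vulgaris*): quality filtering
of array genotypes, admixture estimation between the two domesticated gene
pools (Mesoamerican and Andean), discovery of diagnostic
(ancestry-informative) SNPs, scanning Mesoamerican cultivars for Andean
allelic introgression, per-group diversity statistics and temporal
diversity gain, linkage-disequilibrium decay modelling, hierarchical
AMOVA, and the phenotype/association machinery for a randomized
complete-block trial. Because panels of this kind are typically not
deposited, the package ships a synthetic panel generator with a
ground-truth record, and every estimator is validated against that truth
or against an independent brute-force oracle in the test suite.

# Genotype representation and quality control

Genotypes are held as an accessions x SNPs dosage matrix counting copies
of the alternative allele (0, 1, 2, `NA`), with a map of marker id,
chromosome (`Pv01`..`Pv11`) and bp position. The HapMap dialect used by
array pipelines for biallelic SNPs codes the reference homozygote "A",
the alternative homozygote "G", the heterozygote "R" and missing "N";
`read_hapmap()`/`write_hapmap()` and `read_vcf()`/`write_vcf()` are exact
inverses at the dosage level.

`apply_qc_filters()` removes, in a fixed attribution order (unplaced →
missing → heterozygosity → MAF), SNPs that are unplaced, have more than
10% missing calls, more than 5% heterozygous calls (a red flag for
paralogous assays in a selfing crop), or minor-allele frequency below 3%.
MAF is computed on raw calls before imputation: imputation can only
manufacture certainty, so filters see the data as observed. Missing calls
are then filled by the per-SNP modal dosage (`impute_missing()`), with
ties broken towards the lower dosage. On a panel that is ~98% homozygous
with <10% missingness, mode imputation is close to optimal single
imputation; the method argument exists so an LD-aware imputer can be
added without changing the interface.

# Admixture model

`em_admixture()` fits the standard binomial admixture likelihood: dosage
$g_{il} \sim \mathrm{Binomial}(2, \sum_k q_{ik} p_{kl})$ with membership
coefficients $Q$ (rows summing to 1) and cluster allele frequencies $P$.
The fit is maximum likelihood via EM, with the log-likelihood asserted
non-decreasing at every iteration and the best of several random restarts
retained (default 5; seeds recorded in the result). This estimates the
same $Q$/$P$ as Bayesian MCMC clustering but deterministically given the
seed, orders of magnitude faster, and hence testably. Supervised mode
pins the $Q$ rows of reference accessions (e.g. a known Andean standard)
at their label.

Per-chromosome ancestry (`per_chromosome_ancestry()`) reruns the model on
each chromosome and aligns cluster labels to the genome-wide solution by
matching cluster allele-frequency profiles, removing label switching
without any external alignment tool. `evanno_delta_k()` implements the
second-order rate-of-change criterion
$\Delta K = |\bar L(K+1) - 2\bar L(K) + \bar L(K-1)| / \mathrm{sd}(L(K))$
on replicate runs; it is undefined (flagged, not infinite) when replicate
runs agree exactly.

**Known limitation.** Any unsupervised two-cluster mixture absorbs a
donor segment shared by a sizeable fraction of the recipient pool into
the recipient cluster's allele frequencies: a direct likelihood
comparison shows absorption wins once roughly a fifth of recipients share
the same segment, so such carriers keep membership ~1. Chromosome-level
purity screening is therefore reliable in the regime where individual
introgression events are rare per locus — which is the empirically
relevant one for elite panels, where donor-allele frequencies at
diagnostic loci rarely reach 30% — while the frequency *scan* (below)
remains the instrument that quantifies common introgression.

# Pure lines, diagnostic SNPs, and the introgression scan

`identify_pure_accessions()` keeps accessions whose membership for the
recipient pool is at least `pure_tol` on **every** chromosome. The
default `pure_tol = 0.999` operationalises "100% membership": a finite
likelihood never returns exactly 1, and on simulated panels with
study-like diagnostic density pure lines sit above 0.9999 while carriers
of even a single 2-4 Mb segment fall below 0.85 on the carrier
chromosome.

`find_diagnostic_snps()` contrasts the pure recipient panel against the
donor panel: a SNP is diagnostic iff one panel is entirely one homozygote
and the other panel entirely the opposite homozygote. A heterozygous call
anywhere disqualifies the locus; missing calls are tolerated only up to
`max_missing` per panel (default 0). The two orientations (alternative
allele fixed in the donor vs in the recipient pool) are kept separate and
must be disjoint — the container enforces this invariant.

`introgression_scan()` then computes, at every diagnostic SNP, the
donor-allele frequency among **all** recipient-pool accessions (not only
the pure ones — the asymmetry is deliberate: discovery needs clean
contrast panels, while the scan asks how far donor alleles have spread).
Heterozygotes count as half a dosage; whether heterozygotes should
instead be excluded is not determinable from published descriptions of
this scan, so the half-dosage convention is used and flagged here.
Frequencies are binned `(0, 0.10]`, `(0.10, 0.15]`, `(0.15, 0.20)`,
`[0.20, 1]`; published bin labels ("11-15%", "16-19%", ">20%") leave the
boundaries ambiguous, and these half-open intervals (with 0.20 counted in
the top bin) are the documented resolution.

`detect_segments()` groups qualifying SNPs (donor frequency ≥ 0.20 by
default) greedily along the map: a SNP joins the open segment when its
r² with every member is ≥ 0.8 and the span stays within `max_span_bp`
(default 5 Mb — reported segments are shorter, but no cap is implied by
the procedure itself). `genes_in_window()` annotates a SNP with the gene
models of a GFF3 file intersecting a 2 Mb window centred on it, with
signed distances (0 inside a gene, negative upstream).

# Diversity statistics

For each group, per-locus statistics are computed from the
alternative-allele frequency $p$ and averaged over loci:
$H_o$ (observed heterozygote fraction), $H_e = 2p(1-p)$,
$uH_e = H_e \cdot 2N/(2N-1)$, Shannon's $I = -p\ln p - q\ln q$ (natural
log, the GenAlEx convention), and $PIC = 1 - (p^2+q^2) - 2p^2q^2$.
Private alleles count alleles present in a group and absent in all
others. Rarefied allelic richness uses the hypergeometric rarefaction
formula $R_s = \sum_a [1 - \binom{2N-n_a}{g}/\binom{2N}{g}]$ at gene-copy
size $g$, defaulting to twice the smallest group size (the standard
choice when the original rarefaction size is unreported); it is exact
against exhaustive enumeration in the tests. Averaging over loci is done
*after* forming each per-locus statistic; published tables built from
other software can differ in the third decimal depending on averaging
order, which is why this package documents its order rather than chasing
those digits.

Temporal diversity change uses $\Delta = 1 - v_\mathrm{modern} /
v_\mathrm{old}$, so a gain in the modern group is negative.

Nei's (1972) standard distance
$D = -\ln\left(J_{xy}/\sqrt{J_x J_y}\right)$ is aggregated over loci
before the logarithm, for accessions or groups; unit pairs with zero
shared polymorphism are flagged with infinite distance rather than
silently dropped. UPGMA trees come from average-linkage agglomeration
with nodes at half the merge distance, returned as `ape::phylo` and
serialisable to newick.

# AMOVA

`amova_two_level()` decomposes molecular variance across commercial
classes / cultivars within classes / allele copies within cultivars. Each
accession contributes two allele copies per locus, so the within-cultivar
stratum is the between-copy (heterozygosity) level — forced by the
degrees of freedom bookkeeping ($G-1$, $N-G$, $N$, totalling $2N-1$).
Sums of squares are allele-difference sums of squared deviations summed
over loci; variance components follow from the expected mean squares with
unequal-class-size coefficients, and negative components are reported and
flagged rather than truncated (truncation is available as an option,
mirroring divergent conventions among field tools).
$\Phi_{CT} = \sigma^2_a/\sigma^2_{tot}$,
$\Phi_{SC} = \sigma^2_b/(\sigma^2_b+\sigma^2_c)$,
$\Phi_{ST} = (\sigma^2_a+\sigma^2_b)/\sigma^2_{tot}$.

Each $\Phi$ is tested against its own permutation null (whole accessions
among classes for $\Phi_{CT}$; allele copies among accessions within
classes for $\Phi_{SC}$ — the cultivar level is a single accession here;
copies among all accessions for $\Phi_{ST}$), with the add-one rule
$p = (\#\{ \Phi^* \ge \Phi \} + 1)/(B+1)$. The conventional full run uses
9999 permutations; the test suite uses a few hundred to stay fast, which
changes only the resolution of $p$, not the statistic.

# LD decay

`pairwise_r2()` computes squared Pearson correlation of dosage vectors
for intrachromosomal pairs. On an almost fully inbred panel this equals
the haplotype-frequency r² (verified against haplotype counts in the
tests); the small heterozygous fraction makes it an approximation of
known direction. `corrected_r2()` removes confounding either by
projecting dosages off structure covariates (membership coefficients or
PCs) or by whitening with the inverse square root of a kinship matrix
(`kinship_matrix()`, VanRaden centred cross-product scaled by
$\sum 2p(1-p)$), with a configurable ridge for near-singular kinship.

The decay curve is the drift-recombination expectation of Hill and Weir,
$$E(r^2) = \frac{10+C}{(2+C)(11+C)}\left[1 +
\frac{(3+C)(12+12C+C^2)}{n(2+C)(11+C)}\right], \quad C = \rho d,$$
fitted by bounded nonlinear least squares for $\rho \ge 0$ on raw pairs
(distance-binning is optional upstream, not imposed, since no binning
convention is implied by the model). Note the curve decays to the
finite-sample floor $\approx 1/n$, not to 0. `decay_distance()`
root-brackets the fitted curve at the field-standard threshold
$r^2 = 0.2$ and returns `NA` ("never") when the curve starts below it.
`min_snp_count()` is the genome size divided by the decay distance,
rounded — the marker count at which adjacent markers sit within the
distance at which LD is still useful.

# RCBD phenotypes and scan thresholds

`rcbd_anova()` fits `value = mean + cultivar + block + residual`. Under
balance the sequential decomposition is exact; unbalanced data fall back
to least squares and are flagged. Line-mean broad-sense heritability is
$h^2 = (MS_c - MS_e)/MS_c$, flagged when negative; CV is
$100\sqrt{MS_e}/\bar y$; Shapiro-Wilk is applied to model residuals (the
raw-trait alternative is ambiguous in field reports; residuals are the
quantity the normality assumption actually concerns). `ls_means()`
returns adjusted accession means (equal to arithmetic means under
balance), `trait_correlations()` Pearson r with p-values on those means.

The association scan is a PC-adjusted linear model per SNP
(`gwas_scan()`), computed in closed form on covariate-residualised data;
it matches per-SNP `lm()` to 1e-10 in the tests. A multi-locus iterative
scan engine is intentionally out of scope — the reusable methodology is
the threshold machinery, and the scan engine is pluggable behind the same
interface. An ordinal growth-habit score analysed with this linear model
is a pragmatic convention inherited from field practice and is flagged as
such. `bic_select_pcs()` picks the number of leading PC covariates
maximising $\log L - (k/2)\ln n$ (higher is better) on the
covariate-only model, 0..5 by default.

`permutation_threshold()` permutes the trait (default 300 times), rescans
fully, records each permutation's minimum p-value, and returns the
5%-quantile of those minima, controlling family-wise error at ~5%. Two
deliberate choices: (i) the quantile is the order statistic (type 1), not
an interpolated quantile — a resampling threshold should be an attained
permutation minimum, and interpolation is measurably anticonservative
(~0.059 realised FWER at nominal 0.05 with 100 permutations); (ii) the
published description of this procedure ("the 95% quantile of the minimum
p-values") reads literally as a permissive threshold that nearly any scan
exceeds; the FWER-controlling 5% quantile is the default and the literal
0.95 remains available via `quantile_level`. `bonferroni_threshold()` is
$\alpha/m$ with $\alpha = 0.01$ by default.

# The synthetic panel generator

`simulate_panel()` emulates the statistical structure the analyses
assume, not bean demography:

* two pools with a planted fraction of diagnostic loci fixed for opposite
  homozygotes (default 0.375, ~1060 of ~2827 loci) and non-diagnostic
  loci at pool-specific Beta-distributed frequencies tuned to realised
  mean $H_e$ ≈ 0.12 (Mesoamerican) vs 0.10 (Andean);
* accessions assembled by copying from a small founder-haplotype pool in
  blocks of `ld_block_len_bp` (default 2 Mb), inducing block-wise LD
  sufficient to exercise r²-based segment calling and decay fitting —
  deliberately cheaper and cruder than coalescent simulation, with no
  mutation, selection or pedigree;
* Mesoamerican founders drawn per commercial class (default split
  131/29/25 Carioca/Black/Special, with the Carioca era split 36 old /
  53 modern / 42 lines), so classes differentiate by drift;
* residual heterozygotes injected at 2% at non-diagnostic loci only:
  keeping planted diagnostic loci strictly homozygous makes the generator
  an exact oracle for contrast-based discovery, and ancestry-informative
  assays on a selfing crop are curated to behave this way; observed
  heterozygosity still tracks the nominal rate within ±0.01;
* planted introgression segments overwrite recipient dosages with an
  Andean founder haplotype inside stated coordinates;
* the truth record lists the *realised* fixed-contrast loci — planted
  ones plus any locus that drifted to opposite fixation in the finite
  founder draw — because the built panel, not the intent, is what
  discovery sees.

Default accession counts are the study-scale 175 + 10. The genotype and
phenotype streams are seeded separately so phenotype replicates can be
redrawn on a fixed panel. `simulate_phenotypes()` adds RCBD plot values
with configurable QTLs (DTF and DTM share their first QTL, giving the
positive correlation observed between flowering and maturation), a
polygenic term, and residual variance set from a target line-mean
heritability (default 0.8); growth habit is discretised to ordinal
classes 1-3 (type 4, climbers, is absent from elite panels).

What passing tests on this generator do **not** show: robustness to
genotyping error beyond random missingness, realistic site-frequency
spectra or recombination maps, pedigree relatedness within classes, or
multi-environment phenotype structure. Conclusions about those aspects of
real data are outside what this validation can support.

# Problem sizes and numerical choices

The test suite and the acceptance script run panels of 50-110 accessions,
3 chromosomes and 120-150 SNPs per chromosome, with permutation counts of
100-999 — sizes chosen so the full validation runs in about a minute
while every estimator still faces the structure it must recover; the
full-scale defaults (175+10 accessions, 11 x 257 SNPs, 9999 AMOVA
permutations, 300 scan permutations) are a configuration change, not a
code path change. EM uses `tol = 1e-6` on the log-likelihood gain with up
to 500-2000 iterations (membership coefficients approach the boundary
geometrically, so purity screening benefits from generous iteration
caps); cluster frequencies are clamped to `[1e-6, 1 - 1e-6]`. Modal
imputation breaks ties to the lower dosage. Hill-Weir fitting starts
$\rho$ at 1/median distance and enforces $\rho \ge 0$. Monomorphic SNPs
are skipped in LD (with a reported count) and flagged `p = 1` in the
scan. Degenerate inputs error loudly: empty panels after QC, all-missing
SNPs, groups of one accession, infinite distances entering UPGMA,
non-positive-definite kinship without ridge.
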