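Package: beanpanel
Title: Gene-Pool Structure, Andean Introgression and Diversity Analysis for
    Common Bean Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing SNP diversity panels of common bean
    (Phaseolus vulgaris): HapMap/VCF genotype input with quality filtering,
    EM-based admixture estimation genome-wide and per chromosome, discovery
    of diagnostic (ancestry-informative) SNPs by genotype contrast between
    pure gene-pool panels, Andean-introgression frequency scans with
    LD-block segment calling and gene-window annotation, per-group diversity
    statistics with rarefied allelic richness and diversity-gain estimates,
    Nei distances with UPGMA grouping, hierarchical AMOVA with permutation
    tests, Hill-Weir linkage-disequilibrium decay modelling, and
    randomized-complete-block phenotype analysis with permutation-calibrated
    association-scan thresholds. Includes a synthetic two-gene-pool panel
    generator with ground-truth records for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    MASS,
    minpack.lm,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
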