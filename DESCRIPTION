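Package: skimqtl
Title: Bin Mapping and Seed-Composition QTL Analysis for Skim-Sequenced
    Recombinant Inbred Lines
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantitative trait locus (QTL) analysis of
    recombinant inbred line (RIL) populations genotyped by low-coverage
    ("skim") whole-genome resequencing.  Implements sliding-window
    parent-of-origin genotype calling, recombination-breakpoint detection
    and bin-map construction from sparse, noisy SNP calls; linkage-map
    building with the Kosambi mapping function and sum-of-adjacent
    recombination-fraction (SARF) ripple order verification;
    interval and composite interval mapping by Haley-Knott regression with
    genome-wide permutation LOD thresholds and two-locus epistasis tests;
    mixed-linear-model genome-wide association with VanRaden kinship;
    ANOVA-based variance components, broad-sense heritability and genetic
    correlations; and haplotype clustering of QTL regions.  A pedigree-
    explicit simulator of single-seed-descent RIL populations with planted
    QTL, genotype-by-environment variance and skim-coverage observation
    noise supports end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    ape
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    lme4,
    jsonlite
Config/testthat/edition: 3
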