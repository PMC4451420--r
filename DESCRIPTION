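Package: bovidemog
Title: Population Genomics of Cattle SNP-Array Data: Diversity, Demography
    and Replicated Selection Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for SNP-array population genomics in cattle and other
    livestock: PLINK-text genotype input with call-rate and MAF quality
    control and sliding-window LD pruning; observed and Nei unbiased
    expected heterozygosity with F_IS and Welch group comparisons;
    Reynolds coancestry distances with neighbor-joining dendrograms and
    bootstrap support; linkage-disequilibrium based effective-population-
    size trajectories using Sved's estimator over equal-count distance
    bins; a from-scratch EHH/iHH/XP-EHH selection scan with per-chromosome
    standardization, quantile outlier calling and a replicated-comparison
    consensus rule with gene-window annotation; and a forward Wright-Fisher
    simulator (lineage splits, admixture, population-size change, hard
    sweeps) that generates phased multi-population datasets for testing
    every stage of the pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
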