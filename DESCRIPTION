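Package: mbassays
Title: Quantification Pipelines for Drosophila Models of TDP-43 Proteinopathy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the quantification procedures used to phenotype
    Drosophila models of TDP-43 proteinopathy in the mushroom-body circuit:
    Y-maze spontaneous-alternation scoring (sliding-window alternation score,
    arm bias against the 1/3 null, distance-scaled alternation), Trikinetics
    activity-monitor sleep analysis under the five-minute inactivity rule
    (bout segmentation, day/night sleep proportions, fragmentation metrics),
    Kaplan-Meier lifespan analysis with median survival confidence intervals
    and log-rank comparisons, confocal image quantification (nuclear to
    whole-cell intensity ratio, sectioned nucleus counting, background
    corrected lobe intensity with young-group normalization, Bernsen local
    thresholding and particle analysis with size and circularity filters),
    and RNA immunoprecipitation enrichment post-processing (median-of-ratios
    normalization, a simplified negative-binomial enrichment test, tag-only
    control log2FC subtraction, candidate filtering, set-overlap bookkeeping,
    delta-delta-Ct fold changes, ortholog joins, and cryptic-exon versus
    canonical nucleus comparisons). Seeded synthetic-data generators emulate
    every raw input so each stage carries a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    flexsurv,
    mgcv,
    tiff,
    EBImage,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
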