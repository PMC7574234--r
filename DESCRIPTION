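Package: epiclassr
Title: Methylation-Density Binary Classification of Epiallele Data
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for classifying samples from per-molecule DNA methylation
    density distributions. A sequenced DNA fragment (epiallele) is summarized
    by the fraction of its CpG sites that are methylated; a sample is called
    positive when the fraction (or normalized count) of its fragments whose
    methylation density meets a cutoff MD_min itself exceeds a learned
    epiallelic-fraction cutoff EF_min. The package extracts per-read
    methylation densities from Bismark-style alignments, jointly optimizes the
    two cutoffs by exhaustive Youden-J search, builds ROC/AUC profiles per
    density cutoff, simulates in-silico tumor/background read admixtures,
    calibrates DREAMing melt-peak temperatures to methylation densities with
    per-mL-of-plasma normalization, selects hypermethylated markers from
    beta-value matrices and combines multi-marker scores with a linear
    support-vector model. Synthetic-data generators with known ground truth
    support fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
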