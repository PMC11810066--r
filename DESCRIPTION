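Package: epiage
Title: Three-CpG ELOVL2 Epigenetic Clock with Targeted Bisulfite
    Amplicon Methylation Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the EpiAgePublic three-CpG ELOVL2 epigenetic
    clock: DNA methylation age prediction and epigenetic age
    acceleration from beta values, ordinary-least-squares clock
    refitting with parameter-recovery validation, a targeted
    bisulfite-amplicon methylation caller (adapter/quality trimming,
    conversion-aware ungapped alignment, UMI deduplication,
    mate-overlap-aware per-CpG calling, depth filtering), technical
    replicate precision QC (per-CpG coefficient of variation and
    EpiAge confidence-interval-range binning), cohort comparison
    statistics (group tests with normality screening, Pearson
    correlation with Fisher-z intervals, ROC analysis with sensitivity
    at full specificity, covariate-adjusted regression, score
    binning), and synthetic-data generators for age-structured beta
    cohorts, technical replicates and UMI-tagged bisulfite read pairs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    multcomp,
    optparse,
    S4Vectors,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
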