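Package: methlink
Title: Linking Regulatory-Element DNA Methylation to Transcription Factor Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies key transcription factors (TFs) and the regulatory-element
    (RE) DNA methylation sites they control from matched DNA methylation and gene
    expression cohorts. Methylation probes are first annotated as enhancer or
    promoter sites using histone-mark and open-chromatin interval sets, then
    classified into four methylation categories (unmethylated/methylated in both
    groups, hypo- or hypermethylated in case samples) using automatically
    estimated beta-value cutoffs. Candidate probe-gene links are scored with
    group-mean Z statistics, screened by Benjamini-Hochberg correction and
    refined with Wilcoxon rank-sum tests; TFs are ranked by the number of
    distinct significantly linked RE sites. Downstream helpers provide log-rank
    survival stratification, TAD-based target-gene assignment, position weight
    matrix motif scanning at REs, and heatmap matrix export. A synthetic-cohort
    generator with planted regulons supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
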