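Package: icbscreen
Title: Integrative Analysis of Pooled CRISPR Immune Screens and ICB Cohort
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene prioritization from pooled CRISPR immune screens integrated
    with immune-checkpoint-blockade (ICB) patient transcriptomics. Implements
    guide-level count normalization and log2 fold changes, second-best-guide
    gene statistics with permutation significance, a 0-4 in vitro gene score,
    cross-cohort patient scores with 90th-percentile normalization, merged-score
    sublibrary selection, a modified DrugZ statistic for in vivo screens with
    safe-guide normalization, total-score ranking, concordance testing against
    clinical outcomes, preranked gene-set enrichment, and translation-efficiency
    analysis by Kozak-sequence strength. Ships a seeded synthetic-data generator
    with planted ground truth so the whole pipeline runs end-to-end without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
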