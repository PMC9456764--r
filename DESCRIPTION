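Package: tlaudit
Title: Auditing Transcript-Leader Annotations for False-Positive IRES Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to audit 5' transcript-leader (TL) annotations for the
    promoter, splice-site, and internal transcription-initiation features that
    produce false-positive signals in bicistronic IRES reporter assays.
    Computes a per-TL evidence battery from promoter annotations, CAGE TSS
    peaks, RNA-seq coverage, and sequence (GC content, E-box motifs); tests
    enrichment of each feature in reporter-active versus nonactive TLs
    (chi-squared and Wilcoxon rank-sum); and predicts reporter activity with a
    cross-validated L2-regularized logistic classifier evaluated over repeated
    80/20 splits. Includes a synthetic-cohort generator with planted internal
    promoters and splice sites so the full pipeline is testable at desk scale,
    and a small scanner for loop-loop (kissing) RNA duplexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    pracma,
    jsonlite,
    withr
Config/testthat/edition: 3
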