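Package: clonestab
Title: Genome Stability Analysis of Clonally Expanded Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing genome stability of clonally expanded cell
    cultures (e.g. liver organoids) from multi-sample whole-genome variant
    calls. Implements an eight-step somatic base-substitution filter cascade,
    attribution of somatic variants to pre-existing (in vivo) versus
    culture-acquired classes using a biopsy / parental-clone / subclone design,
    false-negative-rate estimation from germline SNP recovery, GC-corrected
    read-depth copy-number analysis with a binomial-mixture test for
    heterozygous gains, coding-consequence annotation, and growth-kinetics
    utilities (exponential doubling time, ammonia elimination rate). Includes a
    synthetic-data generator emulating the statistical structure of clonal
    designs so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    vcfR,
    Biostrings
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
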