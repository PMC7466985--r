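Package: bsamapr
Title: Bulk-Segregant SNP-Index Mapping of Recessive Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for mapping a single recessive
    nuclear mutation by bulked segregant analysis of whole-genome
    sequencing data (BSA-seq). Implements the per-site SNP-index and
    delta-SNP-index statistics with sliding-window aggregation and a
    simulation-based significance band, Mendelian segregation chi-square
    tests with continuity correction, recombinant-driven fine-mapping
    interval narrowing, coding-effect annotation of point substitutions
    (including premature stop codons), and CAPS (restriction-site
    gain/loss) marker detection. Ships a synthetic-data generator that
    emulates an F2 or backcross bulk-segregant experiment (Haldane
    crossover model, phenotype-selected bulks, binomial read sampling)
    so every stage of the pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
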