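Package: vardepot
Title: Relational Variant Warehouse with Versioned Annotation and Composable Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Imports VCF variant calls into a single-file relational store,
    attaches versioned annotations from offline table-driven sources with
    full change logging and archival, and filters variants with composable
    AND/OR decision trees including de novo, dominant and recessive
    inheritance models, cohort occurrence counts, gene mutation burden and
    in-silico gene panels. Also provides chain-file based genome-build
    liftover with a manual-curation queue, tabular/CSV reporting with call-set
    summary statistics, and a deterministic synthetic-data generator for
    trios, cohorts, gene models and annotation tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    DBI,
    RSQLite,
    jsonlite,
    yaml,
    vcfR,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
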