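Package: benchforge
Title: Construction and Evaluation of Small-Variant Benchmark Sets
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to construct trusted small-variant benchmark sets (a VCF of
    trusted variants paired with a BED of confident regions) by integrating
    variant callsets from multiple sequencing technologies.  Provides exact
    interval algebra over 0-based half-open genomic regions; callable-region
    computation from depth tracks, including haplotype-split long- and
    linked-read tracks; a difficult-region exclusion stack (segmental
    duplications, tandem repeats, an elliptical coverage-outlier copy-number
    statistic, fixed problematic loci) with progressive-subtraction
    accounting; cross-callset arbitration with a per-technology repeat-class
    exclusion matrix; trio Mendelian-consistency evaluation with de novo
    classification; a stratified precision/recall comparison harness; and a
    deterministic synthetic-data generator for a toy diploid trio so that
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
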