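Package: satmut
Title: Saturation Mutagenesis MPRA Analysis
Version: 0.9.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for saturation-mutagenesis massively parallel
    reporter assays (MPRAs): tag-to-variant subassembly from amplicon reads,
    UMI-deduplicated RNA/DNA tag counting with the standard exclusion filters,
    per-variant log2 expression-effect estimation by a combined multiple linear
    regression across transfection replicates, region-level clustering and
    class-comparison statistics, sequence-based annotation scoring (deltaSVM
    from k-mer weight tables, PWM scanning with length-normalized scores), and
    benchmark evaluation of annotation scores against measured effects. A
    seeded synthetic-data generator emulating error-prone-PCR libraries makes
    every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    data.table,
    jsonlite,
    Biostrings,
    methods,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
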