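Package: scnabench
Title: Simulation and Benchmarking of Somatic Copy-Number Callers on
    Targeted-Capture Data
Version: 0.1.0
Authors@R:
    person("scnabench", "developers", email = "scnabench@example.org",
           role = c("aut", "cre"))
Description: A self-contained simulator and evaluation harness for somatic
    copy-number alteration (SCNA) calling on targeted-capture (exome or gene
    panel) sequencing data. Builds diploid control and multi-clone tumor
    genomes by implanting germline SNPs, indels and copy-number variants and
    somatic SCNAs (amplifications as tandem duplications), simulates
    capture-aware paired-end reads with GC bias and sequencing errors, mixes
    subclone read pools and dilutes them with control reads to emulate tumor
    impurity, and exports a gold-standard truth set. Scores any caller's
    segment calls against the truth with nucleotide-, interval- and
    gene-based precision and sensitivity, stratified by allele fraction and
    event size, and ships a naive depth-ratio caller for fully self-contained
    end-to-end benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
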