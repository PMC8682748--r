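Package: mtmethaudit
Title: Audit of Mitochondrial CpG Methylation Calls from Single-Molecule Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to audit CpG methylation signal on the circular mitochondrial
    genome as measured by single-molecule (nanopore) sequencing and by whole-genome
    bisulfite sequencing. Implements log-likelihood-ratio threshold calibration by
    ROC and accuracy scans over labelled methylation controls, per-read call
    binarization and per-site frequency computation with grouped-CpG splitting,
    negative-control blacklisting, heteroplasmic-variant proximity masking,
    sample-specific consensus reference construction and recall checking,
    exponential background-noise modelling by read subsampling, per-strand
    bisulfite bias diagnostics, circular-genome coordinate rotation with
    origin-spanning alignment rescue, variant retention filters and homoplasmic
    concordance, and a synthetic-data generator producing every input the
    pipeline consumes with controlled statistical structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
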