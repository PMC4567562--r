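Package: sangermix
Title: Deconvolution of Mixed-Template Sanger 16S Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Community profiling from mixed-template Sanger sequencing of 16S
    rRNA amplicons. Aligned four-channel chromatogram spectra from many
    samples are factored by multivariate curve resolution with alternating
    non-negative least squares (MCR-ALS) into component spectra and
    per-sample scores without a closure constraint, components are
    base-called and matched to a reference panel, a nucleotide-mixing
    (Gini-Simpson) alpha-diversity is computed per sample from the raw
    spectra, relative bacterial load is derived from paired 16S/vitellogenin
    qPCR with per-assay amplification efficiencies, and seasonal trends are
    tested with one-way ANOVA, Tukey HSD and Bonferroni-corrected t-tests.
    Includes a synthetic-data generator emulating a seasonal honey-bee gut
    sampling design so the whole pipeline is testable without sequencer
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    pracma,
    withr,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
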