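Package: trnacrispr
Title: Design of tRNA-Promoter-Driven CRISPR/Cas9 Constructs for Aspergillus niger
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for planning CRISPR/Cas9 genome-editing constructs that use
    endogenous RNA polymerase III tRNA promoters and terminators to transcribe the
    guide RNA, as developed for Aspergillus niger. Curates multi-predictor tRNA
    gene models into a usable catalog, extracts promoter (gene + 100 bp upstream)
    and poly-T terminator parts, enumerates 20-nt protospacers with NGG PAMs and
    screens the genome for mismatch off-targets, assembles gRNA expression
    cassettes with fusion-PCR fragments, primers and ligation-independent cloning
    (LIC) tails including T4 polymerase chew-back simulation, designs
    gene-replacement donor templates with homology arms, and classifies
    Cas9-induced mutations in amplicon sequences using cut-site-relative
    coordinates. A seeded fixture generator builds synthetic genomes with planted
    tRNA genes, targets, off-targets and mutant amplicons so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
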