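Package: temiR
Title: Translation Efficiency and the Magnitude of miRNA-Mediated Repression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for ribosome-profiling studies of microRNA
    action. Computes translation efficiency (TE) from paired ribosome
    protected fragment (RPF) and RNA-seq count tables, detects and
    classifies canonical miRNA seed-match sites (6mer, 7mer-a1, 7mer-m8,
    8mer) in 3'UTR sequences, calculates the tRNA adaptation index (tAI)
    from tRNA gene-copy tables and redesigns coding sequences toward a
    target tAI, and stratifies miRNA-target fold changes by TE with
    empirical CDFs and Kolmogorov-Smirnov tests. Ships a negative-binomial
    simulator of paired mock/miRNA-transfection RPF and RNA-seq
    experiments with TE-coupled translational repression, used throughout
    the test suite and the worked examples.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
biocViews: RiboSeq, Transcriptomics, GeneRegulation, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
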