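Package: mycometer
Title: Mycobiome Profiling Toolkit: ITS Copy-Number Estimation, Mock-Community
    Benchmarking, Inter-Kingdom Networks and Diet Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative fungal metagenomics. Estimates ribosomal
    ITS copy numbers from genome assemblies by pairing profile-HMM hits to the
    LSU/SSU rRNA flanks (CN-HMM) and from shotgun reads as the ratio of ITS
    mapping depth to the median single-copy marker-gene depth (CN-MD).
    Simulates mock fungal communities, shotgun and copy-number-weighted ITS
    amplicon reads, compositional count matrices with known basis correlations,
    and longitudinal diet tables, so the whole pipeline is testable in silico.
    Includes depth-based taxonomic profiling with off-target handling, alpha
    and beta diversity (Shannon, Chao1, Bray-Curtis, weighted UniFrac),
    rarefaction, TMM normalization, a Stokes sedimentation calculator, SparCC
    compositional correlation with network deconvolution and random-matrix
    thresholding, keystone species selection, power-law degree fits, and
    energy-residual diet association screens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    ape,
    igraph,
    edgeR,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
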