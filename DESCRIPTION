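Package: OphioITS
Title: Multi-Genotype ITS Profiling of Ophiocordyceps sinensis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling the multiple ITS1-5.8S-ITS2 genotypes of
    Ophiocordyceps sinensis that coexist in natural Cordyceps sinensis.
    Implements mismatch-tolerant in-silico PCR with the published universal,
    genotype-specific and species-specific primers; EcoRI restriction-site
    discrimination of GC- versus AT-biased genotypes; global pairwise
    alignment with segment-wise (ITS1, 5.8S, ITS2) identity profiling;
    transition/transversion mutation profiling and compositional-bias
    classification; two-parent chimera (recombinant genotype) detection by
    windowed parental assignment; neighbor-joining phylogenetic cluster
    assignment with bootstrap support; and compartment-wise clone-library
    presence/absence profiling. A synthetic-data generator produces
    ITS-like markers, biased mutants, chimeras and clone libraries with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
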