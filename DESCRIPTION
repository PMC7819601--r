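Package: nucsim
Title: Kinetic Lattice Simulation of Nucleosome Positioning Near
    Transcription Start Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of nucleosome positioning on a
    one-dimensional DNA lattice using the Gillespie algorithm.  The model
    combines thermal diffusion of nucleosomes, a triangular promoter
    barrier upstream of the transcription start site (TSS), a positioning
    well downstream of the TSS, spacer-enzyme remodeling that pulls
    neighboring nucleosomes together at an energy-independent rate, and
    histone absorption/desorption (exchange) controlled by a chemical
    potential.  An accelerated absorption/desorption sampler with an
    effective (enzyme-renormalized) nearest-neighbor attraction
    reproduces the non-equilibrium steady state of the full kinetics.
    The analysis layer computes TSS-anchored normalized density profiles,
    radial distribution functions, inter-nucleosome spacing, +1-ordered
    configuration heatmaps, a yeast/mouse profile classifier, and a
    single-molecule +1-nucleosome heterogeneity pipeline, together with
    sequence-derived nucleosome affinity profiles based on dinucleotide
    periodicity.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
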