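Package: chromadock
Title: Brownian Dynamics Rigid-Body Docking of Linker Histones on Nucleosomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid-body Brownian dynamics docking of linker histone globular
    domains onto nucleosomes under screened (Debye-Hueckel) electrostatics.
    Provides PQR and OpenDX structure/grid input and output, effective-charge
    fitting, an Ermak-McCammon propagator with excluded-volume rejection, an
    energy-ranked RMSD-deduplicated archive of diffusional encounter
    complexes, hierarchical clustering and ranking of docked poses, a
    DNA-groove-contact configuration classifier (on-dyad versus off-dyad
    binding modes), hydrogen-bond tabulation against the DNA phosphate
    backbone, and parameter-level point mutations and posttranslational
    modifications of the linker histone. A synthetic-structure generator
    builds idealized nucleosome and winged-helix fixtures so the whole
    pipeline runs without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
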