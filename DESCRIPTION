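Package: chargepatch
Title: Charged Surface Patch Analysis and pH-Dependent Stability for Protein Solubility Engineering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts recombinant protein solubility from charged surface
    patches. Builds a solvent-accessible dot surface, evaluates the screened
    Coulomb (Debye-Hueckel) electrostatic potential at surface points,
    segments connected patches at +/-25 mV, and scores solubility as the
    ratio of the largest positively-charged patch to a calibrated threshold.
    Includes in-silico charge mutagenesis by sidechain replacement, a
    systematic patch-mutation screen, protonation-state thermodynamics
    (exact enumeration and Metropolis Monte Carlo) giving the pH-dependent
    ionisable-group contribution to folded-state stability, and an
    orthologue-survey mode that models homologue sequences onto a template
    backbone. Deterministic toy-structure generators with analytic
    expectations support testing without external structure files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    bio3d,
    igraph,
    Biostrings,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
NeedsCompilation: yes
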