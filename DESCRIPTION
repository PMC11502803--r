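Package: ctdphase
Title: Coarse-Grained Simulation and Analysis of RNA Polymerase II CTD
    Phase Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying liquid-liquid phase separation of the
    RNA polymerase II carboxy-terminal domain (CTD) at desk scale.
    Builds CTD heptad-repeat constructs and their substitution,
    phosphorylation and proline-isomer variants; runs a bead-per-residue
    sticker-and-spacer Langevin simulator in single-chain and
    condensed-phase (periodic box) modes; generates reference polymer
    ensembles with known Flory scaling exponents; fits internal-distance
    scaling profiles, radius-of-gyration distributions, per-residue
    interaction-energy maps and SPXX beta-turn populations; clusters
    chains by inter-chain contact counts to follow condensate formation
    and dissolution; and quantifies droplet-like objects in fluorescence
    micrographs (Otsu segmentation, shape and intensity filters,
    per-measurement summary statistics), with a synthetic micrograph
    generator providing ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    EBImage,
    bio3d,
    seqinr,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
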