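Package: CSPmap
Title: Minimal Chemical-Shift Mapping and Sin3-Interaction-Domain
    Discovery from 15N-HSQC Peak Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assignment-free chemical shift perturbation (CSP)
    analysis of two-dimensional 15N-HSQC NMR spectra and for
    sequence-based discovery of Sin3-interaction domains (SIDs). Reads
    and writes Sparky and CSV peak lists, excludes Asn/Gln NH2 side-chain
    peaks, picks peaks from 2D intensity grids at a multiple of the
    robust noise level, matches peaks between apo and complex spectra by
    a minimal-distance (optimal assignment or greedy) algorithm with the
    common 7:1 1H:15N weighting, and summarises each spectral comparison
    as the average minimal shift. A SID scanner scores sequence windows
    by helical-wheel geometry, Eisenberg hydrophobic moment, a
    short/long hydrophobic pair motif and alignment conservation. A
    synthetic-data module generates slow-exchange apo/complex peak lists
    and rendered spectra with known ground truth, and a structure module
    superposes helix bundles from PDB files and reports backbone RMSD.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
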