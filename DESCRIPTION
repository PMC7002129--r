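Package: chlfsites
Title: Pigment-Site Analysis for Far-Red-Acclimated Photosystem I Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing chlorophyll f incorporation into far-red-light
    acclimated Photosystem I. Reads PDB/mmCIF coordinate files and censuses
    pigment cofactors; maps chlorin macrocycles to IUPAC positions, fits ring
    planes, finds stacked chlorophyll multimers and magnesium axial ligands;
    scans the C2-substituent environment of every chlorophyll for hydrogen-bond
    donors and ranks candidate chlorophyll f binding sites; superposes
    homologous photosystem structures (Kabsch) and classifies pigment sites as
    conserved, lost or gained; computes Needleman-Wunsch affine-gap sequence
    alignments, identity matrices and windowed conservation tracks; and
    quantifies pigments from HPLC chromatograms by Gaussian peak deconvolution
    and Beer-Lambert conversion with phylloquinone internal-standard
    normalization. Seeded synthetic generators produce toy structures and
    chromatograms with full ground truth so the whole pipeline is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
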