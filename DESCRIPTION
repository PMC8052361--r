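Package: em2struct
Title: Two-Phase Deep Residual Detection of Protein Secondary Structure and
    Nucleic Acids in Intermediate-Resolution Cryo-EM Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns one of four structural classes (alpha-helix, beta-strand,
    other/coil, DNA/RNA) to every other grid point of a cryo-EM density map at
    intermediate resolution (5-10 Angstrom). A first phase of five 3D residual
    convolutional classifiers (four binary, one four-class) scores 11x11x11
    Angstrom density windows on a stride-2 lattice; a second phase refines each
    point from the 7x7x7 neighborhood of first-phase probabilities. Includes
    CCP4/MRC volume I/O with trilinear regridding and contour-aware
    normalization, a Gaussian-kernel map simulator with a toy protein/nucleic
    complex generator, ground-truth voxel labeling with balanced batch
    sampling and redundancy clustering, the full training pipeline, and
    voxel-, residue/nucleotide- and segment-level evaluation metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
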