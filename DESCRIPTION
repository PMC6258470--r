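Package: rnavoxqa
Title: Local and Global Quality Assessment of RNA 3D Structures with a
    Voxel-Based 3D Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores RNA tertiary structure models by examining each
    nucleotide in turn. A body-fixed local coordinate frame is anchored on
    the nucleotide's C1', O5', C5' and glycosidic nitrogen atoms; the
    surrounding atoms within a 32 Angstrom cube are accumulated into a
    32x32x32 three-channel voxel image (occupation, mass, charge) and scored
    by a small VGG-like 3D convolutional network regressing an RMSD-based
    per-nucleotide "unfitness" score. Per-nucleotide scores are summed into
    a global structure score. The package also provides the RMSD-based
    labeling scheme used to train the network (Kabsch superposition),
    training with a plateau-halving learning-rate schedule, gradient
    saliency maps mapped back to atoms, the Enrichment Score metric for
    decoy discrimination, and a synthetic helix/decoy generator so the full
    pipeline trains and evaluates at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'atom-properties.R'
    'structure-io.R'
    'featurize.R'
    'labeling.R'
    'cnn-layers.R'
    'cnn-model.R'
    'cnn-train.R'
    'assess.R'
    'evaluate.R'
    'fixtures.R'
    'utils.R'
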