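#' rnavoxqa: voxel-based quality assessment of RNA 3D structures
#'
#' Scores RNA structure models nucleotide by nucleotide: each nucleotide's
#' 32 Angstrom cubic environment, expressed in a body-fixed local frame, is
#' voxelized into a three-channel (occupation, mass, charge) 32^3 image and
#' regressed to an RMSD-based unfitness score by a small VGG-like 3D
#' convolutional network. Per-nucleotide scores sum to a global structure
#' score (lower is better). The package includes the Kabsch-superposition
#' labeling scheme used for training, mini-batch SGD training with a
#' plateau-halving learning-rate schedule, gradient saliency maps, the
#' Enrichment Score decoy-discrimination metric, and a synthetic
#' helix/decoy generator.
#'
#' Typical flow: \code{\link{readRnaPdb}} (or \code{\link{makeToyRna}}),
#' \code{\link{assignAtomProperties}}, \code{\link{makeTrainingSet}},
#' \code{\link{fitNormalization}}, \code{\link{buildModel}},
#' \code{\link{trainModel}}, \code{\link{scoreStructure}},
#' \code{\link{enrichmentScore}}.
#'
#' @keywords internal
"_PACKAGE"
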