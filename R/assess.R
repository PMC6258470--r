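#' @include AllClasses.R cnn-model.R featurize.R
NULL

#' Score every nucleotide of a structure
#'
#' For each frame-ready nucleotide: build the local frame, extract the
#' 32 Angstrom cube environment, voxelize, normalize with the model's frozen
#' statistics and predict the normalized unfitness score. The global
#' structure score is the sum over nucleotides; lower means better predicted
#' quality. Nucleotides whose frame cannot be built (missing C1'/O5'/C5'/
#' glycosidic nitrogen or degenerate geometry) are listed in \code{skipped}
#' and excluded from the sum, so every nucleotide appears exactly once in
#' either table.
#'
#' @param model a \code{\link{TrainedModel}} with normalization statistics
#'   set.
#' @param structure a property-assigned \code{\link{RnaStructure}}.
#' @param config a \code{\link{FeaturizeConfig}}.
#' @param denormalize logical(1); report scores on the Angstrom label scale
#'   by inverting the label normalization (default FALSE: normalized scale).
#' @return a \code{\link{StructureAssessment}}.
#' @export
scoreStructure <- function(model, structure, config = featurizeConfig(),
                           denormalize = FALSE) {
  stopifnot(is(model, "TrainedModel"), is(structure, "RnaStructure"))
  if (is.null(model@normalization))
    stop("model has no normalization statistics; call setNormalization()")
  if (!structure@propertiesAssigned)
    stop("structure must be property-assigned (assignAtomProperties)")
  keys <- nucleotideKeys(structure)
  if (!nrow(keys)) stop("structure has no nucleotides")
  scores <- data.frame(chain = character(), resno = integer(),
                       resname = character(), score = numeric(),
                       stringsAsFactors = FALSE)
  skipped <- data.frame(chain = character(), resno = integer(),
                        reason = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(keys))) {
    ch <- keys$chain[i]; rn <- keys$resno[i]
    grid <- tryCatch(featurizeNucleotide(structure, ch, rn, config),
                     error = function(e) conditionMessage(e))
    if (is.character(grid)) {
      skipped <- rbind(skipped, data.frame(chain = ch, resno = rn,
                                           reason = grid))
      next
    }
    s <- predictGrid(model, applyNormalization(grid, model@normalization))
    if (denormalize) s <- denormalizeLabel(s, model@normalization)
    scores <- rbind(scores, data.frame(chain = ch, resno = rn,
                                       resname = keys$resname[i], score = s))
  }
  if (!nrow(scores)) stop("no scoreable nucleotides in structure")
  rownames(scores) <- NULL
  new("StructureAssessment", structureId = structure@structureId,
      perNucleotide = scores, globalScore = sum(scores$score),
      skipped = skipped)
}

#' Gradient saliency map of a voxel grid
#'
#' Exact gradient of the scalar network output with respect to every input
#' voxel value of all three channels, computed by backpropagation with
#' dropout inactive. The sign convention is preserved: for a near-native
#' input, voxels with negative gradients are the score-lowering (salient)
#' directions.
#'
#' @param model a \code{\link{TrainedModel}}.
#' @param grid a normalized \code{\link{VoxelGrid}}.
#' @return numeric array of the input shape (3, g, g, g) holding
#'   d(output)/d(voxel).
#' @export
computeSaliency <- function(model, grid) {
  .checkGridForModel(model, grid)
  x <- as.vector(grid@values)
  fwd <- .cnnForward(model@weights, model@plan, x)
  bwd <- .cnnBackward(model@weights, model@plan, fwd, 1, wantInput = TRUE)
  array(bwd$dInput, dim = dim(grid@values))
}

#' Map voxel gradients back to atoms
#'
#' Each environment atom receives the per-channel gradient values of the
#' voxel containing it; atoms sharing a voxel share the attribution.
#'
#' @param saliency gradient array from \code{\link{computeSaliency}}.
#' @param environment the same atom table (with local coordinates) used to
#'   build the grid, from \code{\link{extractEnvironment}}.
#' @param config the \code{\link{FeaturizeConfig}} used for voxelization.
#' @return the environment data.frame with columns \code{gradOccupation},
#'   \code{gradMass}, \code{gradCharge} appended.
#' @export
mapSaliencyToAtoms <- function(saliency, environment,
                               config = featurizeConfig()) {
  g <- config@gridEdge
  stopifnot(length(dim(saliency)) == 4L, dim(saliency)[1] == 3L,
            all(dim(saliency)[2:4] == g))
  if (!nrow(environment)) {
    environment$gradOccupation <- numeric(0)
    environment$gradMass <- numeric(0)
    environment$gradCharge <- numeric(0)
    return(environment)
  }
  idx <- voxelIndex(as.matrix(environment[, c("lx", "ly", "lz")]), config)
  if (any(idx < 1L) || any(idx > g))
    stop("atom voxel index out of range; environment must match the grid")
  environment$gradOccupation <-
    saliency[cbind(1L, idx[, 1], idx[, 2], idx[, 3])]
  environment$gradMass <-
    saliency[cbind(2L, idx[, 1], idx[, 2], idx[, 3])]
  environment$gradCharge <-
    saliency[cbind(3L, idx[, 1], idx[, 2], idx[, 3])]
  environment
}
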