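#' @import methods
NULL

#' RnaStructure: an RNA 3D structure as an ordered atom table
#'
#' Container for one model of an RNA structure. Atoms are stored in a single
#' data.frame (one row per atom) ordered by chain then residue number, the
#' layout used throughout the package. Nucleotide-level views (frames,
#' environments, labels) are derived from the \code{(chain, resno)} grouping.
#'
#' @slot structureId character(1) identifier (file stem or user-supplied).
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{elety} (PDB atom name, e.g. \code{"C1'"}),
#'   \code{element}, \code{x}, \code{y}, \code{z}, \code{mass}, \code{charge}.
#'   \code{mass}/\code{charge} are \code{NA} until
#'   \code{\link{assignAtomProperties}} is called.
#' @slot modelNumber integer(1) PDB MODEL selected at parse time.
#' @slot propertiesAssigned logical(1) whether mass/charge are populated.
#'
#' @seealso \code{\link{readRnaPdb}}, \code{\link{assignAtomProperties}},
#'   \code{\link{makeToyRna}}
#' @export
setClass("RnaStructure",
  representation(
    structureId = "character",
    atoms = "data.frame",
    modelNumber = "integer",
    propertiesAssigned = "logical"
  ),
  prototype(structureId = "rna", modelNumber = 1L, propertiesAssigned = FALSE)
)

.atomColumns <- c("chain", "resno", "resname", "elety", "element",
                  "x", "y", "z", "mass", "charge")

setValidity("RnaStructure", function(object) {
  msg <- character()
  a <- object@atoms
  missing <- setdiff(.atomColumns, names(a))
  if (length(missing))
    msg <- c(msg, paste("atoms lacks columns:", paste(missing, collapse = ", ")))
  if (!length(msg) && nrow(a)) {
    if (any(!is.finite(a$x) | !is.finite(a$y) | !is.finite(a$z)))
      msg <- c(msg, "atom coordinates must be finite")
    ord <- order(a$chain, a$resno)
    if (!identical(ord, seq_len(nrow(a))) &&
        is.unsorted(paste(a$chain, formatC(a$resno, width = 9, flag = "0"))))
      msg <- c(msg, "atoms must be ordered by chain then residue number")
    if (object@propertiesAssigned) {
      if (any(is.na(a$mass)) || any(a$mass < 0))
        msg <- c(msg, "assigned masses must be nonnegative and non-NA")
      if (any(!is.finite(a$charge)))
        msg <- c(msg, "assigned charges must be finite")
    }
  }
  if (length(msg)) msg else TRUE
})

#' LocalFrame: body-fixed nucleotide coordinate system
#'
#' Right-handed orthonormal frame anchored on a nucleotide: origin at C1',
#' x towards the glycosidic nitrogen, y from the O5'/C5' midpoint after
#' Gram-Schmidt, z completing the right-handed triad.
#'
#' @slot origin numeric(3), C1' position in the global frame (Angstrom).
#' @slot xAxis,yAxis,zAxis unit numeric(3) axes in the global frame.
#' @seealso \code{\link{computeLocalFrame}}
#' @export
setClass("LocalFrame",
  representation(origin = "numeric", xAxis = "numeric",
                 yAxis = "numeric", zAxis = "numeric"))

setValidity("LocalFrame", function(object) {
  msg <- character()
  for (nm in c("origin", "xAxis", "yAxis", "zAxis"))
    if (length(slot(object, nm)) != 3L || any(!is.finite(slot(object, nm))))
      msg <- c(msg, paste(nm, "must be a finite 3-vector"))
  if (!length(msg)) {
    x <- object@xAxis; y <- object@yAxis; z <- object@zAxis
    tol <- 1e-9
    if (abs(sqrt(sum(x^2)) - 1) > tol || abs(sqrt(sum(y^2)) - 1) > tol ||
        abs(sqrt(sum(z^2)) - 1) > tol)
      msg <- c(msg, "axes must have unit norm")
    if (abs(sum(x * y)) > tol || abs(sum(y * z)) > tol || abs(sum(x * z)) > tol)
      msg <- c(msg, "axes must be pairwise orthogonal")
    if (max(abs(c(x[2] * y[3] - x[3] * y[2],
                  x[3] * y[1] - x[1] * y[3],
                  x[1] * y[2] - x[2] * y[1]) - z)) > 1e-9)
      msg <- c(msg, "frame must be right-handed (x cross y = z)")
  }
  if (length(msg)) msg else TRUE
})

#' FeaturizeConfig: voxelization geometry and atom-selection options
#'
#' @slot halfWidth numeric(1), half edge of the cubic environment in Angstrom
#'   (default 16; atoms with \code{max(|x|,|y|,|z|) < halfWidth} are kept,
#'   strict inequality).
#' @slot gridEdge integer(1), voxels per axis (default 32).
#' @slot voxelSize numeric(1), derived: \code{2 * halfWidth / gridEdge}.
#' @slot channels character(3), fixed channel order
#'   \code{c("occupation","mass","charge")}.
#' @slot excludeSelf logical(1), drop the assessed nucleotide's own atoms from
#'   its environment (default FALSE; experimental).
#' @slot heavyOnly logical(1), drop hydrogens at property assignment
#'   (default TRUE).
#' @seealso \code{\link{featurizeConfig}}
#' @export
setClass("FeaturizeConfig",
  representation(halfWidth = "numeric", gridEdge = "integer",
                 voxelSize = "numeric", channels = "character",
                 excludeSelf = "logical", heavyOnly = "logical"))

setValidity("FeaturizeConfig", function(object) {
  msg <- character()
  if (object@halfWidth <= 0) msg <- c(msg, "halfWidth must be positive")
  if (object@gridEdge < 1L) msg <- c(msg, "gridEdge must be >= 1")
  if (abs(object@gridEdge * object@voxelSize - 2 * object@halfWidth) > 1e-9)
    msg <- c(msg, "gridEdge * voxelSize must equal 2 * halfWidth")
  if (!identical(object@channels, c("occupation", "mass", "charge")))
    msg <- c(msg, "channels must be (occupation, mass, charge)")
  if (length(msg)) msg else TRUE
})

#' VoxelGrid: the 3-channel voxel image of one nucleotide environment
#'
#' @slot values numeric array of dim \code{(3, g, g, g)} indexed
#'   (channel, i, j, k); channel order occupation, mass, charge.
#' @slot normalized logical(1); raw grids hold accumulated sums, normalized
#'   grids hold min-max scaled values in [0, 1].
#' @slot provenance list with \code{structureId}, \code{chain}, \code{resno}.
#' @seealso \code{\link{voxelizeEnvironment}}, \code{\link{applyNormalization}}
#' @export
setClass("VoxelGrid",
  representation(values = "array", normalized = "logical",
                 provenance = "list"),
  prototype(normalized = FALSE, provenance = list()))

setValidity("VoxelGrid", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 4L || d[1] != 3L)
    msg <- c(msg, "values must be a (3, g, g, g) array")
  else if (length(unique(d[2:4])) != 1L)
    msg <- c(msg, "spatial dimensions must be cubic")
  if (anyNA(object@values)) msg <- c(msg, "values must not contain NA")
  if (isTRUE(object@normalized) &&
      (min(object@values) < -1e-12 || max(object@values) > 1 + 1e-12))
    msg <- c(msg, "normalized values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' NormalizationStats: dataset-wide min-max ranges for grids and labels
#'
#' Fitted once over a training sample stream and frozen with the model; at
#' inference values outside the fitted range saturate at 0/1.
#'
#' @slot channelMin,channelMax numeric(3) per-channel extrema over all voxels
#'   of all training grids.
#' @slot labelMin,labelMax numeric(1) extrema of the raw unfitness labels
#'   (Angstrom).
#' @slot constantChannels logical(3); a channel with max == min maps to 0.
#' @seealso \code{\link{fitNormalization}}, \code{\link{applyNormalization}}
#' @export
setClass("NormalizationStats",
  representation(channelMin = "numeric", channelMax = "numeric",
                 labelMin = "numeric", labelMax = "numeric",
                 constantChannels = "logical"))

setValidity("NormalizationStats", function(object) {
  msg <- character()
  if (length(object@channelMin) != 3L || length(object@channelMax) != 3L)
    msg <- c(msg, "channelMin/channelMax must have length 3")
  else if (any(object@channelMax < object@channelMin))
    msg <- c(msg, "channelMax must be >= channelMin")
  if (object@labelMax < object@labelMin)
    msg <- c(msg, "labelMax must be >= labelMin")
  if (length(msg)) msg else TRUE
})

#' SuperpositionResult: optimal rigid superposition of two point sets
#'
#' @slot rotation 3x3 proper orthonormal matrix (determinant +1).
#' @slot translation numeric(3), Angstrom.
#' @slot rmsd numeric(1), Angstrom, minimized RMSD.
#' @seealso \code{\link{kabschSuperpose}}
#' @export
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsd = "numeric"))

setValidity("SuperpositionResult", function(object) {
  R <- object@rotation
  msg <- character()
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3x3")
  else {
    if (max(abs(crossprod(R) - diag(3))) > 1e-9)
      msg <- c(msg, "rotation must be orthonormal")
    if (abs(det(R) - 1) > 1e-9)
      msg <- c(msg, "rotation must be proper (det +1)")
  }
  if (object@rmsd < -1e-12) msg <- c(msg, "rmsd must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: architecture of the 3D convolutional scoring network
#'
#' The default spec is the full-scale reference architecture: four valid (no
#' padding), stride-1 convolutions of 8, 16, 32, 64 filters with cubic
#' receptive fields 5, 5, 3, 3, a window-2 stride-2 max-pool after the second
#' convolution, one dense layer of 128 ReLU units and a linear scalar output;
#' 4,282,801 trainable parameters on the (3, 32, 32, 32) input.
#'
#' @slot inputChannels integer(1), input channels (3).
#' @slot gridEdge integer(1), input spatial edge in voxels (32).
#' @slot convFilters integer vector, filters per convolutional layer.
#' @slot convKernels integer vector, cubic kernel edge per layer.
#' @slot convStrides integer vector, stride per layer (all 1 in the
#'   reference architecture).
#' @slot poolAfter integer vector, indices of conv layers followed by a
#'   max-pool.
#' @slot poolWindow,poolStride integer(1), pooling window edge and stride.
#' @slot denseUnits integer(1), hidden dense units.
#' @slot dropoutRate numeric(1), dropout ratio during training.
#' @slot dropoutConv integer vector, conv layers carrying dropout.
#' @slot dropoutDense logical(1), dropout on the hidden dense layer.
#' @seealso \code{\link{modelSpec}}, \code{\link{deskModelSpec}},
#'   \code{\link{buildModel}}
#' @export
setClass("ModelSpec",
  representation(inputChannels = "integer", gridEdge = "integer",
                 convFilters = "integer", convKernels = "integer",
                 convStrides = "integer", poolAfter = "integer",
                 poolWindow = "integer", poolStride = "integer",
                 denseUnits = "integer", dropoutRate = "numeric",
                 dropoutConv = "integer", dropoutDense = "logical"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  nc <- length(object@convFilters)
  if (length(object@convKernels) != nc || length(object@convStrides) != nc)
    msg <- c(msg, "convFilters, convKernels, convStrides must share length")
  if (any(object@convKernels < 1L) || any(object@convStrides < 1L))
    msg <- c(msg, "kernels and strides must be >= 1")
  if (any(object@poolAfter < 1L | object@poolAfter > nc))
    msg <- c(msg, "poolAfter indices must reference conv layers")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    msg <- c(msg, "dropoutRate must be in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' TrainingSchedule: optimization settings and learning-rate schedule
#'
#' Mini-batch gradient descent on the mean squared error, batch size 128,
#' initial learning rate 0.05 halved whenever the validation MSE has not
#' strictly improved for five consecutive epochs; training stops when the
#' rate reaches 0.0015625 (five halvings). Glorot-uniform initialization.
#'
#' @slot batchSize integer(1).
#' @slot initialLr,lrDecayFactor,stopLr numeric(1).
#' @slot plateauPatience integer(1), epochs without strict improvement.
#' @slot momentum numeric(1), SGD momentum (default 0: plain gradient
#'   descent).
#' @slot maxEpochs integer(1), safety cap supplementing the lr-based stop.
#' @slot seed integer(1), RNG seed for shuffling and dropout.
#' @seealso \code{\link{trainingSchedule}}, \code{\link{trainModel}}
#' @export
setClass("TrainingSchedule",
  representation(batchSize = "integer", initialLr = "numeric",
                 lrDecayFactor = "numeric", plateauPatience = "integer",
                 stopLr = "numeric", momentum = "numeric",
                 maxEpochs = "integer", seed = "integer"))

setValidity("TrainingSchedule", function(object) {
  msg <- character()
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (object@initialLr <= 0) msg <- c(msg, "initialLr must be positive")
  if (object@lrDecayFactor <= 0 || object@lrDecayFactor >= 1)
    msg <- c(msg, "lrDecayFactor must be in (0, 1)")
  if (object@stopLr <= 0 || object@stopLr > object@initialLr)
    msg <- c(msg, "stopLr must be in (0, initialLr]")
  if (length(msg)) msg else TRUE
})

#' TrainedModel: network weights plus frozen normalization
#'
#' @slot spec \code{\link{ModelSpec}}.
#' @slot weights list of per-layer weight matrices and bias vectors.
#' @slot plan internal per-layer geometry (gather indices for im2col and
#'   pooling), derived from the spec at build time.
#' @slot normalization \code{\link{NormalizationStats}} or NULL before
#'   \code{\link{setNormalization}}.
#' @slot history data.frame of per-epoch train/validation MSE and learning
#'   rate (empty until trained).
#' @slot seed integer(1) used for weight initialization.
#' @seealso \code{\link{buildModel}}, \code{\link{trainModel}},
#'   \code{\link{predictGrid}}
#' @export
setClass("TrainedModel",
  representation(spec = "ModelSpec", weights = "list", plan = "list",
                 normalization = "ANY", history = "data.frame",
                 seed = "integer"),
  prototype(normalization = NULL,
            history = data.frame(epoch = integer(), trainMse = numeric(),
                                 valMse = numeric(), lr = numeric())))

#' StructureAssessment: per-nucleotide and global quality scores
#'
#' Lower scores mean better predicted quality; the global score is the sum of
#' the per-nucleotide unfitness scores. Nucleotides that cannot be assessed
#' (missing frame atoms) are listed in \code{skipped} and excluded from the
#' sum.
#'
#' @slot structureId character(1).
#' @slot perNucleotide data.frame with \code{chain}, \code{resno},
#'   \code{resname}, \code{score}.
#' @slot globalScore numeric(1), sum of per-nucleotide scores.
#' @slot skipped data.frame with \code{chain}, \code{resno}, \code{reason}.
#' @seealso \code{\link{scoreStructure}}, \code{\link{writeScoreReport}}
#' @export
setClass("StructureAssessment",
  representation(structureId = "character", perNucleotide = "data.frame",
                 globalScore = "numeric", skipped = "data.frame"))

setValidity("StructureAssessment", function(object) {
  msg <- character()
  p <- object@perNucleotide
  if (nrow(p) &&
      abs(object@globalScore - sum(p$score)) > 1e-9 * max(1, nrow(p)))
    msg <- c(msg, "globalScore must equal the sum of per-nucleotide scores")
  if (length(msg)) msg else TRUE
})

#' DecoySet: scored decoys of one target for metric computation
#'
#' @slot targetId character(1).
#' @slot records data.frame with \code{decoyId}, \code{rmsd} (Angstrom, to
#'   native), \code{score} (predicted global score).
#' @slot nativeId character(1) decoyId of the native record, or NA if the
#'   set does not include the native.
#' @seealso \code{\link{enrichmentScore}}, \code{\link{countNativeIdentified}}
#' @export
setClass("DecoySet",
  representation(targetId = "character", records = "data.frame",
                 nativeId = "character"),
  prototype(nativeId = NA_character_))

setValidity("DecoySet", function(object) {
  msg <- character()
  r <- object@records
  need <- c("decoyId", "rmsd", "score")
  if (!all(need %in% names(r)))
    msg <- c(msg, "records needs columns decoyId, rmsd, score")
  else {
    if (any(r$rmsd < 0)) msg <- c(msg, "rmsd must be nonnegative")
    if (anyDuplicated(r$decoyId)) msg <- c(msg, "decoyId must be unique")
    if (!is.na(object@nativeId) && !object@nativeId %in% r$decoyId)
      msg <- c(msg, "nativeId must reference a record")
  }
  if (length(msg)) msg else TRUE
})
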