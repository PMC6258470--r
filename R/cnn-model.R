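#' @include AllClasses.R cnn-layers.R
NULL

#' Architecture specifications
#'
#' \code{modelSpec()} with no arguments returns the full-scale reference architecture:
#' four valid stride-1 3D convolutions (8, 16, 32, 64 filters; cubic kernels
#' 5, 5, 3, 3), a window-2 stride-2 max-pool after the second convolution,
#' a 128-unit ReLU dense layer and a linear scalar output, with dropout 0.2
#' on the second and fourth convolutions and the dense layer. On the
#' (3, 32, 32, 32) input this network has 4,282,801 trainable parameters and
#' spatial trace 32, 28, 24, 12, 10, 8.
#'
#' \code{deskModelSpec()} is a small sibling for desk-scale training
#' (minutes on one CPU): one stride-2 3-kernel convolution of 4 filters, a
#' window-3 stride-3 pool, a 3-kernel convolution of 8 filters and a 32-unit
#' dense layer on the same input. It carries no dropout: at desk scale the
#' training runs are overfit-style sanity checks and demos, where
#' regularization would only slow memorization.
#'
#' @param convFilters,convKernels,convStrides integer vectors, one entry per
#'   convolutional layer.
#' @param poolAfter integer vector of conv-layer indices followed by a
#'   max-pool.
#' @param poolWindow,poolStride integer(1) pooling geometry.
#' @param denseUnits integer(1) hidden dense units.
#' @param dropoutRate numeric(1) in [0, 1).
#' @param dropoutConv integer vector of conv layers with dropout.
#' @param dropoutDense logical(1).
#' @param inputChannels,gridEdge integer(1) input tensor geometry.
#' @return a \code{\link{ModelSpec}}.
#' @examples
#' countParameters(modelSpec())   # 4282801
#' @export
modelSpec <- function(convFilters = c(8L, 16L, 32L, 64L),
                      convKernels = c(5L, 5L, 3L, 3L),
                      convStrides = rep(1L, length(convFilters)),
                      poolAfter = 2L, poolWindow = 2L, poolStride = 2L,
                      denseUnits = 128L, dropoutRate = 0.2,
                      dropoutConv = c(2L, 4L), dropoutDense = TRUE,
                      inputChannels = 3L, gridEdge = 32L) {
  dropoutConv <- intersect(as.integer(dropoutConv),
                           seq_along(convFilters))
  new("ModelSpec", inputChannels = as.integer(inputChannels),
      gridEdge = as.integer(gridEdge),
      convFilters = as.integer(convFilters),
      convKernels = as.integer(convKernels),
      convStrides = as.integer(convStrides),
      poolAfter = as.integer(poolAfter),
      poolWindow = as.integer(poolWindow),
      poolStride = as.integer(poolStride),
      denseUnits = as.integer(denseUnits), dropoutRate = dropoutRate,
      dropoutConv = dropoutConv, dropoutDense = dropoutDense)
}

#' @rdname modelSpec
#' @export
deskModelSpec <- function() {
  modelSpec(convFilters = c(4L, 8L), convKernels = c(3L, 3L),
            convStrides = c(2L, 1L), poolAfter = 1L, poolWindow = 3L,
            poolStride = 3L, denseUnits = 32L, dropoutRate = 0,
            dropoutConv = integer(0), dropoutDense = FALSE)
}

#' Build an untrained network from a specification
#'
#' Weights are initialized Glorot-uniform (limit
#' \code{sqrt(6 / (fanIn + fanOut))}) from the given seed; biases start at
#' zero. The same seed reproduces identical initial weights. The gather
#' indices used by the im2col convolution are precomputed here.
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @param seed integer(1) RNG seed for initialization.
#' @return an untrained \code{\link{TrainedModel}}.
#' @export
buildModel <- function(spec = modelSpec(), seed = 1L) {
  validObject(spec)
  plan <- .buildPlan(spec)
  weights <- .withSeed(seed, {
    lapply(plan$layers, function(L) {
      if (L$type == "conv") {
        k3c <- nrow(L$idx)
        fanIn <- k3c
        fanOut <- (k3c / L$inC) * L$outC
        list(W = .glorotUniform(k3c, L$outC, fanIn, fanOut),
             b = numeric(L$outC))
      } else if (L$type == "pool") {
        list()
      } else {
        list(W = .glorotUniform(L$nOut, L$nIn, L$nIn, L$nOut),
             b = numeric(L$nOut))
      }
    })
  })
  new("TrainedModel", spec = spec, weights = weights, plan = plan,
      normalization = NULL, seed = as.integer(seed))
}

#' Count trainable parameters
#'
#' Sum of all weight and bias entries. The reference architecture
#' (\code{modelSpec()}) has 4,282,801.
#'
#' @param object a \code{\link{TrainedModel}} or \code{\link{ModelSpec}}.
#' @return integer(1).
#' @export
countParameters <- function(object) {
  if (is(object, "ModelSpec")) {
    plan <- .buildPlan(object)
    tot <- 0
    for (L in plan$layers) {
      if (L$type == "conv")
        tot <- tot + (L$inC * (nrow(L$idx) / L$inC) + 1) * L$outC
      else if (L$type %in% c("dense", "output"))
        tot <- tot + (L$nIn + 1) * L$nOut
    }
    return(as.integer(tot))
  }
  stopifnot(is(object, "TrainedModel"))
  as.integer(sum(vapply(object@weights,
                        function(w) length(w$W) + length(w$b), numeric(1))))
}

#' Layer-by-layer shape trace
#'
#' Spatial edge and channel count after every layer, plus the flattened
#' feature count, for verifying the architecture (the reference network
#' traces 32, 28, 24, 12, 10, 8 with 8^3 x 64 = 32768 flattened features).
#'
#' @param spec a \code{\link{ModelSpec}}.
#' @return data.frame with columns \code{layer}, \code{edge},
#'   \code{channels}; the flattened feature count is in
#'   \code{attr(, "features")}.
#' @export
shapeTrace <- function(spec = modelSpec()) {
  plan <- .buildPlan(spec)
  out <- plan$trace
  attr(out, "features") <- plan$features
  out
}

#' Attach normalization statistics to a model
#'
#' @param model a \code{\link{TrainedModel}}.
#' @param stats a \code{\link{NormalizationStats}}.
#' @return the model with the statistics frozen in.
#' @export
setNormalization <- function(model, stats) {
  stopifnot(is(model, "TrainedModel"), is(stats, "NormalizationStats"))
  model@normalization <- stats
  model
}

.checkGridForModel <- function(model, grid) {
  if (!is(grid, "VoxelGrid"))
    stop("expected a VoxelGrid")
  d <- dim(grid@values)
  want <- c(model@spec@inputChannels, rep(model@spec@gridEdge, 3))
  if (!all(d == want))
    stop("grid shape (", paste(d, collapse = ","),
         ") does not match model input (", paste(want, collapse = ","), ")")
  if (!isNormalized(grid))
    stop("grid must be normalized (applyNormalization) before prediction")
}

#' Predict the normalized unfitness score of voxel grids
#'
#' Deterministic inference (dropout inactive). \code{predictGrid} scores one
#' normalized grid; \code{predictGrids} scores a list in order.
#'
#' @param model a \code{\link{TrainedModel}}.
#' @param grid a normalized \code{\link{VoxelGrid}}.
#' @return numeric(1) (or numeric vector for \code{predictGrids}).
#' @export
predictGrid <- function(model, grid) {
  .checkGridForModel(model, grid)
  .cnnForward(model@weights, model@plan, as.vector(grid@values))$pred
}

#' @rdname predictGrid
#' @param grids list of normalized \code{\link{VoxelGrid}}s.
#' @export
predictGrids <- function(model, grids) {
  vapply(grids, function(g) predictGrid(model, g), numeric(1))
}

#' @describeIn predictGrid \code{predict} method; \code{newdata} may be one
#'   grid or a list of grids.
#' @param object a \code{\link{TrainedModel}}.
#' @param newdata grid(s) to score.
#' @param ... ignored.
#' @export
setMethod("predict", "TrainedModel", function(object, newdata, ...) {
  if (is(newdata, "VoxelGrid")) predictGrid(object, newdata)
  else predictGrids(object, newdata)
})
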