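#' @include AllClasses.R cnn-layers.R cnn-model.R featurize.R
NULL

#' Construct a training schedule
#'
#' Defaults give the reference training protocol: mean-squared-error loss
#' minimized by plain mini-batch gradient descent, batch size 128, initial
#' learning rate 0.05 halved whenever the validation MSE has not strictly
#' improved for five consecutive epochs, stopping when the rate reaches
#' 0.0015625 (the fifth halving). Momentum is exposed but defaults to 0; a
#' max-epoch cap supplements the rate-based stop.
#'
#' @param batchSize integer(1).
#' @param initialLr,lrDecayFactor,stopLr numeric(1).
#' @param plateauPatience integer(1) epochs without strict improvement.
#' @param momentum numeric(1) in [0, 1).
#' @param maxEpochs integer(1).
#' @param seed integer(1) for shuffling and dropout.
#' @return a \code{\link{TrainingSchedule}}.
#' @export
trainingSchedule <- function(batchSize = 128L, initialLr = 0.05,
                             lrDecayFactor = 0.5, plateauPatience = 5L,
                             stopLr = 0.0015625, momentum = 0,
                             maxEpochs = 500L, seed = 1L) {
  new("TrainingSchedule", batchSize = as.integer(batchSize),
      initialLr = initialLr, lrDecayFactor = lrDecayFactor,
      plateauPatience = as.integer(plateauPatience), stopLr = stopLr,
      momentum = momentum, maxEpochs = as.integer(maxEpochs),
      seed = as.integer(seed))
}

#' @rdname trainingSchedule
#' @details \code{deskTrainingSchedule} is the companion of
#'   \code{\link{deskModelSpec}}: the same loss, batch size and
#'   plateau-halving rate schedule, but with momentum 0.9, which at desk
#'   scale reaches a given training error several times faster than plain
#'   gradient descent.
#' @export
deskTrainingSchedule <- function(maxEpochs = 200L, seed = 1L, ...) {
  trainingSchedule(momentum = 0.9, maxEpochs = maxEpochs, seed = seed, ...)
}

#' Learning-rate schedule decision
#'
#' Deterministic replay of the plateau rule over a validation-MSE history:
#' starting from the schedule's initial rate, a plateau is declared when the
#' best-so-far validation MSE has not strictly improved for
#' \code{plateauPatience} consecutive epochs; each plateau halves the rate
#' (by \code{lrDecayFactor}) and resets the patience counter. \code{stop}
#' becomes TRUE once the rate reaches \code{stopLr} (with the
#' defaults, after the fifth halving: 0.05 * 0.5^5 = 0.0015625).
#'
#' @param history numeric vector of per-epoch validation MSE values.
#' @param schedule a \code{\link{TrainingSchedule}}.
#' @return list with \code{lr} (rate in force after the last epoch) and
#'   \code{stop} (logical).
#' @examples
#' s <- trainingSchedule()
#' nextLearningRate(rep(1, 6), s)    # one plateau: lr 0.025
#' nextLearningRate(rep(1, 26), s)   # five plateaus: lr 0.0015625, stop
#' @export
nextLearningRate <- function(history, schedule = trainingSchedule()) {
  if (!length(history)) stop("history must be nonempty")
  lr <- schedule@initialLr
  best <- Inf
  wait <- 0L
  stop <- FALSE
  for (mse in history) {
    if (mse < best) {
      best <- mse
      wait <- 0L
    } else {
      wait <- wait + 1L
    }
    if (wait >= schedule@plateauPatience) {
      lr <- lr * schedule@lrDecayFactor
      wait <- 0L
      if (lr <= schedule@stopLr * (1 + 1e-12)) {
        stop <- TRUE
        break
      }
    }
  }
  list(lr = lr, stop = stop)
}

# grids (list of normalized VoxelGrid) -> feature matrix, one column per
# sample, checking the normalization contract
.gridMatrix <- function(model, grids) {
  nIn <- model@spec@inputChannels * model@spec@gridEdge^3
  X <- matrix(0, nIn, length(grids))
  for (i in seq_along(grids)) {
    .checkGridForModel(model, grids[[i]])
    X[, i] <- as.vector(grids[[i]]@values)
  }
  X
}

.mseOverSet <- function(weights, plan, sp, y, chunk = 128L) {
  n <- length(sp$samples)
  err2 <- 0
  for (start in seq(1L, n, by = chunk)) {
    cols <- start:min(start + chunk - 1L, n)
    sub <- list(baseline = sp$baseline, samples = sp$samples[cols])
    preds <- .cnnForwardBatch(weights, plan, NULL, sparse = sub)$pred
    err2 <- err2 + sum((preds - y[cols])^2)
  }
  err2 / n
}

#' Train the network by mini-batch gradient descent
#'
#' Minimizes the mean squared error between predicted and true normalized
#' unfitness scores. Each epoch shuffles the training set (seeded), walks it
#' in batches of \code{batchSize} (a final short batch is allowed),
#' applies inverted dropout on the flagged layers during the forward and
#' backward passes only, and updates every weight with the current learning
#' rate. After each epoch the validation MSE is evaluated with dropout
#' inactive and fed to \code{\link{nextLearningRate}}; training stops on the
#' schedule's rate-based signal or at \code{maxEpochs}.
#'
#' @param model an untrained (or partially trained) \code{\link{TrainedModel}}
#'   whose normalization statistics are already set when grids were
#'   normalized with them.
#' @param grids list of normalized \code{\link{VoxelGrid}}s (training set).
#' @param labels numeric vector of normalized labels in [0, 1].
#' @param valGrids,valLabels validation set in the same form (may be the
#'   training set for overfitting checks).
#' @param schedule a \code{\link{TrainingSchedule}}.
#' @param verbose logical(1), print per-epoch progress.
#' @return the model with updated weights and a per-epoch \code{history}
#'   data.frame (epoch, trainMse, valMse, lr).
#' @export
trainModel <- function(model, grids, labels, valGrids = grids,
                       valLabels = labels, schedule = trainingSchedule(),
                       verbose = FALSE) {
  stopifnot(is(model, "TrainedModel"))
  if (!length(grids)) stop("empty training stream")
  if (length(grids) != length(labels))
    stop("grids and labels must have equal length")
  if (any(labels < -1e-9) || any(labels > 1 + 1e-9))
    stop("labels must be normalized to [0, 1]")
  weights <- model@weights
  plan <- model@plan
  # sparse-plus-baseline representation: exact, and fast for the mostly
  # empty voxel grids this network consumes
  sp <- .sparsifyInput(plan, .gridMatrix(model, grids))
  spv <- if (identical(valGrids, grids)) sp
         else .sparsifyInput(plan, .gridMatrix(model, valGrids))
  y <- as.numeric(labels)
  yv <- as.numeric(valLabels)
  n <- length(sp$samples)
  rate <- model@spec@dropoutRate
  velocity <- NULL
  if (schedule@momentum > 0)
    velocity <- lapply(weights, function(w)
      if (length(w)) list(W = w$W * 0, b = w$b * 0) else list())
  history <- data.frame(epoch = integer(), trainMse = numeric(),
                        valMse = numeric(), lr = numeric())
  lr <- schedule@initialLr
  .withSeed(schedule@seed, {
    for (epoch in seq_len(schedule@maxEpochs)) {
      perm <- sample.int(n)
      sqErrSum <- 0
      for (start in seq(1L, n, by = schedule@batchSize)) {
        batch <- perm[start:min(start + schedule@batchSize - 1L, n)]
        bsize <- length(batch)
        masks <- .dropoutMasksBatch(plan, rate, bsize)
        spb <- list(baseline = sp$baseline, samples = sp$samples[batch])
        fwd <- .cnnForwardBatch(weights, plan, NULL, masks, sparse = spb)
        err <- fwd$pred - y[batch]
        sqErrSum <- sqErrSum + sum(err^2)
        acc <- .cnnBackwardBatch(weights, plan, fwd, 2 * err / bsize, masks,
                                 sparse = spb)
        for (li in seq_along(weights)) {
          if (!length(weights[[li]])) next
          if (is.null(velocity)) {
            weights[[li]]$W <- weights[[li]]$W - lr * acc[[li]]$W
            weights[[li]]$b <- weights[[li]]$b - lr * acc[[li]]$b
          } else {
            velocity[[li]]$W <- schedule@momentum * velocity[[li]]$W -
              lr * acc[[li]]$W
            velocity[[li]]$b <- schedule@momentum * velocity[[li]]$b -
              lr * acc[[li]]$b
            weights[[li]]$W <- weights[[li]]$W + velocity[[li]]$W
            weights[[li]]$b <- weights[[li]]$b + velocity[[li]]$b
          }
        }
      }
      valMse <- .mseOverSet(weights, plan, spv, yv)
      history <- rbind(history,
                       data.frame(epoch = epoch, trainMse = sqErrSum / n,
                                  valMse = valMse, lr = lr))
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %.5f  lr %.6f",
                        epoch, sqErrSum / n, valMse, lr))
      decision <- nextLearningRate(history$valMse, schedule)
      lr <- decision$lr
      if (decision$stop) break
    }
  })
  model@weights <- weights
  model@history <- history
  model
}
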