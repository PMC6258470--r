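test_that("full-scale architecture has the expected parameter count and trace", {
  spec <- modelSpec()
  expect_identical(countParameters(spec), 4282801L)
  tr <- shapeTrace(spec)
  expect_equal(tr$edge, c(32, 28, 24, 12, 10, 8))
  expect_equal(tr$channels, c(3, 8, 16, 16, 32, 64))
  expect_identical(attr(tr, "features"), 32768)
  m <- buildModel(spec, seed = 1)
  expect_identical(countParameters(m), 4282801L)
})

test_that("parameter counting matches a hand count on a toy architecture", {
  # input (1,4,4,4), one conv of 2 filters 3^3, no pool, linear output on
  # the 2*2^3 = 16 features: 2*(27+1) + (16+1) = 73
  toy <- modelSpec(convFilters = 2L, convKernels = 3L, convStrides = 1L,
                   poolAfter = integer(0), denseUnits = 0L,
                   dropoutConv = integer(0), dropoutDense = FALSE,
                   inputChannels = 1L, gridEdge = 4L)
  expect_identical(countParameters(toy), 73L)
  expect_identical(countParameters(buildModel(toy, seed = 2)), 73L)
})

test_that("initialization is seeded and biases start at zero", {
  m1 <- buildModel(miniSpec(), seed = 9)
  m2 <- buildModel(miniSpec(), seed = 9)
  m3 <- buildModel(miniSpec(), seed = 10)
  expect_identical(m1@weights, m2@weights)
  expect_false(identical(m1@weights, m3@weights))
  for (w in m1@weights)
    if (length(w)) expect_true(all(w$b == 0))
})

test_that("impossible spatial geometry raises a shape error with a trace", {
  bad <- modelSpec(convFilters = c(8L, 8L), convKernels = c(31L, 5L),
                   convStrides = c(1L, 1L), poolAfter = integer(0))
  expect_error(buildModel(bad, seed = 1), "underflow.*trace",
               ignore.case = TRUE)
})

test_that("plateau rule halves the rate and stops at 0.0015625", {
  s <- trainingSchedule()
  # strictly improving history: rate untouched
  res <- nextLearningRate(c(1, 0.9, 0.8, 0.7), s)
  expect_equal(res$lr, 0.05)
  expect_false(res$stop)
  # one plateau of five stagnant epochs: one halving
  res <- nextLearningRate(c(0.5, rep(0.5, 5)), s)
  expect_equal(res$lr, 0.025)
  expect_false(res$stop)
  # improvement resets the patience counter
  res <- nextLearningRate(c(0.5, rep(0.5, 4), 0.4, rep(0.4, 4)), s)
  expect_equal(res$lr, 0.05)
  # five successive plateaus: exactly 0.0015625 and stop
  res <- nextLearningRate(c(1, rep(1, 25)), s)
  expect_identical(res$lr, 0.0015625)
  expect_true(res$stop)
  expect_error(nextLearningRate(numeric(0), s), "nonempty")
})

test_that("weight gradients match finite differences of the loss", {
  set.seed(4)
  m <- buildModel(miniSpec(), seed = 6)
  g <- randomGrid(8)
  y <- 0.3
  x <- as.vector(gridValues(g))
  fwd <- rnavoxqa:::.cnnForward(m@weights, m@plan, x)
  bwd <- rnavoxqa:::.cnnBackward(m@weights, m@plan, fwd,
                                 2 * (fwd$pred - y))
  lossAt <- function(w) {
    p <- rnavoxqa:::.cnnForward(w, m@plan, x)$pred
    (p - y)^2
  }
  h <- 1e-6
  for (li in which(vapply(m@weights, length, 0L) > 0)) {
    idx <- cbind(sample(nrow(m@weights[[li]]$W), 3, replace = TRUE),
                 sample(ncol(m@weights[[li]]$W), 3, replace = TRUE))
    for (r in 1:3) {
      wp <- m@weights; wp[[li]]$W[idx[r, 1], idx[r, 2]] <-
        wp[[li]]$W[idx[r, 1], idx[r, 2]] + h
      wm <- m@weights; wm[[li]]$W[idx[r, 1], idx[r, 2]] <-
        wm[[li]]$W[idx[r, 1], idx[r, 2]] - h
      fd <- (lossAt(wp) - lossAt(wm)) / (2 * h)
      an <- bwd$grads[[li]]$W[idx[r, 1], idx[r, 2]]
      expect_equal(an, fd, tolerance = 1e-4)
    }
  }
})

test_that("training regresses a constant target to the constant", {
  set.seed(8)
  m <- buildModel(miniSpec(), seed = 6)
  grids <- lapply(1:24, function(i) randomGrid(8))
  labels <- rep(0.42, 24)
  tm <- trainModel(m, grids, labels,
                   schedule = trainingSchedule(batchSize = 24,
                                               maxEpochs = 150,
                                               momentum = 0.9, seed = 2))
  preds <- predictGrids(tm, grids)
  expect_lt(mean((preds - 0.42)^2), 1e-4)
  # loss decreased over training
  h <- trainingHistory(tm)
  expect_lt(h$valMse[nrow(h)], h$valMse[1])
})

test_that("training is deterministic under a fixed seed", {
  set.seed(12)
  grids <- lapply(1:10, function(i) randomGrid(8))
  labels <- runif(10)
  m <- buildModel(miniSpec(), seed = 5)
  s <- trainingSchedule(batchSize = 4, maxEpochs = 5, seed = 31)
  t1 <- trainModel(m, grids, labels, schedule = s)
  t2 <- trainModel(m, grids, labels, schedule = s)
  expect_identical(t1@weights, t2@weights)
  expect_identical(trainingHistory(t1), trainingHistory(t2))
})

test_that("a vanishing learning rate leaves weights unchanged", {
  set.seed(14)
  grids <- lapply(1:6, function(i) randomGrid(8))
  labels <- runif(6)
  m <- buildModel(miniSpec(), seed = 5)
  tm <- trainModel(m, grids, labels,
                   schedule = trainingSchedule(batchSize = 6, maxEpochs = 3,
                                               initialLr = 1e-300,
                                               stopLr = 1e-301, seed = 1))
  for (li in seq_along(m@weights))
    if (length(m@weights[[li]]))
      expect_equal(tm@weights[[li]]$W, m@weights[[li]]$W, tolerance = 1e-12)
})

test_that("prediction is deterministic, batch-consistent and shape-checked", {
  set.seed(15)
  m <- buildModel(miniSpec(), seed = 7)
  g1 <- randomGrid(8); g2 <- randomGrid(8)
  expect_identical(predictGrid(m, g1), predictGrid(m, g1))
  expect_equal(predictGrids(m, list(g1, g2)),
               c(predictGrid(m, g1), predictGrid(m, g2)))
  expect_equal(predict(m, list(g1, g2)), predictGrids(m, list(g1, g2)))
  wrong <- randomGrid(4)
  expect_error(predictGrid(m, wrong), "3,8,8,8")
  raw <- new("VoxelGrid", values = gridValues(g1), normalized = FALSE)
  expect_error(predictGrid(m, raw), "normalized")
})

test_that("training rejects raw grids and degenerate streams", {
  m <- buildModel(miniSpec(), seed = 5)
  raw <- new("VoxelGrid", values = array(2, c(3, 8, 8, 8)),
             normalized = FALSE)
  expect_error(trainModel(m, list(raw), 0.5), "normalized")
  expect_error(trainModel(m, list(), numeric(0)), "empty")
  g <- randomGrid(8)
  expect_error(trainModel(m, list(g), 1.7), "labels")
})
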