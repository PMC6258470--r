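# an untrained desk model with normalization fitted on a handful of fixture
# grids is enough to exercise the assessment plumbing
.assessModel <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) {
      s <- toyAssigned(14)
      grids <- lapply(c(1, 5, 9), function(i)
        featurizeNucleotide(s, "A", i))
      stats <- fitNormalization(grids, c(0, 1, 2))
      cached <<- setNormalization(buildModel(deskModelSpec(), seed = 4),
                                  stats)
    }
    cached
  }
})

test_that("structure scores are per-nucleotide sums with full bookkeeping", {
  s <- toyAssigned(14)
  m <- .assessModel()
  a <- scoreStructure(m, s)
  p <- perNucleotideScores(a)
  expect_equal(nrow(p), 14L)
  expect_equal(globalScore(a), sum(p$score), tolerance = 1e-9 * 14)
  expect_equal(nrow(a@skipped), 0L)
  # deterministic
  a2 <- scoreStructure(m, s)
  expect_identical(perNucleotideScores(a2)$score, p$score)
})

test_that("assessment is invariant under global rigid motion", {
  set.seed(23)
  s <- toyAssigned(14)
  m <- .assessModel()
  moved <- rigidTransform(s, randomRotation(), rnorm(3, 0, 25))
  a1 <- scoreStructure(m, s)
  a2 <- scoreStructure(m, moved)
  expect_equal(perNucleotideScores(a1)$score,
               perNucleotideScores(a2)$score, tolerance = 1e-9)
})

test_that("frame-incomplete nucleotides are skipped, not fatal", {
  s <- toyAssigned(14)
  s@atoms <- s@atoms[!(s@atoms$resno == 7 & s@atoms$elety == "O5'"), ]
  m <- .assessModel()
  a <- scoreStructure(m, s)
  expect_equal(nrow(perNucleotideScores(a)), 13L)
  expect_equal(a@skipped$resno, 7L)
  expect_match(a@skipped$reason, "O5'")
  # every nucleotide accounted for exactly once
  seen <- sort(c(perNucleotideScores(a)$resno, a@skipped$resno))
  expect_equal(seen, 1:14)
})

test_that("saliency gradients have input shape and match finite differences", {
  set.seed(25)
  m <- .assessModel()
  s <- toyAssigned(14)
  grid <- applyNormalization(featurizeNucleotide(s, "A", 7),
                             m@normalization)
  sal <- computeSaliency(m, grid)
  expect_equal(dim(sal), c(3, 32, 32, 32))
  expect_true(all(is.finite(sal)))
  # On a real featurized grid the score is only piecewise linear: conv
  # outputs over the uniform empty-voxel background tie exactly inside
  # max-pool windows, so many voxels sit on kinks where a central
  # difference straddles two linear pieces. The gradient contract is
  # checked where the function is locally smooth (one-sided differences
  # agree); kinked probes are skipped.
  v <- gridValues(grid)
  h <- 1e-3
  f0 <- predictGrid(m, grid)
  smooth <- 0L
  for (t in 1:60) {
    if (smooth >= 8L) break
    i <- cbind(sample(3, 1), sample(32, 1), sample(32, 1), sample(32, 1))
    vp <- v; vp[i] <- vp[i] + h
    vm <- v; vm[i] <- vm[i] - h
    fp <- predictGrid(m, gridWith(grid, vp))
    fm <- predictGrid(m, gridWith(grid, vm))
    d1 <- (fp - f0) / h
    d2 <- (f0 - fm) / h
    if (abs(d1 - d2) > 1e-3 * max(abs(d1), abs(d2), 1e-8)) next
    smooth <- smooth + 1L
    fd <- (fp - fm) / (2 * h)
    denom <- max(abs(fd), abs(sal[i]), 1e-8)
    expect_lt(abs(fd - sal[i]) / denom, 1e-2)
  }
  expect_gte(smooth, 1L)
})

test_that("saliency of an empty environment is finite", {
  m <- .assessModel()
  empty <- applyNormalization(
    voxelizeEnvironment(data.frame(lx = numeric(0), ly = numeric(0),
                                   lz = numeric(0), mass = numeric(0),
                                   charge = numeric(0))),
    m@normalization)
  sal <- computeSaliency(m, empty)
  expect_true(all(is.finite(sal)))
})

test_that("voxel gradients map to the atoms that occupy the voxels", {
  set.seed(27)
  m <- .assessModel()
  s <- toyAssigned(14)
  frame <- computeLocalFrame(s, "A", 7)
  env <- extractEnvironment(s, frame)
  grid <- applyNormalization(voxelizeEnvironment(env), m@normalization)
  sal <- computeSaliency(m, grid)
  mapped <- mapSaliencyToAtoms(sal, env)
  # independent floor-index lookup per atom
  for (j in seq_len(nrow(mapped))) {
    ii <- floor(c(mapped$lx[j], mapped$ly[j], mapped$lz[j]) + 16) + 1
    expect_identical(mapped$gradOccupation[j], sal[1, ii[1], ii[2], ii[3]])
    expect_identical(mapped$gradMass[j], sal[2, ii[1], ii[2], ii[3]])
    expect_identical(mapped$gradCharge[j], sal[3, ii[1], ii[2], ii[3]])
  }
  # atoms sharing a voxel share the attribution
  key <- paste(floor(mapped$lx + 16), floor(mapped$ly + 16),
               floor(mapped$lz + 16))
  shared <- names(which(table(key) > 1))
  if (length(shared)) {
    rows <- which(key == shared[1])
    expect_equal(length(unique(mapped$gradMass[rows])), 1L)
  }
  # a single-atom environment carries its voxel's gradient
  one <- env[1, ]
  gridOne <- applyNormalization(voxelizeEnvironment(one), m@normalization)
  salOne <- computeSaliency(m, gridOne)
  mOne <- mapSaliencyToAtoms(salOne, one)
  iOne <- floor(c(one$lx, one$ly, one$lz) + 16) + 1
  expect_identical(mOne$gradCharge, salOne[3, iOne[1], iOne[2], iOne[3]])
})
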