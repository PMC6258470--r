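test_that("local frame axes follow the prescribed construction", {
  # C1' at origin, N9 at (2,0,0), O5' at (0,3,0), C5' at (0,1,0):
  # the construction forces x=(1,0,0), y=(0,1,0), z=(0,0,1)
  s <- axisAlignedNucleotide()
  f <- computeLocalFrame(s, "A", 1)
  expect_equal(f@origin, c(0, 0, 0))
  expect_equal(f@xAxis, c(1, 0, 0))
  expect_equal(f@yAxis, c(0, 1, 0))
  expect_equal(f@zAxis, c(0, 0, 1))
})

test_that("frames are orthonormal and right-handed for every nucleotide", {
  s <- toyAssigned(14)
  for (i in 1:14) {
    f <- computeLocalFrame(s, "A", i)
    expect_lt(abs(sum(f@xAxis * f@yAxis)), 1e-9)
    expect_lt(abs(sum(f@yAxis * f@zAxis)), 1e-9)
    expect_lt(abs(sum(f@xAxis * f@zAxis)), 1e-9)
    expect_true(validObject(f))   # includes unit norm and handedness
  }
})

test_that("missing frame atoms and degenerate geometry are reported", {
  s <- axisAlignedNucleotide()
  s@atoms <- s@atoms[s@atoms$elety != "O5'", ]
  expect_error(computeLocalFrame(s, "A", 1), "O5'")
  # colinear: O5'/C5' midpoint along the x axis makes z degenerate
  s2 <- axisAlignedNucleotide()
  s2@atoms$x[s2@atoms$elety %in% c("O5'", "C5'")] <- c(3, 1)
  s2@atoms$y[s2@atoms$elety %in% c("O5'", "C5'")] <- 0
  expect_error(computeLocalFrame(s2, "A", 1), "degenerate")
})

test_that("local coordinates are invariant under global rigid motion", {
  set.seed(42)
  s <- toyAssigned(14)
  R <- randomRotation(); tr <- rnorm(3, 0, 20)
  s2 <- rigidTransform(s, R, tr)
  for (i in c(1, 7, 14)) {
    f1 <- computeLocalFrame(s, "A", i)
    f2 <- computeLocalFrame(s2, "A", i)
    l1 <- toLocalCoords(f1, as.matrix(atomData(s)[, c("x", "y", "z")]))
    l2 <- toLocalCoords(f2, as.matrix(atomData(s2)[, c("x", "y", "z")]))
    expect_lt(max(abs(l1 - l2)), 1e-9)
  }
})

test_that("global -> local -> global round trip is exact", {
  set.seed(1)
  s <- toyAssigned(4)
  f <- computeLocalFrame(s, "A", 2)
  pts <- matrix(rnorm(300, 0, 10), ncol = 3)
  back <- fromLocalCoords(f, toLocalCoords(f, pts))
  expect_lt(max(abs(back - pts)), 1e-9)
  # projection sanity: origin maps to 0, origin + 5x maps to (5,0,0)
  expect_equal(as.numeric(toLocalCoords(f, rbind(f@origin))), c(0, 0, 0))
  expect_equal(as.numeric(toLocalCoords(f, rbind(f@origin + 5 * f@xAxis))),
               c(5, 0, 0))
})

test_that("environment inclusion is strict at the 16 Angstrom boundary", {
  extra <- data.frame(chain = "A", resno = 1L, resname = "A",
                      elety = c("C2", "C4", "C6", "C8"), element = "C",
                      x = c(15.999, 16.0, -15.9999, -16.0),
                      y = 0, z = 0, mass = 1, charge = 0)
  s <- axisAlignedNucleotide(extra)
  f <- computeLocalFrame(s, "A", 1)
  env <- extractEnvironment(s, f)
  expect_true("C2" %in% env$elety)    # 15.999 in
  expect_false("C4" %in% env$elety)   # 16.0 out (strict)
  expect_true("C6" %in% env$elety)    # just inside the negative face
  expect_false("C8" %in% env$elety)   # -16.0 out, symmetric with +16.0
})

test_that("environment membership matches a brute-force scan", {
  s <- toyAssigned(14)
  a <- atomData(s)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  for (i in c(1, 8)) {
    f <- computeLocalFrame(s, "A", i)
    env <- extractEnvironment(s, f)
    # independent projection: explicit dot products per atom
    keep <- logical(nrow(a))
    for (j in seq_len(nrow(a))) {
      d <- xyz[j, ] - f@origin
      lc <- c(sum(d * f@xAxis), sum(d * f@yAxis), sum(d * f@zAxis))
      keep[j] <- all(abs(lc) < 16)
    }
    expect_equal(nrow(env), sum(keep))
  }
  # a single-nucleotide structure is its own whole environment
  s1 <- toyAssigned(1)
  f1 <- computeLocalFrame(s1, "A", 1)
  expect_equal(nrow(extractEnvironment(s1, f1)), nrow(atomData(s1)))
})

test_that("voxel accumulation is exact for point placements", {
  cfg <- featurizeConfig()
  env1 <- data.frame(lx = 0.2, ly = 0.2, lz = 0.2, mass = 12.01,
                     charge = -0.5)
  g <- gridValues(voxelizeEnvironment(env1, cfg))
  # local 0.2 falls in cell floor(0.2+16)+1 = 17 on every axis
  expect_equal(g[, 17, 17, 17], c(1, 12.01, -0.5), ignore_attr = TRUE)
  expect_equal(sum(g != 0), 3L)
  # empty environment: all-zero grid
  g0 <- gridValues(voxelizeEnvironment(env1[0, ], cfg))
  expect_true(all(g0 == 0))
  # two atoms in one cell accumulate
  env2 <- rbind(env1, data.frame(lx = 0.7, ly = 0.9, lz = 0.01,
                                 mass = 14.01, charge = 0.2))
  g2 <- gridValues(voxelizeEnvironment(env2, cfg))
  expect_equal(g2[, 17, 17, 17], c(2, 12.01 + 14.01, -0.3),
               ignore_attr = TRUE)
})

test_that("channel sums conserve atom count, mass and charge", {
  s <- toyAssigned(14)
  f <- computeLocalFrame(s, "A", 7)
  env <- extractEnvironment(s, f)
  g <- gridValues(voxelizeEnvironment(env))
  expect_equal(sum(g[1, , , ]), nrow(env))
  expect_equal(sum(g[2, , , ]), sum(env$mass), tolerance = 1e-9)
  expect_equal(sum(g[3, , , ]), sum(env$charge), tolerance = 1e-9)
})

test_that("voxel grids are invariant under global rigid motion", {
  set.seed(99)
  s <- toyAssigned(14)
  s2 <- rigidTransform(s, randomRotation(), rnorm(3, 0, 30))
  for (i in c(2, 9)) {
    g1 <- gridValues(featurizeNucleotide(s, "A", i))
    g2 <- gridValues(featurizeNucleotide(s2, "A", i))
    expect_identical(which(g1 != 0), which(g2 != 0))
    expect_equal(g1, g2, tolerance = 1e-9)
  }
})

test_that("atoms outside the cube cannot influence a grid", {
  s <- toyAssigned(14)
  g1 <- gridValues(featurizeNucleotide(s, "A", 1))
  # move the far end of the helix (already outside residue 1's cube)
  # anywhere else outside: grid must not change
  f <- computeLocalFrame(s, "A", 1)
  a <- s@atoms
  loc <- toLocalCoords(f, as.matrix(a[, c("x", "y", "z")]))
  outside <- apply(abs(loc) >= 16, 1, any)
  expect_true(any(outside))
  s2 <- s
  s2@atoms$x[outside] <- s2@atoms$x[outside] + 500
  g2 <- gridValues(featurizeNucleotide(s2, "A", 1))
  expect_identical(g1, g2)
})

test_that("min-max normalization fits global extrema and clamps", {
  set.seed(5)
  grids <- lapply(1:10, function(i) {
    v <- array(0, c(3, 4, 4, 4))
    v[sample(length(v), 20)] <- rnorm(20, 5, 3)
    new("VoxelGrid", values = v, normalized = FALSE)
  })
  labels <- runif(10, 0, 8)
  st <- fitNormalization(grids, labels)
  # brute-force flat scan oracle
  flat <- sapply(1:3, function(ch)
    range(unlist(lapply(grids, function(g) g@values[ch, , , ]))))
  expect_equal(st@channelMin, flat[1, ], ignore_attr = TRUE)
  expect_equal(st@channelMax, flat[2, ], ignore_attr = TRUE)
  expect_equal(st@labelMin, min(labels))
  expect_equal(st@labelMax, max(labels))
  # endpoints, midpoint, saturation
  expect_equal(normalizeLabel(st@labelMin, st), 0)
  expect_equal(normalizeLabel(st@labelMax, st), 1)
  expect_equal(normalizeLabel((st@labelMin + st@labelMax) / 2, st), 0.5)
  expect_equal(normalizeLabel(st@labelMax + 10, st), 1)
  expect_equal(denormalizeLabel(normalizeLabel(3.3, st), st), 3.3,
               tolerance = 1e-12)
  # a normalized grid attains 0 and 1 on non-constant channels
  gn <- applyNormalization(grids[[1]], fitNormalization(grids[1], 1))
  for (ch in 1:3) {
    vals <- gn@values[ch, , , ]
    expect_equal(min(vals), 0)
    expect_equal(max(vals), 1)
  }
  # constant channel maps to zero under its flag
  gconst <- grids[[1]]
  gconst@values[2, , , ] <- 7
  stc <- fitNormalization(list(gconst), 1)
  expect_true(stc@constantChannels[2])
  expect_true(all(applyNormalization(gconst, stc)@values[2, , , ] == 0))
})
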