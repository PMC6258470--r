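# Independent oracles and small fixture builders used across the suite.

# Horn's quaternion method for optimal rigid superposition of P onto Q.
# Independent of the package's SVD-based Kabsch implementation.
hornRmsd <- function(P, Q) {
  P <- rbind(P); Q <- rbind(Q)
  n <- nrow(P)
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  S <- crossprod(Pc, Qc)   # S[a, b] = sum p_a q_b
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lambda <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  sqrt(max(0, (sum(Pc^2) + sum(Qc^2) - 2 * lambda) / n))
}

# random proper rotation matrix (QR of a Gaussian matrix, det corrected)
randomRotation <- function() {
  qr <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# apply a global rigid transform to every atom of a structure
rigidTransform <- function(structure, R, t) {
  a <- atomData(structure)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, t, "+")
  structure@atoms$x <- xyz[, 1]
  structure@atoms$y <- xyz[, 2]
  structure@atoms$z <- xyz[, 3]
  structure
}

# property-assigned toy helix, memoised per size to keep the suite fast
toyAssigned <- local({
  cache <- list()
  function(n = 14L) {
    key <- as.character(n)
    if (is.null(cache[[key]]))
      cache[[key]] <<- assignAtomProperties(
        makeToyRna(decoyGenConfig(nNucleotides = n)))
    cache[[key]]
  }
})

# a small ModelSpec on an 8-voxel grid for fast training-mechanics tests
miniSpec <- function() {
  modelSpec(convFilters = 2L, convKernels = 3L, convStrides = 1L,
            poolAfter = integer(0), denseUnits = 4L, dropoutConv = integer(0),
            dropoutDense = FALSE, inputChannels = 3L, gridEdge = 8L)
}

# random normalized VoxelGrid of a given edge (sparse like real grids)
randomGrid <- function(edge = 8L, density = 0.02) {
  v <- array(0, c(3, edge, edge, edge))
  nz <- runif(length(v)) < density
  v[nz] <- runif(sum(nz))
  new("VoxelGrid", values = v, normalized = TRUE)
}

# copy of a grid with substituted values, skipping validity: finite
# difference probes legitimately step outside the [0,1] manifold
gridWith <- function(grid, values) {
  methods::slot(grid, "values", check = FALSE) <- values
  grid
}

# minimal one-nucleotide structure with an axis-aligned frame:
# C1' at origin, glycosidic N along +x, O5'/C5' midpoint along +y
axisAlignedNucleotide <- function(extraAtoms = NULL) {
  atoms <- data.frame(
    chain = "A", resno = 1L, resname = "A",
    elety = c("C1'", "N9", "O5'", "C5'"),
    element = c("C", "N", "O", "C"),
    x = c(0, 2, 0, 0), y = c(0, 0, 3, 1), z = c(0, 0, 0, 0),
    mass = 1, charge = 0, stringsAsFactors = FALSE)
  if (!is.null(extraAtoms)) atoms <- rbind(atoms, extraAtoms)
  new("RnaStructure", structureId = "axis", atoms = atoms,
      modelNumber = 1L, propertiesAssigned = TRUE)
}
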