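#' @include AllClasses.R structure-io.R
NULL

#' Construct a voxelization configuration
#'
#' The defaults give the reference featurization: a cube of half-width
#' 16 Angstrom around the assessed nucleotide partitioned into 32 voxels per
#' axis (1 Angstrom voxels), with three channels accumulating atom count,
#' mass and charge.
#'
#' @param halfWidth numeric(1), inclusion threshold in Angstrom; an atom
#'   belongs to the environment iff all of |x|, |y|, |z| in the local frame
#'   are strictly less than \code{halfWidth}.
#' @param gridEdge integer(1), voxels per axis.
#' @param excludeSelf logical(1), drop the assessed nucleotide's own atoms.
#' @param heavyOnly logical(1), recorded preference for hydrogen handling.
#' @return a \code{\link{FeaturizeConfig}}.
#' @export
featurizeConfig <- function(halfWidth = 16, gridEdge = 32L,
                            excludeSelf = FALSE, heavyOnly = TRUE) {
  new("FeaturizeConfig", halfWidth = halfWidth,
      gridEdge = as.integer(gridEdge),
      voxelSize = 2 * halfWidth / gridEdge,
      channels = c("occupation", "mass", "charge"),
      excludeSelf = excludeSelf, heavyOnly = heavyOnly)
}

.unit <- function(v, what, tol = 1e-6) {
  n <- sqrt(sum(v^2))
  if (n < tol)
    stop("degenerate local frame: ", what, " has near-zero norm (", n, ")")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Body-fixed local coordinate frame of a nucleotide
#'
#' Builds the right-handed orthonormal frame that makes featurization
#' invariant to global rotation and translation. With \eqn{r} the global
#' positions of the named atoms: the origin is at C1'; the x axis is the
#' unit vector from C1' to the glycosidic nitrogen (N9 for purines, N1 for
#' pyrimidines); a provisional y points from C1' to the midpoint of O5' and
#' C5'; z is the unit cross product x by provisional-y; the final y is z
#' cross x.
#'
#' @param structure an \code{\link{RnaStructure}}.
#' @param chain,resno nucleotide key.
#' @return a \code{\link{LocalFrame}}.
#' @examples
#' s <- makeToyRna(decoyGenConfig(nNucleotides = 4))
#' computeLocalFrame(s, "A", 2)
#' @export
computeLocalFrame <- function(structure, chain, resno) {
  a <- structure@atoms
  rows <- .nucleotideRows(structure, chain, resno)
  if (!length(rows)) stop("no nucleotide ", chain, resno, " in structure")
  nm <- a$elety[rows]
  glyc <- glycosidicAtom(a$resname[rows[1]])
  pos <- function(atom) {
    i <- rows[match(atom, nm)]
    if (is.na(i))
      stop("cannot build local frame for ", chain, resno,
           ": missing atom ", atom)
    c(a$x[i], a$y[i], a$z[i])
  }
  rC1 <- pos("C1'")
  x <- .unit(pos(glyc) - rC1, "x (glycosidic N - C1')")
  yPre <- (pos("O5'") + pos("C5'")) / 2 - rC1
  z <- .unit(.cross3(x, yPre), "z (x cross provisional y)")
  y <- .cross3(z, x)
  new("LocalFrame", origin = rC1, xAxis = x, yAxis = y, zAxis = z)
}

#' Transform coordinates between global and local frames
#'
#' \code{toLocalCoords} projects global positions onto the frame axes;
#' \code{fromLocalCoords} inverts the transform exactly.
#'
#' @param frame a \code{\link{LocalFrame}}.
#' @param coords numeric matrix with columns x, y, z (one row per atom).
#' @return matrix of the same shape in the other frame.
#' @export
toLocalCoords <- function(frame, coords) {
  coords <- rbind(coords)
  d <- sweep(coords, 2, frame@origin)
  cbind(x = d %*% frame@xAxis, y = d %*% frame@yAxis, z = d %*% frame@zAxis)
}

#' @rdname toLocalCoords
#' @export
fromLocalCoords <- function(frame, coords) {
  coords <- rbind(coords)
  R <- cbind(frame@xAxis, frame@yAxis, frame@zAxis)
  sweep(coords %*% t(R), 2, frame@origin, "+")
}

#' Extract the atoms surrounding a nucleotide
#'
#' Returns every atom of the structure whose local coordinates satisfy
#' \code{max(|x|,|y|,|z|) < halfWidth} (strict inequality on all axes),
#' including the assessed nucleotide's own atoms unless
#' \code{config@excludeSelf}. An empty result is allowed.
#'
#' @param structure a property-assigned \code{\link{RnaStructure}}.
#' @param frame the nucleotide's \code{\link{LocalFrame}}.
#' @param config a \code{\link{FeaturizeConfig}}.
#' @param selfKey optional \code{list(chain=, resno=)} identifying the
#'   assessed nucleotide, needed only when \code{excludeSelf}.
#' @return data.frame of the environment atoms with their global columns
#'   plus local coordinates \code{lx}, \code{ly}, \code{lz}.
#' @export
extractEnvironment <- function(structure, frame, config = featurizeConfig(),
                               selfKey = NULL) {
  a <- structure@atoms
  loc <- toLocalCoords(frame, as.matrix(a[, c("x", "y", "z")]))
  keep <- abs(loc[, 1]) < config@halfWidth &
          abs(loc[, 2]) < config@halfWidth &
          abs(loc[, 3]) < config@halfWidth
  if (config@excludeSelf) {
    if (is.null(selfKey))
      stop("excludeSelf requires selfKey = list(chain=, resno=)")
    keep <- keep & !(a$chain == selfKey$chain & a$resno == selfKey$resno)
  }
  env <- a[keep, , drop = FALSE]
  env$lx <- loc[keep, 1]; env$ly <- loc[keep, 2]; env$lz <- loc[keep, 3]
  rownames(env) <- NULL
  env
}

#' Voxel index of local coordinates
#'
#' Cells are half-open: on each axis, index \code{i} (1-based) covers
#' \code{[(i-1)*voxelSize - halfWidth, i*voxelSize - halfWidth)} Angstrom,
#' i.e. \code{floor((c + halfWidth) / voxelSize) + 1}.
#'
#' @param coords numeric matrix of local coordinates (columns x, y, z).
#' @param config a \code{\link{FeaturizeConfig}}.
#' @return integer matrix of 1-based voxel indices per axis.
#' @export
voxelIndex <- function(coords, config = featurizeConfig()) {
  coords <- rbind(coords)
  idx <- floor((coords + config@halfWidth) / config@voxelSize) + 1
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("i", "j", "k")
  idx
}

#' Accumulate an environment into a raw voxel grid
#'
#' Each atom contributes to exactly one voxel; channel 1 accumulates the
#' occupation count, channel 2 the mass and channel 3 the charge, so the
#' channel sums equal the number, total mass and total charge of the
#' environment atoms.
#'
#' @param environment data.frame from \code{\link{extractEnvironment}}.
#' @param config a \code{\link{FeaturizeConfig}}.
#' @param provenance optional list recorded on the grid.
#' @return a raw \code{\link{VoxelGrid}}.
#' @export
voxelizeEnvironment <- function(environment, config = featurizeConfig(),
                                provenance = list()) {
  g <- config@gridEdge
  vals <- array(0, dim = c(3L, g, g, g))
  if (nrow(environment)) {
    if (anyNA(environment$mass) || anyNA(environment$charge))
      stop("environment atoms must have assigned mass and charge")
    loc <- as.matrix(environment[, c("lx", "ly", "lz")])
    if (any(abs(loc) >= config@halfWidth))
      stop("environment atom outside the cube; extractEnvironment ",
           "guarantees max(|x|,|y|,|z|) < halfWidth")
    idx <- voxelIndex(loc, config)
    lin <- idx[, 1] + g * (idx[, 2] - 1L) + g * g * (idx[, 3] - 1L)
    acc <- rowsum(cbind(1, environment$mass, environment$charge), lin)
    cells <- as.integer(rownames(acc))
    for (ch in 1:3) {
      slab <- array(0, dim = c(g, g, g))
      slab[cells] <- acc[, ch]
      vals[ch, , , ] <- slab
    }
  }
  new("VoxelGrid", values = vals, normalized = FALSE,
      provenance = provenance)
}

#' Featurize one nucleotide end to end
#'
#' Convenience chain: local frame, environment extraction, voxelization.
#'
#' @param structure a property-assigned \code{\link{RnaStructure}}.
#' @param chain,resno nucleotide key.
#' @param config a \code{\link{FeaturizeConfig}}.
#' @return a raw \code{\link{VoxelGrid}}.
#' @export
featurizeNucleotide <- function(structure, chain, resno,
                                config = featurizeConfig()) {
  frame <- computeLocalFrame(structure, chain, resno)
  env <- extractEnvironment(structure, frame, config,
                            selfKey = list(chain = chain, resno = resno))
  voxelizeEnvironment(env, config,
                      provenance = list(structureId = structure@structureId,
                                        chain = chain, resno = resno))
}

#' Fit dataset-wide min-max normalization statistics
#'
#' Scans all voxels of all training grids per channel and all raw labels,
#' recording global minima and maxima. The statistics are frozen into the
#' trained model; at inference values outside the fitted range saturate.
#' A channel whose max equals its min is flagged and maps to 0.
#'
#' @param grids list of raw \code{\link{VoxelGrid}}s.
#' @param labels numeric vector of raw unfitness labels (Angstrom).
#' @return a \code{\link{NormalizationStats}}.
#' @export
fitNormalization <- function(grids, labels) {
  if (!length(grids) || !length(labels))
    stop("need at least one grid and one label")
  mn <- rep(Inf, 3); mx <- rep(-Inf, 3)
  for (gd in grids) {
    stopifnot(is(gd, "VoxelGrid"))
    if (isNormalized(gd)) stop("fitNormalization expects raw grids")
    v <- gd@values
    for (ch in 1:3) {
      mn[ch] <- min(mn[ch], v[ch, , , ])
      mx[ch] <- max(mx[ch], v[ch, , , ])
    }
  }
  const <- (mx - mn) <= 0
  new("NormalizationStats", channelMin = mn, channelMax = mx,
      labelMin = min(labels), labelMax = max(labels),
      constantChannels = const)
}

#' Apply (or invert) min-max normalization
#'
#' \code{applyNormalization} rescales a raw grid channel-wise to [0, 1] with
#' clamping (values outside the fitted range saturate at 0/1);
#' \code{normalizeLabel}/\code{denormalizeLabel} do the same for scalar
#' labels.
#'
#' @param grid a raw \code{\link{VoxelGrid}}.
#' @param stats a fitted \code{\link{NormalizationStats}}.
#' @return a normalized \code{\link{VoxelGrid}}.
#' @export
applyNormalization <- function(grid, stats) {
  stopifnot(is(grid, "VoxelGrid"), is(stats, "NormalizationStats"))
  if (isNormalized(grid)) return(grid)
  v <- grid@values
  for (ch in 1:3) {
    if (stats@constantChannels[ch]) {
      v[ch, , , ] <- 0
    } else {
      rng <- stats@channelMax[ch] - stats@channelMin[ch]
      v[ch, , , ] <- pmin(1, pmax(0, (v[ch, , , ] - stats@channelMin[ch]) / rng))
    }
  }
  initialize(grid, values = v, normalized = TRUE)
}

#' @rdname applyNormalization
#' @param label numeric raw label(s) in Angstrom.
#' @export
normalizeLabel <- function(label, stats) {
  rng <- stats@labelMax - stats@labelMin
  if (rng <= 0) return(rep(0, length(label)))
  pmin(1, pmax(0, (label - stats@labelMin) / rng))
}

#' @rdname applyNormalization
#' @param normalized numeric normalized label(s) in [0, 1].
#' @export
denormalizeLabel <- function(normalized, stats) {
  stats@labelMin + normalized * (stats@labelMax - stats@labelMin)
}
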