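#' @include AllClasses.R
NULL

# --- Low-level 3D CNN machinery -------------------------------------------
#
# Activations are stored as plain numeric vectors in channel-first order:
# the element for (channel c, voxel x, y, z) of a (C, E, E, E) tensor sits at
# linear index c + C*(x-1) + C*E*(y-1) + C*E^2*(z-1), which is exactly
# as.vector() of an R array with dim c(C, E, E, E). Convolutions are
# evaluated as im2col gathers followed by BLAS matrix products; the gather
# index matrices depend only on the layer geometry and are precomputed once
# at model build time.

# im2col index matrix for a valid (no padding) cubic convolution:
# rows run over (channel fastest, then kernel dx, dy, dz), columns over
# output positions (x fastest). x[idx] is the (k^3*C) x outE^3 patch matrix.
.convIndex <- function(channels, edge, kernel, stride) {
  outE <- (edge - kernel) %/% stride + 1L
  C <- channels; E <- edge
  dx <- rep(seq_len(kernel), times = kernel * kernel)
  dy <- rep(rep(seq_len(kernel), each = kernel), times = kernel)
  dz <- rep(seq_len(kernel), each = kernel * kernel)
  rowBase <- as.vector(outer(seq_len(C),
    C * (dx - 1L) + C * E * (dy - 1L) + C * E * E * (dz - 1L), "+"))
  ox <- rep(seq_len(outE), times = outE * outE)
  oy <- rep(rep(seq_len(outE), each = outE), times = outE)
  oz <- rep(seq_len(outE), each = outE * outE)
  colBase <- C * (ox - 1L) * stride + C * E * (oy - 1L) * stride +
    C * E * E * (oz - 1L) * stride
  idx <- outer(rowBase, colBase, "+")
  storage.mode(idx) <- "integer"
  idx
}

# pooling gather index: rows over window elements, columns over
# (channel fastest, then output position) to match channel-first layout.
.poolIndex <- function(channels, edge, window, stride) {
  outE <- (edge - window) %/% stride + 1L
  C <- channels; E <- edge
  dx <- rep(seq_len(window), times = window * window)
  dy <- rep(rep(seq_len(window), each = window), times = window)
  dz <- rep(seq_len(window), each = window * window)
  rowBase <- C * (dx - 1L) + C * E * (dy - 1L) + C * E * E * (dz - 1L)
  ox <- rep(seq_len(outE), times = outE * outE)
  oy <- rep(rep(seq_len(outE), each = outE), times = outE)
  oz <- rep(seq_len(outE), each = outE * outE)
  colSpatial <- C * (ox - 1L) * stride + C * E * (oy - 1L) * stride +
    C * E * E * (oz - 1L) * stride
  colBase <- as.vector(outer(seq_len(C), colSpatial, "+"))
  idx <- outer(rowBase, colBase, "+")
  storage.mode(idx) <- "integer"
  idx
}

# Layer plan: geometry, gather indices and parameter shapes for each layer
# of a ModelSpec. Errors with a per-layer trace if a spatial size underflows.
.buildPlan <- function(spec) {
  layers <- list()
  C <- spec@inputChannels; E <- spec@gridEdge
  trace <- data.frame(layer = "input", edge = E, channels = C,
                      stringsAsFactors = FALSE)
  for (i in seq_along(spec@convFilters)) {
    k <- spec@convKernels[i]; s <- spec@convStrides[i]
    F <- spec@convFilters[i]
    outE <- (E - k) %/% s + 1L
    if (E < k || outE < 1L)
      stop("spatial size underflow at conv", i, " (edge ", E, " < kernel ",
           k, "); shape trace so far: ",
           paste(trace$edge, collapse = " -> "))
    layers[[length(layers) + 1L]] <- list(
      type = "conv", name = paste0("conv", i),
      idx = .convIndex(C, E, k, s), inC = C, outC = F, inE = E, outE = outE,
      nIn = C * E^3, nOut = outE^3,
      dropout = i %in% spec@dropoutConv)
    C <- F; E <- outE
    trace <- rbind(trace, data.frame(layer = paste0("conv", i), edge = E,
                                     channels = C))
    if (i %in% spec@poolAfter) {
      w <- spec@poolWindow; ps <- spec@poolStride
      outE <- (E - w) %/% ps + 1L
      if (E < w || outE < 1L)
        stop("spatial size underflow at pooling after conv", i,
             "; shape trace so far: ", paste(trace$edge, collapse = " -> "))
      layers[[length(layers) + 1L]] <- list(
        type = "pool", name = paste0("pool", i),
        idx = .poolIndex(C, E, w, ps), inC = C, outC = C, inE = E,
        outE = outE, nIn = C * E^3, nOut = C * outE^3)
      E <- outE
      trace <- rbind(trace, data.frame(layer = paste0("pool", i), edge = E,
                                       channels = C))
    }
  }
  features <- C * E^3
  if (spec@denseUnits > 0L) {
    layers[[length(layers) + 1L]] <- list(
      type = "dense", name = "dense", nIn = features,
      nOut = spec@denseUnits, dropout = spec@dropoutDense)
    outIn <- spec@denseUnits
  } else outIn <- features
  layers[[length(layers) + 1L]] <- list(
    type = "output", name = "output", nIn = outIn, nOut = 1L)
  list(layers = layers, trace = trace, features = features,
       cache = new.env(parent = emptyenv()))
}

# gather index for a whole batch: the per-sample index block replicated B
# times with per-sample offsets into the stacked (nIn x B) activation
# matrix. Cached per (layer, B) since it only depends on geometry.
.bigIndex <- function(plan, key, idx, nIn, B) {
  ck <- paste0(key, "_", B)
  got <- plan$cache[[ck]]
  if (!is.null(got)) return(got)
  big <- rep.int(as.vector(idx), B) +
    rep(seq.int(0L, by = as.integer(nIn), length.out = B),
        each = length(idx))
  plan$cache[[ck]] <- big
  big
}

.glorotUniform <- function(nrow, ncol, fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Forward pass for one sample. x: input vector (channel-first). Returns the
# scalar prediction plus per-layer caches needed for backpropagation.
# dropMasks: NULL (inference) or a list of precomputed inverted-dropout
# masks keyed by layer index.
.cnnForward <- function(weights, plan, x, dropMasks = NULL) {
  caches <- vector("list", length(plan$layers))
  a <- x
  for (li in seq_along(plan$layers)) {
    L <- plan$layers[[li]]
    W <- weights[[li]]
    if (L$type == "conv") {
      Xcol <- matrix(a[L$idx], nrow(L$idx), ncol(L$idx))
      Z <- crossprod(Xcol, W$W)                 # nOut x outC
      Z <- sweep(Z, 2, W$b, "+")
      A <- Z * (Z > 0)                          # ReLU
      if (!is.null(dropMasks) && L$dropout)
        A <- A * dropMasks[[li]]
      caches[[li]] <- list(Xcol = Xcol, Z = Z)
      a <- as.vector(t(A))
    } else if (L$type == "pool") {
      vals <- matrix(a[L$idx], nrow(L$idx), ncol(L$idx))
      mi <- max.col(t(vals), ties.method = "first")
      sel <- cbind(mi, seq_len(ncol(vals)))
      out <- vals[sel]
      caches[[li]] <- list(argmax = L$idx[sel])
      a <- out
    } else if (L$type == "dense") {
      z <- as.numeric(W$W %*% a + W$b)
      A <- z * (z > 0)
      if (!is.null(dropMasks) && isTRUE(L$dropout))
        A <- A * dropMasks[[li]]
      caches[[li]] <- list(aIn = a, z = z)
      a <- A
    } else {                                    # output, linear
      z <- as.numeric(W$W %*% a + W$b)
      caches[[li]] <- list(aIn = a)
      a <- z
    }
  }
  list(pred = a, caches = caches)
}

# Backward pass for one sample given d(loss)/d(pred). Returns per-layer
# weight gradients and (when wantInput) the gradient w.r.t. the input
# vector. Gradients of conv/dense layers with dropout masks are masked
# consistently with the forward pass.
.cnnBackward <- function(weights, plan, fwd, dPred, dropMasks = NULL,
                         wantInput = FALSE) {
  nl <- length(plan$layers)
  grads <- vector("list", nl)
  da <- dPred
  for (li in rev(seq_len(nl))) {
    L <- plan$layers[[li]]
    W <- weights[[li]]
    cache <- fwd$caches[[li]]
    if (L$type == "output") {
      grads[[li]] <- list(W = dPred * rbind(cache$aIn), b = dPred)
      da <- as.numeric(t(W$W) * dPred)
    } else if (L$type == "dense") {
      dz <- da * (cache$z > 0)
      if (!is.null(dropMasks) && isTRUE(L$dropout))
        dz <- dz * dropMasks[[li]]
      # note: mask applies to the activation, so it propagates into dz via
      # the chain rule before the ReLU derivative would matter; masked
      # units have zero downstream gradient either way
      grads[[li]] <- list(W = outer(dz, cache$aIn), b = dz)
      da <- as.numeric(crossprod(W$W, dz))
    } else if (L$type == "pool") {
      grads[[li]] <- list()
      dx <- numeric(L$nIn)
      acc <- rowsum(da, cache$argmax)
      dx[as.integer(rownames(acc))] <- acc
      da <- dx
    } else {                                    # conv
      dA <- t(matrix(da, L$outC, L$nOut))       # nOut x outC
      if (!is.null(dropMasks) && L$dropout)
        dA <- dA * dropMasks[[li]]
      dZ <- dA * (cache$Z > 0)
      grads[[li]] <- list(W = cache$Xcol %*% dZ, b = colSums(dZ))
      if (li > 1L || wantInput) {
        dXcol <- W$W %*% t(dZ)
        dx <- numeric(L$nIn)
        acc <- rowsum(as.vector(dXcol), as.vector(L$idx))
        dx[as.integer(rownames(acc))] <- acc
        da <- dx
      } else da <- NULL
    }
  }
  list(grads = grads, dInput = if (wantInput) da else NULL)
}

# Reverse im2col map for the first conv layer, CSR-style by input index:
# for input linear index i, the patch entries (kernel row r, output
# position p) with idx[r, p] == i sit at revR/revP[(starts[i]+1):starts[i+1]].
# Lets a sparse input column skip the full patch gather.
.conv1Reverse <- function(plan) {
  got <- plan$cache[["conv1rev"]]
  if (!is.null(got)) return(got)
  L <- plan$layers[[1L]]
  iVec <- as.vector(L$idx)
  ord <- order(iVec)
  revR <- rep.int(seq_len(nrow(L$idx)), ncol(L$idx))[ord]
  revP <- rep(seq_len(ncol(L$idx)), each = nrow(L$idx))[ord]
  starts <- c(0L, cumsum(tabulate(iVec, nbins = L$nIn)))
  out <- list(revR = revR, revP = revP, starts = starts)
  plan$cache[["conv1rev"]] <- out
  out
}

# Split a stack of input columns into per-channel baselines plus sparse
# deviations. The baseline is the per-channel median (the empty-voxel value
# for these mostly-empty grids); the decomposition x = baseline + delta is
# exact whatever the baseline, sparsity only affects speed.
.sparsifyInput <- function(plan, X) {
  C <- plan$layers[[1L]]$inC
  chan <- rep_len(seq_len(C), nrow(X))
  baseline <- vapply(seq_len(C),
                     function(c) stats::median(X[chan == c, 1L]), numeric(1))
  base <- baseline[chan]
  samples <- lapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    nz <- which(x != base)
    list(i = nz, d = x[nz] - base[nz])
  })
  list(baseline = baseline, base = base, chan = chan, samples = samples)
}

# First-layer convolution on sparse input: the constant baseline feeds every
# valid patch identically (one row vector times W), the deviations scatter
# through the reverse map. Returns the pre-activation Z stacked over the
# batch ((nc*B) x outC), identical to the dense path.
.conv1SparseZ <- function(weights, plan, sp) {
  L <- plan$layers[[1L]]
  W <- weights[[1L]]
  rev <- .conv1Reverse(plan)
  nc <- ncol(L$idx)
  # channel of each patch row (rows are channel-fastest)
  rowChan <- rep_len(seq_len(L$inC), nrow(L$idx))
  z0 <- as.numeric(crossprod(sp$baseline[rowChan], W$W)) + W$b
  B <- length(sp$samples)
  Z <- matrix(rep(z0, each = nc * B), nc * B, L$outC)
  for (j in seq_len(B)) {
    s <- sp$samples[[j]]
    if (!length(s$i)) next
    lens <- rev$starts[s$i + 1L] - rev$starts[s$i]
    sel <- sequence(lens, from = rev$starts[s$i] + 1L)
    M <- W$W[rev$revR[sel], , drop = FALSE] * rep.int(s$d, lens)
    acc <- rowsum(M, rev$revP[sel])
    rows <- as.integer(rownames(acc)) + (j - 1L) * nc
    Z[rows, ] <- Z[rows, ] + acc
  }
  Z
}

# Gradient of the first-layer weights for sparse input:
# dW = Xcol^T dZ splits into the baseline outer product and the per-sample
# sparse contributions.
.conv1SparseGrad <- function(plan, sp, dZ) {
  L <- plan$layers[[1L]]
  rev <- .conv1Reverse(plan)
  nc <- ncol(L$idx)
  rowChan <- rep_len(seq_len(L$inC), nrow(L$idx))
  cs <- colSums(dZ)
  dW <- outer(sp$baseline[rowChan], cs)
  for (j in seq_along(sp$samples)) {
    s <- sp$samples[[j]]
    if (!length(s$i)) next
    lens <- rev$starts[s$i + 1L] - rev$starts[s$i]
    sel <- sequence(lens, from = rev$starts[s$i] + 1L)
    contrib <- dZ[rev$revP[sel] + (j - 1L) * nc, , drop = FALSE] *
      rep.int(s$d, lens)
    acc <- rowsum(contrib, rev$revR[sel])
    ri <- as.integer(rownames(acc))
    dW[ri, ] <- dW[ri, ] + acc
  }
  list(W = dW, b = cs)
}

# Batched forward pass: X is (nIn x B), one column per sample. Convolutions
# gather the im2col patches of the whole batch into one matrix and run a
# single GEMM; the per-sample results are identical to .cnnForward.
# dropMasks: NULL or per-layer masks sized for the whole batch.
.cnnForwardBatch <- function(weights, plan, X, dropMasks = NULL,
                             sparse = NULL) {
  B <- if (is.null(sparse)) ncol(X) else length(sparse$samples)
  caches <- vector("list", length(plan$layers))
  A <- X
  for (li in seq_along(plan$layers)) {
    L <- plan$layers[[li]]
    W <- weights[[li]]
    if (L$type == "conv") {
      nc <- ncol(L$idx)
      if (li == 1L && !is.null(sparse)) {
        Xcol <- NULL
        Z <- .conv1SparseZ(weights, plan, sparse)
      } else {
        big <- .bigIndex(plan, paste0("conv", li), L$idx, L$nIn, B)
        Xcol <- matrix(A[big], nrow(L$idx), nc * B)
        Z <- sweep(crossprod(Xcol, W$W), 2, W$b, "+")  # (nc*B) x outC
      }
      Act <- Z * (Z > 0)
      if (!is.null(dropMasks) && L$dropout)
        Act <- Act * dropMasks[[li]]
      caches[[li]] <- list(Xcol = Xcol, Z = Z)
      # rows are (position within sample, sample); reorder to channel-first
      # vectors per sample: (outC, nc, B) -> (outC*nc, B)
      A <- matrix(aperm(array(Act, c(nc, B, L$outC)), c(3, 1, 2)),
                  L$outC * nc, B)
    } else if (L$type == "pool") {
      ncP <- ncol(L$idx)
      big <- .bigIndex(plan, paste0("pool", li), L$idx, L$nIn, B)
      vals <- matrix(A[big], nrow(L$idx), ncP * B)
      mi <- max.col(t(vals), ties.method = "first")
      sel <- cbind(mi, seq_len(ncol(vals)))
      caches[[li]] <- list(argmax = big[(sel[, 2] - 1L) * nrow(L$idx) +
                                          sel[, 1]],
                           inLen = L$nIn * B)
      A <- matrix(vals[sel], ncP, B)
    } else if (L$type == "dense") {
      Z <- sweep(W$W %*% A, 1, W$b, "+")               # units x B
      Act <- Z * (Z > 0)
      if (!is.null(dropMasks) && isTRUE(L$dropout))
        Act <- Act * dropMasks[[li]]
      caches[[li]] <- list(aIn = A, Z = Z)
      A <- Act
    } else {                                           # output, linear
      caches[[li]] <- list(aIn = A)
      A <- as.numeric(W$W %*% A + W$b)
    }
  }
  list(pred = A, caches = caches, B = B)
}

# Batched backward pass; dPred is the loss gradient per sample (length B).
# Weight gradients come back already summed over the batch.
.cnnBackwardBatch <- function(weights, plan, fwd, dPred, dropMasks = NULL,
                              sparse = NULL) {
  nl <- length(plan$layers)
  B <- fwd$B
  grads <- vector("list", nl)
  da <- NULL
  for (li in rev(seq_len(nl))) {
    L <- plan$layers[[li]]
    W <- weights[[li]]
    cache <- fwd$caches[[li]]
    if (L$type == "output") {
      grads[[li]] <- list(W = t(cache$aIn %*% dPred), b = sum(dPred))
      da <- t(W$W) %*% matrix(dPred, 1, B)
    } else if (L$type == "dense") {
      dz <- da * (cache$Z > 0)
      if (!is.null(dropMasks) && isTRUE(L$dropout))
        dz <- dz * dropMasks[[li]]
      grads[[li]] <- list(W = dz %*% t(cache$aIn), b = rowSums(dz))
      da <- crossprod(W$W, dz)
    } else if (L$type == "pool") {
      grads[[li]] <- list()
      dx <- numeric(cache$inLen)
      acc <- rowsum(as.vector(da), cache$argmax)
      dx[as.integer(rownames(acc))] <- acc
      da <- matrix(dx, L$nIn, B)
    } else {                                           # conv
      nc <- ncol(L$idx)
      dA <- matrix(aperm(array(da, c(L$outC, nc, B)), c(2, 3, 1)),
                   nc * B, L$outC)
      if (!is.null(dropMasks) && L$dropout)
        dA <- dA * dropMasks[[li]]
      dZ <- dA * (cache$Z > 0)
      if (li == 1L && !is.null(sparse))
        grads[[li]] <- .conv1SparseGrad(plan, sparse, dZ)
      else
        grads[[li]] <- list(W = cache$Xcol %*% dZ, b = colSums(dZ))
      if (li > 1L) {
        big <- .bigIndex(plan, paste0("conv", li), L$idx, L$nIn, B)
        dx <- numeric(L$nIn * B)
        acc <- rowsum(as.vector(W$W %*% t(dZ)), big)
        dx[as.integer(rownames(acc))] <- acc
        da <- matrix(dx, L$nIn, B)
      } else da <- NULL
    }
  }
  grads
}

# fresh inverted-dropout masks for one forward/backward pair (training only)
.dropoutMasks <- function(plan, rate) {
  if (rate <= 0) return(NULL)
  masks <- vector("list", length(plan$layers))
  keep <- 1 - rate
  for (li in seq_along(plan$layers)) {
    L <- plan$layers[[li]]
    if (L$type == "conv" && L$dropout)
      masks[[li]] <- matrix((stats::runif(L$nOut * L$outC) < keep) / keep,
                            L$nOut, L$outC)
    else if (L$type == "dense" && isTRUE(L$dropout))
      masks[[li]] <- (stats::runif(L$nOut) < keep) / keep
  }
  masks
}

# batch variant: mask shapes follow the batched activation layout
.dropoutMasksBatch <- function(plan, rate, B) {
  if (rate <= 0) return(NULL)
  masks <- vector("list", length(plan$layers))
  keep <- 1 - rate
  for (li in seq_along(plan$layers)) {
    L <- plan$layers[[li]]
    if (L$type == "conv" && L$dropout) {
      n <- ncol(L$idx) * B * L$outC
      masks[[li]] <- matrix((stats::runif(n) < keep) / keep,
                            ncol(L$idx) * B, L$outC)
    } else if (L$type == "dense" && isTRUE(L$dropout)) {
      masks[[li]] <- matrix((stats::runif(L$nOut * B) < keep) / keep,
                            L$nOut, B)
    }
  }
  masks
}
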