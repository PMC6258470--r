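#' @include AllClasses.R featurize.R
NULL

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation R and translation t minimizing the RMSD of
#' \code{R P + t} onto \code{Q} over paired points, via SVD of the
#' cross-covariance with the reflection branch corrected to determinant +1.
#'
#' @param P,Q numeric matrices (n x 3) of corresponding points, n >= 3.
#' @return a \code{\link{SuperpositionResult}}.
#' @examples
#' P <- matrix(rnorm(30), 10)
#' kabschSuperpose(P, P + 5)@rmsd   # pure translation: 0
#' @export
kabschSuperpose <- function(P, Q) {
  P <- rbind(P); Q <- rbind(Q)
  if (nrow(P) != nrow(Q)) stop("P and Q must have the same number of points")
  if (nrow(P) < 3L) stop("need at least 3 corresponding points")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)                 # 3x3 cross-covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t <- cq - as.numeric(R %*% cp)
  diffs <- Qc - Pc %*% t(R)
  rmsd <- sqrt(max(0, sum(diffs^2) / nrow(P)))
  new("SuperpositionResult", rotation = R, translation = t, rmsd = rmsd)
}

# coordinates of one nucleotide's atoms, named by atom name
.nucleotideCoords <- function(structure, chain, resno) {
  a <- structure@atoms
  rows <- .nucleotideRows(structure, chain, resno)
  m <- as.matrix(a[rows, c("x", "y", "z")])
  rownames(m) <- a$elety[rows]
  m
}

#' RMSD-based unfitness label of one nucleotide
#'
#' The regression target the network is trained on: how poorly a nucleotide
#' fits its surroundings, measured against the native structure. Procedure:
#' (1) match the nucleotide's atoms by name between native and assessed;
#' (2) superpose the assessed nucleotide onto its native conformation
#' (Kabsch on the nucleotide's own atoms only); (3) the self term is that
#' superposition RMSD; (4) the surroundings are the atoms inside the native
#' nucleotide's cube, excluding the nucleotide itself, matched to assessed
#' atoms by (chain, residue number, atom name); (5) the surroundings term is
#' the RMSD of those pairs under the transform from step 2, without
#' re-fitting; (6) the raw score is their sum. A score of 0 means the
#' nucleotide sits in its native conformation and environment; the raw score
#' is invariant under global rigid motion of either structure.
#'
#' @param native,assessed property-assigned \code{\link{RnaStructure}}s
#'   sharing residue numbering.
#' @param chain,resno key of the assessed nucleotide.
#' @param config \code{\link{FeaturizeConfig}} defining the surroundings
#'   cube (native-side membership).
#' @return list with \code{raw} (Angstrom), \code{selfRmsd},
#'   \code{surroundingsRmsd}, \code{nSurrounding} (matched pairs),
#'   \code{coverage} (fraction of native surrounding atoms matched) and
#'   \code{defined} (FALSE when no surrounding atoms matched, in which case
#'   \code{raw} is NA and the sample is excluded from training).
#' @export
nucleotideUnfitness <- function(native, assessed, chain, resno,
                                config = featurizeConfig()) {
  Pn <- .nucleotideCoords(native, chain, resno)
  Pa <- .nucleotideCoords(assessed, chain, resno)
  shared <- intersect(rownames(Pn), rownames(Pa))
  if (length(shared) < 3L)
    stop("fewer than 3 matched atoms for nucleotide ", chain, resno)
  sup <- kabschSuperpose(Pa[shared, , drop = FALSE],
                         Pn[shared, , drop = FALSE])
  selfRmsd <- sup@rmsd

  # surroundings membership decided on the native structure's cube
  frame <- computeLocalFrame(native, chain, resno)
  env <- extractEnvironment(native, frame, config)
  env <- env[!(env$chain == chain & env$resno == resno), , drop = FALSE]
  if (!nrow(env)) {
    return(list(raw = NA_real_, selfRmsd = selfRmsd,
                surroundingsRmsd = NA_real_, nSurrounding = 0L,
                coverage = 0, defined = FALSE))
  }
  aa <- assessed@atoms
  keyEnv <- paste(env$chain, env$resno, env$elety)
  keyAss <- paste(aa$chain, aa$resno, aa$elety)
  hit <- match(keyEnv, keyAss)
  ok <- !is.na(hit)
  coverage <- mean(ok)
  if (!any(ok)) {
    return(list(raw = NA_real_, selfRmsd = selfRmsd,
                surroundingsRmsd = NA_real_, nSurrounding = 0L,
                coverage = 0, defined = FALSE))
  }
  natXyz <- as.matrix(env[ok, c("x", "y", "z")])
  assXyz <- as.matrix(aa[hit[ok], c("x", "y", "z")])
  moved <- sweep(assXyz %*% t(sup@rotation), 2, sup@translation, "+")
  surrRmsd <- sqrt(sum((moved - natXyz)^2) / nrow(natXyz))
  list(raw = surrRmsd + selfRmsd, selfRmsd = selfRmsd,
       surroundingsRmsd = surrRmsd, nSurrounding = nrow(natXyz),
       coverage = coverage, defined = TRUE)
}

#' Global heavy-atom RMSD between two structures
#'
#' Matches atoms by (chain, residue number, atom name), performs a single
#' optimal superposition of the full structures and returns the RMSD over
#' all matched atoms.
#'
#' @param native,assessed \code{\link{RnaStructure}}s sharing numbering.
#' @return numeric(1), Angstrom.
#' @export
structureRmsd <- function(native, assessed) {
  an <- native@atoms; aa <- assessed@atoms
  hit <- match(paste(an$chain, an$resno, an$elety),
               paste(aa$chain, aa$resno, aa$elety))
  ok <- !is.na(hit)
  if (sum(ok) < 3L) stop("fewer than 3 matched atoms between structures")
  kabschSuperpose(as.matrix(aa[hit[ok], c("x", "y", "z")]),
                  as.matrix(an[ok, c("x", "y", "z")]))@rmsd
}

#' Label every nucleotide of an assessed structure
#'
#' Runs \code{\link{nucleotideUnfitness}} for each frame-ready nucleotide.
#'
#' @param native,assessed property-assigned \code{\link{RnaStructure}}s.
#' @param config \code{\link{FeaturizeConfig}}.
#' @return data.frame with \code{chain}, \code{resno}, \code{resname},
#'   \code{raw}, \code{selfRmsd}, \code{surroundingsRmsd}, \code{defined}.
#' @export
labelStructure <- function(native, assessed, config = featurizeConfig()) {
  keys <- nucleotideKeys(native)
  out <- lapply(seq_len(nrow(keys)), function(i) {
    ch <- keys$chain[i]; rn <- keys$resno[i]
    if (!.frameReady(native, ch, rn) || !.frameReady(assessed, ch, rn))
      return(NULL)
    lab <- nucleotideUnfitness(native, assessed, ch, rn, config)
    data.frame(chain = ch, resno = rn, resname = keys$resname[i],
               raw = lab$raw, selfRmsd = lab$selfRmsd,
               surroundingsRmsd = lab$surroundingsRmsd,
               defined = lab$defined, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
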