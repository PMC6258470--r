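#' @include AllClasses.R structure-io.R featurize.R labeling.R
NULL

#' Configuration for synthetic structure and decoy generation
#'
#' Defines the toy single-stranded helix geometry and the Gaussian decoy
#' perturbation used to exercise and train the pipeline at desk scale. The
#' helix defaults (rise 2.8 Angstrom, twist 33 degrees, radius 9 Angstrom)
#' give A-form-like packing density without attempting chemical realism.
#'
#' @param nNucleotides integer(1) >= 1, helix length (default 14).
#' @param perturbationSigma numeric(1) >= 0, per-coordinate Gaussian
#'   displacement in Angstrom for decoys.
#' @param nDecoys integer(1) >= 1 decoys per sigma.
#' @param seed integer(1) base RNG seed; all generation is reproducible
#'   from it.
#' @param risePerResidue,twistPerResidue,helixRadius helix parameters
#'   (Angstrom, degrees, Angstrom).
#' @return a validated list of the above fields.
#' @export
decoyGenConfig <- function(nNucleotides = 14L, perturbationSigma = 1.0,
                           nDecoys = 1L, seed = 1L, risePerResidue = 2.8,
                           twistPerResidue = 33, helixRadius = 9) {
  stopifnot(nNucleotides >= 1L, perturbationSigma >= 0, nDecoys >= 1L)
  list(nNucleotides = as.integer(nNucleotides),
       perturbationSigma = perturbationSigma,
       nDecoys = as.integer(nDecoys), seed = as.integer(seed),
       risePerResidue = risePerResidue,
       twistPerResidue = twistPerResidue, helixRadius = helixRadius)
}

# per-residue atom offsets in the residue's own (radial u, tangential v,
# axial w) frame; chosen so the frame construction is well-conditioned
# (glycosidic N along -u, O5'/C5' midpoint well off that axis)
.toyOffsets <- rbind(
  "C1'" = c(0.0, 0.0, 0.0),
  "N"   = c(-1.47, 0.0, 0.0),
  "O5'" = c(0.5, 1.4, 1.6),
  "C5'" = c(0.3, 1.0, 0.9),
  "P"   = c(0.9, 2.2, 2.0),
  "C4'" = c(0.5, 1.0, -0.6),
  "O4'" = c(-0.4, 0.6, -0.8),
  "C3'" = c(1.2, 0.8, -1.4),
  "O3'" = c(1.8, 1.5, -1.9),
  "C2'" = c(0.3, -0.5, -1.2),
  "O2'" = c(-0.2, -1.3, -1.8))

#' Generate a synthetic toy RNA helix
#'
#' Parametric single-stranded helix of alternating purine/pyrimidine
#' residues (A, U, A, ...). Every nucleotide carries C1', O5', C5', the
#' glycosidic nitrogen (N9 or N1), phosphate P (except residue 1) and six
#' sugar atoms at fixed offsets in the residue's own frame, so every
#' nucleotide is frame-ready and consecutive C1'-C1' distances are equal by
#' construction. The geometry is regular-helical, not A-form-accurate; it
#' exists so the full pipeline is testable and trainable without external
#' structure generators.
#'
#' @param config from \code{\link{decoyGenConfig}}.
#' @param structureId identifier for the structure.
#' @return an \code{\link{RnaStructure}} (properties not assigned).
#' @examples
#' s <- makeToyRna(decoyGenConfig(nNucleotides = 14))
#' nNucleotides(s)   # 14
#' @export
makeToyRna <- function(config = decoyGenConfig(),
                       structureId = sprintf("toy%d", config$nNucleotides)) {
  n <- config$nNucleotides
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    theta <- (i - 1) * config$twistPerResidue * pi / 180
    u <- c(cos(theta), sin(theta), 0)
    v <- c(-sin(theta), cos(theta), 0)
    w <- c(0, 0, 1)
    c1 <- config$helixRadius * u + c(0, 0, (i - 1) * config$risePerResidue)
    resname <- if (i %% 2L == 1L) "A" else "U"
    names <- rownames(.toyOffsets)
    if (i == 1L) names <- setdiff(names, "P")
    xyz <- t(vapply(names, function(nm) {
      o <- .toyOffsets[nm, ]
      c1 + o[1] * u + o[2] * v + o[3] * w
    }, numeric(3)))
    elety <- ifelse(names == "N", glycosidicAtom(resname), names)
    rows[[i]] <- data.frame(
      chain = "A", resno = i, resname = resname, elety = elety,
      element = substr(elety, 1, 1), x = xyz[, 1], y = xyz[, 2],
      z = xyz[, 3], mass = NA_real_, charge = NA_real_,
      stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  new("RnaStructure", structureId = structureId, atoms = atoms,
      modelNumber = 1L, propertiesAssigned = FALSE)
}

#' Gaussian-perturbed decoy of a structure
#'
#' Displaces every atom independently by isotropic Gaussian noise with
#' standard deviation \code{sigma} per coordinate (seeded, reproducible);
#' \code{sigma = 0} returns an identical copy. This stands in for
#' simulation-generated decoy ensembles: the RMSD to the native grows
#' monotonically with sigma, which is the property the labeling and
#' training modules need.
#'
#' @param structure an \code{\link{RnaStructure}}.
#' @param sigma numeric(1) >= 0, Angstrom.
#' @param seed integer(1).
#' @return a perturbed copy with \code{structureId} suffixed by the sigma
#'   and seed.
#' @export
perturbStructure <- function(structure, sigma, seed = 1L) {
  stopifnot(is(structure, "RnaStructure"), sigma >= 0)
  out <- structure
  if (sigma > 0) {
    n <- nrow(out@atoms)
    noise <- .withSeed(seed, matrix(stats::rnorm(3 * n, 0, sigma), n, 3))
    out@atoms$x <- out@atoms$x + noise[, 1]
    out@atoms$y <- out@atoms$y + noise[, 2]
    out@atoms$z <- out@atoms$z + noise[, 3]
  }
  out@structureId <- sprintf("%s_s%g_r%d", structure@structureId, sigma,
                             as.integer(seed))
  out
}

#' Generate a labeled training set from synthetic decoys
#'
#' For each sigma and each decoy replicate, every frame-ready nucleotide of
#' the decoy yields one (raw voxel grid, raw unfitness label) pair: the grid
#' is featurized from the decoy structure, the label measured against the
#' native by \code{\link{nucleotideUnfitness}}. Stream order (sigma, decoy,
#' nucleotide) and all randomness are deterministic under the config seed.
#' Labels are nonnegative and zero exactly for sigma 0.
#'
#' @param config from \code{\link{decoyGenConfig}}; \code{nDecoys} decoys
#'   are drawn per sigma.
#' @param sigmas numeric vector of perturbation sigmas (Angstrom).
#' @param featConfig a \code{\link{FeaturizeConfig}}.
#' @return list with \code{grids} (list of raw \code{\link{VoxelGrid}}),
#'   \code{labels} (numeric, Angstrom), \code{provenance} (data.frame with
#'   sigma, decoy, chain, resno) and \code{native} (the property-assigned
#'   native structure).
#' @export
makeTrainingSet <- function(config = decoyGenConfig(), sigmas = c(0.3, 1.0),
                            featConfig = featurizeConfig()) {
  if (!length(sigmas)) stop("need at least one sigma")
  native <- assignAtomProperties(makeToyRna(config),
                                 heavyOnly = featConfig@heavyOnly)
  grids <- list()
  labels <- numeric()
  prov <- list()
  for (si in seq_along(sigmas)) {
    for (di in seq_len(config$nDecoys)) {
      seed <- config$seed + 7919L * si + di
      decoy <- perturbStructure(native, sigmas[si], seed)
      labs <- labelStructure(native, decoy, featConfig)
      labs <- labs[labs$defined, , drop = FALSE]
      for (j in seq_len(nrow(labs))) {
        grids[[length(grids) + 1L]] <-
          featurizeNucleotide(decoy, labs$chain[j], labs$resno[j],
                              featConfig)
        labels <- c(labels, labs$raw[j])
        prov[[length(prov) + 1L]] <-
          data.frame(sigma = sigmas[si], decoy = di, chain = labs$chain[j],
                     resno = labs$resno[j])
      }
    }
  }
  provenance <- do.call(rbind, prov)
  rownames(provenance) <- NULL
  list(grids = grids, labels = labels, provenance = provenance,
       native = native)
}
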