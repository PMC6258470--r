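#' @include AllClasses.R atom-properties.R
NULL

.canonicalResidues <- c("A", "U", "G", "C")

.purines <- c("A", "G")

#' Base class and glycosidic nitrogen of a residue
#'
#' A and G are purines (glycosidic nitrogen N9); C and U are pyrimidines
#' (N1).
#'
#' @param resname canonical residue name(s).
#' @return \code{baseClass}: "purine" or "pyrimidine";
#'   \code{glycosidicAtom}: "N9" or "N1".
#' @export
baseClass <- function(resname) {
  ifelse(resname %in% .purines, "purine", "pyrimidine")
}

#' @rdname baseClass
#' @export
glycosidicAtom <- function(resname) {
  ifelse(resname %in% .purines, "N9", "N1")
}

#' Read an RNA structure from a PDB file
#'
#' Parses one model of a PDB file through \pkg{bio3d} and keeps only RNA
#' residues (A/U/G/C plus the configured modified-residue aliases, which are
#' renamed to their parents). Waters, ions, proteins and unmapped residues
#' are skipped with a message reporting the count. Alternate locations are
#' resolved to the highest occupancy, ties broken by first appearance. Atom
#' names are normalized to PDB v3 primes (\code{C1*} becomes \code{C1'}).
#'
#' @param file path to a PDB file.
#' @param model integer(1) >= 1, which MODEL to read (1 for single-model
#'   files).
#' @param aliases named character vector mapping modified residue names to
#'   parents (see \code{\link{defaultResidueAliases}}).
#' @param structureId identifier stored on the result; defaults to the file
#'   stem.
#' @return an \code{\link{RnaStructure}} (properties not yet assigned).
#' @examples
#' f <- tempfile(fileext = ".pdb")
#' writeRnaPdb(makeToyRna(decoyGenConfig(nNucleotides = 4)), f)
#' readRnaPdb(f)
#' @export
readRnaPdb <- function(file, model = 1L, aliases = defaultResidueAliases(),
                       structureId = NULL) {
  stopifnot(length(model) == 1L, model >= 1L)
  pdb <- tryCatch(bio3d::read.pdb(file, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("PDB parse error for ", file, ": ",
                         conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || !nrow(at)) stop("no ATOM records in ", file)
  nModels <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (model > nModels)
    stop("model ", model, " not present; available models: 1..", nModels)
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  n <- nrow(at)
  coords <- matrix(xyz[seq_len(3L * n)], ncol = 3L, byrow = TRUE)

  elety <- gsub("\\*", "'", trimws(at$elety))
  resid <- trimws(at$resid)
  a <- data.frame(
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = as.integer(at$resno),
    resname = resid,
    elety = elety,
    element = .elementFromName(elety, at$elesy),
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    mass = NA_real_, charge = NA_real_,
    occ = ifelse(is.na(at$o), 1, at$o),
    stringsAsFactors = FALSE)

  # map modified residues to parents, then keep canonical RNA only
  ali <- match(a$resname, names(aliases))
  a$resname[!is.na(ali)] <- unname(aliases[ali[!is.na(ali)]])
  keep <- a$resname %in% .canonicalResidues
  if (any(!keep)) {
    skippedRes <- unique(paste0(a$chain[!keep], at$resno[!keep]))
    message("skipped ", length(skippedRes),
            " non-RNA or unmapped residue(s) (",
            paste(unique(trimws(at$resid[!keep])), collapse = ", "), ")")
  }
  a <- a[keep, , drop = FALSE]
  if (!nrow(a)) stop("no RNA residues found in ", file)

  # altloc: highest occupancy wins, first appearance breaks ties;
  # original atom order within each residue is preserved
  a$.ord <- seq_len(nrow(a))
  key <- paste(a$chain, a$resno, a$elety)
  a <- a[order(key, -a$occ, a$.ord), , drop = FALSE]
  a <- a[!duplicated(paste(a$chain, a$resno, a$elety)), , drop = FALSE]

  a <- a[order(a$chain, a$resno, a$.ord), , drop = FALSE]
  a$occ <- NULL
  a$.ord <- NULL
  rownames(a) <- NULL
  if (is.null(structureId))
    structureId <- sub("\\.pdb$", "", basename(file), ignore.case = TRUE)
  new("RnaStructure", structureId = structureId, atoms = a,
      modelNumber = as.integer(model), propertiesAssigned = FALSE)
}

#' Write an RnaStructure to a PDB file
#'
#' Thin wrapper over \code{bio3d::write.pdb}; used by the synthetic fixture
#' generator and for round-tripping structures.
#'
#' @param structure an \code{\link{RnaStructure}}.
#' @param file output path.
#' @return \code{file}, invisibly.
#' @export
writeRnaPdb <- function(structure, file) {
  a <- atomData(structure)
  if (!nrow(a)) stop("empty structure")
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, o = rep(1, nrow(a)),
                   b = rep(0, nrow(a)))
  invisible(file)
}

#' Write per-nucleotide and global score reports
#'
#' Emits a TSV with one row per assessed nucleotide (columns \code{chain},
#' \code{resnum}, \code{resname}, \code{unfitness_score}) followed by a
#' final \code{global} row carrying the structure score, which equals the
#' sum of the per-nucleotide rows. Optionally writes a JSON summary
#' (\code{structure_id}, \code{n_nucleotides}, \code{global_score}).
#'
#' @param assessment a \code{\link{StructureAssessment}}.
#' @param file TSV destination path.
#' @param jsonFile optional JSON summary path.
#' @return \code{file}, invisibly.
#' @export
writeScoreReport <- function(assessment, file, jsonFile = NULL) {
  stopifnot(is(assessment, "StructureAssessment"))
  p <- perNucleotideScores(assessment)
  if (!nrow(p)) stop("no per-nucleotide scores to report")
  rows <- data.frame(chain = p$chain, resnum = p$resno, resname = p$resname,
                     unfitness_score = p$score, stringsAsFactors = FALSE)
  rows <- rbind(rows, data.frame(chain = "global", resnum = NA,
                                 resname = "", unfitness_score =
                                   globalScore(assessment)))
  utils::write.table(rows, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (!is.null(jsonFile)) {
    jsonlite::write_json(
      list(structure_id = structureId(assessment),
           n_nucleotides = nrow(p),
           global_score = globalScore(assessment)),
      jsonFile, auto_unbox = TRUE, digits = NA)
  }
  invisible(file)
}

# rows of `structure`'s atom table belonging to one nucleotide
.nucleotideRows <- function(structure, chain, resno) {
  a <- structure@atoms
  which(a$chain == chain & a$resno == resno)
}

# TRUE if the nucleotide carries all four frame-defining atoms
.frameReady <- function(structure, chain, resno) {
  a <- structure@atoms
  rows <- .nucleotideRows(structure, chain, resno)
  if (!length(rows)) return(FALSE)
  need <- c("C1'", "O5'", "C5'", glycosidicAtom(a$resname[rows[1]]))
  all(need %in% a$elety[rows])
}
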