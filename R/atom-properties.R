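#' @include AllClasses.R
NULL

# Element masses (Da) used as fallback when an atom has no table entry.
.elementMasses <- c(H = 1.008, C = 12.01, N = 14.01, O = 16.00, P = 30.97,
                    S = 32.06)

# Amber-force-field-style partial charges (units of e) for the RNA heavy
# atoms: shared sugar-phosphate backbone charges plus per-base base-atom
# charges, covering every canonical heavy atom of A, U, G, C. Scores are
# insensitive to the exact decimals at the package's desk scale; users with
# a preferred parameter set can supply their own table.
.backboneCharges <- c(
  "P" = 1.1662, "OP1" = -0.7760, "OP2" = -0.7760,
  "O5'" = -0.4989, "C5'" = 0.0558, "C4'" = 0.1065, "O4'" = -0.3548,
  "C3'" = 0.2022, "O3'" = -0.5246, "C2'" = 0.0670, "O2'" = -0.6139
)

.baseCharges <- list(
  A = c("C1'" = 0.0394, "N9" = -0.0251, "C8" = 0.2006, "N7" = -0.6073,
        "C5" = 0.0515, "C6" = 0.7009, "N6" = -0.9019, "N1" = -0.7615,
        "C2" = 0.5875, "N3" = -0.6997, "C4" = 0.3053),
  G = c("C1'" = 0.0191, "N9" = 0.0492, "C8" = 0.1374, "N7" = -0.5709,
        "C5" = 0.1744, "C6" = 0.4770, "O6" = -0.5597, "N1" = -0.4787,
        "C2" = 0.7657, "N2" = -0.9672, "N3" = -0.6323, "C4" = 0.1222),
  C = c("C1'" = 0.0066, "N1" = -0.0484, "C6" = 0.0053, "C5" = -0.5215,
        "C4" = 0.8185, "N4" = -0.9530, "N3" = -0.7584, "C2" = 0.7538,
        "O2" = -0.6252),
  U = c("C1'" = 0.0674, "N1" = 0.0418, "C6" = -0.1126, "C5" = -0.3635,
        "C4" = 0.5952, "O4" = -0.5761, "N3" = -0.3549, "C2" = 0.4687,
        "O2" = -0.5477)
)

#' Per-atom mass and charge table for canonical RNA residues
#'
#' Returns the package's atom-property table mapping
#' \code{(resname, elety)} to mass (Da) and partial charge (e). Charges are
#' amber-force-field-style values covering every canonical heavy atom of
#' A, U, G and C (backbone charges shared across residues); masses come from
#' the element. Atoms absent from the table fall back to the element mass
#' and charge 0 during \code{\link{assignAtomProperties}}.
#'
#' @return data.frame with columns \code{resname}, \code{elety},
#'   \code{element}, \code{mass}, \code{charge}.
#' @examples
#' tab <- atomPropertyTable()
#' subset(tab, resname == "U" & elety == "N3")
#' @export
atomPropertyTable <- function() {
  rows <- lapply(names(.baseCharges), function(res) {
    ch <- c(.backboneCharges, .baseCharges[[res]])
    data.frame(resname = res, elety = names(ch),
               element = substr(names(ch), 1, 1),
               mass = unname(.elementMasses[substr(names(ch), 1, 1)]),
               charge = unname(ch), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Modified-residue aliases mapped to parent nucleotides
#'
#' Small alias table mapping common modified residue names to their canonical
#' parent (e.g. pseudouridine PSU to U). Residues not in
#' \code{c("A","U","G","C")} and not aliased are skipped at parse time with
#' a warning.
#'
#' @return named character vector: names are PDB residue names, values the
#'   canonical parent.
#' @export
defaultResidueAliases <- function() {
  c(PSU = "U", "5MU" = "U", H2U = "U", "4SU" = "U", UR3 = "U",
    "1MA" = "A", MA6 = "A", "2MG" = "G", "7MG" = "G", M2G = "G",
    OMG = "G", YG = "G", "5MC" = "C", OMC = "C",
    RA = "A", RU = "U", RG = "G", RC = "C",
    ADE = "A", URA = "U", GUA = "G", CYT = "C")
}

.elementFromName <- function(elety, elesy = NULL) {
  if (!is.null(elesy)) {
    e <- toupper(trimws(elesy))
    ok <- !is.na(e) & nzchar(e)
    if (all(ok)) return(e)
  } else {
    e <- rep(NA_character_, length(elety))
    ok <- rep(FALSE, length(elety))
  }
  guess <- toupper(substr(gsub("^[0-9]", "", elety), 1, 1))
  e[!ok] <- guess[!ok]
  e
}

#' Attach masses and charges to every atom of a structure
#'
#' Every retained atom receives a mass (Da) and partial charge (e) from the
#' property table; atoms without a table entry fall back to the element mass
#' with charge 0 (counted in a message). Hydrogens are dropped when
#' \code{heavyOnly} (the default: crystal structures lack them and decoy
#' sources differ, so excluding them keeps scores comparable across
#' sources). Idempotent.
#'
#' @param structure an \code{\link{RnaStructure}}.
#' @param table property table as returned by \code{\link{atomPropertyTable}}.
#' @param heavyOnly logical(1), drop hydrogen atoms (default TRUE).
#' @return the structure with \code{mass}/\code{charge} populated.
#' @examples
#' s <- assignAtomProperties(makeToyRna(decoyGenConfig(nNucleotides = 4)))
#' head(atomData(s))
#' @export
assignAtomProperties <- function(structure, table = atomPropertyTable(),
                                 heavyOnly = TRUE) {
  stopifnot(is(structure, "RnaStructure"))
  a <- structure@atoms
  if (heavyOnly) {
    isH <- a$element == "H" | grepl("^[0-9]*H", a$elety)
    a <- a[!isH, , drop = FALSE]
  }
  if (!nrow(a)) stop("no atoms remain after hydrogen filtering")
  key <- paste(a$resname, a$elety)
  tabKey <- paste(table$resname, table$elety)
  hit <- match(key, tabKey)
  a$mass <- table$mass[hit]
  a$charge <- table$charge[hit]
  miss <- is.na(hit)
  if (any(miss)) {
    fb <- .elementMasses[a$element[miss]]
    if (anyNA(fb)) {
      bad <- unique(paste(a$resname[miss], a$elety[miss])[is.na(fb)])
      stop("atoms with unknown element and no fallback mass: ",
           paste(bad, collapse = ", "))
    }
    a$mass[miss] <- unname(fb)
    a$charge[miss] <- 0
    message(sum(miss), " atom(s) without a table entry used the element-mass",
            " fallback with charge 0")
  }
  rownames(a) <- NULL
  structure@atoms <- a
  structure@propertiesAssigned <- TRUE
  validObject(structure)
  structure
}
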