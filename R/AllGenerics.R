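#' @include AllClasses.R
NULL

#' Accessors for package classes
#'
#' Small accessor generics so code never reaches into slots directly.
#'
#' @param object an object of one of the package classes.
#' @return \code{structureId}: character(1); \code{atomData}: the atom
#'   data.frame; \code{nucleotideKeys}: data.frame of (chain, resno, resname)
#'   per nucleotide; \code{nNucleotides}: integer(1); \code{gridValues}: the
#'   (3, g, g, g) array; \code{isNormalized}: logical(1); \code{globalScore}:
#'   numeric(1); \code{perNucleotideScores}: data.frame;
#'   \code{trainingHistory}: data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("structureId", function(object) standardGeneric("structureId"))
#' @rdname accessors
#' @export
setGeneric("atomData", function(object) standardGeneric("atomData"))
#' @rdname accessors
#' @export
setGeneric("nucleotideKeys", function(object) standardGeneric("nucleotideKeys"))
#' @rdname accessors
#' @export
setGeneric("nNucleotides", function(object) standardGeneric("nNucleotides"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))
#' @rdname accessors
#' @export
setGeneric("globalScore", function(object) standardGeneric("globalScore"))
#' @rdname accessors
#' @export
setGeneric("perNucleotideScores",
           function(object) standardGeneric("perNucleotideScores"))
#' @rdname accessors
#' @export
setGeneric("trainingHistory",
           function(object) standardGeneric("trainingHistory"))

#' @rdname accessors
setMethod("structureId", "RnaStructure", function(object) object@structureId)
#' @rdname accessors
setMethod("structureId", "StructureAssessment",
          function(object) object@structureId)
#' @rdname accessors
setMethod("atomData", "RnaStructure", function(object) object@atoms)
#' @rdname accessors
setMethod("nucleotideKeys", "RnaStructure", function(object) {
  a <- object@atoms
  k <- unique(a[, c("chain", "resno", "resname")])
  rownames(k) <- NULL
  k
})
#' @rdname accessors
setMethod("nNucleotides", "RnaStructure",
          function(object) nrow(nucleotideKeys(object)))
#' @rdname accessors
setMethod("gridValues", "VoxelGrid", function(object) object@values)
#' @rdname accessors
setMethod("isNormalized", "VoxelGrid", function(object) object@normalized)
#' @rdname accessors
setMethod("globalScore", "StructureAssessment",
          function(object) object@globalScore)
#' @rdname accessors
setMethod("perNucleotideScores", "StructureAssessment",
          function(object) object@perNucleotide)
#' @rdname accessors
setMethod("trainingHistory", "TrainedModel", function(object) object@history)

setMethod("show", "RnaStructure", function(object) {
  cat("RnaStructure", sQuote(object@structureId),
      sprintf("(model %d)\n", object@modelNumber))
  cat(" ", nNucleotides(object), "nucleotides,", nrow(object@atoms),
      "atoms\n")
  cat("  properties assigned:", object@propertiesAssigned, "\n")
})

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat(sprintf("VoxelGrid %dx%dx%dx%d (%s)\n", d[1], d[2], d[3], d[4],
              if (object@normalized) "normalized" else "raw"))
  if (length(object@provenance))
    cat("  from:", object@provenance$structureId,
        paste0(object@provenance$chain, object@provenance$resno), "\n")
  cat("  occupation sum:", sum(object@values[1, , , ]), "\n")
})

setMethod("show", "TrainedModel", function(object) {
  s <- object@spec
  cat("TrainedModel:",
      paste0("conv ", paste(s@convFilters, collapse = "/"),
             " @ ", paste(s@convKernels, collapse = "/"), "^3"),
      "-> dense", s@denseUnits, "-> 1\n")
  cat("  parameters:", countParameters(object), "\n")
  cat("  trained epochs:", nrow(object@history), "\n")
  cat("  normalization:",
      if (is.null(object@normalization)) "unset" else "frozen", "\n")
})

setMethod("show", "StructureAssessment", function(object) {
  cat("StructureAssessment of", sQuote(object@structureId), "\n")
  cat(sprintf("  %d nucleotides scored, %d skipped\n",
              nrow(object@perNucleotide), nrow(object@skipped)))
  cat(sprintf("  global score: %.4f (lower is better)\n", object@globalScore))
})

setMethod("show", "DecoySet", function(object) {
  cat("DecoySet", sQuote(object@targetId), "with", nrow(object@records),
      "records;", if (is.na(object@nativeId)) "no native flagged"
      else paste("native:", object@nativeId), "\n")
})
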