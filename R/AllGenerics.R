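#' @rdname RNAStructure-class
#' @param object,x an object.
#' @export
setGeneric("structureID", function(x) standardGeneric("structureID"))

#' @rdname RNAStructure-class
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' @rdname RNAStructure-class
#' @export
setGeneric("residueTable", function(x) standardGeneric("residueTable"))

#' @rdname RNAStructure-class
#' @export
setGeneric("structureLength", function(x) standardGeneric("structureLength"))

#' @rdname RNAStructure-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname RNAStructure-class
#' @export
setGeneric("processingLog", function(x) standardGeneric("processingLog"))

#' @rdname radiusOfGyration
#' @export
setGeneric("radiusOfGyration",
           function(x, ...) standardGeneric("radiusOfGyration"))

#' @rdname gyrationTensor
#' @export
setGeneric("gyrationTensor",
           function(x, ...) standardGeneric("gyrationTensor"))

#' @rdname shapeDescriptors
#' @export
setGeneric("shapeDescriptors",
           function(x, ...) standardGeneric("shapeDescriptors"))

#' @export
#' @rdname RNAStructure-class
setMethod("structureID", "RNAStructure", function(x) x@id)

#' @export
#' @rdname RNAStructure-class
setMethod("atomTable", "RNAStructure", function(x) x@atoms)

#' @export
#' @rdname RNAStructure-class
setMethod("residueTable", "RNAStructure", function(x) {
  a <- x@atoms
  first <- !duplicated(a$residx)
  data.frame(residx = a$residx[first], chain = a$chain[first],
             resno = a$resno[first], base = a$base[first],
             natoms = as.integer(table(factor(a$residx,
                                              levels = a$residx[first]))),
             row.names = NULL)
})

#' @export
#' @rdname RNAStructure-class
setMethod("structureLength", "RNAStructure",
          function(x) length(unique(x@atoms$residx)))

#' @export
#' @rdname RNAStructure-class
setMethod("nAtoms", "RNAStructure", function(x) nrow(x@atoms))

#' @export
#' @rdname RNAStructure-class
setMethod("processingLog", "RNAStructure", function(x) x@log)

setMethod("show", "RNAStructure", function(object) {
  rt <- residueTable(object)
  cat("RNAStructure:", object@id, "\n")
  cat("  ", structureLength(object), "residues in",
      length(unique(rt$chain)), "chain(s);", nAtoms(object),
      "heavy atoms\n")
  comp <- table(rt$base)
  cat("  composition:",
      paste(names(comp), comp, sep = ":", collapse = " "), "\n")
  if (length(object@log))
    cat("  log:", length(object@log), "note(s); see processingLog()\n")
})

setMethod("show", "ShapeDescriptors", function(object) {
  cat("ShapeDescriptors (", object@nAtoms, " heavy atoms)\n", sep = "")
  cat(sprintf("  Rg = %.3f A;  eigenvalues = %.3f %.3f %.3f A^2\n",
              object@rg, object@eigenvalues[1], object@eigenvalues[2],
              object@eigenvalues[3]))
  cat(sprintf("  asphericity = %.4f;  shape = %.4f\n",
              object@asphericity, object@shape))
})

setMethod("show", "SecondaryStructure", function(object) {
  cat("SecondaryStructure on", object@length, "nt\n")
  cat("  stems:", length(object@stems),
      " lone pairs:", nrow(object@lonePairs),
      " pseudoknot pairs:", nrow(object@pseudoknotPairs), "\n")
  if (nrow(object@loops))
    print(table(object@loops$kind))
  cat("  ", object@dotbracket, "\n", sep = "")
})

setMethod("show", "DatasetSummary", function(object) {
  cat("DatasetSummary over", object@nStructures, "structure(s)\n")
  if (!is.null(object@fits$power_law))
    cat(sprintf("  Rg ~ %.3f * L^%.3f\n",
                object@fits$power_law["a"], object@fits$power_law["b"]))
  if (!is.null(object@fits$bp_slope))
    cat(sprintf("  Nbp ~ %.3f * L; non-canonical ~ %.3f * L\n",
                object@fits$bp_slope, object@fits$bp_noncanonical_slope))
  cat(sprintf("  fraction with asphericity < 0.2: %.3f\n",
              object@asphericityBelow02))
})
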