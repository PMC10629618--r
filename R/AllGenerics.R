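#' @rdname FamilySet-class
#' @param x a `FamilySet`
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' @rdname FamilySet-class
#' @export
setGeneric("nFamilies", function(x) standardGeneric("nFamilies"))

#' @rdname FamilySet-class
#' @export
setGeneric("familySizes", function(x) standardGeneric("familySizes"))

#' @rdname FamilySet-class
#' @export
setGeneric("unassignedIds", function(x) standardGeneric("unassignedIds"))

#' @rdname FamilySet-class
#' @export
setGeneric("familyAnnotations", function(x) standardGeneric("familyAnnotations"))

#' @rdname MaskReport-class
#' @param x a `MaskReport`
#' @export
setGeneric("maskedRegions", function(x) standardGeneric("maskedRegions"))

#' @rdname MaskReport-class
#' @export
setGeneric("maskedFraction", function(x) standardGeneric("maskedFraction"))

#' @rdname MaskReport-class
#' @export
setGeneric("regionCounts", function(x) standardGeneric("regionCounts"))

setMethod("families", "FamilySet", function(x) x@families)
setMethod("nFamilies", "FamilySet", function(x) length(x@families))
setMethod("familySizes", "FamilySet",
          function(x) lengths(x@families))
setMethod("unassignedIds", "FamilySet", function(x) x@unassigned)
setMethod("familyAnnotations", "FamilySet", function(x) x@annotations)

setMethod("show", "FamilySet", function(object) {
  cat(sprintf("FamilySet (%s): %d families over %d sequences\n",
              object@method, length(object@families),
              length(unlist(object@families, use.names = FALSE))))
  sz <- lengths(object@families)
  if (length(sz))
    cat(sprintf("  sizes: max %d / median %g / singletons %d\n",
                max(sz), stats::median(sz), sum(sz == 1L)))
  if (length(object@unassigned))
    cat(sprintf("  unassigned: %d\n", length(object@unassigned)))
  if (nrow(object@annotations))
    cat(sprintf("  multi-domain annotations: %d memberships for %d proteins\n",
                nrow(object@annotations),
                length(unique(object@annotations$protein))))
  invisible(NULL)
})

setMethod("maskedRegions", "MaskReport", function(x) x@regions)

setMethod("maskedFraction", "MaskReport", function(x) {
  if (x@totalResidues == 0L) return(0)
  x@maskedPositions / x@totalResidues
})

setMethod("regionCounts", "MaskReport", function(x) {
  if (!nrow(x@regions)) return(table(factor(character(0))))
  table(factor(x@regions$residue))
})

setMethod("show", "MaskReport", function(object) {
  cat(sprintf("MaskReport: %d low-complexity regions in %d/%d records\n",
              nrow(object@regions),
              length(unique(object@regions$record_id)), object@nRecords))
  cat(sprintf("  masked positions: %d of %d residues (%.2f%%)\n",
              object@maskedPositions, object@totalResidues,
              100 * maskedFraction(object)))
  if (nrow(object@regions)) {
    cc <- sort(table(object@regions$residue), decreasing = TRUE)
    cat("  regions per residue:",
        paste(sprintf("%s=%d", names(cc), cc), collapse = " "), "\n")
  }
  invisible(NULL)
})
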