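## Accessor generics. Slot access from user code goes through these.

#' @rdname StackManifest-class
#' @param object,x an object of the documented class
#' @export
setGeneric("imagePaths", function(x) standardGeneric("imagePaths"))
#' @rdname StackManifest-class
#' @export
setMethod("imagePaths", "StackManifest", function(x) x@imagePaths)

#' @rdname StackManifest-class
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))
#' @rdname StackManifest-class
#' @export
setMethod("pixelSizeUm", "StackManifest", function(x) x@pixelSizeUm)

#' @rdname StackManifest-class
#' @export
setGeneric("zStepUm", function(x) standardGeneric("zStepUm"))
#' @rdname StackManifest-class
#' @export
setMethod("zStepUm", "StackManifest", function(x) x@zStepUm)
#' @rdname AlignmentMap-class
#' @export
setMethod("zStepUm", "AlignmentMap", function(x) x@zStepUm)

#' @rdname AlignmentMap-class
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))
#' @rdname AlignmentMap-class
#' @export
setMethod("anchors", "AlignmentMap", function(x) x@anchors)

#' @rdname AlignmentMap-class
#' @export
setGeneric("nPlanes", function(x) standardGeneric("nPlanes"))
#' @rdname AlignmentMap-class
#' @export
setMethod("nPlanes", "AlignmentMap", function(x) x@nPlanes)
#' @rdname StackManifest-class
#' @export
setMethod("nPlanes", "StackManifest", function(x) length(x@imagePaths))

#' @rdname AtlasPlate-class
#' @export
setGeneric("apCoordinate", function(x) standardGeneric("apCoordinate"))
#' @rdname AtlasPlate-class
#' @export
setMethod("apCoordinate", "AtlasPlate", function(x) x@apMm)

#' @rdname AtlasPlate-class
#' @export
setGeneric("labelMask", function(x) standardGeneric("labelMask"))
#' @rdname AtlasPlate-class
#' @export
setMethod("labelMask", "AtlasPlate", function(x) x@labelMask)

#' @rdname AtlasPlate-class
#' @export
setGeneric("plateOutline", function(x) standardGeneric("plateOutline"))
#' @rdname AtlasPlate-class
#' @export
setMethod("plateOutline", "AtlasPlate", function(x) x@outline)

#' @rdname AtlasBundle-class
#' @export
setGeneric("plates", function(x) standardGeneric("plates"))
#' @rdname AtlasBundle-class
#' @export
setMethod("plates", "AtlasBundle", function(x) x@plates)

#' @rdname AtlasBundle-class
#' @export
setGeneric("ontology", function(x) standardGeneric("ontology"))
#' @rdname AtlasBundle-class
#' @export
setMethod("ontology", "AtlasBundle", function(x) x@ontology)

#' @rdname AtlasBundle-class
#' @export
setGeneric("referenceTable", function(x) standardGeneric("referenceTable"))
#' @rdname AtlasBundle-class
#' @export
setMethod("referenceTable", "AtlasBundle", function(x) x@referenceTable)

#' @rdname CorrespondencePointSet-class
#' @export
setGeneric("pointPairs", function(x) standardGeneric("pointPairs"))
#' @rdname CorrespondencePointSet-class
#' @export
setMethod("pointPairs", "CorrespondencePointSet", function(x) x@pairs)
#' @rdname Warp-class
#' @export
setMethod("pointPairs", "Warp", function(x) x@controlPairs)

#' @rdname MorphProfile-class
#' @export
setGeneric("intervals", function(x) standardGeneric("intervals"))
#' @rdname MorphProfile-class
#' @export
setMethod("intervals", "MorphProfile", function(x) x@intervals)

## show methods -----------------------------------------------------------

setMethod("show", "StackManifest", function(object) {
  cat(sprintf("StackManifest: %d planes ('%s')\n", length(object@imagePaths),
              object@channelTag))
  cat(sprintf("  z step %.3g um, pixel %.3g um\n", object@zStepUm,
              object@pixelSizeUm))
  if (length(object@imagePaths))
    cat(sprintf("  first: %s\n  last:  %s\n",
                basename(object@imagePaths[1]),
                basename(object@imagePaths[length(object@imagePaths)])))
})

setMethod("show", "AlignmentMap", function(object) {
  a <- object@anchors
  cat(sprintf("AlignmentMap: %d anchors over %d planes (z step %.3g um)\n",
              nrow(a), object@nPlanes, object@zStepUm))
  if (nrow(a))
    cat(sprintf("  AP range %+.3f .. %+.3f mm; sources: %s\n",
                a$ap_mm[1], a$ap_mm[nrow(a)],
                paste(sprintf("%s=%d", names(table(a$source)),
                              as.integer(table(a$source))), collapse = ", ")))
})

setMethod("show", "AtlasBundle", function(object) {
  cat(sprintf("AtlasBundle: %d plates, %d regions\n",
              length(object@plates), nrow(object@ontology)))
  if (length(object@plates)) {
    aps <- vapply(object@plates, function(p) p@apMm, numeric(1))
    cat(sprintf("  AP %+.2f .. %+.2f mm\n", max(aps), min(aps)))
  }
  root <- object@ontology$acronym[is.na(object@ontology$parent_id)]
  cat(sprintf("  ontology root: %s\n", root))
})

setMethod("show", "Warp", function(object) {
  cat(sprintf("Warp: thin-plate spline, %d control pairs, lambda = %g\n",
              nrow(object@controlPairs), object@lambda))
})

setMethod("show", "CorrespondencePointSet", function(object) {
  cat(sprintf("CorrespondencePointSet: %d pairs, history depth %d\n",
              nrow(object@pairs), length(object@history)))
})

setMethod("show", "MorphProfile", function(object) {
  iv <- object@intervals
  cat(sprintf("MorphProfile: %d intervals, ratio range %.3f .. %.3f\n",
              nrow(iv), min(iv$morph_ratio), max(iv$morph_ratio)))
})
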