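#' @rdname estimateManifold
#' @export
setGeneric("estimateManifold", function(x, ...)
    standardGeneric("estimateManifold"))

#' @rdname pairGeometry
#' @export
setGeneric("pairGeometry", function(a, b, m, ...)
    standardGeneric("pairGeometry"))

#' @rdname geometryGrid
#' @export
setGeneric("geometryGrid", function(x, m, ...)
    standardGeneric("geometryGrid"))

#' @rdname randomSubspace
#' @export
setGeneric("randomSubspace", function(x, k, seed, ...)
    standardGeneric("randomSubspace"))

#' @rdname randomProject
#' @export
setGeneric("randomProject", function(x, d, seed, ...)
    standardGeneric("randomProject"))

# ---- accessors ----

#' @rdname ManifoldSummary-accessors
#' @export
setGeneric("centroid", function(x) standardGeneric("centroid"))

#' @rdname ManifoldSummary-accessors
#' @export
setGeneric("manifoldRadii", function(x) standardGeneric("manifoldRadii"))

#' @rdname ManifoldSummary-accessors
#' @export
setGeneric("principalDirections", function(x)
    standardGeneric("principalDirections"))

#' @rdname ManifoldSummary-accessors
#' @export
setGeneric("totalRadiusSq", function(x) standardGeneric("totalRadiusSq"))

#' @rdname ManifoldSummary-accessors
#' @export
setGeneric("dimensionality", function(x) standardGeneric("dimensionality"))

#' @rdname ManifoldSummary-accessors
#' @export
setGeneric("nExemplars", function(x) standardGeneric("nExemplars"))

#' @rdname ActivitySet-accessors
#' @export
setGeneric("activityPatterns", function(x) standardGeneric("activityPatterns"))

#' @rdname ActivitySet-accessors
#' @export
setGeneric("conceptLabels", function(x) standardGeneric("conceptLabels"))

#' @rdname ActivitySet-accessors
#' @export
setGeneric("conceptNames", function(x) standardGeneric("conceptNames"))

#' @rdname ActivitySet-accessors
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))

#' @rdname ActivitySet-accessors
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname PairGeometry-accessors
#' @export
setGeneric("geometricSignal", function(x) standardGeneric("geometricSignal"))

#' @rdname PairGeometry-accessors
#' @export
setGeneric("geometricBias", function(x) standardGeneric("geometricBias"))

#' @rdname PairGeometry-accessors
#' @export
setGeneric("overlaps", function(x) standardGeneric("overlaps"))

#' @rdname PairGeometry-accessors
#' @export
setGeneric("combinedOverlap", function(x) standardGeneric("combinedOverlap"))

#' @rdname PairGeometry-accessors
#' @export
setGeneric("geometricSNR", function(x) standardGeneric("geometricSNR"))

#' @rdname PairGeometry-accessors
#' @export
setGeneric("predictedError", function(x) standardGeneric("predictedError"))

#' @rdname FewShotResult-accessors
#' @export
setGeneric("errorMean", function(x) standardGeneric("errorMean"))

#' @rdname FewShotResult-accessors
#' @export
setGeneric("errorStd", function(x) standardGeneric("errorStd"))

#' @rdname FewShotResult-accessors
#' @export
setGeneric("foldGeometry", function(x) standardGeneric("foldGeometry"))
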