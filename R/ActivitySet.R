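#' Construct an ActivitySet from an exemplar-by-unit matrix
#'
#' @param patterns numeric matrix, one row per exemplar presentation, one
#'   column per unit (voxel/feature).
#' @param concepts character (or coercible) concept label per row.
#' @param trials optional integer trial identifier per row, grouping
#'   repeated presentations of the same exemplar.
#' @param unitIds optional unit (column) names; defaults to the column
#'   names of \code{patterns} or \code{unit1 ... unitV}.
#' @return an \linkS4class{ActivitySet}.
#' @examples
#' x <- ActivitySet(matrix(rnorm(40), 10, 4),
#'                  rep(c("face", "house"), each = 5))
#' conceptNames(x)
#' @export
ActivitySet <- function(patterns, concepts, trials = NULL, unitIds = NULL) {
    patterns <- as.matrix(patterns)
    if (!is.numeric(patterns))
        stop("'patterns' must be a numeric matrix")
    concepts <- as.character(concepts)
    if (length(concepts) != nrow(patterns))
        stop("one concept label per row of 'patterns' is required")
    if (is.null(unitIds))
        unitIds <- colnames(patterns)
    if (is.null(unitIds))
        unitIds <- paste0("unit", seq_len(ncol(patterns)))
    cd <- S4Vectors::DataFrame(concept = concepts)
    if (!is.null(trials)) {
        if (length(trials) != nrow(patterns))
            stop("one trial id per row of 'patterns' is required")
        cd$trial <- as.integer(trials)
    }
    a <- t(patterns)
    dimnames(a) <- list(unitIds, NULL)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(activity = a), colData = cd)
    new("ActivitySet", se)
}

#' ActivitySet accessors
#'
#' \code{activityPatterns} returns the exemplar-by-unit matrix;
#' \code{conceptLabels} the per-exemplar labels; \code{conceptNames} the
#' distinct concepts (in order of first appearance); \code{trialIds} the
#' trial identifiers or \code{NULL}; \code{nExemplars}/\code{nUnits} the
#' dataset size.
#'
#' @param x an \linkS4class{ActivitySet}.
#' @return see the individual descriptions above.
#' @name ActivitySet-accessors
NULL

#' @rdname ActivitySet-accessors
#' @export
setMethod("activityPatterns", "ActivitySet", function(x)
    t(SummarizedExperiment::assay(x, "activity")))

#' @rdname ActivitySet-accessors
#' @export
setMethod("conceptLabels", "ActivitySet", function(x)
    as.character(SummarizedExperiment::colData(x)$concept))

#' @rdname ActivitySet-accessors
#' @export
setMethod("conceptNames", "ActivitySet", function(x)
    unique(conceptLabels(x)))

#' @rdname ActivitySet-accessors
#' @export
setMethod("trialIds", "ActivitySet", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("trial" %in% colnames(cd)) as.integer(cd$trial) else NULL
})

#' @rdname ActivitySet-accessors
#' @export
setMethod("nUnits", "ActivitySet", function(x) nrow(x))

#' @rdname ActivitySet-accessors
#' @export
setMethod("nExemplars", "ActivitySet", function(x) ncol(x))

setMethod("show", "ActivitySet", function(object) {
    lab <- conceptLabels(object)
    cat("ActivitySet:", ncol(object), "exemplar presentations x",
        nrow(object), "units\n")
    cat("  concepts (", length(unique(lab)), "): ",
        paste(head(unique(lab), 6), collapse = ", "),
        if (length(unique(lab)) > 6) ", ..." else "", "\n", sep = "")
    if (!is.null(trialIds(object)))
        cat("  trial repeats present (",
            length(unique(trialIds(object))), " exemplars)\n", sep = "")
})

# concept -> row indices, preserving first-appearance order of concepts
.conceptIndex <- function(x) {
    lab <- conceptLabels(x)
    split(seq_along(lab), factor(lab, levels = unique(lab)))
}

# exemplar-by-unit matrix of one concept
.conceptMatrix <- function(x, concept) {
    lab <- conceptLabels(x)
    if (!(concept %in% lab))
        stop("concept '", concept, "' not present in the dataset")
    activityPatterns(x)[lab == concept, , drop = FALSE]
}
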