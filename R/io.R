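#' Read an ActivitySet from a delimited text file
#'
#' The canonical interchange dialect: a header line, first column the
#' concept label, optional second column \code{trial}/\code{trial_id},
#' remaining columns numeric unit activities. Tab-separated by default;
#' commas are accepted (the delimiter is sniffed). UTF-8, '.' decimal.
#'
#' @param path file to read.
#' @return an \linkS4class{ActivitySet}; dimensions are reported via a
#'   message.
#' @seealso \code{\link{writeActivityDataset}}
#' @export
readActivityDataset <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    dt <- data.table::fread(path, header = TRUE, sep = "auto",
                            data.table = FALSE, na.strings = c("NA", "NaN"))
    if (ncol(dt) < 2L)
        stop("parse error: at least a label column and one unit ",
             "column are required")
    labels <- as.character(dt[[1L]])
    unitStart <- 2L
    trials <- NULL
    if (tolower(colnames(dt)[2L]) %in% c("trial", "trial_id")) {
        trials <- as.integer(dt[[2L]])
        unitStart <- 3L
    }
    units <- dt[, seq(unitStart, ncol(dt)), drop = FALSE]
    for (j in seq_along(units)) {
        col <- units[[j]]
        if (!is.numeric(col)) {
            bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
            stop("parse error: non-numeric cell in column '",
                 colnames(units)[j], "', data row ", bad)
        }
        if (any(!is.finite(col))) {
            bad <- which(!is.finite(col))[1L]
            stop("parse error: missing/non-finite value in column '",
                 colnames(units)[j], "', data row ", bad)
        }
    }
    x <- ActivitySet(as.matrix(units), labels, trials = trials,
                     unitIds = colnames(units))
    message("read ", nExemplars(x), " rows x ", nUnits(x),
            " units (", length(conceptNames(x)), " concepts) from ",
            path)
    x
}

#' Write an ActivitySet to a delimited text file
#'
#' @param x an \linkS4class{ActivitySet}.
#' @param path output file.
#' @param sep field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
writeActivityDataset <- function(x, path, sep = "\t") {
    df <- data.frame(concept = conceptLabels(x),
                     check.names = FALSE)
    if (!is.null(trialIds(x)))
        df$trial <- trialIds(x)
    df <- cbind(df, as.data.frame(activityPatterns(x)))
    data.table::fwrite(df, path, sep = sep, quote = FALSE)
    invisible(path)
}

#' Write geometry tables
#'
#' Writes the long-format pairwise table (one row per ordered pair) and
#' the per-concept summary table of a \code{\link{geometryGrid}} result
#' as TSV.
#'
#' @param grid result of \code{\link{geometryGrid}}.
#' @param dir output directory (created if needed).
#' @return character vector of the written paths, invisibly.
#' @export
writeGeometryTables <- function(grid, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pp <- file.path(dir, "pair_geometry.tsv")
    cp <- file.path(dir, "concept_geometry.tsv")
    data.table::fwrite(grid$pairs, pp, sep = "\t", quote = FALSE)
    data.table::fwrite(grid$concepts, cp, sep = "\t", quote = FALSE)
    invisible(c(pp, cp))
}

#' Write few-shot error matrices
#'
#' @param result a \linkS4class{FewShotResult}.
#' @param dir output directory (created if needed).
#' @return written paths, invisibly.
#' @export
writeFewShotResult <- function(result, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, c("fewshot_error_mean.tsv",
                              "fewshot_error_std.tsv",
                              "fewshot_fold_geometry.tsv"))
    .writeMatrix(errorMean(result), paths[1])
    .writeMatrix(errorStd(result), paths[2])
    data.table::fwrite(foldGeometry(result), paths[3], sep = "\t",
                       quote = FALSE)
    invisible(paths)
}

.writeMatrix <- function(m, path) {
    df <- data.frame(concept = rownames(m), m, check.names = FALSE)
    data.table::fwrite(df, path, sep = "\t", quote = FALSE)
}

#' Read a concept-by-concept matrix written by the package
#' @param path TSV with a leading \code{concept} column.
#' @return numeric matrix with concept dimnames.
#' @export
readMatrixTSV <- function(path) {
    df <- data.table::fread(path, header = TRUE, sep = "\t",
                            data.table = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    m
}

#' Read / write a ManifoldSpec as JSON
#'
#' @param spec a \linkS4class{ManifoldSpec}.
#' @param path JSON file.
#' @return \code{readManifoldSpec}: a \linkS4class{ManifoldSpec};
#'   \code{writeManifoldSpec}: \code{path}, invisibly.
#' @export
writeManifoldSpec <- function(spec, path) {
    obj <- list(
        ambient_dim = spec@ambientDim,
        concepts = lapply(seq_along(spec@conceptNames), function(i)
            list(name = spec@conceptNames[i],
                 center = spec@centers[, i],
                 spectrum = spec@spectra[[i]],
                 basis = spec@bases[[i]],
                 exemplar_count = spec@exemplarCount[i])))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeManifoldSpec
#' @export
readManifoldSpec <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    cs <- obj$concepts
    getf <- function(field) {
        if (is.data.frame(cs)) cs[[field]] else
            lapply(cs, `[[`, field)
    }
    names <- unlist(getf("name"))
    centers <- getf("center")
    spectra <- getf("spectrum")
    bases <- lapply(getf("basis"), function(b) {
        b <- as.matrix(b)
        storage.mode(b) <- "double"
        b
    })
    manifoldSpec(ambientDim = obj$ambient_dim,
                 centers = do.call(cbind, centers),
                 spectra = spectra, bases = bases,
                 exemplarCount = unlist(getf("exemplar_count")),
                 conceptNames = names)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the standard sequence on one dataset: read (or sample
#' from a spec), optionally embed (random subspace, random projection),
#' estimate the pairwise geometry, run the empirical few-shot protocol,
#' fit the log-linear Overlap model, score error-matrix symmetry and,
#' when a hierarchy graph is supplied, relate success to hop distance.
#' All outputs are written as TSV under \code{outDir} together with a
#' machine-readable \code{manifest.json} (configuration and versions);
#' rerunning with the same configuration reproduces every table
#' byte-identically.
#'
#' @param config named list or path to a JSON configuration with fields:
#'   \code{input} (activity TSV) or \code{spec} (ManifoldSpec JSON; one
#'   of the two required), \code{outDir} (required), \code{seed}
#'   (required), and optional \code{m} (default 5), \code{nOuter},
#'   \code{nInner} (default 16), \code{holdoutFraction} (default 0.1),
#'   \code{subspaceDim}, \code{projectionDim}, \code{distanceGraph}
#'   (edge-list file).
#' @return invisibly, a list with the in-memory results and the written
#'   paths.
#' @export
runPipeline <- function(config) {
    if (is.character(config) && length(config) == 1L)
        config <- jsonlite::read_json(config, simplifyVector = TRUE)
    if (is.null(config$seed))
        stop("configuration error: 'seed' is required")
    if (is.null(config$outDir))
        stop("configuration error: 'outDir' is required")
    if (is.null(config$input) && is.null(config$spec))
        stop("configuration error: one of 'input' or 'spec' is required")
    m <- if (is.null(config$m)) 5L else as.integer(config$m)
    nOuter <- if (is.null(config$nOuter)) 16L else
        as.integer(config$nOuter)
    nInner <- if (is.null(config$nInner)) 16L else
        as.integer(config$nInner)
    hf <- if (is.null(config$holdoutFraction)) 0.10 else
        as.numeric(config$holdoutFraction)
    seed <- as.integer(config$seed)
    stage <- function(name, expr)
        tryCatch(expr, error = function(e)
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE))
    seeds <- spawnSeeds(seed, 4L)
    x <- stage("input", {
        if (!is.null(config$input)) readActivityDataset(config$input)
        else sampleManifolds(readManifoldSpec(config$spec),
                             seed = seeds[1])
    })
    if (!is.null(config$subspaceDim))
        x <- stage("subspace",
                   randomSubspace(x, as.integer(config$subspaceDim),
                                  seeds[2]))
    if (!is.null(config$projectionDim) &&
        as.integer(config$projectionDim) < nUnits(x))
        x <- stage("projection",
                   randomProject(x, as.integer(config$projectionDim),
                                 seeds[3]))
    outDir <- config$outDir
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    grid <- stage("geometry", geometryGrid(x, m))
    paths <- writeGeometryTables(grid, outDir)
    fs <- stage("fewshot",
                fewShotErrorProtocol(x, m, nOuter, nInner, hf,
                                     seed = seeds[4]))
    paths <- c(paths, writeFewShotResult(fs, outDir))
    fit <- tryCatch(fitLogLinearOverlap(grid$pairs, m),
                    error = function(e) {
                        warning("log-linear overlap fit skipped: ",
                                conditionMessage(e))
                        NULL
                    })
    if (!is.null(fit)) {
        fitDf <- data.frame(alpha = fit@alpha, beta = fit@beta,
                            gamma = fit@gamma, r_squared = fit@rSquared,
                            r_squared_signal_only =
                                fit@rSquaredSignalOnly,
                            n_points = fit@nPoints,
                            n_excluded = fit@nExcluded, m = fit@m)
        fp <- file.path(outDir, "loglinear_fit.tsv")
        data.table::fwrite(fitDf, fp, sep = "\t", quote = FALSE)
        paths <- c(paths, fp)
    }
    sym <- stage("symmetry", tryCatch(symmetryScore(errorMean(fs)),
                                      error = function(e) NA_real_))
    dist <- NULL
    if (!is.null(config$distanceGraph)) {
        dm <- stage("distances",
                    hierarchyPathDistance(config$distanceGraph,
                                          conceptNames(x)))
        dist <- stage("distance-curve", accuracyVsDistance(fs, dm))
        dp <- file.path(outDir, "distance_curve.tsv")
        data.table::fwrite(dist$curve, dp, sep = "\t", quote = FALSE)
        paths <- c(paths, dp)
    }
    manifest <- list(
        config = config,
        package = "conceptManifolds",
        package_version =
            as.character(utils::packageVersion("conceptManifolds")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        seed = seed,
        symmetry_score = sym,
        outputs = basename(paths))
    mp <- file.path(outDir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(list(dataset = x, geometry = grid, fewshot = fs,
                   fit = fit, symmetry = sym, distance = dist,
                   paths = c(paths, mp)))
}
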