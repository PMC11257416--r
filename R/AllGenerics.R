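#' Accessors for the censoredCP classes
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("tensorValues", function(x) standardGeneric("tensorValues"))

#' @rdname accessors
#' @export
setGeneric("observedMask", function(x) standardGeneric("observedMask"))

#' @rdname accessors
#' @export
setGeneric("factorMatrices", function(x) standardGeneric("factorMatrices"))

#' @rdname accessors
#' @export
setGeneric("cpRank", function(x) standardGeneric("cpRank"))

#' @rdname accessors
#' @export
setGeneric("heldOutIndices", function(x) standardGeneric("heldOutIndices"))

#' @rdname accessors
#' @export
setGeneric("fitTrace", function(x) standardGeneric("fitTrace"))

#' @rdname accessors
#' @export
setGeneric("imputeTrace", function(x) standardGeneric("imputeTrace"))

#' @rdname accessors
#' @export
setGeneric("timeTrace", function(x) standardGeneric("timeTrace"))

#' @rdname accessors
#' @export
setGeneric("hasConverged", function(x) standardGeneric("hasConverged"))

#' @rdname accessors
#' @export
setGeneric("iterationCount", function(x) standardGeneric("iterationCount"))

#' @rdname accessors
#' @export
setGeneric("trueFactors", function(x) standardGeneric("trueFactors"))

#' @rdname accessors
#' @export
setGeneric("benchmarkRecords", function(x) standardGeneric("benchmarkRecords"))

#' @rdname accessors
#' @export
setGeneric("benchmarkSummaries",
    function(x) standardGeneric("benchmarkSummaries"))

#' @rdname accessors
#' @export
setMethod("tensorValues", "MaskedTensor", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("observedMask", "MaskedTensor", function(x) x@observed)

#' @rdname accessors
#' @export
setMethod("dim", "MaskedTensor", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("factorMatrices", "CPFactors", function(x) x@factors)

#' @rdname accessors
#' @export
setMethod("cpRank", "CPFactors", function(x) x@rank)

#' @rdname accessors
#' @export
setMethod("factorMatrices", "FitResult", function(x) x@factors@factors)

#' @rdname accessors
#' @export
setMethod("cpRank", "FitResult", function(x) x@factors@rank)

#' @rdname accessors
#' @export
setMethod("heldOutIndices", "HeldOutMask", function(x) x@indices)

#' @rdname accessors
#' @export
setMethod("fitTrace", "FitResult", function(x) x@fitTrace)

#' @rdname accessors
#' @export
setMethod("imputeTrace", "FitResult", function(x) x@imputeTrace)

#' @rdname accessors
#' @export
setMethod("timeTrace", "FitResult", function(x) x@timeTrace)

#' @rdname accessors
#' @export
setMethod("hasConverged", "FitResult", function(x) x@converged)

#' @rdname accessors
#' @export
setMethod("iterationCount", "FitResult", function(x) x@iterations)

#' @rdname accessors
#' @export
setMethod("trueFactors", "SyntheticInstance", function(x) x@trueFactors)

#' @rdname accessors
#' @export
setMethod("tensorValues", "SyntheticInstance", function(x) x@tensor@values)

#' @rdname accessors
#' @export
setMethod("benchmarkRecords", "BenchmarkSummary", function(x) x@records)

#' @rdname accessors
#' @export
setMethod("benchmarkSummaries", "BenchmarkSummary", function(x) x@summaries)

setMethod("show", "MaskedTensor", function(object) {
    d <- dim(object@values)
    nObs <- sum(object@observed)
    cat(sprintf("MaskedTensor %s | %d/%d observed (%.1f%% missing)\n",
        paste(d, collapse = " x "), nObs, length(object@values),
        100 * (1 - nObs / length(object@values))))
})

setMethod("show", "CPFactors", function(object) {
    d <- vapply(object@factors, nrow, integer(1))
    cat(sprintf("CPFactors rank %d over modes %s\n",
        object@rank, paste(d, collapse = " x ")))
})

setMethod("show", "HeldOutMask", function(object) {
    cat(sprintf("HeldOutMask: %d %s-wise coordinates (fraction %.3g, seed %d)%s\n",
        nrow(object@indices), object@style, object@fraction, object@seed,
        if (object@style == "chord") {
            sprintf(", chords along mode %d", object@chordMode)
        } else ""))
})

setMethod("show", "FitResult", function(object) {
    cat(sprintf("FitResult [%s] rank %d | %d iterations | converged: %s\n",
        object@method, object@factors@rank, object@iterations,
        object@converged))
    if (length(object@fitTrace)) {
        cat(sprintf("  final fitting error: %.6g\n",
            object@fitTrace[length(object@fitTrace)]))
    }
    if (length(object@imputeTrace)) {
        cat(sprintf("  final imputation error: %.6g\n",
            object@imputeTrace[length(object@imputeTrace)]))
    }
})

setMethod("show", "SyntheticInstance", function(object) {
    cat(sprintf(
        "SyntheticInstance rank %d, noise sd %.3g, missing fraction %.3g\n",
        object@trueFactors@rank, object@noiseSD, object@missingFraction))
    show(object@tensor)
})

setMethod("show", "BenchmarkSummary", function(object) {
    cat(sprintf("BenchmarkSummary: %d records (%s)\n",
        nrow(object@records),
        paste(unique(object@records$method), collapse = ", ")))
    if (length(object@bestRank)) {
        cat("  best imputed rank:",
            paste(names(object@bestRank), object@bestRank,
                sep = "=", collapse = ", "), "\n")
    }
})
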