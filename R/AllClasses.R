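#' @import methods
NULL

#' MaskedTensor: a dense N-mode tensor with an observation mask
#'
#' The central data container: a dense real-valued array of at least three
#' modes together with a logical array of the same shape flagging which
#' entries were observed. Missing entries carry \code{NA} in \code{values}
#' and \code{FALSE} in \code{observed}.
#'
#' @slot values N-dimensional numeric array; \code{NA} at unobserved cells.
#' @slot observed logical array of identical shape; \code{TRUE} iff the cell
#'   holds a finite measurement.
#'
#' @examples
#' v <- array(rnorm(24), c(2, 3, 4))
#' v[1, 1, 1] <- NA
#' mt <- MaskedTensor(v)
#' dim(mt)
#' sum(observedMask(mt))
#' @export
setClass("MaskedTensor",
    representation(values = "array", observed = "array"))

setValidity("MaskedTensor", function(object) {
    dv <- dim(object@values)
    do <- dim(object@observed)
    if (!identical(dv, do)) {
        return("values and observed must have identical shape")
    }
    if (length(dv) < 3L) {
        return("a tensor needs at least 3 modes")
    }
    if (!is.logical(object@observed)) {
        return("observed must be a logical array")
    }
    obs <- object@observed
    if (anyNA(obs)) {
        return("observed may not contain NA")
    }
    if (!any(obs)) {
        return("at least one observed entry is required")
    }
    vo <- object@values[obs]
    if (!all(is.finite(vo))) {
        return("observed entries must be finite")
    }
    if (any(!is.na(object@values[!obs]))) {
        return("unobserved entries must carry the NA sentinel")
    }
    TRUE
})

#' @describeIn MaskedTensor Constructor. When \code{observed} is omitted it
#'   is taken as \code{!is.na(values)}.
#' @param values numeric array with at least 3 modes.
#' @param observed optional logical array marking observed cells.
#' @export
MaskedTensor <- function(values, observed = !is.na(values)) {
    values <- as.array(values)
    storage.mode(values) <- "double"
    observed <- as.array(observed)
    values[!observed] <- NA_real_
    new("MaskedTensor", values = values, observed = observed)
}

#' CPFactors: per-mode factor matrices of a CP model
#'
#' An ordered list of N factor matrices sharing a common column count R, the
#' number of components. Mode n's matrix has one row per index along mode n.
#'
#' @slot factors list of numeric matrices, all with \code{rank} columns.
#' @slot rank integer, the number of components R.
#'
#' @examples
#' f <- CPFactors(list(matrix(1, 4, 2), matrix(1, 3, 2), matrix(1, 2, 2)))
#' cpRank(f)
#' dim(cpReconstruct(f))
#' @export
setClass("CPFactors",
    representation(factors = "list", rank = "integer"))

setValidity("CPFactors", function(object) {
    fl <- object@factors
    if (length(fl) < 1L) {
        return("at least one factor matrix is required")
    }
    if (!all(vapply(fl, is.matrix, logical(1)))) {
        return("factors must be matrices")
    }
    ncols <- vapply(fl, ncol, integer(1))
    if (length(unique(ncols)) != 1L) {
        return("all factor matrices must share the same column count")
    }
    if (ncols[1L] != object@rank) {
        return("rank slot must equal the shared column count")
    }
    if (object@rank < 1L) {
        return("rank must be >= 1")
    }
    if (!all(vapply(fl, function(m) all(is.finite(m)), logical(1)))) {
        return("factor entries must all be finite")
    }
    TRUE
})

#' @describeIn CPFactors Constructor from a list of matrices.
#' @param factors list of numeric matrices sharing a column count.
#' @export
CPFactors <- function(factors) {
    factors <- lapply(factors, function(m) {
        m <- as.matrix(m)
        storage.mode(m) <- "double"
        m
    })
    new("CPFactors", factors = factors, rank = as.integer(ncol(factors[[1L]])))
}

#' HeldOutMask: artificially hidden coordinates for imputation testing
#'
#' A set of tensor coordinates that were observed in the parent tensor but
#' are withheld from fitting so the solver's reconstruction there can be
#' scored as imputation error. Built by \code{\link{maskEntries}} or
#' \code{\link{maskChords}}; always disjoint from pre-existing missingness.
#'
#' @slot indices integer matrix, one row per held-out coordinate (1-based).
#' @slot style \code{"entry"} or \code{"chord"}.
#' @slot chordMode mode along which chords run (\code{NA} for entry style).
#' @slot fraction requested fraction of observed entries.
#' @slot seed integer seed that generated the mask.
#' @export
setClass("HeldOutMask",
    representation(indices = "matrix", style = "character",
        chordMode = "integer", fraction = "numeric", seed = "integer"))

setValidity("HeldOutMask", function(object) {
    if (!object@style %in% c("entry", "chord")) {
        return("style must be 'entry' or 'chord'")
    }
    if (object@style == "chord" && is.na(object@chordMode)) {
        return("chord masks must record chordMode")
    }
    if (object@fraction < 0 || object@fraction >= 1) {
        return("fraction must lie in [0, 1)")
    }
    idx <- object@indices
    if (nrow(idx) > 0L) {
        if (any(idx < 1L) || any(idx != floor(idx))) {
            return("indices must be positive integers")
        }
        if (anyDuplicated(as.data.frame(idx))) {
            return("indices contain duplicate coordinates")
        }
    }
    TRUE
})

#' SolverConfig: shared solver settings
#'
#' @slot tolerance relative change in fitting error below which a solver
#'   stops (all solvers share this rule; default \code{1e-6}).
#' @slot maxSweeps sweep cap for the alternating least squares solvers.
#' @slot doMaxIter iteration cap for the direct optimizer. The strict
#'   historical setting is 50; the default is deliberately higher because the
#'   gradient route needs far more iterations to converge than the
#'   least-squares sweeps.
#' @slot recordTrace record per-iteration error/time traces.
#'
#' @param tolerance,maxSweeps,doMaxIter,recordTrace see slot descriptions.
#' @examples
#' SolverConfig(tolerance = 1e-8, maxSweeps = 200L)
#' @export
setClass("SolverConfig",
    representation(tolerance = "numeric", maxSweeps = "integer",
        doMaxIter = "integer", recordTrace = "logical"))

setValidity("SolverConfig", function(object) {
    if (length(object@tolerance) != 1L || object@tolerance <= 0) {
        return("tolerance must be a single positive number")
    }
    if (object@maxSweeps < 1L) {
        return("maxSweeps must be >= 1")
    }
    if (object@doMaxIter < 1L) {
        return("doMaxIter must be >= 1")
    }
    TRUE
})

#' @describeIn SolverConfig Constructor with protocol defaults.
#' @export
SolverConfig <- function(tolerance = 1e-6, maxSweeps = 500L,
                         doMaxIter = 500L, recordTrace = TRUE) {
    new("SolverConfig", tolerance = as.numeric(tolerance),
        maxSweeps = as.integer(maxSweeps), doMaxIter = as.integer(doMaxIter),
        recordTrace = as.logical(recordTrace))
}

#' FitResult: a solved CP model plus its convergence history
#'
#' @slot method solver name: \code{"cals"}, \code{"als-si"} or \code{"do"}.
#' @slot factors the solved \code{\linkS4class{CPFactors}}.
#' @slot fitTrace fitting error (observed, non-held-out entries) per
#'   iteration.
#' @slot imputeTrace imputation error (held-out entries) per iteration;
#'   length 0 when no held-out mask was supplied.
#' @slot timeTrace elapsed seconds at the end of each iteration.
#' @slot converged whether the stopping tolerance was reached before the
#'   iteration cap.
#' @slot iterations iteration count (sweeps for the ALS solvers, gradient
#'   evaluations for the direct optimizer).
#' @export
setClass("FitResult",
    representation(method = "character", factors = "CPFactors",
        fitTrace = "numeric", imputeTrace = "numeric", timeTrace = "numeric",
        converged = "logical", iterations = "integer"))

setValidity("FitResult", function(object) {
    if (length(object@imputeTrace) &&
        length(object@imputeTrace) != length(object@fitTrace)) {
        return("imputeTrace must be empty or match fitTrace length")
    }
    if (length(object@timeTrace) != length(object@fitTrace)) {
        return("timeTrace must match fitTrace length")
    }
    if (any(object@fitTrace < 0) || any(object@imputeTrace < 0)) {
        return("errors must be nonnegative")
    }
    TRUE
})

#' SyntheticInstance: a generated ground-truth low-rank tensor
#'
#' @slot tensor the generated \code{\linkS4class{MaskedTensor}}.
#' @slot trueFactors the factors the tensor was built from.
#' @slot noiseSD standard deviation of the additive Gaussian noise.
#' @slot missingFraction fraction of cells made missing before any held-out
#'   masking.
#' @slot seed generation seed.
#' @export
setClass("SyntheticInstance",
    representation(tensor = "MaskedTensor", trueFactors = "CPFactors",
        noiseSD = "numeric", missingFraction = "numeric", seed = "integer"))

#' BenchmarkSummary: records and summaries of an imputation benchmark
#'
#' @slot records one row per (method, rank, replicate) with final errors,
#'   iteration count, wall time and convergence flag.
#' @slot summaries per (method, rank) medians and quartiles of the final
#'   fitting and imputation errors.
#' @slot bestRank named integer vector: per method, the rank with the lowest
#'   median imputation error (fitting error when nothing was held out).
#' @export
setClass("BenchmarkSummary",
    representation(records = "data.frame", summaries = "data.frame",
        bestRank = "integer"))
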