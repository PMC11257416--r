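#' Fill unusable entries from a reconstruction
#'
#' Builds the complete tensor used by single-imputation ALS: cells flagged
#' usable by \code{effectiveMask} keep their original values, every other
#' cell (pre-existing missing or held out) takes the value of the current
#' reconstruction.
#'
#' @param tensor a \code{\linkS4class{MaskedTensor}}.
#' @param effectiveMask logical array marking usable cells.
#' @param reconstruction dense array of the same shape.
#' @return a dense numeric array with no missing values.
#' @export
imputeFill <- function(tensor, effectiveMask, reconstruction) {
    stopifnot(is(tensor, "MaskedTensor"))
    dims <- dim(tensor)
    if (!identical(dim(effectiveMask), dims) ||
        !identical(dim(reconstruction), dims)) {
        stop("effectiveMask and reconstruction must match the tensor shape")
    }
    out <- tensor@values
    out[!effectiveMask] <- reconstruction[!effectiveMask]
    out
}

#' Plain ALS update of one mode on a complete tensor
#'
#' The classical alternating least squares step: the mode-n factor matrix is
#' the exact least squares minimizer of the complete (imputed) tensor's
#' mode-n unfolding against the Khatri-Rao chain of the other factors.
#'
#' @param completeValues dense numeric array with no missing entries.
#' @param factors current \code{\linkS4class{CPFactors}}.
#' @param mode mode to update.
#' @return the updated factor matrix.
#' @export
alsUpdateMode <- function(completeValues, factors, mode) {
    stopifnot(is(factors, "CPFactors"))
    if (anyNA(completeValues)) {
        stop("completeValues must contain no missing entries")
    }
    alsUpdateModeInternal(completeValues, factors@factors, as.integer(mode))
}

# Internal: same update from a raw factor list. Routed through the same
# pseudoinverse as the censored path so that on complete data the two
# solvers produce bitwise-identical iterates.
alsUpdateModeInternal <- function(completeValues, factorList, mode) {
    Z <- designMatrix(factorList, mode)
    t(lstsqPinv(Z, t(unfoldTensor(completeValues, mode))))
}

#' Fit a CP model by ALS with single imputation
#'
#' An expectation-maximization style loop: missing (and held-out) entries
#' are first filled from the reconstruction of the seed-initialized factors;
#' each iteration then runs one complete-data ALS sweep over all modes on
#' the filled tensor and refills from the new reconstruction. Fitting and
#' imputation errors are always computed on the ORIGINAL observed and
#' held-out entries, never on filled values. The stopping rule and error
#' definitions are identical to \code{\link{fitCALS}}, and on a tensor with
#' no missing and no held-out entries the two solvers produce the same
#' iterates.
#'
#' Because refilled cells have zero residual, the complete-data loss
#' minimized by each sweep upper-bounds the observed-entry loss, so the
#' observed fitting error is non-increasing across iterations.
#'
#' @inheritParams fitCALS
#' @return a \code{\linkS4class{FitResult}}.
#' @export
fitALSSI <- function(tensor, rank, seed, config = SolverConfig(),
                     heldout = NULL) {
    stopifnot(is(tensor, "MaskedTensor"))
    dims <- dim(tensor)
    vals <- tensor@values
    sweepFun <- function(state, eff) {
        filled <- vals
        filled[!eff] <- state$recon[!eff]
        for (n in seq_along(dims)) {
            state$facs[[n]] <- alsUpdateModeInternal(filled, state$facs, n)
        }
        state$recon <- cpReconstructList(state$facs, dims)
        state
    }
    alsFitLoop(tensor, as.integer(rank), seed, config, heldout, sweepFun,
        "als-si")
}
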