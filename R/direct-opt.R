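#' Pack CP factors into a flat parameter vector
#'
#' The direct optimizer treats every factor entry as a free parameter. The
#' layout concatenates the column-major vectorization of each mode's matrix
#' in mode order; \code{\link{unpackFactors}} inverts it exactly.
#'
#' @param factors a \code{\linkS4class{CPFactors}} object.
#' @return numeric vector of length \code{sum(dims) * rank}.
#' @export
packFactors <- function(factors) {
    stopifnot(is(factors, "CPFactors"))
    unlist(lapply(factors@factors, as.numeric), use.names = FALSE)
}

#' Unpack a flat parameter vector into CP factors
#'
#' @param par numeric vector laid out as by \code{\link{packFactors}}.
#' @param dims integer vector of mode lengths.
#' @param rank number of components.
#' @return a \code{\linkS4class{CPFactors}} object.
#' @export
unpackFactors <- function(par, dims, rank) {
    dims <- as.integer(dims)
    rank <- as.integer(rank)
    if (length(par) != sum(dims) * rank) {
        stop("parameter vector length inconsistent with dims and rank")
    }
    ends <- cumsum(dims * rank)
    starts <- c(1L, head(ends, -1L) + 1L)
    CPFactors(lapply(seq_along(dims), function(n) {
        matrix(par[starts[n]:ends[n]], dims[n], rank)
    }))
}

# Internal loss/gradient cores working on raw pieces. `values0` carries 0 at
# every cell excluded by `eff`, so plain dense algebra applies.
maskedLossCore <- function(factorList, values0, eff, dims) {
    recon <- cpReconstructList(factorList, dims)
    resid <- values0 - recon
    resid[!eff] <- 0
    sum(resid * resid)
}

maskedGradCore <- function(factorList, values0, eff, dims) {
    recon <- cpReconstructList(factorList, dims)
    resid <- values0 - recon
    resid[!eff] <- 0
    unlist(lapply(seq_along(dims), function(n) {
        as.numeric(-2 * (unfoldTensor(resid, n) %*%
            designMatrix(factorList, n)))
    }), use.names = FALSE)
}

#' Masked CP reconstruction loss
#'
#' The squared error between tensor and reconstruction summed ONLY over
#' cells flagged by \code{effectiveMask}; excluded cells (missing or held
#' out) contribute exactly zero, so they exert no pull on the optimizer.
#'
#' @param par flat parameter vector (see \code{\link{packFactors}}).
#' @param tensor a \code{\linkS4class{MaskedTensor}}.
#' @param rank number of components encoded in \code{par}.
#' @param effectiveMask logical array of usable cells; defaults to the
#'   observation mask.
#' @return a single nonnegative number.
#' @export
maskedLoss <- function(par, tensor, rank,
                       effectiveMask = observedMask(tensor)) {
    stopifnot(is(tensor, "MaskedTensor"))
    dims <- dim(tensor)
    eff <- effectiveMask & tensor@observed
    values0 <- tensor@values
    values0[!eff] <- 0
    maskedLossCore(unpackFactors(par, dims, rank)@factors, values0, eff, dims)
}

#' Analytic gradient of the masked loss
#'
#' For mode n the gradient block is \code{-2 * (M_(n) * (T_(n) - F_n W')) W}
#' with W the descending Khatri-Rao chain of the other factors and M_(n) the
#' unfolded effective mask; blocks are flattened in the
#' \code{\link{packFactors}} layout. Matches central finite differences of
#' \code{\link{maskedLoss}}.
#'
#' @inheritParams maskedLoss
#' @return numeric vector the same length as \code{par}.
#' @export
maskedLossGradient <- function(par, tensor, rank,
                               effectiveMask = observedMask(tensor)) {
    stopifnot(is(tensor, "MaskedTensor"))
    dims <- dim(tensor)
    eff <- effectiveMask & tensor@observed
    values0 <- tensor@values
    values0[!eff] <- 0
    maskedGradCore(unpackFactors(par, dims, rank)@factors, values0, eff, dims)
}

#' Fit a CP model by direct gradient-based optimization
#'
#' Minimizes the masked reconstruction loss over all factor matrices
#' simultaneously with L-BFGS-B, starting from the packed seed-initialized
#' factors. The function-change stopping tolerance is the shared solver
#' tolerance (\code{factr = tolerance / .Machine$double.eps}); the iteration
#' cap is \code{doMaxIter} in the \code{\link{SolverConfig}} (set it to 50
#' for the strict historical budget). Error and time traces are recorded at
#' every gradient evaluation, and \code{iterationCount} reports the number
#' of gradient evaluations. Optimizer failure is surfaced through the
#' convergence flag, never silently.
#'
#' @inheritParams fitCALS
#' @param lower,upper optional box constraints on every packed parameter
#'   (unbounded by default).
#' @return a \code{\linkS4class{FitResult}}.
#' @export
fitDO <- function(tensor, rank, seed, config = SolverConfig(),
                  heldout = NULL, lower = -Inf, upper = Inf) {
    stopifnot(is(tensor, "MaskedTensor"))
    rank <- as.integer(rank)
    if (rank < 1L) {
        stop("rank must be >= 1")
    }
    dims <- dim(tensor)
    held <- heldOutArray(heldout, dims)
    if (!is.null(heldout)) {
        checkHeldOutAgainst(tensor, heldout)
    }
    eff <- tensor@observed & !held
    if (!any(eff)) {
        stop("tensor has no usable entries after masking")
    }
    impCoords <- if (!is.null(heldout) && nrow(heldout@indices) > 0L) {
        heldout@indices
    }
    values0 <- tensor@values
    values0[!eff] <- 0
    par0 <- packFactors(initializeFactors(dims, rank, seed))

    trace <- new.env(parent = emptyenv())
    trace$fit <- trace$imp <- trace$time <- numeric(0)
    t0 <- proc.time()[["elapsed"]]
    fn <- function(par) {
        maskedLossCore(unpackFactors(par, dims, rank)@factors,
            values0, eff, dims)
    }
    gr <- function(par) {
        fl <- unpackFactors(par, dims, rank)@factors
        recon <- cpReconstructList(fl, dims)
        trace$fit <- c(trace$fit,
            relSubsetError(tensor@values, recon, eff))
        if (!is.null(impCoords)) {
            trace$imp <- c(trace$imp,
                relCoordError(tensor@values, recon, impCoords))
        }
        trace$time <- c(trace$time, proc.time()[["elapsed"]] - t0)
        resid <- values0 - recon
        resid[!eff] <- 0
        unlist(lapply(seq_along(dims), function(n) {
            as.numeric(-2 * (unfoldTensor(resid, n) %*%
                designMatrix(fl, n)))
        }), use.names = FALSE)
    }
    res <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
        lower = lower, upper = upper,
        control = list(maxit = config@doMaxIter,
            factr = config@tolerance / .Machine$double.eps, pgtol = 0))
    fitTr <- trace$fit
    impTr <- trace$imp
    timeTr <- trace$time
    if (length(fitTr) == 0L) {
        # optimizer never evaluated the gradient (already at a minimum)
        recon <- cpReconstructList(unpackFactors(res$par, dims, rank)@factors,
            dims)
        fitTr <- relSubsetError(tensor@values, recon, eff)
        if (!is.null(impCoords)) {
            impTr <- relCoordError(tensor@values, recon, impCoords)
        }
        timeTr <- proc.time()[["elapsed"]] - t0
    }
    if (!config@recordTrace) {
        keep <- length(fitTr)
        fitTr <- fitTr[keep]
        if (length(impTr)) impTr <- impTr[keep]
        timeTr <- timeTr[keep]
    }
    new("FitResult", method = "do",
        factors = unpackFactors(res$par, dims, rank),
        fitTrace = fitTr, imputeTrace = impTr, timeTrace = timeTr,
        converged = identical(res$convergence, 0L),
        iterations = as.integer(unname(res$counts["gradient"])))
}
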