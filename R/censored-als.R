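#' Group matrix rows by shared missing-value pattern
#'
#' Rows of a censored least squares target that miss the same columns can be
#' solved in one batched call, because they share the same observed
#' submatrix of the design. This returns the partition of row indices by
#' identical mask rows.
#'
#' @param rowMask logical matrix; \code{TRUE} where the target is observed.
#' @return a list with one element per distinct pattern, each a list with
#'   \code{pattern} (logical vector) and \code{rows} (integer row indices).
#' @examples
#' groupRowsByPattern(rbind(c(TRUE, TRUE), c(TRUE, TRUE), c(TRUE, FALSE)))
#' @export
groupRowsByPattern <- function(rowMask) {
    rowMask <- as.matrix(rowMask)
    keys <- apply(rowMask, 1L, function(r) rawToChar(as.raw(44L + r)))
    if (nrow(rowMask) == 0L) {
        return(list())
    }
    groups <- split(seq_len(nrow(rowMask)), factor(keys, levels = unique(keys)))
    lapply(groups, function(rows) {
        list(pattern = rowMask[rows[1L], ], rows = rows)
    })
}

#' Censored linear least squares, batched by missingness pattern
#'
#' Solves \code{min_A || M * (T - A W) ||_F^2} row by row: row i of the
#' result is the minimum-norm least squares solution fitted ONLY on the
#' columns where row i of the target is observed, ignoring missing columns
#' entirely. Rows sharing a missingness pattern are solved in a single
#' batched pseudoinverse call; batching does not change the solution.
#'
#' A row with no observed columns is degenerate: it is set to all zeros (the
#' minimum-norm solution of an empty system) with a warning.
#'
#' @param W complete design matrix, R x P.
#' @param targets I x P matrix; cells at \code{!rowMask} may be \code{NA}.
#' @param rowMask logical I x P matrix, \code{TRUE} where \code{targets} is
#'   observed. Defaults to \code{!is.na(targets)}.
#' @return the solved I x R coefficient matrix.
#' @examples
#' W <- rbind(c(1, 0, 1), c(0, 1, 1))
#' censoredLstsq(W, rbind(c(2, 3, NA)))
#' @export
censoredLstsq <- function(W, targets, rowMask = !is.na(targets)) {
    W <- as.matrix(W)
    targets <- as.matrix(targets)
    rowMask <- as.matrix(rowMask)
    if (!all(is.finite(W))) {
        stop("design matrix W must be complete and finite")
    }
    if (!identical(dim(targets), dim(rowMask))) {
        stop("targets and rowMask must have identical shape")
    }
    if (ncol(targets) != ncol(W)) {
        stop("targets must have one column per design column")
    }
    R <- nrow(W)
    A <- matrix(0, nrow(targets), R)
    for (g in groupRowsByPattern(rowMask)) {
        alpha <- which(g$pattern)
        if (length(alpha) == 0L) {
            warning(sprintf(
                "%d row(s) with zero observed entries set to zero",
                length(g$rows)))
            next
        }
        # min-norm LS of Z x ~ t over observed columns, Z = t(W[, alpha])
        Z <- t(W[, alpha, drop = FALSE])
        X <- lstsqPinv(Z, t(targets[g$rows, alpha, drop = FALSE]))
        A[g$rows, ] <- t(X)
    }
    A
}

# Internal: censored update of one mode's factor matrix from raw pieces.
calsUpdateModeInternal <- function(values, factorList, mode, effMask) {
    Z <- designMatrix(factorList, mode)
    censoredLstsq(t(Z), unfoldTensor(values, mode),
        unfoldTensor(effMask, mode))
}

#' Censored ALS update of one mode
#'
#' Replaces the plain least squares step of an ALS sweep with censored least
#' squares: the mode-n factor matrix is re-solved against the mode-n
#' unfolding using only entries flagged usable by \code{effectiveMask}
#' (observed and not held out). Given the other modes, every row is an exact
#' least squares minimizer, so the masked fitting loss cannot increase.
#'
#' @param tensor a \code{\linkS4class{MaskedTensor}}.
#' @param factors current \code{\linkS4class{CPFactors}}.
#' @param mode mode to update, in \code{1..N}.
#' @param effectiveMask logical array marking entries usable for fitting;
#'   defaults to the tensor's observation mask.
#' @return the updated factor matrix for \code{mode}.
#' @export
calsUpdateMode <- function(tensor, factors, mode,
                           effectiveMask = observedMask(tensor)) {
    stopifnot(is(tensor, "MaskedTensor"), is(factors, "CPFactors"))
    calsUpdateModeInternal(tensor@values, factors@factors, as.integer(mode),
        effectiveMask)
}

# Shared post-sweep bookkeeping for the two ALS-type solvers: error traces
# and the relative-change stopping rule on the fitting error.
alsFitLoop <- function(tensor, rank, seed, config, heldout, sweepFun,
                       method) {
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
    facs <- initializeFactors(dims, rank, seed)@factors
    state <- list(facs = facs,
        recon = cpReconstructList(facs, dims))
    fitTr <- impTr <- timeTr <- numeric(0)
    prevErr <- NA_real_
    convergedFlag <- FALSE
    iters <- 0L
    t0 <- proc.time()[["elapsed"]]
    for (s in seq_len(config@maxSweeps)) {
        state <- sweepFun(state, eff)
        iters <- s
        fitErr <- relSubsetError(tensor@values, state$recon, eff)
        fitTr <- c(fitTr, fitErr)
        if (!is.null(impCoords)) {
            impTr <- c(impTr,
                relCoordError(tensor@values, state$recon, impCoords))
        }
        timeTr <- c(timeTr, proc.time()[["elapsed"]] - t0)
        # exact fits bottom out at machine precision where the relative
        # change is pure floating-point noise; treat them as converged
        if (fitErr <= .Machine$double.eps ||
            (!is.na(prevErr) &&
                relChange(prevErr, fitErr) < config@tolerance)) {
            convergedFlag <- TRUE
            break
        }
        prevErr <- fitErr
    }
    if (!config@recordTrace) {
        keep <- length(fitTr)
        fitTr <- fitTr[keep]
        if (length(impTr)) impTr <- impTr[keep]
        timeTr <- timeTr[keep]
    }
    new("FitResult", method = method, factors = CPFactors(state$facs),
        fitTrace = fitTr, imputeTrace = impTr, timeTrace = timeTr,
        converged = convergedFlag, iterations = iters)
}

#' Fit a CP model by censored alternating least squares
#'
#' Starting from seed-initialized factors, sweeps the modes in ascending
#' order, re-solving each factor matrix by \code{\link{censoredLstsq}} on the
#' entries that are observed and not held out. After every full sweep the
#' fitting error (normalized squared residual on the usable entries) and,
#' when a held-out mask is supplied, the imputation error on the held-out
#' entries are recorded. Iteration stops when the relative change in fitting
#' error drops below \code{tolerance} or the sweep cap is reached.
#'
#' @param tensor a \code{\linkS4class{MaskedTensor}}.
#' @param rank number of components.
#' @param seed initialization seed (shared across solvers for comparison).
#' @param config a \code{\link{SolverConfig}}.
#' @param heldout optional \code{\linkS4class{HeldOutMask}} of artificially
#'   hidden entries scored as imputation error.
#' @return a \code{\linkS4class{FitResult}}.
#' @examples
#' inst <- simulateCPTensor(c(10, 8, 6), rank = 2, seed = 3)
#' fit <- fitCALS(inst@tensor, rank = 2, seed = 7)
#' fit
#' @export
fitCALS <- function(tensor, rank, seed, config = SolverConfig(),
                    heldout = NULL) {
    stopifnot(is(tensor, "MaskedTensor"))
    dims <- dim(tensor)
    vals <- tensor@values
    sweepFun <- function(state, eff) {
        for (n in seq_along(dims)) {
            state$facs[[n]] <- calsUpdateModeInternal(vals, state$facs, n, eff)
        }
        state$recon <- cpReconstructList(state$facs, dims)
        state
    }
    alsFitLoop(tensor, as.integer(rank), seed, config, heldout, sweepFun,
        "cals")
}
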