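#' Generate a ground-truth low-rank tensor with noise and missingness
#'
#' Draws factor matrices with i.i.d. standard normal entries, reconstructs
#' the rank-\code{rank} tensor, adds i.i.d. Gaussian noise of standard
#' deviation \code{noiseSD}, and finally removes a fraction of cells as
#' pre-existing missingness, either entrywise or chordwise (reusing the
#' masking machinery). At \code{noiseSD = 0} the observed entries equal the
#' CP reconstruction of the true factors exactly. Deterministic given
#' \code{seed}.
#'
#' The optional \code{collinearity} parameter (0-1) mixes every component
#' with a shared random direction per mode, producing the ill-conditioned,
#' correlated-factor instances useful for stress testing; the default 0
#' keeps components independent.
#'
#' @param dims integer vector of mode lengths (at least 3 modes).
#' @param rank number of ground-truth components.
#' @param noiseSD standard deviation of the additive Gaussian noise, in the
#'   units of the tensor values (signal entries have sd about
#'   \code{sqrt(rank)} under the standard normal factors).
#' @param missingFraction fraction of cells made missing, in \code{[0, 1)}.
#' @param missingStyle \code{"entry"} or \code{"chord"}.
#' @param chordMode chord direction when \code{missingStyle = "chord"}.
#' @param seed integer generation seed.
#' @param collinearity component collinearity level in \code{[0, 1)}.
#' @return a \code{\linkS4class{SyntheticInstance}}.
#' @examples
#' inst <- simulateCPTensor(c(20, 15, 10), rank = 3, noiseSD = 0.05,
#'                          missingFraction = 0.2, seed = 42)
#' inst
#' @export
simulateCPTensor <- function(dims, rank, noiseSD = 0, missingFraction = 0,
                             missingStyle = c("entry", "chord"),
                             chordMode = 1L, seed, collinearity = 0) {
    missingStyle <- match.arg(missingStyle)
    dims <- as.integer(dims)
    rank <- as.integer(rank)
    if (rank < 1L) {
        stop("rank must be >= 1")
    }
    if (missingFraction < 0 || missingFraction >= 1) {
        stop("missingFraction must lie in [0, 1)")
    }
    if (collinearity < 0 || collinearity >= 1) {
        stop("collinearity must lie in [0, 1)")
    }
    pieces <- withSeed(seed, {
        fl <- lapply(dims, function(d) {
            F <- matrix(stats::rnorm(d * rank), d, rank)
            if (collinearity > 0) {
                shared <- stats::rnorm(d)
                F <- sqrt(1 - collinearity^2) * F +
                    collinearity * matrix(shared, d, rank)
            }
            F
        })
        noise <- if (noiseSD > 0) {
            array(stats::rnorm(prod(dims), sd = noiseSD), dims)
        } else {
            array(0, dims)
        }
        maskSeed <- sample.int(.Machine$integer.max - 1L, 1L)
        list(fl = fl, noise = noise, maskSeed = maskSeed)
    })
    truth <- CPFactors(pieces$fl)
    values <- cpReconstruct(truth) + pieces$noise
    tensor <- MaskedTensor(values)
    if (missingFraction > 0) {
        pre <- if (missingStyle == "entry") {
            maskEntries(tensor, missingFraction, pieces$maskSeed)
        } else {
            maskChords(tensor, missingFraction, chordMode, pieces$maskSeed)
        }
        values[pre@indices] <- NA_real_
        tensor <- MaskedTensor(values)
    }
    new("SyntheticInstance", tensor = tensor, trueFactors = truth,
        noiseSD = as.numeric(noiseSD),
        missingFraction = as.numeric(missingFraction),
        seed = as.integer(seed))
}

#' Factor match score between two CP factor sets
#'
#' Permutation- and scale-invariant recovery metric: for a component
#' matching, each pair's score is the product over modes of the absolute
#' cosine similarity of the matched columns, and the overall score is the
#' mean over components, maximized over component permutations. The
#' permutation is searched exhaustively for ranks up to 6 and greedily
#' above. Invariant to column rescaling with compensating rescaling across
#' modes and to paired sign flips — the inherent indeterminacies of the CP
#' model.
#'
#' @param truth,estimate \code{\linkS4class{CPFactors}} with equal shapes
#'   and ranks.
#' @return a number in \code{[0, 1]}; 1 means perfect recovery.
#' @examples
#' f <- initializeFactors(c(10, 8, 6), 2, seed = 1)
#' factorMatchScore(f, f)
#' @export
factorMatchScore <- function(truth, estimate) {
    stopifnot(is(truth, "CPFactors"), is(estimate, "CPFactors"))
    if (truth@rank != estimate@rank) {
        stop("ranks differ")
    }
    dT <- vapply(truth@factors, nrow, integer(1))
    dE <- vapply(estimate@factors, nrow, integer(1))
    if (!identical(dT, dE)) {
        stop("factor shapes differ")
    }
    R <- truth@rank
    normalize <- function(M) {
        nrm <- sqrt(colSums(M^2))
        nrm[nrm == 0] <- 1
        sweep(M, 2L, nrm, "/")
    }
    # S[r, s] = prod_n |cos(truth col r, estimate col s)|
    S <- Reduce(`*`, lapply(seq_along(dT), function(n) {
        abs(crossprod(normalize(truth@factors[[n]]),
            normalize(estimate@factors[[n]])))
    }))
    if (R <= 6L) {
        best <- 0
        for (p in permutationsOf(R)) {
            best <- max(best, mean(S[cbind(seq_len(R), p)]))
        }
        best
    } else {
        # greedy: repeatedly take the best remaining pair
        tot <- 0
        Sw <- S
        for (i in seq_len(R)) {
            ij <- arrayInd(which.max(Sw), dim(Sw))
            tot <- tot + S[ij]
            Sw[ij[1L], ] <- -Inf
            Sw[, ij[2L]] <- -Inf
        }
        tot / R
    }
}
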