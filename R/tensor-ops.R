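#' Unfold (matricize) a tensor along one mode
#'
#' Rearranges an N-mode array into a matrix whose rows index the chosen mode
#' and whose columns enumerate all combinations of the remaining modes. The
#' remaining modes are kept in ascending order with the lowest-index one
#' varying fastest, so for a 3-mode tensor the mode-1 unfolding concatenates
#' the frontal slices \code{[T[,,1] T[,,2] ...]}.
#'
#' @param x numeric (or logical) array with at least one dimension.
#' @param mode mode to place on the rows, in \code{1..N}.
#' @return a matrix of shape \code{dim(x)[mode]} x \code{prod(dim(x)[-mode])}.
#' @examples
#' x <- array(0:7, c(2, 2, 2))
#' unfoldTensor(x, 1)
#' @seealso \code{\link{foldTensor}} for the inverse.
#' @export
unfoldTensor <- function(x, mode) {
    d <- dim(x)
    if (is.null(d)) {
        stop("x must be an array")
    }
    mode <- as.integer(mode)
    if (mode < 1L || mode > length(d)) {
        stop("mode out of range")
    }
    perm <- c(mode, setdiff(seq_along(d), mode))
    matrix(aperm(x, perm), nrow = d[mode])
}

#' Fold a matrix back into a tensor
#'
#' Inverse of \code{\link{unfoldTensor}}: \code{foldTensor(unfoldTensor(x, m),
#' m, dim(x))} recovers \code{x} exactly.
#'
#' @param mat matrix produced by (or shaped like) a mode-\code{mode}
#'   unfolding.
#' @param mode the mode that sits on the rows of \code{mat}.
#' @param dims integer vector, the target tensor shape.
#' @return an array of shape \code{dims}.
#' @export
foldTensor <- function(mat, mode, dims) {
    dims <- as.integer(dims)
    mode <- as.integer(mode)
    if (mode < 1L || mode > length(dims)) {
        stop("mode out of range")
    }
    if (nrow(mat) != dims[mode] || ncol(mat) != prod(dims[-mode])) {
        stop("matrix shape inconsistent with mode and dims")
    }
    perm <- c(mode, setdiff(seq_along(dims), mode))
    aperm(array(mat, dims[perm]), order(perm))
}

#' Khatri-Rao product of a list of matrices
#'
#' Column-matched product: the result's column r is the Kronecker product of
#' the inputs' r-th columns, so each output row is the elementwise product of
#' one row from every input. Rows are ordered with the LAST-listed matrix's
#' row index varying fastest, matching the convention in which the product
#' of B (J x R) and C (K x R) stacks rows b_1*c_1, b_1*c_2, ..., b_J*c_K.
#'
#' @param matrices list of numeric matrices sharing a column count R.
#' @return a \code{prod(rows)} x R matrix.
#' @examples
#' B <- matrix(1:4, 2, byrow = TRUE)
#' C <- matrix(5:8, 2, byrow = TRUE)
#' khatriRao(list(B, C))
#' @export
khatriRao <- function(matrices) {
    if (!is.list(matrices) || length(matrices) < 1L) {
        stop("matrices must be a nonempty list")
    }
    matrices <- lapply(matrices, as.matrix)
    ncols <- vapply(matrices, ncol, integer(1))
    if (length(unique(ncols)) != 1L) {
        stop("all matrices must share the same column count")
    }
    Reduce(function(A, B) {
        A[rep(seq_len(nrow(A)), each = nrow(B)), , drop = FALSE] *
            B[rep(seq_len(nrow(B)), times = nrow(A)), , drop = FALSE]
    }, matrices)
}

# Design matrix of the mode-n least squares subproblem: the Khatri-Rao chain
# of the remaining factor matrices taken in DESCENDING mode order, so its row
# ordering matches the unfold column ordering (lowest remaining mode fastest).
designMatrix <- function(factorList, mode) {
    others <- rev(setdiff(seq_along(factorList), mode))
    khatriRao(factorList[others])
}

# Reconstruction from a plain list of factor matrices.
cpReconstructList <- function(factorList, dims) {
    Z <- designMatrix(factorList, 1L)
    foldTensor(factorList[[1L]] %*% t(Z), 1L, dims)
}

#' Reconstruct the dense tensor implied by CP factors
#'
#' Entry \code{(i_1, ..., i_N)} of the reconstruction is
#' \code{sum_r prod_n F_n[i_n, r]}: the sum of R rank-one tensors, each the
#' outer product of one factor column per mode. The reconstruction is always
#' complete, which is what makes a CP fit usable as an imputation of the
#' missing cells.
#'
#' @param factors a \code{\linkS4class{CPFactors}} object.
#' @return a dense numeric array.
#' @export
cpReconstruct <- function(factors) {
    stopifnot(is(factors, "CPFactors"))
    fl <- factors@factors
    cpReconstructList(fl, vapply(fl, nrow, integer(1)))
}

#' Normalized reconstruction error on a coordinate subset
#'
#' The scale-free squared error used for both the fitting and the imputation
#' score: \code{sum((T - That)^2) / sum(T^2)}, both sums restricted to the
#' supplied coordinates. The subset must consist of observed coordinates —
#' pre-existing missing cells have no true value to score against.
#'
#' @param tensor a \code{\linkS4class{MaskedTensor}}.
#' @param reconstruction dense array of the same shape.
#' @param subset integer matrix of 1-based coordinates, one row per cell.
#' @return a single nonnegative number.
#' @examples
#' mt <- MaskedTensor(array(2, c(1, 1, 2)))
#' maskedError(mt, array(1, c(1, 1, 2)), rbind(c(1, 1, 1)))
#' @export
maskedError <- function(tensor, reconstruction, subset) {
    stopifnot(is(tensor, "MaskedTensor"))
    dims <- dim(tensor)
    if (!identical(dim(reconstruction), dims)) {
        stop("reconstruction shape must match the tensor")
    }
    subset <- assertCoords(subset, dims)
    if (!all(tensor@observed[subset])) {
        stop("subset contains pre-existing missing positions")
    }
    relCoordError(tensor@values, reconstruction, subset)
}

#' Deterministic random initialization of CP factors
#'
#' Draws every factor entry i.i.d. standard normal under the given seed. The
#' same (shape, rank, seed) always yields bit-identical factors, so all
#' solvers can be started from a shared point and compared fairly.
#'
#' @param dims integer vector of mode lengths.
#' @param rank number of components R (>= 1).
#' @param seed integer seed.
#' @return a \code{\linkS4class{CPFactors}} object.
#' @examples
#' f <- initializeFactors(c(4, 3, 2), 2, seed = 1)
#' identical(factorMatrices(f),
#'           factorMatrices(initializeFactors(c(4, 3, 2), 2, seed = 1)))
#' @export
initializeFactors <- function(dims, rank, seed) {
    rank <- as.integer(rank)
    if (rank < 1L) {
        stop("rank must be >= 1")
    }
    dims <- as.integer(dims)
    fl <- withSeed(seed,
        lapply(dims, function(d) matrix(stats::rnorm(d * rank), d, rank)))
    CPFactors(fl)
}
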