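# Internal helpers shared across solvers. None of these are exported.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb the
# user's RNG stream.
withSeed <- function(seed, code) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
    code
}

# Half-away-from-zero rounding of a nonnegative count target.
roundHalfUp <- function(x) floor(x + 0.5)

# Moore-Penrose pseudoinverse via SVD. Singular values below
# max(dim) * eps * sigma_max are treated as zero (rank-revealing cutoff).
pinvMat <- function(M) {
    M <- as.matrix(M)
    if (any(dim(M) == 0L)) {
        return(matrix(0, ncol(M), nrow(M)))
    }
    s <- svd(M)
    tol <- max(dim(M)) * .Machine$double.eps * s$d[1L]
    pos <- s$d > tol
    if (!any(pos)) {
        return(matrix(0, ncol(M), nrow(M)))
    }
    s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Minimum-norm least squares: argmin_X ||Z X - Y||_F.
lstsqPinv <- function(Z, Y) pinvMat(Z) %*% Y

# Relative change used by every stopping rule: |prev - cur| scaled by |prev|.
relChange <- function(prev, cur) {
    abs(prev - cur) / max(abs(prev), .Machine$double.xmin)
}

# Normalized squared residual restricted to the TRUE cells of a logical array.
relSubsetError <- function(values, recon, maskArr) {
    idx <- which(maskArr)
    num <- sum((values[idx] - recon[idx])^2)
    den <- sum(values[idx]^2)
    if (den == 0) {
        stop("error denominator is zero on the evaluated subset")
    }
    num / den
}

# Same metric on an explicit coordinate matrix (rows = 1-based coordinates).
relCoordError <- function(values, recon, coords) {
    num <- sum((values[coords] - recon[coords])^2)
    den <- sum(values[coords]^2)
    if (den == 0) {
        stop("error denominator is zero on the evaluated subset")
    }
    num / den
}

# Validate an n x N coordinate matrix against tensor dimensions.
assertCoords <- function(coords, dims, what = "subset") {
    coords <- as.matrix(coords)
    if (nrow(coords) == 0L) {
        stop(what, " is empty")
    }
    if (ncol(coords) != length(dims)) {
        stop(what, " must have one column per tensor mode")
    }
    if (any(coords != floor(coords))) {
        stop(what, " coordinates must be integers")
    }
    if (any(coords < 1L) || any(coords > rep(dims, each = nrow(coords)))) {
        stop(what, " coordinates out of tensor bounds")
    }
    if (anyDuplicated(as.data.frame(coords))) {
        stop(what, " contains duplicate coordinates")
    }
    storage.mode(coords) <- "integer"
    coords
}

# All permutations of 1..n as a list (used for factor matching, n <= 6).
permutationsOf <- function(n) {
    if (n == 1L) {
        return(list(1L))
    }
    sub <- permutationsOf(n - 1L)
    out <- vector("list", n * length(sub))
    k <- 0L
    for (i in seq_len(n)) {
        rest <- setdiff(seq_len(n), i)
        for (p in sub) {
            k <- k + 1L
            out[[k]] <- c(i, rest[p])
        }
    }
    out
}
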