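# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no khatriRao/designMatrix/pinvMat) so that agreement is a real
# cross-check, not a tautology.

# Khatri-Rao by explicit nested loops over row multi-indices; the row index
# of a later-listed matrix varies fastest.
krOracle <- function(matrices) {
    R <- ncol(matrices[[1L]])
    rowsList <- lapply(matrices, nrow)
    grid <- do.call(expand.grid, rev(lapply(matrices, function(m) {
        seq_len(nrow(m))
    })))
    grid <- grid[, rev(seq_along(matrices)), drop = FALSE] # first matrix col 1
    out <- matrix(1, nrow(grid), R)
    for (i in seq_len(nrow(grid))) {
        for (m in seq_along(matrices)) {
            out[i, ] <- out[i, ] * matrices[[m]][grid[i, m], ]
        }
    }
    out
}

# CP reconstruction by looping over every tensor entry.
reconOracle <- function(factorList) {
    dims <- vapply(factorList, nrow, integer(1))
    out <- array(0, dims)
    coords <- as.matrix(do.call(expand.grid, lapply(dims, seq_len)))
    R <- ncol(factorList[[1L]])
    for (i in seq_len(nrow(coords))) {
        tot <- 0
        for (r in seq_len(R)) {
            p <- 1
            for (n in seq_along(dims)) {
                p <- p * factorList[[n]][coords[i, n], r]
            }
            tot <- tot + p
        }
        out[matrix(coords[i, ], 1L)] <- tot
    }
    out
}

# Censored least squares row by row via MASS::ginv, no pattern grouping.
censoredOracle <- function(W, targets, rowMask) {
    A <- matrix(0, nrow(targets), nrow(W))
    for (i in seq_len(nrow(targets))) {
        alpha <- which(rowMask[i, ])
        if (length(alpha) == 0L) {
            next
        }
        Z <- t(W[, alpha, drop = FALSE])
        A[i, ] <- as.numeric(MASS::ginv(Z) %*% targets[i, alpha])
    }
    A
}

# Reference complete-data CP-ALS via the normal equations: the mode-n Gram
# matrix is the Hadamard product of the other modes' Gram matrices, and the
# cross-product against the unfolding is built with kronecker() directly.
# Stops on the same relative-change-in-error rule.
alsOracle <- function(values, rank, initFactors, tol = 1e-6,
                      maxSweeps = 500L) {
    dims <- dim(values)
    N <- length(dims)
    facs <- initFactors
    denom <- sum(values^2)
    unfoldO <- function(n) {
        perm <- c(n, setdiff(seq_len(N), n))
        matrix(aperm(values, perm), nrow = dims[n])
    }
    krChain <- function(n) {
        mats <- facs[rev(setdiff(seq_len(N), n))]
        out <- mats[[1L]]
        for (m in mats[-1L]) {
            nxt <- matrix(0, nrow(out) * nrow(m), rank)
            for (r in seq_len(rank)) {
                nxt[, r] <- kronecker(out[, r], m[, r])
            }
            out <- nxt
        }
        out
    }
    trace <- numeric(0)
    prev <- NA_real_
    for (s in seq_len(maxSweeps)) {
        for (n in seq_len(N)) {
            V <- Reduce(`*`, lapply(facs[-n], crossprod))
            facs[[n]] <- unfoldO(n) %*% krChain(n) %*% solve(V)
        }
        recon <- facs[[1L]] %*% t(krChain(1L))
        err <- sum((unfoldO(1L) - recon)^2) / denom
        trace <- c(trace, err)
        if (!is.na(prev) && abs(prev - err) / max(prev, 1e-300) < tol) {
            break
        }
        prev <- err
    }
    list(factors = facs, fitTrace = trace)
}

# Central finite differences of a scalar function.
fdGradient <- function(f, x, h = 1e-6) {
    g <- numeric(length(x))
    for (i in seq_along(x)) {
        xp <- x
        xm <- x
        xp[i] <- xp[i] + h
        xm[i] <- xm[i] - h
        g[i] <- (f(xp) - f(xm)) / (2 * h)
    }
    g
}

# A random masked tensor (values standard normal, entrywise missingness).
randMaskedTensor <- function(dims, missFrac = 0, seed = 1) {
    set.seed(seed)
    vals <- array(rnorm(prod(dims)), dims)
    if (missFrac > 0) {
        drop <- sample.int(prod(dims), floor(missFrac * prod(dims)))
        vals[drop] <- NA_real_
    }
    MaskedTensor(vals)
}

finalFit <- function(fit) tail(fitTrace(fit), 1)
finalImpute <- function(fit) tail(imputeTrace(fit), 1)
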