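#' Hold out a random subset of observed entries
#'
#' Samples, uniformly without replacement, exactly
#' \code{round(fraction * #observed)} observed coordinates (half away from
#' zero rounding) to hide from fitting. Held-out cells are always disjoint
#' from pre-existing missingness. Deterministic given the seed.
#'
#' @param tensor a \code{\linkS4class{MaskedTensor}}.
#' @param fraction fraction of observed entries to hide, in \code{[0, 1)}.
#' @param seed integer seed.
#' @return a \code{\linkS4class{HeldOutMask}} with \code{style = "entry"}.
#' @examples
#' mt <- MaskedTensor(array(rnorm(1000), c(10, 10, 10)))
#' m <- maskEntries(mt, 0.1, seed = 1)
#' nrow(heldOutIndices(m))
#' @export
maskEntries <- function(tensor, fraction, seed) {
    stopifnot(is(tensor, "MaskedTensor"))
    if (fraction < 0 || fraction >= 1) {
        stop("fraction must lie in [0, 1)")
    }
    obsCoords <- which(tensor@observed, arr.ind = TRUE)
    dimnames(obsCoords) <- NULL
    nObs <- nrow(obsCoords)
    target <- roundHalfUp(fraction * nObs)
    if (target >= nObs) {
        stop("cannot hold out every observed entry")
    }
    idx <- if (target > 0L) {
        withSeed(seed, sample.int(nObs, target))
    } else {
        integer(0)
    }
    coords <- obsCoords[idx, , drop = FALSE]
    out <- new("HeldOutMask", indices = coords, style = "entry",
        chordMode = NA_integer_, fraction = as.numeric(fraction),
        seed = as.integer(seed))
    warnEmptySlabs(tensor, out)
    out
}

#' Hold out whole chords (fibers) of observed entries
#'
#' A chord along \code{mode} is the vector of entries with the remaining
#' modes' indices fixed. Chords containing at least one observed entry are
#' sampled uniformly without replacement, each masked in full (its observed
#' portion), until the cumulative held-out entry count first reaches
#' \code{round(fraction * #observed)} — so the achieved count may overshoot
#' the target by at most one chord. Deterministic given the seed.
#'
#' @param tensor a \code{\linkS4class{MaskedTensor}}.
#' @param fraction target fraction of observed ENTRIES to hide, in
#'   \code{[0, 1)}.
#' @param mode the mode along which chords run.
#' @param seed integer seed.
#' @return a \code{\linkS4class{HeldOutMask}} with \code{style = "chord"}.
#' @export
maskChords <- function(tensor, fraction, mode, seed) {
    stopifnot(is(tensor, "MaskedTensor"))
    dims <- dim(tensor)
    mode <- as.integer(mode)
    if (mode < 1L || mode > length(dims)) {
        stop("mode out of range")
    }
    if (fraction < 0 || fraction >= 1) {
        stop("fraction must lie in [0, 1)")
    }
    nObs <- sum(tensor@observed)
    target <- roundHalfUp(fraction * nObs)
    others <- setdiff(seq_along(dims), mode)
    obsPerChord <- apply(tensor@observed, others, sum)
    cand <- which(obsPerChord > 0L, arr.ind = TRUE)
    if (is.null(dim(cand))) {
        cand <- matrix(cand, ncol = 1L)
    }
    dimnames(cand) <- NULL
    counts <- obsPerChord[cand]
    coords <- matrix(integer(0), 0L, length(dims))
    if (target > 0L) {
        if (sum(counts) < target) {
            stop("requested fraction unreachable even masking all chords")
        }
        ord <- withSeed(seed, sample.int(nrow(cand)))
        csum <- cumsum(counts[ord])
        k <- which(csum >= target)[1L]
        sel <- ord[seq_len(k)]
        if (csum[k] > target) {
            message(sprintf(
                "chord masking overshoot: %d entries masked for target %d",
                csum[k], target))
        }
        pieces <- lapply(sel, function(ci) {
            full <- matrix(0L, dims[mode], length(dims))
            full[, mode] <- seq_len(dims[mode])
            full[, others] <- matrix(cand[ci, ], dims[mode],
                length(others), byrow = TRUE)
            full[tensor@observed[full], , drop = FALSE]
        })
        coords <- do.call(rbind, pieces)
    }
    out <- new("HeldOutMask", indices = coords, style = "chord",
        chordMode = mode, fraction = as.numeric(fraction),
        seed = as.integer(seed))
    warnEmptySlabs(tensor, out)
    out
}

#' Expand a held-out mask to a logical array
#'
#' @param heldout a \code{\linkS4class{HeldOutMask}} or \code{NULL}.
#' @param dims tensor shape.
#' @return logical array, \code{TRUE} at held-out coordinates.
#' @export
heldOutArray <- function(heldout, dims) {
    arr <- array(FALSE, dims)
    if (!is.null(heldout) && nrow(heldout@indices) > 0L) {
        arr[heldout@indices] <- TRUE
    }
    arr
}

# Stop if a held-out mask touches pre-existing missing cells or exceeds
# bounds for this tensor.
checkHeldOutAgainst <- function(tensor, heldout) {
    idx <- heldout@indices
    if (nrow(idx) == 0L) {
        return(invisible(TRUE))
    }
    dims <- dim(tensor)
    if (ncol(idx) != length(dims) ||
        any(idx > rep(dims, each = nrow(idx)))) {
        stop("held-out coordinates out of bounds for this tensor")
    }
    if (!all(tensor@observed[idx])) {
        stop("held-out mask overlaps pre-existing missing entries")
    }
    invisible(TRUE)
}

# Log (message) when masking leaves some index of some mode with no usable
# entry at all — allowed, but worth flagging.
warnEmptySlabs <- function(tensor, heldout) {
    if (nrow(heldout@indices) == 0L) {
        return(invisible(FALSE))
    }
    dims <- dim(tensor)
    eff <- tensor@observed & !heldOutArray(heldout, dims)
    for (n in seq_along(dims)) {
        nUsable <- apply(eff, n, sum)
        if (any(nUsable == 0L)) {
            message(sprintf(
                "masking leaves %d index/indices of mode %d without usable entries",
                sum(nUsable == 0L), n))
        }
    }
    invisible(TRUE)
}

#' Serialize / restore a held-out mask as a coordinate CSV
#'
#' Coordinates are written 0-based (one column per mode) for audit and
#' replay; \code{readHeldOutMask} restores an equivalent object.
#'
#' @param heldout a \code{\linkS4class{HeldOutMask}}.
#' @param path file path.
#' @export
writeHeldOutMask <- function(heldout, path) {
    stopifnot(is(heldout, "HeldOutMask"))
    idx <- heldout@indices - 1L
    colnames(idx) <- paste0("mode", seq_len(ncol(idx)))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# style: %s fraction: %.17g seed: %d chordMode: %d",
        heldout@style, heldout@fraction, heldout@seed,
        if (is.na(heldout@chordMode)) -1L else heldout@chordMode), con)
    utils::write.csv(as.data.frame(idx), con, row.names = FALSE)
}

#' @rdname writeHeldOutMask
#' @export
readHeldOutMask <- function(path) {
    hdr <- readLines(path, n = 1L)
    m <- regmatches(hdr, regexec(
        "# style: (\\S+) fraction: (\\S+) seed: (\\S+) chordMode: (\\S+)",
        hdr))[[1L]]
    if (length(m) != 5L) {
        stop("malformed held-out mask header")
    }
    idx <- as.matrix(utils::read.csv(path, comment.char = "#"))
    dimnames(idx) <- NULL
    storage.mode(idx) <- "integer"
    chordMode <- as.integer(m[5L])
    new("HeldOutMask", indices = idx + 1L, style = m[2L],
        chordMode = if (chordMode < 0L) NA_integer_ else chordMode,
        fraction = as.numeric(m[3L]), seed = as.integer(m[4L]))
}
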