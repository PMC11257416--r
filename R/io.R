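#' Read a masked tensor from a plain-text file
#'
#' Two formats are supported, both with 0-based coordinates on disk (the
#' in-memory API is 1-based, matching R array indexing):
#' \describe{
#'   \item{\code{"long"}}{CSV with one row per OBSERVED entry: one integer
#'     coordinate column per mode, then a final \code{value} column. A
#'     comment line \code{# shape: d1 d2 ...} may declare the shape; absent
#'     that, each mode length is inferred as max index + 1. Coordinates not
#'     listed are missing.}
#'   \item{\code{"dense"}}{a \code{# shape: ...} header line followed by one
#'     value per line in column-major order, with \code{NA}/\code{NaN} as
#'     the missing sentinel.}
#' }
#'
#' @param path input file path.
#' @param format \code{"long"} or \code{"dense"}.
#' @param shape optional integer vector overriding / supplying the tensor
#'   shape (long format only).
#' @return a \code{\linkS4class{MaskedTensor}}.
#' @seealso \code{\link{writeTensor}}
#' @export
readTensor <- function(path, format = c("long", "dense"), shape = NULL) {
    format <- match.arg(format)
    declared <- parseShapeHeader(path)
    if (!is.null(shape)) {
        declared <- as.integer(shape)
    }
    if (format == "dense") {
        if (is.null(declared)) {
            stop("dense format requires a '# shape:' header line")
        }
        vals <- scan(path, what = double(), comment.char = "#",
            quiet = TRUE, na.strings = c("NA", "NaN"))
        if (length(vals) != prod(declared)) {
            stop("dense file length does not match its declared shape")
        }
        return(MaskedTensor(array(vals, declared)))
    }
    df <- utils::read.csv(path, comment.char = "#")
    if (ncol(df) < 4L) {
        stop("long format needs at least 3 coordinate columns and a value")
    }
    coord <- as.matrix(df[, -ncol(df), drop = FALSE])
    vals <- df[[ncol(df)]]
    if (!is.numeric(vals) || anyNA(vals)) {
        stop("value column must be numeric with no missing entries")
    }
    if (!is.numeric(coord) || any(coord != floor(coord)) || any(coord < 0)) {
        stop("coordinates must be nonnegative integers")
    }
    storage.mode(coord) <- "integer"
    coord <- coord + 1L
    dims <- if (!is.null(declared)) declared else apply(coord, 2L, max)
    if (any(coord > rep(dims, each = nrow(coord)))) {
        stop("coordinates exceed the declared shape")
    }
    if (anyDuplicated(as.data.frame(coord))) {
        stop("duplicate coordinates in long-format file")
    }
    values <- array(NA_real_, dims)
    values[coord] <- vals
    MaskedTensor(values)
}

#' Write a masked tensor to a plain-text file
#'
#' Inverse of \code{\link{readTensor}}; values are printed with 17
#' significant digits so a write/read round trip is bit-exact. The long
#' format emits observed entries only, sorted lexicographically by
#' coordinate, after a \code{# shape:} header.
#'
#' @param tensor a \code{\linkS4class{MaskedTensor}}.
#' @param path output file path.
#' @param format \code{"long"} or \code{"dense"}.
#' @export
writeTensor <- function(tensor, path, format = c("long", "dense")) {
    stopifnot(is(tensor, "MaskedTensor"))
    format <- match.arg(format)
    dims <- dim(tensor)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste("# shape:", paste(dims, collapse = " ")), con)
    if (format == "dense") {
        writeLines(sprintf("%.17g", as.numeric(tensor@values)), con)
        return(invisible(path))
    }
    coords <- which(tensor@observed, arr.ind = TRUE)
    dimnames(coords) <- NULL
    ord <- do.call(order, lapply(seq_len(ncol(coords)),
        function(j) coords[, j]))
    coords <- coords[ord, , drop = FALSE]
    vals <- tensor@values[coords]
    header <- c(paste0("mode", seq_along(dims)), "value")
    writeLines(paste(header, collapse = ","), con)
    writeLines(paste(apply(coords - 1L, 1L, paste, collapse = ","),
        sprintf("%.17g", vals), sep = ","), con)
    invisible(path)
}

# First '# shape:' comment line of a file, as an integer vector, or NULL.
parseShapeHeader <- function(path) {
    for (ln in readLines(path, n = 5L)) {
        if (grepl("^#\\s*shape:", ln)) {
            return(as.integer(strsplit(
                trimws(sub("^#\\s*shape:", "", ln)), "[ ,]+")[[1L]]))
        }
        if (!startsWith(ln, "#")) {
            break
        }
    }
    NULL
}

#' Persist a fit result as plain-text files
#'
#' Writes the factor matrices (one CSV per mode), the error/time traces and
#' a small JSON metadata record under \code{dir}, using \code{prefix} as the
#' file stem. Everything needed to reconstruct or audit the fit is kept in
#' open formats.
#'
#' @param fit a \code{\linkS4class{FitResult}}.
#' @param dir output directory (created if absent).
#' @param prefix file stem, default \code{"fit"}.
#' @return invisibly, the paths written.
#' @export
writeFitResult <- function(fit, dir, prefix = "fit") {
    stopifnot(is(fit, "FitResult"))
    if (!dir.exists(dir)) {
        dir.create(dir, recursive = TRUE)
    }
    paths <- character(0)
    for (n in seq_along(fit@factors@factors)) {
        p <- file.path(dir, sprintf("%s-factor-mode%d.csv", prefix, n))
        utils::write.csv(fit@factors@factors[[n]], p, row.names = FALSE)
        paths <- c(paths, p)
    }
    tr <- data.frame(iteration = seq_along(fit@fitTrace),
        fitError = fit@fitTrace,
        imputeError = if (length(fit@imputeTrace)) {
            fit@imputeTrace
        } else NA_real_,
        elapsed = fit@timeTrace)
    p <- file.path(dir, paste0(prefix, "-trace.csv"))
    utils::write.csv(tr, p, row.names = FALSE)
    paths <- c(paths, p)
    meta <- file.path(dir, paste0(prefix, "-meta.json"))
    writeLines(sprintf(
        paste0('{"method": "%s", "rank": %d, "iterations": %d, ',
            '"converged": %s}'),
        fit@method, fit@factors@rank, fit@iterations,
        tolower(as.character(fit@converged))), meta)
    invisible(c(paths, meta))
}
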