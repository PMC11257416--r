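#' Fit a CP model with the selected solver
#'
#' Thin dispatcher over \code{\link{fitCALS}}, \code{\link{fitALSSI}} and
#' \code{\link{fitDO}}, so benchmark code can treat solvers uniformly.
#'
#' @inheritParams fitCALS
#' @param method one of \code{"cals"}, \code{"als-si"}, \code{"do"}.
#' @return a \code{\linkS4class{FitResult}}.
#' @export
fitCP <- function(tensor, rank, method = c("cals", "als-si", "do"), seed,
                  config = SolverConfig(), heldout = NULL) {
    method <- match.arg(method)
    switch(method,
        "cals" = fitCALS(tensor, rank, seed, config, heldout),
        "als-si" = fitALSSI(tensor, rank, seed, config, heldout),
        "do" = fitDO(tensor, rank, seed, config, heldout))
}

#' Median and quartiles of a set of errors
#'
#' Quartiles use the linear-interpolation convention (type 7), the default
#' in most numerical software.
#'
#' @param values nonempty numeric vector.
#' @return named numeric vector \code{c(median, q1, q3)}.
#' @examples
#' summarizeErrors(c(1, 2, 3))
#' @export
summarizeErrors <- function(values) {
    if (length(values) == 0L) {
        stop("values must be nonempty")
    }
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE,
        na.rm = TRUE)
    c(median = q[2L], q1 = q[1L], q3 = q[3L])
}

# Default rank sweep: 1..10 for 3-mode tensors, 1..20 for 4 and more modes.
defaultRanks <- function(nModes) {
    if (nModes <= 3L) 1:10 else 1:20
}

# One (pattern seed, init seed) pair per replicate, derived deterministically
# from the base seed and shared across all methods of that replicate.
replicateSeeds <- function(baseSeed, nReplicates) {
    withSeed(baseSeed, matrix(sample.int(.Machine$integer.max - 1L,
        2L * nReplicates), nReplicates, 2L,
        dimnames = list(NULL, c("pattern", "init"))))
}

#' Run the multi-replicate imputation benchmark
#'
#' The evaluation protocol: for each of \code{nReplicates} replicates a
#' (pattern seed, init seed) pair is derived from \code{baseSeed}; one
#' held-out mask is generated from the pattern seed; every method is then
#' run at every rank from the SAME initialization and against the SAME
#' mask, and the final fitting error, imputation error, iteration count and
#' wall time are recorded. Per (method, rank) the medians and interquartile
#' ranges are summarized and the best imputed rank is selected per method.
#' The whole run is deterministic given \code{baseSeed}. A solver failure
#' is recorded in that record, never fatal to the run.
#'
#' @param tensor a \code{\linkS4class{MaskedTensor}}.
#' @param methods character vector of solver names.
#' @param ranks integer vector of component numbers; defaults to 1-10 for
#'   3-mode and 1-20 for 4-mode tensors.
#' @param maskStyle \code{"entry"}, \code{"chord"}, or \code{"none"} for a
#'   fitting-only sweep without held-out masking.
#' @param fraction fraction of observed entries to hold out.
#' @param chordMode mode along which chords run (chord style only).
#' @param nReplicates number of mask/initialization replicates (default 20).
#' @param baseSeed master seed for the whole run.
#' @param config a \code{\link{SolverConfig}} shared by all methods.
#' @return a \code{\linkS4class{BenchmarkSummary}}.
#' @examples
#' inst <- simulateCPTensor(c(8, 6, 5), rank = 2, noiseSD = 0.1, seed = 1)
#' bm <- runBenchmark(inst@tensor, methods = "cals", ranks = 1:3,
#'                    nReplicates = 3, baseSeed = 1)
#' bestImputedRank(bm, "cals")
#' @export
runBenchmark <- function(tensor, methods = c("cals", "als-si", "do"),
                         ranks = NULL,
                         maskStyle = c("entry", "chord", "none"),
                         fraction = 0.1, chordMode = 1L,
                         nReplicates = 20L, baseSeed = 1L,
                         config = SolverConfig()) {
    stopifnot(is(tensor, "MaskedTensor"))
    maskStyle <- match.arg(maskStyle)
    nReplicates <- as.integer(nReplicates)
    if (nReplicates < 1L) {
        stop("nReplicates must be >= 1")
    }
    if (is.null(ranks)) {
        ranks <- defaultRanks(length(dim(tensor)))
    }
    ranks <- as.integer(ranks)
    if (length(ranks) == 0L) {
        stop("ranks must be nonempty")
    }
    seeds <- replicateSeeds(baseSeed, nReplicates)
    rows <- list()
    for (rep_i in seq_len(nReplicates)) {
        heldout <- switch(maskStyle,
            entry = maskEntries(tensor, fraction, seeds[rep_i, "pattern"]),
            chord = maskChords(tensor, fraction, chordMode,
                seeds[rep_i, "pattern"]),
            none = NULL)
        for (method in methods) {
            for (rank in ranks) {
                rec <- tryCatch({
                    fit <- fitCP(tensor, rank, method,
                        seed = seeds[rep_i, "init"],
                        config = config, heldout = heldout)
                    nIt <- length(fit@fitTrace)
                    data.frame(method = method, rank = rank,
                        replicate = rep_i,
                        fitError = fit@fitTrace[nIt],
                        imputeError = if (length(fit@imputeTrace)) {
                            fit@imputeTrace[nIt]
                        } else NA_real_,
                        iterations = fit@iterations,
                        totalTime = fit@timeTrace[nIt],
                        converged = fit@converged,
                        error = NA_character_)
                }, error = function(e) {
                    data.frame(method = method, rank = rank,
                        replicate = rep_i, fitError = NA_real_,
                        imputeError = NA_real_, iterations = NA_integer_,
                        totalTime = NA_real_, converged = NA,
                        error = conditionMessage(e))
                })
                rows[[length(rows) + 1L]] <- rec
            }
        }
    }
    records <- do.call(rbind, rows)
    summaries <- summarizeRecords(records)
    best <- vapply(unique(records$method), function(m) {
        bestRankFromSummaries(summaries, m)
    }, integer(1))
    new("BenchmarkSummary", records = records, summaries = summaries,
        bestRank = best)
}

# Per (method, rank) median/quartile reduction of the record table.
summarizeRecords <- function(records) {
    keys <- unique(records[, c("method", "rank")])
    out <- lapply(seq_len(nrow(keys)), function(i) {
        sel <- records$method == keys$method[i] & records$rank == keys$rank[i]
        naSummary <- c(median = NA_real_, q1 = NA_real_, q3 = NA_real_)
        fit <- if (all(is.na(records$fitError[sel]))) {
            naSummary
        } else {
            summarizeErrors(records$fitError[sel])
        }
        imp <- if (all(is.na(records$imputeError[sel]))) {
            naSummary
        } else {
            summarizeErrors(records$imputeError[sel])
        }
        data.frame(method = keys$method[i], rank = keys$rank[i],
            fitMedian = fit["median"], fitQ1 = fit["q1"], fitQ3 = fit["q3"],
            imputeMedian = imp["median"], imputeQ1 = imp["q1"],
            imputeQ3 = imp["q3"], row.names = NULL)
    })
    do.call(rbind, out)
}

bestRankFromSummaries <- function(summaries, method) {
    s <- summaries[summaries$method == method, ]
    if (nrow(s) == 0L) {
        stop("method not present in this benchmark: ", method)
    }
    s <- s[order(s$rank), ]
    crit <- if (all(is.na(s$imputeMedian))) s$fitMedian else s$imputeMedian
    if (all(is.na(crit))) {
        return(NA_integer_)
    }
    as.integer(s$rank[which.min(crit)])
}

#' Best imputed rank of a benchmarked method
#'
#' The rank with the lowest median imputation error across replicates; when
#' the benchmark was run without held-out masking the lowest median fitting
#' error decides instead. Ties break toward the smaller rank.
#'
#' @param summary a \code{\linkS4class{BenchmarkSummary}}.
#' @param method solver name present in the summary.
#' @return an integer rank.
#' @export
bestImputedRank <- function(summary, method) {
    stopifnot(is(summary, "BenchmarkSummary"))
    bestRankFromSummaries(summary@summaries, method)
}

#' Plot benchmark error against rank
#'
#' Draws the median fitting and imputation error per rank for each method,
#' with vertical bars spanning the interquartile range (the same summary the
#' benchmark tables report; whiskers at 1.5 IQR belong to the box plot
#' variant of this display).
#'
#' @param summary a \code{\linkS4class{BenchmarkSummary}}.
#' @param metric \code{"imputation"} or \code{"fitting"}.
#' @param log use a logarithmic error axis.
#' @return invisibly, the summary table that was plotted.
#' @export
plotErrorVsRank <- function(summary, metric = c("imputation", "fitting"),
                            log = TRUE) {
    stopifnot(is(summary, "BenchmarkSummary"))
    metric <- match.arg(metric)
    s <- summary@summaries
    med <- if (metric == "imputation") s$imputeMedian else s$fitMedian
    lo <- if (metric == "imputation") s$imputeQ1 else s$fitQ1
    hi <- if (metric == "imputation") s$imputeQ3 else s$fitQ3
    if (all(is.na(med))) {
        stop("no ", metric, " errors recorded in this benchmark")
    }
    methods <- unique(s$method)
    cols <- seq_along(methods)
    graphics::plot(range(s$rank), range(c(lo, hi), na.rm = TRUE), type = "n",
        log = if (log) "y" else "", xlab = "components",
        ylab = paste(metric, "error"))
    for (i in seq_along(methods)) {
        sel <- s$method == methods[i]
        ord <- order(s$rank[sel])
        graphics::lines(s$rank[sel][ord], med[sel][ord], col = cols[i],
            type = "b", pch = 16)
        graphics::arrows(s$rank[sel][ord], lo[sel][ord], s$rank[sel][ord],
            hi[sel][ord], angle = 90, code = 3, length = 0.03,
            col = cols[i])
    }
    graphics::legend("topright", legend = methods, col = cols, lty = 1,
        pch = 16, bty = "n")
    invisible(s)
}

#' Export benchmark records as tidy CSV
#'
#' One row per (method, rank, replicate); the summaries can always be
#' recomputed from this table.
#'
#' @param summary a \code{\linkS4class{BenchmarkSummary}}.
#' @param path output file path.
#' @export
writeBenchmark <- function(summary, path) {
    stopifnot(is(summary, "BenchmarkSummary"))
    utils::write.csv(summary@records, path, row.names = FALSE)
}
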