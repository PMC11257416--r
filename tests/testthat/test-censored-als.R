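test_that("row grouping partitions rows by identical mask pattern", {
    g <- groupRowsByPattern(rbind(c(TRUE, TRUE), c(TRUE, TRUE),
        c(TRUE, FALSE)))
    expect_length(g, 2)
    expect_equal(g[[1]]$rows, c(1L, 2L))
    expect_equal(g[[2]]$rows, 3L)
    expect_equal(g[[2]]$pattern, c(TRUE, FALSE))

    allTrue <- groupRowsByPattern(matrix(TRUE, 5, 4))
    expect_length(allTrue, 1)
    expect_equal(allTrue[[1]]$rows, 1:5)

    distinct <- groupRowsByPattern(diag(3) > 0)
    expect_length(distinct, 3)
    rows <- sort(unname(unlist(lapply(distinct, `[[`, "rows"))))
    expect_equal(rows, 1:3)
})

test_that("censored least squares solves each row on its observed columns", {
    # single observed equation
    expect_equal(censoredLstsq(matrix(c(1, 2), 1), rbind(c(3, NA))),
        matrix(3))
    # exactly determined by the two observed columns
    W <- rbind(c(1, 0, 1), c(0, 1, 1))
    expect_equal(censoredLstsq(W, rbind(c(2, 3, NA))), rbind(c(2, 3)))
    # full mask reduces to ordinary least squares
    set.seed(21)
    W2 <- matrix(rnorm(3 * 12), 3)
    T2 <- matrix(rnorm(5 * 12), 5)
    ols <- t(MASS::ginv(t(W2)) %*% t(T2))
    expect_equal(censoredLstsq(W2, T2), ols, tolerance = 1e-10)
})

test_that("pattern-grouped solve matches the ungrouped per-row oracle", {
    set.seed(31)
    for (trial in 1:30) {
        R <- sample(1:6, 1)
        I <- sample(5:30, 1)
        P <- sample((R + 1):40, 1)
        W <- matrix(rnorm(R * P), R)
        targets <- matrix(rnorm(I * P), I)
        miss <- matrix(runif(I * P) < runif(1, 0, 0.6), I)
        # keep at least one observed column per row for this comparison
        for (i in which(rowSums(!miss) == P)) miss[i, 1] <- FALSE
        targets[miss] <- NA
        got <- censoredLstsq(W, targets)
        want <- censoredOracle(W, targets, !miss)
        expect_equal(got, want, tolerance = 1e-10)
    }
})

test_that("rows with zero observed entries go to zero with a warning", {
    W <- matrix(rnorm(2 * 4), 2)
    targets <- rbind(rnorm(4), rep(NA_real_, 4))
    expect_warning(A <- censoredLstsq(W, targets), "zero observed")
    expect_equal(A[2, ], c(0, 0))
})

test_that("the censored mode update interpolates consistent systems and reduces to plain ALS", {
    set.seed(41)
    truth <- lapply(c(8, 6, 5), function(d) matrix(rnorm(d), d, 1))
    vals <- cpReconstruct(CPFactors(truth))
    drop <- sample(length(vals), round(0.2 * length(vals)))
    masked <- vals
    masked[drop] <- NA
    mt <- MaskedTensor(masked)
    # every mode-1 row keeps some observed entries here
    start <- CPFactors(list(matrix(rnorm(8), 8, 1), truth[[2]], truth[[3]]))
    upd <- calsUpdateMode(mt, start, 1)
    expect_lt(max(abs(upd - truth[[1]])) / max(abs(truth[[1]])), 1e-8)

    # complete mask: identical to the plain least squares update
    full <- MaskedTensor(vals)
    f0 <- initializeFactors(c(8, 6, 5), 2, seed = 2)
    expect_equal(calsUpdateMode(full, f0, 2),
        alsUpdateMode(vals, f0, 2), tolerance = 1e-12)
})

test_that("each censored update cannot increase the masked fitting loss", {
    set.seed(51)
    for (trial in 1:5) {
        mt <- randMaskedTensor(c(7, 6, 5), missFrac = 0.25,
            seed = 100 + trial)
        eff <- observedMask(mt)
        facs <- factorMatrices(initializeFactors(dim(mt), 2,
            seed = trial))
        lossOf <- function(fl) {
            r <- tensorValues(mt) - cpReconstruct(CPFactors(fl))
            sum(r[eff]^2)
        }
        for (n in 1:3) {
            before <- lossOf(facs)
            facs[[n]] <- calsUpdateMode(mt, CPFactors(facs), n)
            after <- lossOf(facs)
            expect_lte(after, before * (1 + 1e-10))
        }
    }
})

test_that("censored ALS converges under its stopping rule and reports it", {
    inst <- simulateCPTensor(c(12, 9, 7), rank = 2, noiseSD = 0.1, seed = 61)
    fit <- fitCALS(inst@tensor, 2, seed = 8)
    expect_true(hasConverged(fit))
    tr <- fitTrace(fit)
    n <- length(tr)
    expect_lt(abs(tr[n - 1] - tr[n]) / tr[n - 1], 1e-6)
    expect_equal(length(timeTrace(fit)), n)
    expect_error(fitCALS(inst@tensor, 0, seed = 1), "rank")
})

test_that("noiseless low-rank completion is exact at the true rank", {
    inst <- simulateCPTensor(c(20, 15, 10), rank = 3, noiseSD = 0, seed = 71)
    held <- maskEntries(inst@tensor, 0.1, seed = 72)
    fit <- fitCALS(inst@tensor, 3, seed = 73,
        config = SolverConfig(tolerance = 1e-9, maxSweeps = 500),
        heldout = held)
    expect_lt(finalImpute(fit), 1e-4)
    expect_gt(factorMatchScore(trueFactors(inst), fit@factors), 0.99)
})
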