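test_that("imputeFill keeps usable cells and fills the rest from the reconstruction", {
    set.seed(1)
    vals <- array(rnorm(8), c(2, 2, 2))
    mt <- MaskedTensor(vals)
    recon <- array(rnorm(8), c(2, 2, 2))
    allTrue <- array(TRUE, c(2, 2, 2))
    expect_identical(imputeFill(mt, allTrue, recon), vals)
    expect_identical(imputeFill(mt, !allTrue, recon), recon)
    mix <- array(c(TRUE, FALSE), c(2, 2, 2))
    filled <- imputeFill(mt, mix, recon)
    expect_identical(filled[mix], vals[mix])
    expect_identical(filled[!mix], recon[!mix])
    expect_false(anyNA(filled))
    expect_error(imputeFill(mt, mix, array(0, c(2, 2, 3))), "shape")
})

test_that("the plain ALS update solves its mode exactly", {
    set.seed(2)
    truth <- lapply(c(6, 5, 4), function(d) matrix(rnorm(d), d, 1))
    vals <- cpReconstruct(CPFactors(truth))
    start <- CPFactors(list(matrix(rnorm(6), 6, 1), truth[[2]], truth[[3]]))
    upd <- alsUpdateMode(vals, start, 1)
    expect_equal(upd, truth[[1]], tolerance = 1e-10)
    expect_error(alsUpdateMode(array(NA_real_, c(2, 2, 2)), start, 1),
        "missing")

    # full-data loss cannot increase
    f0 <- factorMatrices(initializeFactors(c(6, 5, 4), 2, seed = 3))
    lossOf <- function(fl) sum((vals - cpReconstruct(CPFactors(fl)))^2)
    before <- lossOf(f0)
    f0[[2]] <- alsUpdateMode(vals, CPFactors(f0), 2)
    expect_lte(lossOf(f0), before * (1 + 1e-12))
})

test_that("observed fitting error is non-increasing across fill-then-sweep iterations", {
    for (trial in 1:5) {
        mt <- randMaskedTensor(c(9, 7, 6), missFrac = 0.2, seed = 200 + trial)
        fit <- fitALSSI(mt, 2, seed = trial,
            config = SolverConfig(maxSweeps = 40))
        tr <- fitTrace(fit)
        expect_true(all(diff(tr) <= 1e-10 * pmax(tr[-length(tr)], 1)))
    }
})

test_that("refilled positions carry exactly the generating reconstruction", {
    mt <- randMaskedTensor(c(6, 5, 4), missFrac = 0.3, seed = 9)
    recon <- cpReconstruct(initializeFactors(dim(mt), 2, seed = 4))
    filled <- imputeFill(mt, observedMask(mt), recon)
    off <- !observedMask(mt)
    expect_identical(filled[off], recon[off])
})

test_that("single imputation and censored ALS coincide on complete data", {
    inst <- simulateCPTensor(c(10, 8, 6), rank = 3, noiseSD = 0.1, seed = 5)
    cfg <- SolverConfig(tolerance = 1e-300, maxSweeps = 10)
    a <- fitCALS(inst@tensor, 3, seed = 6, config = cfg)
    b <- fitALSSI(inst@tensor, 3, seed = 6, config = cfg)
    expect_equal(fitTrace(a), fitTrace(b), tolerance = 1e-9)
    expect_equal(factorMatrices(a), factorMatrices(b), tolerance = 1e-9)
})

test_that("imputation error of single-imputation ALS is small on easy completions", {
    inst <- simulateCPTensor(c(14, 10, 8), rank = 2, noiseSD = 0, seed = 77)
    held <- maskEntries(inst@tensor, 0.05, seed = 78)
    fit <- fitALSSI(inst@tensor, 2, seed = 79,
        config = SolverConfig(tolerance = 1e-9, maxSweeps = 800),
        heldout = held)
    expect_lt(finalImpute(fit), 1e-3)
    # cross-check against the censored route on the same instance
    fit2 <- fitCALS(inst@tensor, 2, seed = 79,
        config = SolverConfig(tolerance = 1e-9, maxSweeps = 800),
        heldout = held)
    expect_lt(finalImpute(fit2), 1e-3)
})
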