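test_that("unfolding follows the frontal-slice column ordering", {
    x <- array(0:7, c(2, 2, 2)) # entry(i,j,k) = (i-1) + 2(j-1) + 4(k-1)
    expect_equal(unfoldTensor(x, 1),
        matrix(c(0, 1, 2, 3, 4, 5, 6, 7), 2))
    expect_identical(unfoldTensor(array(5, c(1, 1, 1)), 2), matrix(5))
    expect_error(unfoldTensor(x, 4), "mode")
})

test_that("fold inverts unfold exactly on every mode", {
    set.seed(7)
    x <- array(rnorm(60), c(3, 4, 5))
    for (m in 1:3) {
        expect_identical(foldTensor(unfoldTensor(x, m), m, dim(x)), x)
    }
    expect_identical(
        foldTensor(matrix(c(0, 1, 2, 3, 4, 5, 6, 7), 2), 1, c(2, 2, 2)),
        array(0:7 + 0, c(2, 2, 2)))
    expect_error(foldTensor(matrix(1, 2, 3), 1, c(2, 2, 2)), "inconsistent")
})

test_that("Khatri-Rao product matches its row definition and the loop oracle", {
    B <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)
    C <- matrix(c(5, 6, 7, 8), 2, byrow = TRUE)
    expect_equal(khatriRao(list(B, C)),
        rbind(c(5, 12), c(7, 16), c(15, 24), c(21, 32)))
    expect_equal(khatriRao(list(diag(2), diag(2))),
        rbind(c(1, 0), c(0, 0), c(0, 0), c(0, 1)))
    expect_identical(khatriRao(list(B)), B)
    expect_error(khatriRao(list(B, matrix(1, 2, 3))), "column count")

    set.seed(11)
    for (shapes in list(c(4, 5), c(3, 4, 5), c(2, 5, 6))) {
        mats <- lapply(shapes, function(d) matrix(rnorm(d * 3), d, 3))
        expect_equal(khatriRao(mats), krOracle(mats), tolerance = 1e-12)
    }
})

test_that("CP reconstruction agrees with the entrywise sum-of-products oracle", {
    ones <- CPFactors(list(matrix(1, 2, 1), matrix(1, 3, 1), matrix(1, 4, 1)))
    expect_equal(cpReconstruct(ones), array(1, c(2, 3, 4)))

    f <- CPFactors(list(matrix(1:2), matrix(3:4), matrix(5:6)))
    rec <- cpReconstruct(f)
    expect_equal(rec[2, 2, 2], 2 * 4 * 6)
    expect_equal(rec, reconOracle(factorMatrices(f)), tolerance = 1e-12)

    set.seed(3)
    for (shapes in list(c(4, 3, 2), c(6, 5, 4, 3))) {
        fl <- lapply(shapes, function(d) matrix(rnorm(d * 4), d, 4))
        expect_equal(cpReconstruct(CPFactors(fl)), reconOracle(fl),
            tolerance = 1e-12)
    }
})

test_that("matricized reconstructions agree across modes", {
    set.seed(5)
    fl <- lapply(c(4, 3, 5), function(d) matrix(rnorm(d * 2), d, 2))
    f <- CPFactors(fl)
    rec <- cpReconstruct(f)
    for (n in 1:3) {
        others <- rev(setdiff(1:3, n))
        expect_equal(unfoldTensor(rec, n),
            fl[[n]] %*% t(khatriRao(fl[others])), tolerance = 1e-12)
    }
})

test_that("maskedError is the subset-restricted normalized squared residual", {
    vals <- array(rnorm(24), c(2, 3, 4))
    mt <- MaskedTensor(vals)
    coords <- rbind(c(1, 2, 3), c(2, 1, 4))
    expect_equal(maskedError(mt, vals, coords), 0)

    one <- MaskedTensor(array(2, c(1, 1, 2)))
    expect_equal(maskedError(one, array(1, c(1, 1, 2)), rbind(c(1, 1, 1))),
        0.25)

    # doubling every residual quadruples the error
    recon <- vals + 0.3
    e1 <- maskedError(mt, recon, coords)
    e2 <- maskedError(mt, vals + 0.6, coords)
    expect_equal(e2, 4 * e1, tolerance = 1e-12)

    # invariant to subset row order
    expect_equal(maskedError(mt, recon, coords[2:1, ]), e1)

    expect_error(maskedError(mt, recon, coords[0, , drop = FALSE]), "empty")
    holey <- vals
    holey[1, 1, 1] <- NA
    mh <- MaskedTensor(holey)
    expect_error(maskedError(mh, recon, rbind(c(1, 1, 1))), "missing")
    zero <- MaskedTensor(array(0, c(1, 1, 3)) + c(0, 0, 1))
    expect_error(maskedError(zero, tensorValues(zero), rbind(c(1, 1, 1))),
        "denominator")
})

test_that("factor initialization is a deterministic function of (shape, rank, seed)", {
    a <- initializeFactors(c(4, 3, 2), 2, seed = 99)
    b <- initializeFactors(c(4, 3, 2), 2, seed = 99)
    expect_identical(factorMatrices(a), factorMatrices(b))
    d <- initializeFactors(c(4, 3, 2), 2, seed = 100)
    expect_false(identical(factorMatrices(a), factorMatrices(d)))
    expect_equal(vapply(factorMatrices(a), dim, integer(2)),
        matrix(c(4L, 2L, 3L, 2L, 2L, 2L), 2))
    expect_error(initializeFactors(c(4, 3, 2), 0, seed = 1), "rank")
    # seeding must not disturb the caller's RNG stream
    set.seed(1)
    before <- rnorm(1)
    set.seed(1)
    invisible(initializeFactors(c(3, 3, 3), 2, seed = 7))
    expect_identical(rnorm(1), before)
})

test_that("MaskedTensor and CPFactors validity catch malformed objects", {
    expect_error(MaskedTensor(matrix(1, 2, 2)), "3 modes")
    expect_error(MaskedTensor(array(NA_real_, c(2, 2, 2))), "at least one")
    v <- array(1, c(2, 2, 2))
    v[1, 1, 1] <- Inf
    expect_error(MaskedTensor(v), "finite")
    expect_error(CPFactors(list(matrix(1, 2, 2), matrix(1, 3, 3))),
        "column count")
})
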