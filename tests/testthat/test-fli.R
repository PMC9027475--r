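test_that("fliImpute recovers exact convex-combination profiles", {
    tr <- ExpressionMatrix(rbind(c(1, 0, 2), c(0, 1, 4)))
    res <- fliImpute(tr, MaskedProfile(c(0.5, 0.5, NA)))
    expect_equal(completedValues(res), c(0.5, 0.5, 3), tolerance = 1e-6)
    expect_equal(imputeWeights(res), c(0.5, 0.5), tolerance = 1e-6)

    # profile equal to a training row: one-hot weights are feasible, so the
    # returned objective cannot exceed the (zero) one-hot objective
    set.seed(11)
    tr2 <- randomTrain(5, 12, seed = 11)
    X <- exprValues(tr2)
    mask <- rep(FALSE, 12)
    mask[sample.int(12, 4)] <- TRUE
    v <- X[3L, ]
    v[mask] <- NA
    res2 <- fliImpute(tr2, MaskedProfile(v, mask = mask))
    known <- !mask
    expect_lte(sum((crossprod(X[, known], imputeWeights(res2)) -
                    X[3L, known])^2), 1e-10)
    expect_equal(completedValues(res2)[mask], unname(X[3L, mask]),
                 tolerance = 1e-6)
})

test_that("FLI weights live on the probability simplex", {
    for (seed in 1:20) {
        set.seed(seed)
        n <- sample(2:10, 1)
        p <- sample(4:20, 1)
        tr <- randomTrain(n, p, seed = seed)
        pr <- randomMaskedProfile(p, nMissing = sample(seq_len(p - 1L), 1),
                                  seed = seed)
        w <- imputeWeights(fliImpute(tr, pr))
        expect_gte(min(w), 0)
        expect_lte(abs(sum(w) - 1), 1e-6)
    }
})

test_that("FLI objective matches the exhaustive simplex oracle", {
    for (seed in 1:30) {
        set.seed(seed)
        n <- sample(2:8, 1)
        p <- sample(3:12, 1)
        tr <- randomTrain(n, p, seed = seed * 3L)
        nMissing <- sample(seq_len(p - 1L), 1)
        pr <- randomMaskedProfile(p, nMissing = nMissing, seed = seed * 3L)
        res <- fliImpute(tr, pr)
        known <- !pr@mask
        A <- t(exprValues(tr)[, known, drop = FALSE])
        b <- pr@values[known]
        oracle <- simplexLsOracle(A, b)
        obj <- sum((A %*% imputeWeights(res) - b)^2)
        expect_lte(obj, oracle$obj * (1 + 1e-5) + 1e-10)
    }
})

test_that("imputed entries stay within the training feature ranges", {
    for (seed in 1:30) {
        set.seed(seed)
        n <- sample(2:12, 1)
        p <- sample(4:25, 1)
        tr <- randomTrain(n, p, seed = seed * 7L, nonneg = FALSE)
        pr <- randomMaskedProfile(p, nMissing = sample(seq_len(p - 1L), 1),
                                  seed = seed * 7L, nonneg = FALSE)
        res <- fliImpute(tr, pr)
        X <- exprValues(tr)
        lo <- apply(X, 2L, min)
        hi <- apply(X, 2L, max)
        idx <- which(pr@mask)
        expect_true(all(completedValues(res)[idx] >= lo[idx] - 1e-8))
        expect_true(all(completedValues(res)[idx] <= hi[idx] + 1e-8))
        # pass-through of known entries is exact
        expect_identical(completedValues(res)[!pr@mask],
                         pr@values[!pr@mask])
    }
})

test_that("degenerate inputs follow the documented fallbacks", {
    tr <- randomTrain(4, 6, seed = 2)
    # all-missing profile: mean fallback with a warning
    prAll <- MaskedProfile(rep(NA_real_, 6))
    expect_warning(res <- fliImpute(tr, prAll), "mean")
    expect_equal(completedValues(res), unname(colMeans(exprValues(tr))))
    expect_equal(res@method, "fli")
    # no missing entries: identity
    v <- abs(rnorm(6))
    resId <- fliImpute(tr, MaskedProfile(v, mask = rep(FALSE, 6)))
    expect_identical(completedValues(resId), v)
    # single training sample: copy its missing entries
    tr1 <- randomTrain(1, 6, seed = 3)
    pr <- randomMaskedProfile(6, nMissing = 2, seed = 3)
    res1 <- fliImpute(tr1, pr)
    expect_equal(completedValues(res1)[pr@mask],
                 unname(exprValues(tr1)[1L, pr@mask]))
    expect_equal(imputeWeights(res1), 1)
})

test_that("batchImpute is an independent per-profile dispatcher", {
    tr <- randomTrain(5, 10, seed = 4)
    profiles <- lapply(1:6, function(i)
        randomMaskedProfile(10, nMissing = 3, seed = 40 + i))
    expect_identical(batchImpute(tr, list(), "fli"), list())
    expect_error(batchImpute(tr, profiles, "nope"), "unknown-method")

    resB <- batchImpute(tr, profiles, "fli")
    resS <- lapply(profiles, function(p) fliImpute(tr, p))
    for (i in seq_along(profiles))
        expect_equal(completedValues(resB[[i]]), completedValues(resS[[i]]),
                     tolerance = 1e-8)

    resZ <- batchImpute(tr, profiles[1], "zero")
    expect_equal(completedValues(resZ[[1]]),
                 completedValues(zeroImpute(profiles[[1]])))
})
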