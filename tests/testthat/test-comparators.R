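test_that("viper_like stage-2 matches the box-constrained QP oracle", {
    for (seed in 1:8) {
        set.seed(seed)
        tr <- randomTrain(3, 9, seed = 200 + seed)
        pr <- randomMaskedProfile(9, nMissing = 3, seed = 200 + seed)
        cfg <- comparatorConfig(lassoPenalty = 1e-4)  # keep all samples
        res <- viperLikeImpute(tr, pr, cfg)
        w <- imputeWeights(res)
        expect_true(all(w >= -1e-9 & w <= 1 + 1e-9))
        known <- !pr@mask
        A <- t(exprValues(tr)[, known, drop = FALSE])
        b <- pr@values[known]
        support <- which(w != 0)
        if (length(support) == 3L) {
            oracle <- boxLsOracle(A, b)
            obj <- sum((A %*% w - b)^2)
            expect_lte(obj, oracle$obj * (1 + 1e-5) + 1e-8)
        }
    }
})

test_that("viper_like with a huge penalty falls back to nearest neighbour", {
    tr <- randomTrain(5, 10, seed = 21)
    pr <- randomMaskedProfile(10, nMissing = 3, seed = 21)
    cfg <- comparatorConfig(lassoPenalty = 1e6)
    expect_warning(res <- viperLikeImpute(tr, pr, cfg), "nearest")
    w <- imputeWeights(res)
    expect_equal(sum(w == 1), 1L)
    expect_equal(sum(w), 1)
    known <- !pr@mask
    X <- exprValues(tr)
    d2 <- rowSums((X[, known, drop = FALSE] -
        matrix(pr@values[known], 5, sum(known), byrow = TRUE))^2)
    nn <- unname(which.min(d2))
    expect_equal(which(w == 1), nn)
    expect_equal(completedValues(res)[pr@mask], unname(X[nn, pr@mask]))
})

test_that("scimpute_like with K = 1 reduces to plain NNLS over all samples", {
    tr <- randomTrain(6, 12, seed = 22)
    pr <- randomMaskedProfile(12, nMissing = 4, seed = 22)
    res <- scimputeLikeImpute(tr, list(pr),
                              comparatorConfig(nClusters = 1L))[[1L]]
    w <- imputeWeights(res)
    expect_gte(min(w), 0)
    known <- !pr@mask
    A <- t(exprValues(tr)[, known, drop = FALSE])
    b <- pr@values[known]
    oracle <- nnlsOracle(A, b)
    expect_lte(sum((A %*% w - b)^2), oracle$obj * (1 + 1e-5) + 1e-8)
})

test_that("scimpute_like routes profiles to the correct Gaussian blob", {
    set.seed(30)
    nb <- 12
    blobA <- matrix(rnorm(nb * 8, mean = 0, sd = 0.2), nb, 8)
    blobB <- matrix(rnorm(nb * 8, mean = 30, sd = 0.2), nb, 8)
    tr <- ExpressionMatrix(rbind(blobA, blobB),
                           sampleIds = paste0("s", 1:(2 * nb)),
                           featureIds = paste0("f", 1:8))
    v <- as.numeric(blobA[1L, ]) + rnorm(8, sd = 0.05)
    mask <- c(rep(FALSE, 5), rep(TRUE, 3))
    v[mask] <- NA
    res <- scimputeLikeImpute(tr, list(MaskedProfile(v, mask = mask)),
                              comparatorConfig(nClusters = 2L))[[1L]]
    w <- imputeWeights(res)
    expect_gte(sum(w[1:nb]) / max(sum(w), 1e-12), 0.99)
})

test_that("scimpute_like with K = n uses the single assigned sample", {
    tr <- randomTrain(4, 8, seed = 23)
    pr <- randomMaskedProfile(8, nMissing = 2, seed = 23)
    res <- scimputeLikeImpute(tr, list(pr),
                              comparatorConfig(nClusters = 4L))[[1L]]
    w <- imputeWeights(res)
    expect_equal(sum(w > 0), 1L)
    # one-column NNLS: imputed entries are a nonnegative scaling of the
    # assigned sample's missing entries
    j <- which(w > 0)
    X <- exprValues(tr)
    expect_equal(completedValues(res)[pr@mask],
                 unname(w[j] * X[j, pr@mask]), tolerance = 1e-8)
    expect_error(scimputeLikeImpute(tr, list(pr),
                                    comparatorConfig(nClusters = 5L)),
                 "exceeds")
})
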