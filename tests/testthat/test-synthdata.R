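test_that("digit generation is reproducible and well-formed", {
    d1 <- genDigits(2, classes = c(1, 7), noiseSd = 0.05, seed = 5)
    d2 <- genDigits(2, classes = c(1, 7), noiseSd = 0.05, seed = 5)
    expect_identical(exprValues(d1), exprValues(d2))
    expect_equal(dim(exprValues(d1)), c(4L, 784L))
    expect_true(all(exprValues(d1) >= 0 & exprValues(d1) <= 1))
    expect_equal(as.character(sampleLabels(d1)), c("1", "1", "7", "7"))
    expect_error(genDigits(1, classes = 12), "subset")
})

test_that("the class-1 template concentrates ink in a vertical bar", {
    d <- genDigits(1, classes = 1, noiseSd = 0, seed = 1, jitter = FALSE)
    img <- matrix(exprValues(d)[1L, ], 28, 28)   # rows = image rows
    colMass <- colSums(img)
    # most of the stroke mass lies in the central columns
    expect_gte(sum(colMass[12:18]) / sum(colMass), 0.6)
    # and spans most of the vertical extent
    rowsInked <- which(rowSums(img) > 0.5)
    expect_gte(diff(range(rowsInked)), 15)
})

test_that("templates of different digits are distinct", {
    d <- genDigits(1, classes = 0:9, noiseSd = 0, seed = 1, jitter = FALSE)
    X <- exprValues(d)
    cc <- cor(t(X))
    expect_true(all(cc[upper.tri(cc)] < 0.95))
})

test_that("mvn generator produces the requested correlation structure", {
    m <- genMVN(500, p = 40, blockSize = 10, withinBlockCorr = 0,
                seed = 3, nClasses = 1)
    cc <- cor(exprValues(m))
    off <- abs(cc[upper.tri(cc)])
    expect_lt(max(off), 0.25)
    expect_lt(mean(off), 0.06)

    m2 <- genMVN(1000, p = 40, blockSize = 10, withinBlockCorr = 0.9,
                 seed = 4, nClasses = 1)
    cc2 <- cor(exprValues(m2))
    within <- cc2[1:10, 1:10][upper.tri(diag(10))]
    expect_true(all(within > 0.85 & within < 0.95))

    expect_error(genMVN(10, p = 20, blockSize = 5, withinBlockCorr = 1),
                 "positive definite")
    expect_error(genMVN(10, p = 20, blockSize = 7), "divide")

    # columns are scaled to unit variance
    expect_equal(unname(apply(exprValues(m2), 2, sd)), rep(1, 40),
                 tolerance = 1e-8)
})

test_that("no class signal means chance-level classification", {
    m <- genMVN(300, p = 30, blockSize = 5, withinBlockCorr = 0.5,
                seed = 8, nClasses = 2, classShift = 0)
    sp <- stratifiedSplit(sampleLabels(m), 0.3, seed = 8)
    X <- exprValues(m)
    mod <- trainSoftmax(ExpressionMatrix(X[sp$train, ],
        labels = sampleLabels(m)[sp$train]))
    cm <- classificationMetrics(mod, ExpressionMatrix(X[sp$test, ],
        labels = sampleLabels(m)[sp$test]))
    expect_lt(abs(cm[["auc"]] - 0.5), 0.2)
})

test_that("masks have exact cardinality and are seed-reproducible", {
    X <- genMVN(20, p = 50, blockSize = 10, seed = 2)
    m1 <- applyMissingness(X, 0.3, seed = 9)
    m2 <- applyMissingness(X, 0.3, seed = 9)
    counts <- vapply(m1$profiles, function(p) sum(p@mask), integer(1))
    expect_true(all(counts == 15L))
    for (i in seq_along(m1$profiles))
        expect_identical(m1$profiles[[i]]@mask, m2$profiles[[i]]@mask)
    # truth is passed through untouched
    expect_identical(exprValues(m1$truth), exprValues(X))

    m0 <- applyMissingness(X, 0, seed = 1)
    expect_true(all(vapply(m0$profiles, function(p) !any(p@mask),
                           logical(1))))
    expect_error(applyMissingness(X, 0.999, seed = 1), "no known")
})

test_that("masking 550 of 784 pixels is 70% of the dimensions", {
    d <- genDigits(1, classes = 1, seed = 1)
    masked <- applyMissingness(d, 550 / 784, seed = 1)
    nMissing <- sum(masked$profiles[[1L]]@mask)
    expect_identical(nMissing, 550L)
    expect_equal(round(100 * nMissing / nFeatures(d)), 70)
})

test_that("masks are independent across samples", {
    X <- genMVN(200, p = 100, blockSize = 10, seed = 5)
    m <- applyMissingness(X, 0.5, seed = 11)
    M <- do.call(rbind, lapply(m$profiles, function(p) p@mask))
    # expected pairwise overlap is 25 of 100 under independence
    ov <- tcrossprod(M * 1)
    pairs <- ov[upper.tri(ov)]
    expect_gt(mean(pairs), 23)
    expect_lt(mean(pairs), 27)
    expect_gt(sd(pairs), 1)    # not identical masks
})
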