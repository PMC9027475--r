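test_that("softmax classifier separates a separable toy problem", {
    d <- toyClassificationData(60, seed = 1)
    mod <- trainSoftmax(d)
    cm <- classificationMetrics(mod, d)
    expect_equal(cm[["acc"]], 1)
    expect_equal(cm[["auc"]], 1)
    expect_equal(cm[["f1"]], 1)
    probs <- predictProbs(mod, d)
    expect_equal(unname(rowSums(probs)), rep(1, 60), tolerance = 1e-8)

    noLab <- ExpressionMatrix(exprValues(d))
    expect_error(trainSoftmax(noLab), "labels")
    oneClass <- ExpressionMatrix(exprValues(d), labels = rep("a", 60))
    expect_error(trainSoftmax(oneClass), "single class")
})

test_that("label permutation drives held-out AUC to chance", {
    d <- toyClassificationData(120, seed = 2)
    set.seed(99)
    perm <- sample(as.character(sampleLabels(d)))
    dPerm <- ExpressionMatrix(exprValues(d), labels = perm)
    sp <- stratifiedSplit(sampleLabels(dPerm), 0.4, seed = 2)
    X <- exprValues(dPerm)
    mod <- trainSoftmax(ExpressionMatrix(X[sp$train, ],
        labels = perm[sp$train]))
    cm <- classificationMetrics(mod, ExpressionMatrix(X[sp$test, ],
        labels = perm[sp$test]))
    expect_lt(abs(cm[["auc"]] - 0.5), 0.25)
})

test_that("metrics match hand-computed confusion-matrix values", {
    # constant positive prediction on balanced binary data:
    # ACC = 0.5 and F1 of the positive class = 2/3
    truth <- factor(rep(c("a", "b"), each = 10), levels = c("a", "b"))
    pred <- factor(rep("b", 20), levels = c("a", "b"))
    f1 <- fliImpute:::classF1(truth, pred, "b")
    expect_equal(f1, 2 / 3)
    expect_equal(mean(pred == truth), 0.5)
    # F1 with an empty denominator scores 0
    expect_equal(fliImpute:::classF1(truth, pred, "a"), 0)
})

test_that("imputation errors implement the relative l2 definition", {
    X <- matrix(c(3, 4, 0, 5), 2, 2, byrow = TRUE)
    truth <- ExpressionMatrix(X, c("s1", "s2"), c("f1", "f2"))
    mk <- function(v, id) new("ImputationResult", completed = v,
        weights = fliImpute:::uniformWeights(1L), method = "zero",
        elapsedSeconds = 0, sampleId = id)
    # perfect imputation
    perfect <- list(mk(X[1, ], "s1"), mk(X[2, ], "s2"))
    expect_equal(unname(imputationErrors(perfect, truth)), c(0, 0, 0))
    # zeroing one entry of sample 1: error = |x_miss| / ||x||
    res <- list(mk(c(3, 0), "s1"), mk(X[2, ], "s2"))
    ee <- imputationErrors(res, truth)
    e1 <- 4 / 5
    expect_equal(ee[["eps_mu"]], e1 / 2)
    expect_equal(ee[["eps_sigma"]], e1 / 2)     # population sd of (e1, 0)
    expect_equal(ee[["eps_max"]], e1)
    expect_error(imputationErrors(perfect[1], truth), "mismatch")
})

test_that("zero-imputing a fraction f of squared norm gives eps = sqrt(f)", {
    set.seed(13)
    x <- rnorm(100)
    mask <- rep(FALSE, 100)
    mask[sample.int(100, 40)] <- TRUE
    prof <- zeroImpute(MaskedProfile(replace(x, mask, NA), mask = mask))
    f <- sum(x[mask]^2) / sum(x^2)
    truth <- ExpressionMatrix(matrix(x, 1, 100,
        dimnames = list("s1", paste0("f", 1:100))))
    ee <- imputationErrors(list(prof), truth)
    expect_equal(ee[["eps_mu"]], sqrt(f), tolerance = 1e-10)
})

test_that("runSweep at fraction 0 reproduces the clean baseline", {
    d <- toyClassificationData(80, seed = 3)
    sp <- stratifiedSplit(sampleLabels(d), 0.3, seed = 3)
    X <- exprValues(d)
    trn <- ExpressionMatrix(X[sp$train, ],
        labels = sampleLabels(d)[sp$train])
    tst <- ExpressionMatrix(X[sp$test, ], labels = sampleLabels(d)[sp$test])
    sw <- runSweep(trn, tst, methods = c("fli", "zero", "mean"),
                   fractions = 0, seed = 1)
    tab <- sweepTable(sw)
    clean <- classificationMetrics(trainSoftmax(trn), tst)
    expect_equal(tab$auc, rep(clean[["auc"]], 3), tolerance = 1e-8)
    expect_equal(tab$acc, rep(clean[["acc"]], 3), tolerance = 1e-8)
    expect_equal(tab$eps_mu, rep(0, 3), tolerance = 1e-10)

    expect_error(runSweep(trn, tst, methods = "nope", fractions = 0.1),
                 "unknown-method")
    expect_error(runSweep(trn, tst, fractions = numeric(0)), "empty")
})

test_that("summarizeSweep averages rows over the fraction grid", {
    d <- toyClassificationData(80, seed = 4)
    sp <- stratifiedSplit(sampleLabels(d), 0.3, seed = 4)
    X <- exprValues(d)
    trn <- ExpressionMatrix(X[sp$train, ],
        labels = sampleLabels(d)[sp$train])
    tst <- ExpressionMatrix(X[sp$test, ], labels = sampleLabels(d)[sp$test])
    sw <- runSweep(trn, tst, methods = "mean", fractions = c(0.2, 0.6),
                   seed = 2)
    tab <- sweepTable(sw)
    sm <- summarizeSweep(sw)
    expect_equal(nrow(sm), 1L)
    expect_equal(sm$acc, mean(tab$acc))
    expect_equal(sm$eps_mu, mean(tab$eps_mu))
    expect_equal(sm$t_max, max(sweepSamples(sw)$time))
    expect_named(sm, c("method", "auc", "acc", "f1", "eps_mu", "eps_sigma",
                       "eps_max", "t_mu", "t_sigma", "t_max"))

    sw1 <- runSweep(trn, tst, methods = "mean", fractions = 0.4, seed = 2)
    sm1 <- summarizeSweep(sw1)
    expect_equal(sm1$f1, sweepTable(sw1)$f1)
})

test_that("eps_sigma never exceeds eps_max in sweeps", {
    d <- toyClassificationData(60, seed = 5)
    sp <- stratifiedSplit(sampleLabels(d), 0.3, seed = 5)
    X <- exprValues(d)
    sw <- runSweep(ExpressionMatrix(X[sp$train, ],
                       labels = sampleLabels(d)[sp$train]),
                   ExpressionMatrix(X[sp$test, ],
                       labels = sampleLabels(d)[sp$test]),
                   methods = c("fli", "zero"),
                   fractions = c(0.2, 0.5, 0.8), seed = 3)
    tab <- sweepTable(sw)
    expect_true(all(tab$eps_sigma <= tab$eps_max + 1e-12))
    expect_true(all(is.finite(unlist(tab[, 3:11]))))
})
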