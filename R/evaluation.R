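#' Train the softmax classifier
#'
#' Fits multinomial logistic regression (softmax) on standardised features
#' with a small fixed ridge penalty, which keeps the fit deterministic and
#' well-posed when features outnumber samples. Standardisation statistics
#' (per-feature mean and standard deviation; zero-variance features get
#' scale 1) come from the training data only and are reused at prediction.
#'
#' @param train an [ExpressionMatrix-class] with labels (at least 2 classes).
#' @param lambda ridge penalty (default 0.01).
#' @return A [SoftmaxModel-class].
#' @export
trainSoftmax <- function(train, lambda = 0.01) {
    stopifnot(is(train, "ExpressionMatrix"))
    y <- sampleLabels(train)
    if (is.null(y))
        stop("training matrix has no labels")
    y <- droplevels(factor(y))
    if (nlevels(y) < 2L)
        stop("single class: the classifier needs at least 2 classes")
    X <- exprValues(train)
    ctr <- colMeans(X)
    scl <- apply(X, 2L, sd)
    scl[scl == 0] <- 1
    Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
    fit <- glmnet::glmnet(Xs, y, family = "multinomial", alpha = 0,
                          lambda = c(10, 1, 0.1, lambda),
                          standardize = FALSE)
    new("SoftmaxModel", fit = fit, center = ctr, scale = scl,
        classes = levels(y), lambda = lambda)
}

#' Predict class probabilities
#'
#' @param model a [SoftmaxModel-class].
#' @param X an [ExpressionMatrix-class] (or samples-by-features matrix) on
#'   the same features as the training data.
#' @return Matrix of class probabilities, one row per sample; rows sum to 1.
#' @export
predictProbs <- function(model, X) {
    stopifnot(is(model, "SoftmaxModel"))
    V <- if (is(X, "ExpressionMatrix")) exprValues(X) else as.matrix(X)
    Vs <- sweep(sweep(V, 2L, model@center), 2L, model@scale, "/")
    pr <- predict(model@fit, newx = Vs, type = "response",
                  s = model@lambda)[, , 1L, drop = FALSE]
    pr <- matrix(pr, nrow(Vs), length(model@classes),
                 dimnames = list(rownames(V), model@classes))
    pr
}

#' Classification-retention metrics
#'
#' Computes AUC, accuracy and F1 of a fitted softmax model on labelled data.
#' Accuracy is the fraction correct under argmax. For two classes, AUC is
#' the standard ROC AUC of the positive (second-level) class and F1 is the
#' positive-class F1. For more classes, AUC is the macro one-vs-rest average
#' and F1 the macro average over classes; classes absent from the data are
#' excluded with a warning. A per-class F1 with an empty denominator
#' (no predictions and no truths of that class counted) is scored 0.
#'
#' @param model a [SoftmaxModel-class].
#' @param X a labelled [ExpressionMatrix-class] to score.
#' @return Named numeric vector `c(auc, acc, f1)`, all in \[0, 1\].
#' @export
classificationMetrics <- function(model, X) {
    stopifnot(is(model, "SoftmaxModel"), is(X, "ExpressionMatrix"))
    truth <- sampleLabels(X)
    if (is.null(truth))
        stop("data to score has no labels")
    truth <- factor(as.character(truth), levels = model@classes)
    if (anyNA(truth))
        stop("labels outside the model's classes")
    probs <- predictProbs(model, X)
    pred <- factor(model@classes[max.col(probs, ties.method = "first")],
                   levels = model@classes)
    acc <- mean(pred == truth)
    present <- model@classes[model@classes %in% as.character(truth)]
    if (length(present) < length(model@classes))
        warning("classes absent from the scored data are excluded from ",
                "macro metrics: ",
                paste(setdiff(model@classes, present), collapse = ", "))
    if (length(model@classes) == 2L) {
        pos <- model@classes[2L]
        auc <- binaryAuc(truth == pos, probs[, pos])
        f1 <- classF1(truth, pred, pos)
    } else {
        aucs <- vapply(present, function(cl)
            binaryAuc(truth == cl, probs[, cl]), numeric(1))
        f1s <- vapply(present, function(cl)
            classF1(truth, pred, cl), numeric(1))
        auc <- mean(aucs)
        f1 <- mean(f1s)
    }
    c(auc = auc, acc = acc, f1 = f1)
}

#' Relative imputation-error statistics over a test set
#'
#' For each test sample, the error is the relative Euclidean distance
#' between the completed and true profiles over the full feature vector,
#' \eqn{\epsilon_i = \|\hat{x}_i - x_i\|_2 / \|x_i\|_2} (known entries pass
#' through, so they contribute zero). Returns the mean, the population
#' standard deviation (n denominator) and the maximum of the per-sample
#' errors. A zero-norm truth scores 0 if the completion is also all-zero,
#' otherwise `Inf` with a warning.
#'
#' @param completed list of [ImputationResult-class], aligned with the rows
#'   of `truth`.
#' @param truth the complete [ExpressionMatrix-class] ground truth.
#' @return Named numeric vector `c(eps_mu, eps_sigma, eps_max)`.
#' @export
imputationErrors <- function(completed, truth) {
    stopifnot(is(truth, "ExpressionMatrix"))
    V <- exprValues(truth)
    if (length(completed) != nrow(V))
        stop("length mismatch: ", length(completed), " results for ",
             nrow(V), " truth samples")
    eps <- vapply(seq_along(completed), function(i) {
        xh <- completedValues(completed[[i]])
        x <- V[i, ]
        nx <- sqrt(sum(x^2))
        if (nx == 0) {
            if (all(xh == 0)) return(0)
            warning("zero-norm truth sample with nonzero completion: ",
                    "error is infinite")
            return(Inf)
        }
        sqrt(sum((xh - x)^2)) / nx
    }, numeric(1))
    c(eps_mu = mean(eps),
      eps_sigma = sqrt(mean((eps - mean(eps))^2)),
      eps_max = max(eps))
}

#' Sweep classification retention and imputation error over missing fractions
#'
#' The paper-style evaluation harness: a softmax classifier is trained once
#' on the complete training set; then, for every missing fraction in the
#' grid, the test profiles are masked uniformly at random
#' ([applyMissingness()], one derived seed per fraction), imputed with each
#' method, and scored — classification metrics on the imputed test set,
#' relative imputation errors against the ground truth, and per-profile
#' imputation wall times.
#'
#' For `"viper_like"` with an unset `lassoPenalty`, the penalty is selected
#' once per fraction by deterministic cross validation on the first masked
#' profile and reused across profiles at that fraction.
#'
#' @param train complete labelled training [ExpressionMatrix-class].
#' @param test complete labelled test [ExpressionMatrix-class] (ground truth).
#' @param methods character vector of method names (see [batchImpute()]).
#' @param fractions missing-dimension fractions, each in \[0, 1).
#' @param seed integer master seed for the per-fraction masks.
#' @param config a [ComparatorConfig-class] for the comparator methods.
#' @return A [SweepResult-class].
#' @export
runSweep <- function(train, test, methods = c("fli", "zero", "mean"),
                     fractions = defaultFractionGrid(), seed = 1,
                     config = comparatorConfig()) {
    stopifnot(is(train, "ExpressionMatrix"), is(test, "ExpressionMatrix"))
    if (length(fractions) == 0L)
        stop("empty fraction list")
    valid <- c("fli", "zero", "mean", "regression", "viper_like",
               "scimpute_like")
    bad <- setdiff(methods, valid)
    if (length(bad))
        stop("unknown-method: ", paste(bad, collapse = ", "))
    model <- trainSoftmax(train)
    rows <- list()
    samples <- list()
    for (fi in seq_along(fractions)) {
        f <- fractions[fi]
        masked <- applyMissingness(test, f, seed = as.integer(seed) + fi)
        cfg <- config
        for (m in methods) {
            if (m == "viper_like" && is.na(cfg@lassoPenalty)) {
                p1 <- masked$profiles[[1L]]
                known <- !p1@mask
                lam <- if (sum(known) >= 10L && nSamples(train) >= 2L) {
                    A <- t(exprValues(train)[, known, drop = FALSE])
                    selectLassoPenalty(A, p1@values[known])
                } else 1e-3
                cfg <- comparatorConfig(lassoPenalty = lam,
                                        nClusters = config@nClusters)
            }
            res <- batchImpute(train, masked$profiles, m, cfg)
            comp <- do.call(rbind, lapply(res, completedValues))
            scored <- ExpressionMatrix(comp, sampleIds = sampleIds(test),
                                       featureIds = featureIds(test),
                                       labels = sampleLabels(test))
            cm <- classificationMetrics(model, scored)
            ee <- imputationErrors(res, masked$truth)
            times <- vapply(res, function(r) r@elapsedSeconds, numeric(1))
            epsI <- vapply(seq_along(res), function(i) {
                x <- exprValues(masked$truth)[i, ]
                nx <- sqrt(sum(x^2))
                if (nx == 0) 0 else
                    sqrt(sum((completedValues(res[[i]]) - x)^2)) / nx
            }, numeric(1))
            rows[[length(rows) + 1L]] <- data.frame(
                method = m, fraction = f,
                auc = cm[["auc"]], acc = cm[["acc"]], f1 = cm[["f1"]],
                eps_mu = ee[["eps_mu"]], eps_sigma = ee[["eps_sigma"]],
                eps_max = ee[["eps_max"]],
                t_mu = mean(times),
                t_sigma = sqrt(mean((times - mean(times))^2)),
                t_max = max(times))
            samples[[length(samples) + 1L]] <- data.frame(
                method = m, fraction = f, sample = sampleIds(test),
                eps = epsI, time = times)
        }
    }
    new("SweepResult", table = do.call(rbind, rows),
        samples = do.call(rbind, samples))
}

#' Summarise a sweep: grid means per method
#'
#' Per-method unweighted means of each classification and error metric over
#' the fraction grid (the "mean values over curves" summary), with the
#' timing statistics pooled over every individual imputation: `t_mu`/`t_max`
#' are the mean/max per-profile time and `t_sigma` its population standard
#' deviation, across all fractions.
#'
#' @param sweep a [SweepResult-class].
#' @return A data.frame, one row per method, columns `method`, `auc`, `acc`,
#'   `f1`, `eps_mu`, `eps_sigma`, `eps_max`, `t_mu`, `t_sigma`, `t_max`.
#' @export
summarizeSweep <- function(sweep) {
    stopifnot(is(sweep, "SweepResult"))
    tab <- sweep@table
    smp <- sweep@samples
    out <- lapply(unique(tab$method), function(m) {
        sub <- tab[tab$method == m, , drop = FALSE]
        tm <- smp$time[smp$method == m]
        data.frame(method = m,
                   auc = mean(sub$auc), acc = mean(sub$acc),
                   f1 = mean(sub$f1),
                   eps_mu = mean(sub$eps_mu),
                   eps_sigma = mean(sub$eps_sigma),
                   eps_max = mean(sub$eps_max),
                   t_mu = mean(tm),
                   t_sigma = sqrt(mean((tm - mean(tm))^2)),
                   t_max = max(tm))
    })
    do.call(rbind, out)
}

#' Default missing-fraction grid
#'
#' 5% to 95% in steps of 5% (19 points): on column-standardised data the
#' grid mean of `sqrt(f)`, 0.6731, matches the zero-imputation mean relative
#' error this harness reports.
#'
#' @return Numeric vector of 19 fractions.
#' @export
defaultFractionGrid <- function() seq(0.05, 0.95, by = 0.05)

#' Stratified train/test split
#'
#' @param labels factor of class labels.
#' @param testFraction fraction of each class placed in the test set.
#' @param seed integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratifiedSplit <- function(labels, testFraction = 0.3, seed = 1) {
    stopifnot(testFraction > 0, testFraction < 1)
    labels <- factor(labels)
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
    test <- unlist(lapply(levels(labels), function(l) {
        idx <- which(labels == l)
        sample(idx, max(1L, round(testFraction * length(idx))))
    }), use.names = FALSE)
    list(train = setdiff(seq_along(labels), test), test = sort(test))
}

# internal metric helpers ----------------------------------------------------

binaryAuc <- function(isPos, score) {
    r <- pROC::roc(response = as.integer(isPos), predictor = score,
                   levels = c(0, 1), direction = "<", quiet = TRUE)
    as.numeric(pROC::auc(r))
}

classF1 <- function(truth, pred, cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    den <- 2 * tp + fp + fn
    if (den == 0) 0 else 2 * tp / den
}
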