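#' Fast linear imputation (FLI)
#'
#' Imputes the missing entries of a profile as a convex combination of the
#' training profiles. The weights solve a nonnegative least-squares problem
#' on the known features with the sum-to-one constraint embedded as a stiff
#' penalty row ([buildConstrainedSystem()]), solved by [nncgls()]. Because
#' the weights are (numerically) on the probability simplex, every imputed
#' value lies within the per-feature min-max range of the training data.
#' The method takes no tuning hyperparameters.
#'
#' Degenerate inputs: a profile with no known entries falls back to mean
#' imputation with a warning; a single-sample training matrix copies that
#' sample's values into the missing entries; a profile with no missing
#' entries is returned unchanged.
#'
#' @param train an [ExpressionMatrix-class] of complete training profiles.
#' @param profile a [MaskedProfile-class].
#' @return An [ImputationResult-class]; known entries are passed through
#'   bit-for-bit.
#' @examples
#' tr <- ExpressionMatrix(rbind(c(1, 0, 2), c(0, 1, 4)))
#' res <- fliImpute(tr, MaskedProfile(c(0.5, 0.5, NA)))
#' completedValues(res)   # third entry imputed as 3 = (2+4)/2
#' @export
fliImpute <- function(train, profile) {
    .fliImpute(train, profile, trainGram = NULL)
}

# trainGram: optional tcrossprod(exprValues(train)) over all features,
# shared across profiles by batchImpute so each call only pays for the
# masked-block update of the known-feature Gram
.fliImpute <- function(train, profile, trainGram = NULL) {
    t0 <- proc.time()[["elapsed"]]
    checkShapes(train, profile)
    known <- !profile@mask
    if (!any(known)) {
        warning("profile ", profile@sampleId,
                " has no known entries; falling back to mean imputation")
        res <- meanImpute(train, profile)
        res@method <- "fli"
        return(res)
    }
    X <- exprValues(train)
    n <- nrow(X)
    if (!any(profile@mask)) {
        wv <- new("WeightVector", w = rep(1 / n, n),
                  residualNorm = sqrt(sum((crossprod(X, rep(1 / n, n)) -
                                           profile@values)^2)),
                  iterations = 0L, converged = TRUE,
                  residualTrace = numeric(0))
        return(newResult(profile@values, wv, "fli", t0, profile@sampleId))
    }
    if (n == 1L) {
        completed <- profile@values
        completed[profile@mask] <- X[1L, profile@mask]
        rn <- sqrt(sum((X[1L, known] - profile@values[known])^2))
        wv <- new("WeightVector", w = 1, residualNorm = rn, iterations = 0L,
                  converged = TRUE, residualTrace = numeric(0))
        return(newResult(completed, wv, "fli", t0, profile@sampleId))
    }
    # Gram of the known-feature block, reusing the full-feature Gram when
    # supplied (subtracting the masked block is cheaper whenever fewer than
    # half the features are missing)
    b0 <- profile@values[known]
    G0 <- if (!is.null(trainGram) && sum(profile@mask) < sum(known)) {
        Xm <- X[, profile@mask, drop = FALSE]
        trainGram - tcrossprod(Xm)
    } else {
        tcrossprod(X[, known, drop = FALSE])
    }
    g0 <- as.numeric(X[, known, drop = FALSE] %*% b0)
    scale <- 1e3 * sqrt(max(diag(G0)))
    if (scale <= 0) scale <- 1e3      # all-zero known block: constraint only
    sys <- buildConstrainedSystem(train, profile, constraintScale = scale)
    # short CG warm start to identify the support; the exact polish below
    # finishes the solve, so a long CG tail buys nothing
    wv <- nncgls(sys$design, sys$rhs, maxIter = 30L,
                 gram = G0 + scale^2, crossRhs = g0 + scale^2)
    # exact refinement on the identified support: solve the sum-constrained
    # face KKT system directly, which removes the penalty-row approximation
    # and the CG truncation error at once
    pol <- polishNnls(G0, g0, wv@w, sumToOne = TRUE)
    if (!is.null(pol) && all(pol$w >= 0) &&
        (pol$converged ||
         objValue(G0, g0, b0, pol$w) <=
             objValue(G0, g0, b0, wv@w) * (1 + 1e-9) + 1e-12)) {
        wv <- new("WeightVector", w = pol$w,
                  residualNorm = sqrt(sum((sys$design %*% pol$w -
                                           sys$rhs)^2)),
                  iterations = wv@iterations,
                  converged = pol$converged || wv@converged,
                  residualTrace = wv@residualTrace)
    }
    completed <- profile@values
    completed[profile@mask] <-
        as.numeric(crossprod(X[, profile@mask, drop = FALSE], wv@w))
    newResult(completed, wv, "fli", t0, profile@sampleId)
}

# data-block objective ||A0 w - b0||^2 evaluated through the Gram
objValue <- function(G0, g0, b0, w) {
    max(sum(b0^2) - 2 * sum(w * g0) + sum(w * (G0 %*% w)), 0)
}

#' Impute a list of profiles with one method
#'
#' Thin dispatcher over the imputation methods. Profiles are imputed
#' independently (results are identical to per-profile calls); per-profile
#' wall time is recorded on each result.
#'
#' @param train an [ExpressionMatrix-class] of complete training profiles.
#' @param profiles list of [MaskedProfile-class] objects.
#' @param method one of `"fli"`, `"zero"`, `"mean"`, `"regression"`,
#'   `"viper_like"`, `"scimpute_like"`.
#' @param config a [ComparatorConfig-class] (used by the two comparators).
#' @return A list of [ImputationResult-class], one per profile.
#' @export
batchImpute <- function(train, profiles, method,
                        config = comparatorConfig()) {
    methods <- c("fli", "zero", "mean", "regression", "viper_like",
                 "scimpute_like")
    if (length(method) != 1L || !method %in% methods)
        stop("unknown-method: '", paste(method, collapse = ","),
             "'; valid methods are ", paste(methods, collapse = ", "))
    if (length(profiles) == 0L) return(list())
    stopifnot(all(vapply(profiles, is, logical(1), "MaskedProfile")))
    switch(method,
        fli = {
            trainGram <- tcrossprod(exprValues(train))
            lapply(profiles, function(p)
                .fliImpute(train, p, trainGram = trainGram))
        },
        zero = lapply(profiles, zeroImpute),
        mean = lapply(profiles, function(p) meanImpute(train, p)),
        regression = {
            trainGram <- tcrossprod(exprValues(train))
            lapply(profiles, function(p)
                .regressionImpute(train, p, trainGram = trainGram))
        },
        viper_like = lapply(profiles, function(p)
            viperLikeImpute(train, p, config)),
        scimpute_like = scimputeLikeImpute(train, profiles, config))
}

# shared helpers ------------------------------------------------------------

checkShapes <- function(train, profile) {
    stopifnot(is(train, "ExpressionMatrix"), is(profile, "MaskedProfile"))
    if (length(profile@mask) != nFeatures(train))
        stop("shape-mismatch: profile has ", length(profile@mask),
             " features, training matrix has ", nFeatures(train))
    invisible(TRUE)
}

newResult <- function(completed, weights, method, t0, sampleId) {
    new("ImputationResult", completed = as.numeric(completed),
        weights = weights, method = method,
        elapsedSeconds = proc.time()[["elapsed"]] - t0,
        sampleId = sampleId)
}

uniformWeights <- function(n) {
    new("WeightVector", w = rep(1 / n, n), residualNorm = 0,
        iterations = 0L, converged = TRUE, residualTrace = numeric(0))
}
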