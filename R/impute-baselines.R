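#' Baseline imputers: zero, mean, unconstrained regression
#'
#' @description
#' `zeroImpute()` fills missing entries with 0 (i.e. no imputation).
#'
#' `meanImpute()` fills each missing entry with the arithmetic mean of that
#' feature's training column.
#'
#' `regressionImpute()` fits unconstrained least squares of the known test
#' entries on the training samples and reconstructs the missing entries from
#' the fitted weights. The minimum-2-norm solution is used (via the normal
#' equations when the system is comfortably full rank, with an SVD
#' pseudoinverse fallback at a relative singular-value cutoff of 1e-10).
#' Weights may be
#' negative and need not sum to one, so the imputed values are not confined
#' to the training range; at high missing fractions this baseline overfits
#' and produces severe artifacts.
#'
#' @param train an [ExpressionMatrix-class] of complete training profiles.
#' @param profile a [MaskedProfile-class].
#' @return An [ImputationResult-class].
#' @examples
#' pr <- MaskedProfile(c(1, NA, 3))
#' completedValues(zeroImpute(pr))           # 1 0 3
#' @name baselines
NULL

#' @rdname baselines
#' @export
zeroImpute <- function(profile) {
    t0 <- proc.time()[["elapsed"]]
    stopifnot(is(profile, "MaskedProfile"))
    completed <- profile@values
    completed[profile@mask] <- 0
    newResult(completed, uniformWeights(1L), "zero", t0, profile@sampleId)
}

#' @rdname baselines
#' @export
meanImpute <- function(train, profile) {
    t0 <- proc.time()[["elapsed"]]
    checkShapes(train, profile)
    completed <- profile@values
    if (any(profile@mask)) {
        X <- exprValues(train)
        completed[profile@mask] <-
            colMeans(X[, profile@mask, drop = FALSE])
    }
    newResult(completed, uniformWeights(nSamples(train)), "mean", t0,
              profile@sampleId)
}

#' @rdname baselines
#' @export
regressionImpute <- function(train, profile) {
    .regressionImpute(train, profile, trainGram = NULL)
}

.regressionImpute <- function(train, profile, trainGram = NULL) {
    t0 <- proc.time()[["elapsed"]]
    checkShapes(train, profile)
    known <- !profile@mask
    if (!any(known))
        stop("no-known-values: the profile has no observed entries")
    completed <- profile@values
    X <- exprValues(train)
    A <- t(X[, known, drop = FALSE])            # k x n
    b <- profile@values[known]
    w <- minNormSolve(A, b, X, known, trainGram)
    if (any(profile@mask))
        completed[profile@mask] <-
            as.numeric(crossprod(X[, profile@mask, drop = FALSE], w))
    wv <- new("WeightVector", w = w,
              residualNorm = sqrt(sum((A %*% w - b)^2)),
              iterations = 0L, converged = TRUE, residualTrace = numeric(0))
    newResult(completed, wv, "regression", t0, profile@sampleId)
}

# minimum-norm least squares via SVD with relative cutoff 1e-10
pinvSolve <- function(A, b, rcond = 1e-10) {
    sv <- svd(A)
    keep <- sv$d > rcond * sv$d[1L]
    if (!any(keep)) return(rep(0, ncol(A)))
    as.numeric(sv$v[, keep, drop = FALSE] %*%
        ((crossprod(sv$u[, keep, drop = FALSE], b)) / sv$d[keep]))
}

# minimum-norm least squares; well-conditioned full-rank systems go through
# the (dual) normal equations by Cholesky, which matches the pseudoinverse
# solution to machine precision; anything rank-deficient falls back to the
# SVD cutoff. trainGram (full-feature X X') lets batch callers form the
# known-block Gram by subtracting the masked block.
minNormSolve <- function(A, b, X, known, trainGram = NULL) {
    k <- nrow(A)
    n <- ncol(A)
    if (k >= n) {
        G <- if (!is.null(trainGram) && sum(!known) < k) {
            trainGram - tcrossprod(X[, !known, drop = FALSE])
        } else {
            crossprod(A)
        }
        R <- tryCatch(chol(G), error = function(e) NULL)
        if (!is.null(R) && min(diag(R)) > 1e-7 * max(diag(R)))
            return(as.numeric(backsolve(R, backsolve(R, crossprod(A, b),
                                                     transpose = TRUE))))
    } else {
        Gd <- tcrossprod(A)                     # k x k dual Gram
        R <- tryCatch(chol(Gd), error = function(e) NULL)
        if (!is.null(R) && min(diag(R)) > 1e-7 * max(diag(R)))
            return(as.numeric(crossprod(A,
                backsolve(R, backsolve(R, b, transpose = TRUE)))))
    }
    pinvSolve(A, b)
}
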