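#' Lasso-neighbour box-constrained imputation
#'
#' Two-stage comparator in the style of lasso-based neighbour imputation for
#' expression data. Stage 1 regresses the known test entries on the training
#' samples with a lasso penalty (coordinate descent via glmnet, no
#' intercept); the samples with nonzero coefficients form the neighbour
#' support. Stage 2 refits least squares over the selected neighbours with
#' each weight box-constrained to \[0, 1\] (L-BFGS-B), and the missing
#' entries are reconstructed from those weights. If the lasso support is
#' empty (penalty too large), the single nearest training sample in
#' Euclidean distance on the known features is copied, with a warning.
#'
#' When `lassoPenalty` is `NA`, it is selected by 5-fold cross validation
#' with deterministic folds; below 10 known entries CV is unreliable and a
#' small fixed penalty is used instead.
#'
#' @param train an [ExpressionMatrix-class] of complete training profiles.
#' @param profile a [MaskedProfile-class].
#' @param config a [ComparatorConfig-class]; only `lassoPenalty` is used.
#' @return An [ImputationResult-class] with full-length weights (zero
#'   outside the selected support, each in \[0, 1\]).
#' @export
viperLikeImpute <- function(train, profile, config = comparatorConfig()) {
    t0 <- proc.time()[["elapsed"]]
    checkShapes(train, profile)
    stopifnot(is(config, "ComparatorConfig"))
    known <- !profile@mask
    if (!any(known))
        stop("no-known-values: the profile has no observed entries")
    X <- exprValues(train)
    n <- nrow(X)
    completed <- profile@values
    if (!any(profile@mask))
        return(newResult(completed, uniformWeights(n), "viper_like", t0,
                         profile@sampleId))
    A <- t(X[, known, drop = FALSE])            # k x n
    b <- profile@values[known]
    k <- nrow(A)

    support <- integer(0)
    if (n >= 2L && k >= 2L) {
        lambda <- config@lassoPenalty
        if (is.na(lambda)) lambda <- selectLassoPenalty(A, b)
        fit <- glmnet::glmnet(A, b, alpha = 1, lambda = lambda,
                              intercept = FALSE, standardize = FALSE)
        beta <- as.numeric(coef(fit, s = lambda))[-1L]
        support <- which(beta != 0)
    }
    w <- rep(0, n)
    if (length(support) == 0L) {
        warning("empty lasso support for profile ", profile@sampleId,
                "; falling back to the nearest training sample")
        d2 <- rowSums((t(A) - matrix(b, n, k, byrow = TRUE))^2)
        nn <- which.min(d2)
        w[nn] <- 1
        completed[profile@mask] <- X[nn, profile@mask]
    } else {
        As <- A[, support, drop = FALSE]
        ws <- boxLeastSquares(As, b)
        w[support] <- ws
        completed[profile@mask] <-
            as.numeric(crossprod(X[support, profile@mask, drop = FALSE], ws))
    }
    rn <- sqrt(sum((A %*% w - b)^2))
    wv <- new("WeightVector", w = w, residualNorm = rn, iterations = 0L,
              converged = TRUE, residualTrace = numeric(0))
    newResult(completed, wv, "viper_like", t0, profile@sampleId)
}

#' Spectral-clustering nonnegative-regression imputation
#'
#' Comparator in the style of cluster-then-regress imputation: the training
#' samples are partitioned into `nClusters` groups by spectral clustering
#' (Gaussian affinity with median-distance bandwidth, symmetric normalised
#' Laplacian embedding, k-means with fixed seed 0); each profile is assigned
#' to the cluster whose centroid is nearest on the profile's known features,
#' and its missing entries are reconstructed by plain nonnegative least
#' squares (no sum constraint) over that cluster's members.
#'
#' @param train an [ExpressionMatrix-class] of complete training profiles.
#' @param profiles list of [MaskedProfile-class] objects (clustering is done
#'   once per call).
#' @param config a [ComparatorConfig-class]; only `nClusters` is used.
#' @return A list of [ImputationResult-class] with full-length nonnegative
#'   weights (zero outside the assigned cluster).
#' @export
scimputeLikeImpute <- function(train, profiles,
                               config = comparatorConfig()) {
    stopifnot(is(train, "ExpressionMatrix"), is(config, "ComparatorConfig"))
    X <- exprValues(train)
    n <- nrow(X)
    K <- config@nClusters
    if (K > n)
        stop("nClusters (", K, ") exceeds the number of training samples (",
             n, ")")
    if (length(profiles) == 0L) return(list())
    cl <- spectralClusters(X, K)
    centroids <- do.call(rbind, lapply(seq_len(K), function(k)
        colMeans(X[cl == k, , drop = FALSE])))
    lapply(profiles, function(profile) {
        t0 <- proc.time()[["elapsed"]]
        checkShapes(train, profile)
        known <- !profile@mask
        if (!any(known))
            stop("no-known-values: the profile has no observed entries")
        completed <- profile@values
        if (!any(profile@mask))
            return(newResult(completed, uniformWeights(n), "scimpute_like",
                             t0, profile@sampleId))
        b <- profile@values[known]
        d2 <- rowSums((centroids[, known, drop = FALSE] -
                       matrix(b, K, length(b), byrow = TRUE))^2)
        members <- which(cl == which.min(d2))
        Ac <- t(X[members, known, drop = FALSE])
        G0 <- crossprod(Ac)
        g0 <- as.numeric(crossprod(Ac, b))
        wv <- nncgls(Ac, b, maxIter = 30L, gram = G0, crossRhs = g0)
        pol <- polishNnls(G0, g0, wv@w, sumToOne = FALSE)
        if (!is.null(pol) && all(pol$w >= 0) &&
            (pol$converged ||
             objValue(G0, g0, b, pol$w) <=
                 objValue(G0, g0, b, wv@w) * (1 + 1e-9) + 1e-12)) {
            wv <- new("WeightVector", w = pol$w,
                      residualNorm = sqrt(sum((Ac %*% pol$w - b)^2)),
                      iterations = wv@iterations,
                      converged = pol$converged || wv@converged,
                      residualTrace = wv@residualTrace)
        }
        w <- rep(0, n)
        w[members] <- wv@w
        completed[profile@mask] <-
            as.numeric(crossprod(X[members, profile@mask, drop = FALSE],
                                 wv@w))
        full <- new("WeightVector", w = w, residualNorm = wv@residualNorm,
                    iterations = wv@iterations, converged = wv@converged,
                    residualTrace = wv@residualTrace)
        newResult(completed, full, "scimpute_like", t0, profile@sampleId)
    })
}

# internal helpers ----------------------------------------------------------

# deterministic 5-fold CV choice of the lasso penalty
selectLassoPenalty <- function(A, b) {
    k <- nrow(A)
    if (k < 10L) return(1e-3)
    foldid <- rep_len(1:5, k)
    cv <- glmnet::cv.glmnet(A, b, alpha = 1, intercept = FALSE,
                            standardize = FALSE, foldid = foldid, nfolds = 5,
                            nlambda = 30L)
    cv$lambda.min
}

# minimise ||A w - b||^2 over w in [0,1]^n (L-BFGS-B, analytic gradient)
boxLeastSquares <- function(A, b) {
    n <- ncol(A)
    AtA <- crossprod(A)
    Atb <- crossprod(A, b)
    fn <- function(w) {
        r <- A %*% w - b
        0.5 * sum(r^2)
    }
    gr <- function(w) as.numeric(AtA %*% w - Atb)
    out <- optim(rep(min(1, 1 / n), n), fn, gr, method = "L-BFGS-B",
                 lower = 0, upper = 1,
                 control = list(maxit = 500L, factr = 1e4))
    pmin(pmax(out$par, 0), 1)
}

# spectral clustering of the rows of X into K groups; fixed k-means seed
spectralClusters <- function(X, K) {
    n <- nrow(X)
    if (K == 1L) return(rep(1L, n))
    if (K == n) return(seq_len(n))
    d <- as.matrix(dist(X))
    sigma <- median(d[upper.tri(d)])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
    Aff <- exp(-d^2 / (2 * sigma^2))
    diag(Aff) <- 0
    deg <- rowSums(Aff)
    deg[deg <= 0] <- 1e-12
    Dm <- 1 / sqrt(deg)
    L <- diag(n) - (Dm * Aff) * rep(Dm, each = n)   # I - D^-1/2 A D^-1/2
    ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
    U <- ev$vectors[, seq(n, n - K + 1L), drop = FALSE]  # K smallest
    rn <- sqrt(rowSums(U^2))
    rn[rn == 0] <- 1
    U <- U / rn
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(0)
    kmeans(U, centers = K, nstart = 10L, iter.max = 100L)$cluster
}
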