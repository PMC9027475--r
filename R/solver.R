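#' Build the simplex-penalised least-squares system
#'
#' Assembles the design matrix and right-hand side whose nonnegative
#' least-squares solution carries out the regression and the weight
#' normalisation simultaneously: rows 1..k are the training samples
#' restricted to the profile's known features (columns index training
#' samples), and an extra row of the constant `constraintScale` pushes the
#' weight sum towards 1. With a stiff scale (default: 1000 times the largest
#' column 2-norm of the unaugmented design, chosen by [fliImpute()]) the
#' sum-to-one deviation of the NNLS solution is below 1e-6 in practice.
#'
#' @param train an [ExpressionMatrix-class] of complete training profiles.
#' @param profile a [MaskedProfile-class] with at least one known entry.
#' @param constraintScale positive weight of the sum-to-one penalty row.
#' @return A list with `design` ((k+1) x n matrix) and `rhs` (length k+1).
#' @examples
#' tr <- ExpressionMatrix(rbind(c(1, 0, 2), c(0, 1, 2)))
#' pr <- MaskedProfile(c(1, 0, NA))
#' buildConstrainedSystem(tr, pr, constraintScale = 10)
#' @export
buildConstrainedSystem <- function(train, profile, constraintScale) {
    stopifnot(is(train, "ExpressionMatrix"), is(profile, "MaskedProfile"))
    if (length(profile@mask) != nFeatures(train))
        stop("shape-mismatch: profile has ", length(profile@mask),
             " features, training matrix has ", nFeatures(train))
    if (!is.numeric(constraintScale) || length(constraintScale) != 1L ||
        !is.finite(constraintScale) || constraintScale <= 0)
        stop("constraintScale must be a single positive number")
    known <- !profile@mask
    if (!any(known))
        stop("no-known-values: the profile has no observed entries")
    X <- exprValues(train)                      # n x p
    design <- rbind(t(X[, known, drop = FALSE]), constraintScale)
    rhs <- c(profile@values[known], constraintScale)
    dimnames(design) <- NULL
    list(design = design, rhs = rhs)
}

#' Nonnegative conjugate-gradient least squares (active-set restarted CGLS)
#'
#' Minimises \eqn{\|A w - b\|_2^2} subject to \eqn{w \ge 0}. Conjugate
#' gradient runs on the normal equations of the currently free coordinates.
#' When a CG step would drive free coordinates negative, the full step is
#' projected onto the nonnegative orthant and accepted if it decreases the
#' residual (this retires many coordinates at once, as in
#' gradient-projection CG methods from image reconstruction); otherwise the
#' step is truncated at the first zero crossing. Either way the coordinates
#' that reach zero join the active set and CG restarts on the reduced face.
#' After each CG segment the Karush-Kuhn-Tucker conditions are checked on
#' the projected gradient; active coordinates with a negative gradient are
#' released. The iterate starts at the uniform vector (1/n, ..., 1/n), so
#' the returned objective never exceeds the objective of uniform weights,
#' and the residual norm is non-increasing along the whole trajectory.
#'
#' Because the number of weights (training samples) is small relative to
#' the number of observations, the Gram matrix \eqn{A'A} and \eqn{A'b} are
#' formed once up front, so every CG iteration works on an n x n in-cache
#' system; the returned residual norm is recomputed from the original
#' system.
#'
#' @param design numeric matrix `A` (m x n), all entries finite.
#' @param rhs numeric vector `b` of length m.
#' @param maxIter cap on total inner CG iterations (default 500).
#' @param tol relative projected-gradient tolerance for the KKT stopping
#'   test (default 1e-10, relative to `||A'b||`; the tight default resolves
#'   the data-space optimum even when a stiff sum-constraint penalty row
#'   dominates the gradient scale).
#' @param gram,crossRhs optional precomputed `crossprod(design)` and
#'   `crossprod(design, rhs)`, so callers imputing many profiles against
#'   the same training matrix can share the Gram computation.
#' @return A [WeightVector-class].
#' @examples
#' wv <- nncgls(diag(2), c(-1, 2))
#' imputeWeights(wv)      # (0, 2): one active bound
#' @export
nncgls <- function(design, rhs, maxIter = 500L, tol = 1e-10,
                   gram = NULL, crossRhs = NULL) {
    design <- as.matrix(design)
    storage.mode(design) <- "double"
    rhs <- as.numeric(rhs)
    if (!all(is.finite(design)) || !all(is.finite(rhs)))
        stop("invalid-input: design and rhs must be finite")
    if (nrow(design) < 1L || ncol(design) < 1L)
        stop("invalid-input: design must have at least one row and column")
    if (length(rhs) != nrow(design))
        stop("invalid-input: rhs length must equal nrow(design)")
    stopifnot(maxIter >= 1L, tol > 0)

    n <- ncol(design)
    G <- if (is.null(gram)) crossprod(design) else gram   # n x n, formed once
    Atb <- if (is.null(crossRhs)) as.numeric(crossprod(design, rhs))
           else as.numeric(crossRhs)
    btb <- sum(rhs^2)
    rssOf <- function(w) max(btb - 2 * sum(w * Atb) + sum(w * (G %*% w)), 0)

    w <- rep(1 / n, n)
    free <- rep(TRUE, n)
    gradRef <- max(sqrt(sum(Atb^2)), 1e-12)
    total <- 0L
    converged <- FALSE
    trace <- numeric(maxIter + 1L)
    rss <- rssOf(w)
    trace[1L] <- sqrt(rss)

    repeat {
        restart <- FALSE
        if (any(free)) {
            # CG on the face of the currently free coordinates; active
            # coordinates are zeroed in the search direction, so no
            # submatrix is ever formed. s = A'(b - Aw) throughout.
            s <- Atb - as.numeric(G %*% w)
            sf <- s
            sf[!free] <- 0
            gamma <- sum(sf^2)
            p <- sf
            while (total < maxIter && sqrt(gamma) > tol * gradRef) {
                q <- as.numeric(G %*% p)
                pq <- sum(p * q)
                if (pq <= 0) break
                alpha <- gamma / pq
                wNew <- w + alpha * p
                total <- total + 1L
                if (any(wNew[free] < 0)) {
                    # projected step first: retiring every crossing
                    # coordinate at once is far cheaper than one boundary
                    # hit per restart, and is accepted only if it keeps the
                    # residual decreasing
                    wProj <- pmax(wNew, 0)
                    rssProj <- rssOf(wProj)
                    if (rssProj < rss) {
                        w <- wProj
                        rss <- rssProj
                    } else {
                        crossing <- p < 0 & wNew < 0
                        step <- min(-w[crossing] / p[crossing])
                        w <- w + step * p
                        w[free & w < 1e-13] <- 0
                        rss <- rssOf(w)
                    }
                    free <- free & w > 0
                    trace[total + 1L] <- sqrt(rss)
                    restart <- TRUE
                    break
                }
                w <- wNew
                rss <- max(rss - alpha * gamma, 0)   # exact CG decrease
                trace[total + 1L] <- sqrt(rss)
                s <- s - alpha * q
                sf <- s
                sf[!free] <- 0
                gammaNew <- sum(sf^2)
                p <- sf + (gammaNew / gamma) * p
                gamma <- gammaNew
            }
            if (restart) next
        }
        # KKT check on the full gradient of 0.5*||Aw-b||^2 (g = -s)
        s <- Atb - as.numeric(G %*% w)
        pg <- -s
        pg[!free & s < 0] <- 0
        if (sqrt(sum(pg^2)) <= tol * gradRef) {
            converged <- TRUE
            break
        }
        viol <- !free & s > tol * gradRef
        if (any(viol) && total < maxIter) {
            free[viol] <- TRUE
        } else {
            break
        }
    }

    w[w < 0] <- 0
    new("WeightVector", w = w,
        residualNorm = sqrt(sum((design %*% w - rhs)^2)),
        iterations = total, converged = converged,
        residualTrace = trace[seq_len(total + 1L)])
}

# Exact refinement of a (possibly sum-constrained) nonnegative
# least-squares solution on the support identified by nncgls. Block
# principal pivoting (Kim-Park style): solve the unconstrained face system,
# move every negative primal out of the face and the most infeasible duals
# in, all at once; when the total infeasibility count stops improving, fall
# back to safeguarded single exchanges, which terminate finitely. G0 and g0
# are crossprod of the *unaugmented* data block and its right-hand side, so
# the sum-to-one constraint is handled exactly rather than through the
# penalty row. Returns NULL when the face systems are too degenerate.
polishNnls <- function(G0, g0, w0, sumToOne = TRUE, maxSolves = 400L) {
    n <- length(g0)
    tolP <- 0                       # primal feasibility: exact nonnegativity
    tolD <- 1e-7 * max(abs(g0), 1)  # dual feasibility, relative
    inFace <- w0 > 1e-3 * max(w0, 0)
    if (!any(inFace)) inFace[which.max(g0)] <- TRUE
    faceSolve <- function(Fs) {
        k <- length(Fs)
        Gff <- G0[Fs, Fs, drop = FALSE]
        K <- if (sumToOne)
            rbind(cbind(Gff, 1), c(rep(1, k), 0))
        else Gff
        rhsK <- if (sumToOne) c(g0[Fs], 1) else g0[Fs]
        sol <- tryCatch(solve(K, rhsK), error = function(e) NULL)
        if (is.null(sol)) {
            diag(K)[seq_len(k)] <- diag(K)[seq_len(k)] +
                1e-10 * max(mean(diag(Gff)), 1)
            sol <- tryCatch(solve(K, rhsK), error = function(e) NULL)
        }
        sol
    }
    bestInfeas <- Inf
    slack <- 3L                      # full-block exchanges left before
                                     # dropping to single exchanges
    solves <- 0L
    while (solves < maxSolves) {
        Fset <- which(inFace)
        sol <- faceSolve(Fset)
        solves <- solves + 1L
        if (is.null(sol)) return(NULL)
        z <- sol[seq_along(Fset)]
        lambda <- if (sumToOne) sol[length(Fset) + 1L] else 0
        negs <- Fset[z < tolP]
        w <- numeric(n)
        w[Fset] <- pmax(z, 0)
        g <- as.numeric(G0[, Fset, drop = FALSE] %*% pmax(z, 0)) - g0 + lambda
        viols <- which(g < -tolD & !inFace)
        nInf <- length(negs) + length(viols)
        if (nInf == 0L)
            return(list(w = w, converged = TRUE))
        if (nInf < bestInfeas) {
            bestInfeas <- nInf
            slack <- 3L
        } else {
            slack <- slack - 1L
        }
        if (slack > 0L) {
            # full block exchange
            inFace[negs] <- FALSE
            inFace[viols] <- TRUE
        } else {
            # safeguarded single exchange: flip only the worst offender
            if (length(negs)) {
                worst <- negs[which.min(z[match(negs, Fset)])]
                inFace[worst] <- FALSE
            } else {
                inFace[viols[which.min(g[viols])]] <- TRUE
            }
        }
        if (!any(inFace)) inFace[which.max(g0)] <- TRUE
    }
    NULL
}
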