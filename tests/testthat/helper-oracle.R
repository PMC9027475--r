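# Independent brute-force oracles for small constrained least-squares
# problems. These enumerate candidate active sets exhaustively and solve
# each face by a direct linear solve, so they share no code path with the
# package's CG/pivoting solver.

# minimise ||A w - b||^2  s.t.  w >= 0, sum(w) = 1   (exhaustive supports)
simplexLsOracle <- function(A, b) {
    n <- ncol(A)
    best <- list(obj = Inf, w = NULL)
    for (bits in seq_len(2^n - 1L)) {
        S <- which(bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0L)
        As <- A[, S, drop = FALSE]
        k <- length(S)
        K <- rbind(cbind(crossprod(As), rep(1, k)), c(rep(1, k), 0))
        sol <- tryCatch(solve(K, c(crossprod(As, b), 1)),
                        error = function(e) NULL)
        if (is.null(sol)) next
        wS <- sol[seq_len(k)]
        if (any(wS < -1e-9)) next
        wS <- pmax(wS, 0)
        wS <- wS / sum(wS)
        w <- numeric(n)
        w[S] <- wS
        obj <- sum((A %*% w - b)^2)
        if (obj < best$obj) best <- list(obj = obj, w = w)
    }
    best
}

# minimise ||A w - b||^2  s.t.  w >= 0   (exhaustive supports)
nnlsOracle <- function(A, b) {
    n <- ncol(A)
    best <- list(obj = sum(b^2), w = numeric(n))   # empty support
    for (bits in seq_len(2^n - 1L)) {
        S <- which(bitwAnd(bits, 2^(seq_len(n) - 1L)) > 0L)
        As <- A[, S, drop = FALSE]
        wS <- tryCatch(solve(crossprod(As), crossprod(As, b)),
                       error = function(e) NULL)
        if (is.null(wS)) next
        wS <- as.numeric(wS)
        if (any(wS < -1e-9)) next
        w <- numeric(n)
        w[S] <- pmax(wS, 0)
        obj <- sum((A %*% w - b)^2)
        if (obj < best$obj) best <- list(obj = obj, w = w)
    }
    best
}

# minimise ||A w - b||^2  s.t.  0 <= w <= 1   (enumerate bound patterns:
# each coordinate free, at 0, or at 1)
boxLsOracle <- function(A, b) {
    n <- ncol(A)
    best <- list(obj = Inf, w = NULL)
    patterns <- expand.grid(rep(list(c("free", "lo", "hi")), n),
                            stringsAsFactors = FALSE)
    for (r in seq_len(nrow(patterns))) {
        pat <- unlist(patterns[r, ], use.names = FALSE)
        w <- numeric(n)
        w[pat == "hi"] <- 1
        Fs <- which(pat == "free")
        if (length(Fs)) {
            res <- b - A %*% w
            Af <- A[, Fs, drop = FALSE]
            wF <- tryCatch(solve(crossprod(Af), crossprod(Af, res)),
                           error = function(e) NULL)
            if (is.null(wF)) next
            wF <- as.numeric(wF)
            if (any(wF < -1e-9) || any(wF > 1 + 1e-9)) next
            w[Fs] <- pmin(pmax(wF, 0), 1)
        }
        obj <- sum((A %*% w - b)^2)
        if (obj < best$obj) best <- list(obj = obj, w = w)
    }
    best
}
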