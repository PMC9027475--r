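#' Generate synthetic handwritten-digit images
#'
#' Renders 28 x 28 grayscale digit images from hand-coded stroke templates
#' (one per digit class 0-9) and flattens them to 784-feature expression-like
#' profiles with pixel values in \[0, 1\]. Each image applies a random affine
#' jitter to the template strokes — rotation up to 5 degrees, translation up
#' to 1 px per axis, scale within +-5% — followed by additive Gaussian pixel
#' noise of standard deviation `noiseSd`, clipped back to \[0, 1\]. The
#' jitter is deliberately modest: the generator emulates machine-rendered
#' digit sets on which simple linear classifiers are essentially perfect
#' (held-out softmax accuracy ~1), which is the premise of the
#' classification-retention experiments.
#'
#' @param nPerClass images per class (`>= 1`).
#' @param classes digit classes to render, a subset of 0:9.
#' @param noiseSd standard deviation of the additive pixel noise.
#' @param seed integer seed controlling jitter and noise.
#' @param jitter logical; `FALSE` renders the raw templates (no affine
#'   jitter), useful for inspecting the stroke definitions.
#' @return An [ExpressionMatrix-class] with `length(classes) * nPerClass`
#'   samples, 784 features named `px<row>_<col>`, and digit labels.
#' @examples
#' d <- genDigits(2, classes = c(1, 7), noiseSd = 0, seed = 1)
#' dim(exprValues(d))
#' @export
genDigits <- function(nPerClass, classes = 0:9, noiseSd = 0.05, seed = 1,
                      jitter = TRUE) {
    stopifnot(nPerClass >= 1L, noiseSd >= 0)
    classes <- as.integer(classes)
    if (length(classes) == 0L || !all(classes %in% 0:9))
        stop("classes must be a non-empty subset of 0:9")
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))

    grid <- expand.grid(y = 0:27, x = 0:27)     # row-major flattening
    px <- grid$x
    py <- 27 - grid$y                            # y grows upward in templates
    nTot <- length(classes) * nPerClass
    out <- matrix(0, nTot, 784L)
    labels <- integer(nTot)
    row <- 0L
    for (cl in classes) {
        pts <- digitStrokes(cl)                  # 2-column matrix (x, y)
        for (i in seq_len(nPerClass)) {
            row <- row + 1L
            p <- pts
            if (jitter) {
                th <- runif(1, -5, 5) * pi / 180
                sc <- runif(1, 0.95, 1.05)
                dx <- runif(1, -1, 1)
                dy <- runif(1, -1, 1)
                cx <- p[, 1L] - 13.5
                cy <- p[, 2L] - 13.5
                p <- cbind(13.5 + dx + sc * (cos(th) * cx - sin(th) * cy),
                           13.5 + dy + sc * (sin(th) * cx + cos(th) * cy))
            }
            img <- rasterizeStrokes(p, px, py)
            if (noiseSd > 0)
                img <- img + rnorm(784L, 0, noiseSd)
            out[row, ] <- pmin(pmax(img, 0), 1)
            labels[row] <- cl
        }
    }
    ExpressionMatrix(out,
        sampleIds = sprintf("img%04d_d%d", seq_len(nTot), labels),
        featureIds = sprintf("px%d_%d", grid$y + 1L, grid$x + 1L),
        labels = factor(labels, levels = sort(unique(classes))))
}

#' Generate correlated multivariate-normal expression data
#'
#' Draws `n` samples from a zero-mean multivariate normal with
#' block-diagonal correlation (blocks of `blockSize` features, constant
#' off-diagonal correlation `withinBlockCorr` within each block), emulating
#' the strong inter-feature correlation of miRNA expression panels. Class
#' `c` (labels cycle over `nClasses`) receives a mean shift of `classShift`
#' on its own feature subset (features with index congruent to `c` modulo
#' `nClasses`); columns are then scaled to unit variance over the generated
#' sample (no centring, so class signal is preserved).
#'
#' @param n number of samples.
#' @param p number of features (`blockSize` must divide `p`).
#' @param blockSize size of each correlated block.
#' @param withinBlockCorr within-block correlation, in \[0, 1).
#' @param seed integer seed.
#' @param nClasses number of classes (1 = unlabelled structure only).
#' @param classShift mean shift applied to each class's feature subset.
#' @return An [ExpressionMatrix-class] with labels `c1..c<nClasses>`.
#' @export
genMVN <- function(n, p = 200L, blockSize = 20L, withinBlockCorr = 0.8,
                   seed = 1, nClasses = 2L, classShift = 1) {
    stopifnot(n >= 2L, p >= 1L, blockSize >= 1L, nClasses >= 1L)
    if (withinBlockCorr < 0 || withinBlockCorr >= 1)
        stop("withinBlockCorr must be in [0, 1): the equicorrelation ",
             "matrix is not positive definite otherwise")
    if (p %% blockSize != 0L)
        stop("blockSize must divide p")
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))

    R <- matrix(withinBlockCorr, blockSize, blockSize)
    diag(R) <- 1
    U <- chol(R)
    X <- matrix(rnorm(n * p), n, p)
    for (b in seq_len(p %/% blockSize)) {
        idx <- ((b - 1L) * blockSize + 1L):(b * blockSize)
        X[, idx] <- X[, idx] %*% U
    }
    cls <- rep_len(seq_len(nClasses), n)
    if (nClasses > 1L && classShift != 0) {
        for (c in seq_len(nClasses)) {
            feat <- which((seq_len(p) - 1L) %% nClasses == (c - 1L))
            X[cls == c, feat] <- X[cls == c, feat] + classShift
        }
    }
    sds <- apply(X, 2L, sd)
    sds[sds == 0] <- 1
    X <- sweep(X, 2L, sds, "/")
    ExpressionMatrix(X,
        sampleIds = sprintf("mvn%04d", seq_len(n)),
        featureIds = sprintf("g%03d", seq_len(p)),
        labels = if (nClasses > 1L) factor(paste0("c", cls)) else NULL)
}

#' Mask a fixed fraction of each sample's features uniformly at random
#'
#' Every sample receives its own independent mask of exactly
#' `floor(fraction * p + 0.5)` missing features (round half away from zero),
#' drawn uniformly without replacement. The complete input is returned
#' alongside as ground truth for error computation.
#'
#' @param X an [ExpressionMatrix-class] to mask.
#' @param fraction missing-dimension fraction in \[0, 1).
#' @param seed integer seed; identical seeds give identical masks.
#' @return A list with `profiles` (list of [MaskedProfile-class]) and
#'   `truth` (the input `X`).
#' @examples
#' d <- genMVN(4, p = 20, blockSize = 5, seed = 1)
#' m <- applyMissingness(d, 0.5, seed = 1)
#' sum(m$profiles[[1]]@mask)    # 10
#' @export
applyMissingness <- function(X, fraction, seed = 1) {
    stopifnot(is(X, "ExpressionMatrix"))
    if (fraction < 0 || fraction >= 1)
        stop("fraction must be in [0, 1)")
    p <- nFeatures(X)
    count <- floor(fraction * p + 0.5)
    if (count >= p)
        stop("fraction ", fraction, " would leave no known entries")
    V <- exprValues(X)
    ids <- sampleIds(X)
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(as.integer(seed))
    profiles <- lapply(seq_len(nrow(V)), function(i) {
        mask <- rep(FALSE, p)
        if (count > 0L)
            mask[sample.int(p, count)] <- TRUE
        MaskedProfile(V[i, ], mask = mask, sampleId = ids[i])
    })
    list(profiles = profiles, truth = X)
}

# stroke templates ----------------------------------------------------------
# Each digit is a dense polyline/arc point set in a 28 x 28 box, x right,
# y up, spacing ~0.35 px. Shapes are deliberately clean and well separated.

digitStrokes <- function(class) {
    seg <- function(x0, y0, x1, y1) {
        len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
        t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.35)))
        cbind(x0 + t * (x1 - x0), y0 + t * (y1 - y0))
    }
    arc <- function(cx, cy, rx, ry, from, to) {
        len <- (abs(to - from) * pi / 180) * max(rx, ry)
        a <- seq(from, to, length.out = max(2L, ceiling(len / 0.35))) *
            pi / 180
        cbind(cx + rx * cos(a), cy + ry * sin(a))
    }
    switch(as.character(class),
        "0" = arc(14, 14, 6, 9, 0, 360),
        "1" = rbind(seg(14, 4, 14, 23), seg(10, 19, 14, 23), seg(10, 4, 18, 4)),
        "2" = rbind(arc(14, 18, 5, 5, 180, 0), seg(19, 18, 9, 5),
                    seg(9, 5, 20, 5)),
        "3" = rbind(arc(13, 18.5, 5, 4.5, 150, -90), arc(13, 9.5, 5, 4.5,
                    90, -150)),
        "4" = rbind(seg(16, 23, 16, 4), seg(16, 23, 8, 11), seg(8, 11, 21, 11)),
        "5" = rbind(seg(19, 22, 9, 22), seg(9, 22, 9, 14),
                    arc(12.5, 9.5, 6, 5, 110, -120)),
        "6" = rbind(seg(17, 23, 11, 13), arc(13.5, 9, 5, 5, 0, 360)),
        "7" = rbind(seg(8, 22, 20, 22), seg(20, 22, 11, 4)),
        "8" = rbind(arc(14, 18, 4.5, 4.5, 0, 360), arc(14, 8.5, 5.5, 5.5,
                    0, 360)),
        "9" = rbind(arc(13.5, 17, 5, 5, 0, 360), seg(18.5, 17, 15, 4)),
        stop("invalid digit class: ", class))
}

# distance-to-stroke rasterisation with a Gaussian pen profile
rasterizeStrokes <- function(pts, px, py, pen = 0.75) {
    dx <- outer(px, pts[, 1L], "-")
    dy <- outer(py, pts[, 2L], "-")
    mind2 <- do.call(pmin, c(asplit(dx^2 + dy^2, 2L), list(na.rm = FALSE)))
    exp(-mind2 / (2 * pen^2))
}
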