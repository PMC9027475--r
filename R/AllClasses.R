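#' Complete expression matrix with sample labels
#'
#' `ExpressionMatrix` is the package's container for a complete (no missing
#' entries) expression data set: `n` samples measured on `p` features, with
#' optional per-sample class labels. It extends
#' [SummarizedExperiment::SummarizedExperiment]; internally the single assay
#' `"expr"` is stored features-by-samples in the Bioconductor orientation,
#' while the constructor and [exprValues()] present the samples-by-features
#' orientation natural for regression on profiles.
#'
#' @slot .Data see [SummarizedExperiment::SummarizedExperiment]
#' @seealso [ExpressionMatrix()], [exprValues()], [sampleLabels()]
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
    if (!"expr" %in% SummarizedExperiment::assayNames(object))
        return("assay 'expr' is required")
    m <- SummarizedExperiment::assay(object, "expr")
    if (!is.numeric(m))
        return("assay 'expr' must be numeric")
    if (ncol(m) < 1L || nrow(m) < 1L)
        return("need at least one sample and one feature")
    if (anyNA(m) || !all(is.finite(m)))
        return("training/truth matrices must be complete: no NA or non-finite entries")
    if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
        return("sample IDs must be present and unique")
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
        return("feature IDs must be present and unique")
    lab <- object$label
    if (!is.null(lab) && length(lab) != ncol(m))
        return("labels must have one entry per sample")
    TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix, samples in rows, features in columns.
#' @param sampleIds character vector of unique sample identifiers
#'   (default: `rownames(values)`).
#' @param featureIds character vector of unique feature identifiers
#'   (default: `colnames(values)`).
#' @param labels optional class labels, one per sample (coerced to factor).
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' x <- ExpressionMatrix(matrix(1:6, 2, 3), c("s1", "s2"),
#'                       c("f1", "f2", "f3"), labels = c("a", "b"))
#' exprValues(x)
#' @export
ExpressionMatrix <- function(values, sampleIds = rownames(values),
                             featureIds = colnames(values), labels = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(sampleIds))
        sampleIds <- paste0("s", seq_len(nrow(values)))
    if (is.null(featureIds))
        featureIds <- paste0("f", seq_len(ncol(values)))
    expr <- t(values)
    dimnames(expr) <- list(as.character(featureIds), as.character(sampleIds))
    cd <- if (is.null(labels)) {
        S4Vectors::DataFrame(row.names = colnames(expr))
    } else {
        S4Vectors::DataFrame(label = factor(labels), row.names = colnames(expr))
    }
    new("ExpressionMatrix",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(expr = expr), colData = cd))
}

#' One test profile with a missingness mask
#'
#' Holds a single test expression profile together with a boolean mask
#' (`TRUE` = the entry is missing and must be imputed). Values under the mask
#' are ignored by all imputers; known values must be finite.
#'
#' @slot values numeric vector, length = number of features.
#' @slot mask logical vector, same length; `TRUE` marks a missing entry.
#' @slot sampleId single sample identifier.
#' @exportClass MaskedProfile
setClass("MaskedProfile",
    representation(values = "numeric", mask = "logical", sampleId = "character"))

setValidity("MaskedProfile", function(object) {
    if (length(object@mask) != length(object@values))
        return("mask length must equal feature count")
    if (anyNA(object@mask))
        return("mask must not contain NA")
    known <- object@values[!object@mask]
    if (length(known) && !all(is.finite(known)))
        return("known entries must be finite")
    if (length(object@sampleId) != 1L)
        return("sampleId must be a single string")
    TRUE
})

#' Construct a MaskedProfile
#'
#' @param values numeric profile; entries under the mask may be `NA`.
#' @param mask logical missingness mask; defaults to `is.na(values)`.
#' @param sampleId sample identifier.
#' @return A [MaskedProfile-class] object.
#' @export
MaskedProfile <- function(values, mask = is.na(values), sampleId = "sample") {
    new("MaskedProfile", values = as.numeric(values), mask = as.logical(mask),
        sampleId = as.character(sampleId))
}

#' Regression weights on (or near) the probability simplex
#'
#' Result of the nonnegative least-squares solve: one weight per training
#' sample, the final least-squares residual norm, the number of inner
#' conjugate-gradient iterations used, a convergence flag, and the trace of
#' the residual norm after each accepted CG step (restarts included), which
#' is non-increasing by construction.
#'
#' @slot w numeric weights. [nncgls()] guarantees componentwise
#'   nonnegativity after the final clip; the unconstrained
#'   [regressionImpute()] baseline stores signed weights here.
#' @slot residualNorm `||design %*% w - rhs||_2` at the returned `w`.
#' @slot iterations total inner CG iterations.
#' @slot converged whether the projected-gradient KKT test passed.
#' @slot residualTrace residual norm after each accepted step.
#' @exportClass WeightVector
setClass("WeightVector",
    representation(w = "numeric", residualNorm = "numeric",
                   iterations = "integer", converged = "logical",
                   residualTrace = "numeric"))

setValidity("WeightVector", function(object) {
    if (length(object@residualNorm) != 1L || object@residualNorm < 0)
        return("residualNorm must be a single nonnegative number")
    if (length(object@iterations) != 1L || object@iterations < 0L)
        return("iterations must be a single nonnegative integer")
    if (anyNA(object@w) || !all(is.finite(object@w)))
        return("weights must be finite")
    TRUE
})

#' Result of imputing one profile
#'
#' @slot completed numeric vector: the profile with missing entries filled in;
#'   known entries are passed through unchanged.
#' @slot weights the [WeightVector-class] used (uniform placeholder for
#'   methods that do not fit weights, e.g. zero/mean imputation).
#' @slot method imputation method name.
#' @slot elapsedSeconds wall time spent on this profile.
#' @slot sampleId identifier of the imputed profile.
#' @exportClass ImputationResult
setClass("ImputationResult",
    representation(completed = "numeric", weights = "WeightVector",
                   method = "character", elapsedSeconds = "numeric",
                   sampleId = "character"))

#' Hyperparameters for the comparator imputers
#'
#' The two literature-style comparators each take one hyperparameter:
#' `lassoPenalty` for the lasso neighbour-selection stage of
#' [viperLikeImpute()] (`NA` = choose by deterministic 5-fold cross
#' validation) and `nClusters` for the spectral clustering stage of
#' [scimputeLikeImpute()].
#'
#' @slot lassoPenalty positive lasso penalty, or `NA` for CV selection.
#' @slot nClusters number of spectral clusters (`>= 1`).
#' @exportClass ComparatorConfig
setClass("ComparatorConfig",
    representation(lassoPenalty = "numeric", nClusters = "integer"),
    prototype(lassoPenalty = NA_real_, nClusters = 2L))

setValidity("ComparatorConfig", function(object) {
    if (length(object@lassoPenalty) != 1L)
        return("lassoPenalty must be a single number (NA = select by CV)")
    if (!is.na(object@lassoPenalty) && object@lassoPenalty <= 0)
        return("lassoPenalty must be > 0")
    if (length(object@nClusters) != 1L || is.na(object@nClusters) ||
        object@nClusters < 1L)
        return("nClusters must be a single integer >= 1")
    TRUE
})

#' @param lassoPenalty see slot description.
#' @param nClusters see slot description.
#' @rdname ComparatorConfig-class
#' @return `comparatorConfig()` returns a validated `ComparatorConfig`.
#' @export
comparatorConfig <- function(lassoPenalty = NA_real_, nClusters = 2L) {
    new("ComparatorConfig", lassoPenalty = as.numeric(lassoPenalty),
        nClusters = as.integer(nClusters))
}

#' Fitted softmax (multinomial logistic) classifier
#'
#' Wraps a ridge-penalised multinomial logistic fit together with the
#' training-set standardisation statistics, so that prediction standardises
#' new data exactly as the training data were standardised.
#'
#' @slot fit the underlying glmnet fit.
#' @slot center,scale per-feature training mean and standard deviation
#'   (zero-variance features get scale 1).
#' @slot classes class labels in model order.
#' @slot lambda ridge penalty used at prediction time.
#' @exportClass SoftmaxModel
setClass("SoftmaxModel",
    representation(fit = "ANY", center = "numeric", scale = "numeric",
                   classes = "character", lambda = "numeric"))

#' Missing-fraction sweep results
#'
#' Long-format results of [runSweep()]: one row per (method, fraction) with
#' classification retention metrics and imputation-error statistics, plus a
#' per-sample table (`sweepSamples()`) holding each profile's relative error
#' and imputation time, from which [summarizeSweep()] pools the timing
#' statistics exactly.
#'
#' @slot table data.frame with columns `method`, `fraction`, `auc`, `acc`,
#'   `f1`, `eps_mu`, `eps_sigma`, `eps_max`, `t_mu`, `t_sigma`, `t_max`.
#' @slot samples data.frame with columns `method`, `fraction`, `sample`,
#'   `eps`, `time`.
#' @exportClass SweepResult
setClass("SweepResult",
    representation(table = "data.frame", samples = "data.frame"))
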