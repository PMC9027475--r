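#' @name accessors
#' @title Accessors for fliImpute classes
#' @description Small accessor generics: slot access is never needed by users.
#' @param x an object of the documented class.
#' @return `exprValues()` a samples-by-features numeric matrix;
#'   `sampleIds()`/`featureIds()` character vectors; `sampleLabels()` a factor
#'   or `NULL`; `nSamples()`/`nFeatures()` integers; `completedValues()` the
#'   imputed profile; `imputeWeights()` the numeric weight vector;
#'   `sweepTable()`/`sweepSamples()` data.frames.
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname accessors
#' @export
setGeneric("sampleLabels", function(x) standardGeneric("sampleLabels"))

#' @rdname accessors
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname accessors
#' @export
setGeneric("completedValues", function(x) standardGeneric("completedValues"))

#' @rdname accessors
#' @export
setGeneric("imputeWeights", function(x) standardGeneric("imputeWeights"))

#' @rdname accessors
#' @export
setGeneric("sweepTable", function(x) standardGeneric("sweepTable"))

#' @rdname accessors
#' @export
setGeneric("sweepSamples", function(x) standardGeneric("sweepSamples"))

#' @rdname accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x)
    t(SummarizedExperiment::assay(x, "expr")))

#' @rdname accessors
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("featureIds", "ExpressionMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("sampleLabels", "ExpressionMatrix", function(x) x$label)

#' @rdname accessors
#' @export
setMethod("nSamples", "ExpressionMatrix", function(x) ncol(x))

#' @rdname accessors
#' @export
setMethod("nFeatures", "ExpressionMatrix", function(x) nrow(x))

#' @rdname accessors
#' @export
setMethod("completedValues", "ImputationResult", function(x) x@completed)

#' @rdname accessors
#' @export
setMethod("imputeWeights", "ImputationResult", function(x) x@weights@w)

#' @rdname accessors
#' @export
setMethod("imputeWeights", "WeightVector", function(x) x@w)

#' @rdname accessors
#' @export
setMethod("sweepTable", "SweepResult", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("sweepSamples", "SweepResult", function(x) x@samples)

setMethod("show", "MaskedProfile", function(object) {
    cat("MaskedProfile", object@sampleId, "-", length(object@values),
        "features,", sum(object@mask), "missing\n")
})

setMethod("show", "WeightVector", function(object) {
    cat(sprintf(
        "WeightVector: %d weights, sum=%.6f, residual=%.4g, %d iters, %s\n",
        length(object@w), sum(object@w), object@residualNorm,
        object@iterations,
        if (object@converged) "converged" else "not converged"))
})

setMethod("show", "ImputationResult", function(object) {
    cat(sprintf("ImputationResult[%s] %s: %d features (%.3g s)\n",
        object@method, object@sampleId, length(object@completed),
        object@elapsedSeconds))
})

setMethod("show", "SweepResult", function(object) {
    cat("SweepResult:", nrow(object@table), "method x fraction rows,",
        length(unique(object@table$method)), "methods\n")
    print(utils::head(object@table, 4))
})
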