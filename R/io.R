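#' Read and write expression matrices and profiles
#'
#' @description
#' `readExpressionMatrix()` reads a complete matrix from CSV/TSV: header row
#' of feature IDs, first column of sample IDs, optional `label` column.
#' Missing cells are an error here — training (and truth) matrices must be
#' complete; use `readProfiles()` for test data with missing entries.
#'
#' `readProfiles()` reads test profiles from the same dialect; empty cells
#' or `NA` mark missing entries, or a separate 0/1 mask file of the same
#' shape can be supplied (1 = missing).
#'
#' `writeExpressionMatrix()` writes the same dialect back (round-trips
#' exactly through `readExpressionMatrix()`).
#'
#' The delimiter is sniffed from the extension (`.tsv`/`.tab` = tab,
#' otherwise comma) and can be overridden with `sep`.
#'
#' @param path file to read or write.
#' @param sep field delimiter, or `NULL` to sniff from the extension.
#' @param maskPath optional 0/1 mask file (same shape as the profile file).
#' @param x an [ExpressionMatrix-class] to write.
#' @return `readExpressionMatrix()` an [ExpressionMatrix-class];
#'   `readProfiles()` a list of [MaskedProfile-class];
#'   `writeExpressionMatrix()` the path, invisibly.
#' @name expression-io
NULL

sniffSep <- function(path, sep) {
    if (!is.null(sep)) return(sep)
    if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
}

readTable <- function(path, sep) {
    df <- read.csv(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
    if (ncol(df) < 2L)
        stop("expected a sample-ID column plus at least one feature")
    ids <- as.character(df[[1L]])
    if (anyDuplicated(ids))
        stop("duplicate-id: sample IDs must be unique")
    df <- df[, -1L, drop = FALSE]
    labels <- NULL
    if ("label" %in% names(df)) {
        labels <- df[["label"]]
        df <- df[, names(df) != "label", drop = FALSE]
    }
    bad <- !vapply(df, is.numeric, logical(1))
    if (any(bad))
        stop("non-numeric cells in feature column(s): ",
             paste(names(df)[bad], collapse = ", "))
    m <- as.matrix(df)
    rownames(m) <- ids
    list(values = m, labels = labels)
}

#' @rdname expression-io
#' @export
readExpressionMatrix <- function(path, sep = NULL) {
    tb <- readTable(path, sniffSep(path, sep))
    if (anyNA(tb$values))
        stop("matrix contains missing entries; complete data required ",
             "(use readProfiles() for test data with missing values)")
    ExpressionMatrix(tb$values, labels = tb$labels)
}

#' @rdname expression-io
#' @export
readProfiles <- function(path, maskPath = NULL, sep = NULL) {
    tb <- readTable(path, sniffSep(path, sep))
    V <- tb$values
    if (is.null(maskPath)) {
        masks <- is.na(V)
    } else {
        mk <- readTable(maskPath, sniffSep(maskPath, sep))$values
        if (!identical(dim(mk), dim(V)))
            stop("mask file shape does not match the profile file")
        masks <- (mk != 0) | is.na(V)    # NA cells are missing regardless
    }
    lapply(seq_len(nrow(V)), function(i)
        MaskedProfile(V[i, ], mask = masks[i, ], sampleId = rownames(V)[i]))
}

#' @rdname expression-io
#' @export
writeExpressionMatrix <- function(x, path, sep = NULL) {
    stopifnot(is(x, "ExpressionMatrix"))
    sep <- sniffSep(path, sep)
    V <- exprValues(x)
    df <- data.frame(sample = sampleIds(x), V, check.names = FALSE)
    lab <- sampleLabels(x)
    if (!is.null(lab)) df$label <- as.character(lab)
    write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write imputation/sweep outputs and a reproducibility manifest
#'
#' Writes whichever outputs are supplied into `dir`: the completed test
#' matrix (`completed.csv`), the long-format sweep table (`sweep.csv`), the
#' per-method grid-mean summary (`summary.csv`), and a JSON run manifest
#' (`manifest.json`) recording the configuration, seed and package version
#' so a run can be reproduced exactly.
#'
#' @param dir output directory (created if needed).
#' @param completed optional [ExpressionMatrix-class] of completed profiles.
#' @param sweep optional [SweepResult-class].
#' @param manifest optional named list of run parameters (seed, methods, ...).
#' @return Character vector of the files written, invisibly.
#' @export
writeResults <- function(dir, completed = NULL, sweep = NULL,
                         manifest = NULL) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
        stop("cannot create output directory ", dir)
    written <- character(0)
    if (!is.null(completed)) {
        f <- file.path(dir, "completed.csv")
        writeExpressionMatrix(completed, f)
        written <- c(written, f)
    }
    if (!is.null(sweep)) {
        f <- file.path(dir, "sweep.csv")
        write.csv(sweepTable(sweep), f, row.names = FALSE, quote = FALSE)
        s <- file.path(dir, "summary.csv")
        write.csv(summarizeSweep(sweep), s, row.names = FALSE, quote = FALSE)
        written <- c(written, f, s)
    }
    if (!is.null(manifest)) {
        f <- file.path(dir, "manifest.json")
        manifest$package <- "fliImpute"
        manifest$version <- as.character(utils::packageVersion("fliImpute"))
        jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                             pretty = TRUE)
        written <- c(written, f)
    }
    invisible(written)
}
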