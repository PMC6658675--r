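#' Read a tab-separated expression table
#'
#' Reads firehose-style RSEM normalized-count tables: tab-separated text, one
#' header row, first column holding identifiers. With
#' `orientation = "genes_in_rows"` (the firehose layout) the header row
#' carries sample ids and the first column gene ids; with
#' `"samples_in_rows"` the table is the transpose. Either way the returned
#' matrix is oriented samples x genes.
#'
#' @param path path to a TSV file.
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @return numeric matrix, samples in rows, genes in columns.
#' @export
readExpressionTable <- function(path,
                                orientation = c("genes_in_rows",
                                                "samples_in_rows")) {
    orientation <- match.arg(orientation)
    if (!file.exists(path)) stop("expression file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, colClasses = "character")
    if (nrow(tab) == 0L || ncol(tab) < 2L)
        stop("empty or malformed expression table: ", path)
    ids <- tab[[1L]]
    body <- as.matrix(tab[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(body), dim = dim(body),
                                  dimnames = dimnames(body)))
    if (anyNA(num)) {
        bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
        stop(sprintf("non-numeric value at row %d, column '%s' of %s",
                     bad[["row"]], colnames(body)[bad[["col"]]], path))
    }
    rownames(num) <- ids
    if (orientation == "genes_in_rows") num <- t(num)
    if (anyDuplicated(colnames(num))) {
        dup <- colnames(num)[duplicated(colnames(num))][1L]
        stop("duplicate gene id: ", dup)
    }
    if (anyDuplicated(rownames(num))) {
        dup <- rownames(num)[duplicated(rownames(num))][1L]
        stop("duplicate sample id: ", dup)
    }
    num
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpressionTable()]; values round-trip to near machine
#' precision (15 significant digits).
#'
#' @param x samples x genes numeric matrix with dimnames.
#' @param path output path.
#' @param orientation layout to write; see [readExpressionTable()].
#' @param idColumn name for the identifier column header.
#' @export
writeExpressionTable <- function(x, path,
                                 orientation = c("genes_in_rows",
                                                 "samples_in_rows"),
                                 idColumn = "gene_id") {
    orientation <- match.arg(orientation)
    m <- if (orientation == "genes_in_rows") t(x) else x
    df <- data.frame(id = rownames(m),
                     format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1L] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a clinical survival table
#'
#' Expects a TSV with columns `sample_id`, `time_days` (positive) and
#' `censored` (0 = event observed, 1 = right-censored).
#'
#' @param path path to a TSV file.
#' @return data.frame with columns `sample_id` (character), `time_days`
#'   (numeric) and `censored` (logical).
#' @export
readClinicalTable <- function(path) {
    if (!file.exists(path)) stop("clinical file not found: ", path)
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE,
                             stringsAsFactors = FALSE)
    need <- c("sample_id", "time_days", "censored")
    miss <- setdiff(need, names(tab))
    if (length(miss))
        stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
    tm <- as.numeric(tab$time_days)
    if (anyNA(tm) || any(!is.finite(tm)) || any(tm <= 0))
        stop("'time_days' must be finite and > 0")
    cs <- tab$censored
    if (!all(cs %in% c(0, 1)))
        stop("'censored' must be coded 0 (event) or 1 (censored)")
    data.frame(sample_id = as.character(tab$sample_id),
               time_days = tm, censored = cs == 1,
               stringsAsFactors = FALSE)
}

#' log2(x + 1) transform
#'
#' Count-scale expression is heavily right-skewed; adding one and taking
#' log2 compresses the dynamic range while mapping zero counts to zero.
#'
#' @param x non-negative numeric matrix (samples x genes) or
#'   [SurvivalCohort-class].
#' @return object of the same type, transformed elementwise.
#' @export
logTransform <- function(x) {
    if (is(x, "SurvivalCohort")) {
        assay(x, "exprs") <- logTransform(assay(x, "exprs"))
        return(x)
    }
    if (any(x < 0)) stop("logTransform requires non-negative values")
    log2(x + 1)
}

#' Per-gene min-max normalization
#'
#' Rescales every gene to [0, 1] over the cohort:
#' `(x - min) / (max - min)` per gene. Genes with zero range are an error;
#' remove them first with [dropZeroVariance()]. A previously fitted range
#' (e.g. from training samples only) can be supplied to transform new data
#' on the same scale.
#'
#' @param x samples x genes numeric matrix or [SurvivalCohort-class].
#' @param fit optional result of [minMaxFit()]; default fits on `x` itself.
#' @return same type as `x`, each gene rescaled.
#' @export
minMaxNormalize <- function(x, fit = NULL) {
    if (is(x, "SurvivalCohort")) {
        assay(x, "exprs") <- t(minMaxNormalize(exprMatrix(x), fit = fit))
        return(x)
    }
    if (is.null(fit)) fit <- minMaxFit(x)
    if (!identical(colnames(x), names(fit$min)))
        stop("gene set of 'fit' does not match 'x'")
    rng <- fit$max - fit$min
    sweep(sweep(x, 2L, fit$min, "-"), 2L, rng, "/")
}

#' @rdname minMaxNormalize
#' @export
minMaxFit <- function(x) {
    mins <- apply(x, 2L, min)
    maxs <- apply(x, 2L, max)
    zero <- maxs == mins
    if (any(zero))
        stop("zero-range gene(s): ",
             paste(utils::head(colnames(x)[zero], 5L), collapse = ", "),
             "; run dropZeroVariance() first")
    list(min = mins, max = maxs)
}

#' Remove genes with no variance
#'
#' Drops genes whose value is identical (exact equality) across all samples;
#' the order of the survivors is preserved.
#'
#' @param x samples x genes numeric matrix or [SurvivalCohort-class].
#' @return same type as `x` without the constant genes.
#' @export
dropZeroVariance <- function(x) {
    if (is(x, "SurvivalCohort")) {
        m <- exprMatrix(x)
        keep <- colnames(dropZeroVariance(m))
        return(x[keep, ])
    }
    constant <- apply(x, 2L, function(v) all(v == v[1L]))
    if (all(constant)) stop("all genes have zero variance")
    x[, !constant, drop = FALSE]
}

#' Standard preprocessing: drop constants, log-transform, min-max normalize
#'
#' @param x samples x genes matrix or [SurvivalCohort-class].
#' @return same type, preprocessed.
#' @export
preprocessExpression <- function(x) {
    minMaxNormalize(logTransform(dropZeroVariance(x)))
}
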