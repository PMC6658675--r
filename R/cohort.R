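#' Construct a survival-annotated expression cohort
#'
#' Bundles an expression matrix with per-sample survival time and a
#' right-censoring indicator into a [SurvivalCohort-class] (a
#' `SummarizedExperiment` with genes in rows).
#'
#' @param exprs numeric matrix of non-negative expression values, samples in
#'   rows and genes in columns (the orientation produced by
#'   [readExpressionTable()]); dimnames are required and must be unique.
#' @param timeDays positive numeric vector of follow-up times in days, one
#'   per sample.
#' @param censored logical (or 0/1) vector; `TRUE` means the death event was
#'   not observed (right-censored).
#' @return a `SurvivalCohort`.
#' @examples
#' x <- matrix(rpois(12, 50), 3, 4,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
#' SurvivalCohort(x, timeDays = c(100, 400, 900),
#'                censored = c(FALSE, TRUE, FALSE))
#' @export
SurvivalCohort <- function(exprs, timeDays, censored) {
    if (!is.matrix(exprs) || !is.numeric(exprs))
        stop("'exprs' must be a numeric matrix (samples x genes)")
    if (is.null(rownames(exprs)) || is.null(colnames(exprs)))
        stop("'exprs' must have sample row names and gene column names")
    if (length(timeDays) != nrow(exprs) || length(censored) != nrow(exprs))
        stop("clinical vectors must have one entry per sample (row)")
    if (is.numeric(censored)) {
        if (!all(censored %in% c(0, 1)))
            stop("'censored' must be logical or coded 0/1")
        censored <- censored == 1
    }
    se <- SummarizedExperiment(
        assays = list(exprs = t(exprs)),
        colData = DataFrame(time_days = as.numeric(timeDays),
                            censored = as.logical(censored),
                            row.names = rownames(exprs)))
    new("SurvivalCohort", se)
}

#' @describeIn SurvivalCohort expression values as a samples x genes matrix.
#' @export
setMethod("exprMatrix", "SurvivalCohort", function(x) t(assay(x, "exprs")))

#' @describeIn SurvivalCohort follow-up time in days, one value per sample.
#' @export
setMethod("survTime", "SurvivalCohort", function(x) {
    stats::setNames(colData(x)$time_days, colnames(x))
})

#' @describeIn SurvivalCohort logical right-censoring indicator per sample.
#' @export
setMethod("isCensored", "SurvivalCohort", function(x) {
    stats::setNames(colData(x)$censored, colnames(x))
})

#' @describeIn SurvivalCohort brief cohort summary.
#' @export
setMethod("show", "SurvivalCohort", function(object) {
    cs <- colData(object)$censored
    cat(sprintf(
        "SurvivalCohort: %d genes x %d samples (%d events, %d censored, %.1f%% censored)\n",
        nrow(object), ncol(object), sum(!cs), sum(cs),
        100 * mean(cs)))
    cat(sprintf("  follow-up: %.0f-%.0f days (median %.0f)\n",
                min(colData(object)$time_days),
                max(colData(object)$time_days),
                stats::median(colData(object)$time_days)))
})
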