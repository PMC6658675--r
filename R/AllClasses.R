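#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- colData assayNames
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Survival-annotated expression cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding one assay,
#' `"exprs"`, with genes in rows and samples in columns, together with two
#' mandatory clinical columns in `colData`: `time_days` (positive follow-up
#' time in days) and `censored` (`TRUE` = right-censored, `FALSE` = death
#' event observed).
#'
#' Use [SurvivalCohort()] to construct one and the accessors [exprMatrix()],
#' [survTime()] and [isCensored()] to read from it.
#'
#' @slot .. inherits all slots from `SummarizedExperiment`.
#' @seealso [SurvivalCohort()]
#' @export
setClass("SurvivalCohort", contains = "SummarizedExperiment")

setValidity("SurvivalCohort", function(object) {
    msg <- character()
    if (!("exprs" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'exprs' is required")
    cd <- colData(object)
    if (!all(c("time_days", "censored") %in% colnames(cd))) {
        msg <- c(msg, "colData must contain 'time_days' and 'censored'")
    } else {
        tm <- cd$time_days
        cs <- cd$censored
        if (!is.numeric(tm) || anyNA(tm) || any(!is.finite(tm)) || any(tm <= 0))
            msg <- c(msg, "'time_days' must be finite and > 0")
        if (!is.logical(cs) || anyNA(cs))
            msg <- c(msg, "'censored' must be logical without NAs")
    }
    if ("exprs" %in% SummarizedExperiment::assayNames(object)) {
        x <- assay(object, "exprs")
        if (anyNA(x) || any(!is.finite(x)))
            msg <- c(msg, "expression values must be finite")
        if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
            msg <- c(msg, "gene identifiers must be present and unique")
        if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
            msg <- c(msg, "sample identifiers must be present and unique")
    }
    if (length(msg)) msg else TRUE
})

#' A pair of survival cutoffs defining one cascade step
#'
#' Patients deceased within `deathCutYears` form the high-risk class;
#' patients who demonstrably survived beyond `surviveCutYears` form the
#' low-risk class; everyone else is excluded from that step's training.
#'
#' @slot deathCutYears positive numeric, years.
#' @slot surviveCutYears positive numeric, years; `>= deathCutYears`.
#' @seealso [cutoffYears()], [assignRiskLabels()]
#' @export
setClass("CutoffPair",
    representation(deathCutYears = "numeric", surviveCutYears = "numeric"))

setValidity("CutoffPair", function(object) {
    d <- object@deathCutYears
    s <- object@surviveCutYears
    if (length(d) != 1L || length(s) != 1L || !is.finite(d) || !is.finite(s))
        return("cutoffs must be single finite numbers")
    if (d <= 0 || s <= 0) return("cutoffs must be positive")
    if (d > s) return("deathCutYears must be <= surviveCutYears")
    TRUE
})

#' Per-sample risk-group labels for one cascade step
#'
#' @slot sampleIds character, sample identifiers.
#' @slot labels factor with levels HIGH, LOW, EXCLUDED.
#' @slot cutoffs the [CutoffPair-class] that produced the labels.
#' @export
setClass("RiskLabels",
    representation(sampleIds = "character", labels = "factor",
                   cutoffs = "CutoffPair"))

setValidity("RiskLabels", function(object) {
    if (length(object@sampleIds) != length(object@labels))
        return("sampleIds and labels lengths differ")
    if (!identical(levels(object@labels), c("HIGH", "LOW", "EXCLUDED")))
        return("labels must have levels HIGH, LOW, EXCLUDED")
    if (anyDuplicated(object@sampleIds))
        return("duplicate sample ids")
    TRUE
})

#' Trained two-output softmax classifier weights
#'
#' Holds the input-to-output weights of a softmax (no hidden layer) trained
#' to separate high- from low-risk samples, as used by the discriminating
#' power score.
#'
#' @slot wHigh,wLow named numeric, one weight per gene for the HIGH / LOW
#'   output unit.
#' @slot biases numeric length 2 (HIGH, LOW output biases).
#' @slot trainingLog list: chosen learning rate, epochs run, best validation
#'   loss, seed.
#' @export
setClass("SoftmaxFit",
    representation(wHigh = "numeric", wLow = "numeric", biases = "numeric",
                   trainingLog = "list"))

setValidity("SoftmaxFit", function(object) {
    if (length(object@wHigh) != length(object@wLow))
        return("wHigh and wLow lengths differ")
    if (!identical(names(object@wHigh), names(object@wLow)))
        return("wHigh and wLow gene names differ")
    if (any(!is.finite(object@wHigh)) || any(!is.finite(object@wLow)) ||
        any(!is.finite(object@biases)))
        return("weights must be finite")
    TRUE
})

#' A total ranking of genes by prognostic score
#'
#' Rank 1 is the most prognostic gene. `eliminatedAtStep` records cascade
#' provenance: 0 for genes that survived to the final step, otherwise the
#' step after which the gene was cut.
#'
#' @slot geneIds character in rank order.
#' @slot scores numeric, the score each gene held when it was last scored.
#' @slot eliminatedAtStep integer provenance per gene.
#' @export
setClass("FeatureRanking",
    representation(geneIds = "character", scores = "numeric",
                   eliminatedAtStep = "integer"))

setValidity("FeatureRanking", function(object) {
    n <- length(object@geneIds)
    if (length(object@scores) != n || length(object@eliminatedAtStep) != n)
        return("slot lengths differ")
    if (anyDuplicated(object@geneIds)) return("duplicate gene ids")
    if (any(!is.finite(object@scores))) return("scores must be finite")
    TRUE
})

#' Configuration of the cascaded feature-selection run
#'
#' @slot steps list of [CutoffPair-class]; defaults to the 3 vs 3, 2 vs 4
#'   and 1 vs 5 year cutoff pairs.
#' @slot keepFraction fraction of features retained after each non-final
#'   step (default 0.25).
#' @slot scorerName `"wx"` or `"fisher"`.
#' @slot hyperparams a list as returned by [classifierHyperparams()].
#' @export
setClass("CascadeConfig",
    representation(steps = "list", keepFraction = "numeric",
                   scorerName = "character", hyperparams = "list"))

setValidity("CascadeConfig", function(object) {
    if (length(object@steps) < 1L) return("at least one cascade step required")
    if (!all(vapply(object@steps, is, logical(1), class2 = "CutoffPair")))
        return("steps must be CutoffPair objects")
    kf <- object@keepFraction
    if (length(kf) != 1L || !is.finite(kf) || kf <= 0 || kf > 1)
        return("keepFraction must be in (0, 1]")
    TRUE
})

#' Fitted Faraggi-Simon survival network
#'
#' One hidden layer of sigmoid units feeding a scalar log-hazard output,
#' fitted by minimising the negative log partial likelihood.
#'
#' @slot W1 input-to-hidden weight matrix (genes x hidden).
#' @slot b1 hidden biases.
#' @slot w2 hidden-to-output weights.
#' @slot b2 output bias (scalar).
#' @slot geneIds genes the model was fitted on, in column order.
#' @slot hiddenUnits integer.
#' @slot activation character, currently `"sigmoid"`.
#' @slot trainingLog list: chosen learning rate, epochs, best validation
#'   c-index, seed.
#' @export
setClass("SurvivalModel",
    representation(W1 = "matrix", b1 = "numeric", w2 = "numeric",
                   b2 = "numeric", geneIds = "character",
                   hiddenUnits = "integer", activation = "character",
                   trainingLog = "list"))

setValidity("SurvivalModel", function(object) {
    if (nrow(object@W1) != length(object@geneIds))
        return("W1 rows must match geneIds")
    if (ncol(object@W1) != object@hiddenUnits ||
        length(object@b1) != object@hiddenUnits ||
        length(object@w2) != object@hiddenUnits)
        return("hidden-layer dimensions inconsistent")
    if (any(!is.finite(object@W1)) || any(!is.finite(object@b1)) ||
        any(!is.finite(object@w2)) || !is.finite(object@b2))
        return("weights must be finite")
    TRUE
})
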