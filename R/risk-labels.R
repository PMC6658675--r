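DAYS_PER_YEAR <- 365.25

#' Create a cutoff pair (in years)
#'
#' @param deathCutYears patients with an observed death within this many
#'   years are high risk.
#' @param surviveCutYears patients who lived beyond this many years
#'   (censored or not) are low risk.
#' @return a [CutoffPair-class].
#' @examples
#' cutoffYears(2, 4)
#' @export
cutoffYears <- function(deathCutYears, surviveCutYears = deathCutYears) {
    new("CutoffPair", deathCutYears = as.numeric(deathCutYears),
        surviveCutYears = as.numeric(surviveCutYears))
}

#' @describeIn CutoffPair-class print cutoffs.
#' @param object a `CutoffPair`.
#' @export
setMethod("show", "CutoffPair", function(object) {
    cat(sprintf("CutoffPair: death within %g y = HIGH, alive beyond %g y = LOW\n",
                object@deathCutYears, object@surviveCutYears))
})

#' Assign high/low/excluded risk labels at a survival cutoff pair
#'
#' One cascade step's binary classification target. A sample is `HIGH` when
#' its death was observed at or before `deathCutYears`; `LOW` when it
#' demonstrably survived beyond `surviveCutYears` (whether or not it was
#' later censored); otherwise `EXCLUDED` — censored before the survive
#' cutoff (its outcome at the cutoff horizon is unknown), or deceased in the
#' gap between the two cutoffs.
#'
#' @param x a [SurvivalCohort-class], or a numeric vector of follow-up times
#'   in days.
#' @param cutoffs a [CutoffPair-class].
#' @param censored logical vector; required when `x` is a numeric vector.
#' @param requireBothClasses error when either HIGH or LOW ends up empty
#'   (such a step cannot train a classifier). Default `TRUE`.
#' @return a [RiskLabels-class].
#' @examples
#' labs <- assignRiskLabels(c(2.9, 1.0, 4.5) * 365.25, cutoffYears(3, 3),
#'                          censored = c(FALSE, TRUE, TRUE))
#' riskGroups(labs)
#' @export
assignRiskLabels <- function(x, cutoffs, censored = NULL,
                             requireBothClasses = TRUE) {
    if (is(x, "SurvivalCohort")) {
        timeDays <- survTime(x)
        censored <- isCensored(x)
        ids <- colnames(x)
    } else {
        timeDays <- x
        if (is.null(censored) || length(censored) != length(timeDays))
            stop("'censored' must accompany a numeric time vector")
        ids <- names(timeDays)
        if (is.null(ids)) ids <- paste0("sample", seq_along(timeDays))
    }
    stopifnot(is(cutoffs, "CutoffPair"))
    if (any(timeDays <= 0)) stop("survival times must be positive")
    deathCut <- cutoffs@deathCutYears * DAYS_PER_YEAR
    surviveCut <- cutoffs@surviveCutYears * DAYS_PER_YEAR

    lab <- rep("EXCLUDED", length(timeDays))
    lab[!censored & timeDays <= deathCut] <- "HIGH"
    lab[timeDays > surviveCut] <- "LOW"
    lab <- factor(lab, levels = c("HIGH", "LOW", "EXCLUDED"))
    if (requireBothClasses && (sum(lab == "HIGH") == 0L ||
                               sum(lab == "LOW") == 0L))
        stop(sprintf(
            "untrainable step: HIGH has %d and LOW has %d samples at cutoffs (%g, %g) years",
            sum(lab == "HIGH"), sum(lab == "LOW"),
            cutoffs@deathCutYears, cutoffs@surviveCutYears))
    new("RiskLabels", sampleIds = ids, labels = lab, cutoffs = cutoffs)
}

#' @describeIn RiskLabels-class named factor of labels (HIGH/LOW/EXCLUDED).
#' @export
setMethod("riskGroups", "RiskLabels", function(x) {
    stats::setNames(x@labels, x@sampleIds)
})

#' @describeIn RiskLabels-class summary of the label partition.
#' @param object a `RiskLabels`.
#' @export
setMethod("show", "RiskLabels", function(object) {
    tab <- table(object@labels)
    cat(sprintf(
        "RiskLabels at (%g, %g) years: %d HIGH, %d LOW, %d EXCLUDED (n = %d)\n",
        object@cutoffs@deathCutYears, object@cutoffs@surviveCutYears,
        tab[["HIGH"]], tab[["LOW"]], tab[["EXCLUDED"]],
        length(object@labels)))
})
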