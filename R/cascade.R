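#' Configure a cascaded feature-selection run
#'
#' Defaults follow the three-step design: 3-year, 2-vs-4-year and
#' 1-vs-5-year cutoff pairs, keeping the top quarter of the features after
#' every step but the last.
#'
#' @param steps list of [CutoffPair-class] objects, one per cascade step.
#' @param keepFraction fraction of features retained after each non-final
#'   step, in (0, 1].
#' @param scorerName `"wx"` or `"fisher"`; see [getScorer()].
#' @param hyperparams classifier hyperparameters
#'   ([classifierHyperparams()]); its seed is overridden per step by the
#'   `seed` given to [runCascade()].
#' @return a [CascadeConfig-class].
#' @export
cascadeConfig <- function(steps = list(cutoffYears(3, 3), cutoffYears(2, 4),
                                       cutoffYears(1, 5)),
                          keepFraction = 0.25,
                          scorerName = c("wx", "fisher"),
                          hyperparams = classifierHyperparams()) {
    scorerName <- match.arg(scorerName)
    new("CascadeConfig", steps = steps, keepFraction = keepFraction,
        scorerName = scorerName, hyperparams = hyperparams)
}

#' @describeIn CascadeConfig-class print configuration.
#' @param object a `CascadeConfig`.
#' @export
setMethod("show", "CascadeConfig", function(object) {
    cuts <- vapply(object@steps, function(s)
        sprintf("(%g, %g)", s@deathCutYears, s@surviveCutYears), character(1))
    cat(sprintf("CascadeConfig: %d step(s) %s y; keep %.0f%%; scorer '%s'\n",
                length(object@steps), paste(cuts, collapse = " -> "),
                100 * object@keepFraction, object@scorerName))
})

#' Run the cascaded feature-selection procedure
#'
#' At each step, samples are labeled high/low risk at that step's cutoff
#' pair, the configured scorer is trained on the currently surviving genes
#' restricted to the labeled samples, and — except after the final step —
#' only the top `floor(keepFraction * d)` genes (at least 1) survive to the
#' next step. The final ranking is total over all input genes: final-step
#' survivors first (ordered by their final-step score), then genes
#' eliminated at later steps above genes eliminated earlier, each block
#' ordered by its elimination-step score. Ties are broken by gene id.
#'
#' @param cohort a preprocessed [SurvivalCohort-class] (log-transformed,
#'   zero-variance-filtered, min-max normalized expression).
#' @param config a [CascadeConfig-class].
#' @param seed master seed; each step trains from a fresh,
#'   step-specific seed derived via [deriveSeed()] with stage label
#'   `"cascade_step_<s>"`.
#' @return a [FeatureRanking-class] covering every input gene, with
#'   `eliminationStep()` provenance.
#' @examples
#' \donttest{
#' syn <- generateCohort(syntheticConfig(nSamples = 120, nGenes = 60,
#'                                       nCausal = 4, seed = 1))
#' ranking <- runCascade(preprocessExpression(syn$cohort),
#'                       cascadeConfig(), seed = 1)
#' head(rankedGenes(ranking))
#' }
#' @export
runCascade <- function(cohort, config = cascadeConfig(), seed = 1L) {
    stopifnot(is(cohort, "SurvivalCohort"), is(config, "CascadeConfig"))
    X <- exprMatrix(cohort)
    scorer <- getScorer(config@scorerName)
    nSteps <- length(config@steps)

    surviving <- colnames(X)
    eliminated <- list()   # per step: named score vectors of cut genes
    finalScores <- NULL
    for (s in seq_len(nSteps)) {
        labels <- tryCatch(
            assignRiskLabels(cohort, config@steps[[s]]),
            error = function(e) stop("cascade step ", s, ": ",
                                     conditionMessage(e), call. = FALSE))
        hp <- config@hyperparams
        hp$seed <- deriveSeed(seed, paste0("cascade_step_", s))
        scores <- scorer(X[, surviving, drop = FALSE], labels, hp)
        if (s < nSteps) {
            nKeep <- max(1L, floor(config@keepFraction * length(surviving)))
            stepRank <- rankFeatures(scores)
            keep <- rankedGenes(stepRank)[seq_len(nKeep)]
            cutGenes <- setdiff(names(scores), keep)
            eliminated[[s]] <- scores[cutGenes]
            surviving <- surviving[surviving %in% keep]
        } else {
            finalScores <- scores
        }
    }

    ids <- character(0); sc <- numeric(0); prov <- integer(0)
    finalRank <- rankFeatures(finalScores)
    ids <- rankedGenes(finalRank)
    sc <- unname(featureScores(finalRank))
    prov <- integer(length(ids))
    for (s in rev(seq_along(eliminated))) {
        if (length(eliminated[[s]]) == 0L) next
        blk <- rankFeatures(eliminated[[s]])
        ids <- c(ids, rankedGenes(blk))
        sc <- c(sc, unname(featureScores(blk)))
        prov <- c(prov, rep(s, length(eliminated[[s]])))
    }
    new("FeatureRanking", geneIds = ids, scores = sc,
        eliminatedAtStep = as.integer(prov))
}
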