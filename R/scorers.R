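#' Wx discriminating-power scores from a trained softmax
#'
#' For every gene j the score is
#' `DP_j = | wHigh_j * mean(x_j | HIGH)  -  wLow_j * mean(x_j | LOW) |`,
#' combining the classifier's two output weights with the class means of the
#' (normalized) inputs it was trained on. Larger DP means the gene moves the
#' softmax decision more between the risk groups.
#'
#' @param fit a [SoftmaxFit-class] trained on the same gene set as `X`.
#' @param X samples x genes matrix actually fed to the classifier.
#' @param labels the [RiskLabels-class] used in training.
#' @return named non-negative numeric vector, one score per gene of `X`.
#' @export
wxDpScores <- function(fit, X, labels) {
    stopifnot(is(fit, "SoftmaxFit"), is(labels, "RiskLabels"))
    if (!identical(names(fit@wHigh), colnames(X)))
        stop("gene set of the fit does not match the matrix")
    grp <- riskGroups(labels)
    hi <- names(grp)[grp == "HIGH"]
    lo <- names(grp)[grp == "LOW"]
    if (length(hi) == 0L || length(lo) == 0L)
        stop("both classes must be non-empty")
    mHigh <- colMeans(X[hi, , drop = FALSE])
    mLow <- colMeans(X[lo, , drop = FALSE])
    abs(fit@wHigh * mHigh - fit@wLow * mLow)
}

#' Two-class Fisher scores
#'
#' The classical Fisher criterion per gene: between-class spread over
#' within-class spread,
#' `sum_c n_c (mu_jc - mu_j)^2 / sum_c sum_{i in c} (x_ij - mu_jc)^2`.
#' Genes that separate the classes perfectly (zero pooled within-class
#' variation) are assigned one more than the largest finite score so they
#' rank above everything else.
#'
#' @param X samples x genes matrix.
#' @param labels a [RiskLabels-class]; both classes need at least 2 samples.
#' @return named non-negative numeric vector of scores.
#' @export
fisherScores <- function(X, labels) {
    stopifnot(is(labels, "RiskLabels"))
    grp <- riskGroups(labels)
    hi <- names(grp)[grp == "HIGH"]
    lo <- names(grp)[grp == "LOW"]
    if (length(hi) < 2L || length(lo) < 2L)
        stop("each class needs at least 2 samples for the Fisher score")
    Xh <- X[hi, , drop = FALSE]
    Xl <- X[lo, , drop = FALSE]
    nh <- nrow(Xh); nl <- nrow(Xl)
    muH <- colMeans(Xh); muL <- colMeans(Xl)
    mu <- (nh * muH + nl * muL) / (nh + nl)
    between <- nh * (muH - mu)^2 + nl * (muL - mu)^2
    within <- colSums(sweep(Xh, 2L, muH)^2) + colSums(sweep(Xl, 2L, muL)^2)
    s <- ifelse(within == 0, Inf, between / within)
    s[within == 0 & muH == muL] <- 0  # constant gene: no separation at all
    if (any(is.infinite(s))) {
        top <- if (any(is.finite(s))) max(s[is.finite(s)]) else 0
        s[is.infinite(s)] <- top + 1
    }
    s
}

#' Rank features by descending score
#'
#' Ties are broken by ascending gene identifier so rankings are
#' deterministic.
#'
#' @param scores named numeric vector of non-negative feature scores.
#' @param eliminatedAtStep optional integer provenance (default all 0).
#' @return a [FeatureRanking-class]; rank 1 is the highest score.
#' @export
rankFeatures <- function(scores, eliminatedAtStep = NULL) {
    if (anyNA(scores)) stop("scores contain NA/NaN")
    if (is.null(names(scores))) stop("scores must be named by gene id")
    ord <- order(-scores, names(scores), method = "radix")
    if (is.null(eliminatedAtStep))
        eliminatedAtStep <- integer(length(scores))
    new("FeatureRanking",
        geneIds = names(scores)[ord],
        scores = as.numeric(scores[ord]),
        eliminatedAtStep = as.integer(eliminatedAtStep[ord]))
}

#' Look up a feature scorer by name
#'
#' A scorer maps `(X, labels, hyperparams)` to a named score vector over
#' exactly the genes of `X`. Built-ins: `"wx"` (softmax discriminating
#' power) and `"fisher"`.
#'
#' @param name `"wx"` or `"fisher"`.
#' @return a scorer function.
#' @export
getScorer <- function(name = c("wx", "fisher")) {
    name <- match.arg(name)
    switch(name,
        wx = function(X, labels, hyperparams = classifierHyperparams()) {
            fit <- trainSoftmaxClassifier(X, labels, hyperparams)
            wxDpScores(fit, X, labels)
        },
        fisher = function(X, labels, hyperparams = NULL) {
            fisherScores(X, labels)
        })
}

#' @describeIn FeatureRanking-class gene ids in rank order (rank 1 first).
#' @export
setMethod("rankedGenes", "FeatureRanking", function(x) x@geneIds)

#' @describeIn FeatureRanking-class scores in rank order, named by gene.
#' @export
setMethod("featureScores", "FeatureRanking", function(x) {
    stats::setNames(x@scores, x@geneIds)
})

#' @describeIn FeatureRanking-class cascade provenance in rank order
#'   (0 = survived to the final step).
#' @export
setMethod("eliminationStep", "FeatureRanking", function(x) {
    stats::setNames(x@eliminatedAtStep, x@geneIds)
})

#' @describeIn FeatureRanking-class print the top of the ranking.
#' @param object a `FeatureRanking`.
#' @export
setMethod("show", "FeatureRanking", function(object) {
    n <- length(object@geneIds)
    cat(sprintf("FeatureRanking over %d genes (%d survived to final step)\n",
                n, sum(object@eliminatedAtStep == 0L)))
    k <- min(5L, n)
    cat("  top:", paste(sprintf("%s (%.3g)", object@geneIds[seq_len(k)],
                                object@scores[seq_len(k)]),
                        collapse = ", "), "\n")
})

#' Convert a ranking to a data.frame
#'
#' @param x a [FeatureRanking-class].
#' @param ... ignored.
#' @return data.frame with columns rank, gene_id, score,
#'   eliminated_at_step.
#' @export
as.data.frame.FeatureRanking <- function(x, ...) {
    data.frame(rank = seq_along(x@geneIds), gene_id = x@geneIds,
               score = x@scores, eliminated_at_step = x@eliminatedAtStep,
               stringsAsFactors = FALSE)
}
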