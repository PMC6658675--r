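#' Harrell's concordance index
#'
#' Over all comparable pairs — those where the sample with the shorter
#' follow-up had an observed event and the times differ — a pair is
#' concordant when that shorter-lived sample has the strictly higher
#' predicted risk, and risk ties receive half credit:
#' `c = (concordant + 0.5 * tied) / (concordant + discordant + tied)`.
#'
#' @param risk numeric predicted risk scores (higher = worse prognosis).
#' @param timeDays positive survival times.
#' @param censored logical right-censoring indicator.
#' @return list with `value`, and the pair counts `concordant`,
#'   `discordant`, `tied_risk`, `comparable`.
#' @examples
#' harrellCIndex(c(3, 2, 1), c(1, 2, 3), c(FALSE, FALSE, FALSE))$value  # 1
#' @export
harrellCIndex <- function(risk, timeDays, censored) {
    n <- length(risk)
    stopifnot(length(timeDays) == n, length(censored) == n)
    if (any(!is.finite(risk))) stop("non-finite risk scores")
    # pair (i, j): comparable iff S_i < S_j and C_i = 0 (i indexes the
    # earlier event); enumerate via vectorised outer comparisons
    earlier <- outer(timeDays, timeDays, "<") & !censored  # [i, j]
    riskDiff <- outer(risk, risk, "-")                     # risk_i - risk_j
    conc <- sum(earlier & riskDiff > 0)
    disc <- sum(earlier & riskDiff < 0)
    tied <- sum(earlier & riskDiff == 0)
    total <- conc + disc + tied
    if (total == 0L) stop("no comparable pairs")
    list(value = (conc + 0.5 * tied) / total,
         concordant = conc, discordant = disc, tied_risk = tied,
         comparable = total)
}

#' Two-group log-rank test
#'
#' The standard Mantel-Haenszel log-rank statistic (observed minus expected
#' events accumulated over distinct event times with hypergeometric
#' variance), with the p-value from a chi-square distribution on 1 degree
#' of freedom. Computed via [survival::survdiff()].
#'
#' @param timeDays positive survival times.
#' @param censored logical right-censoring indicator.
#' @param group vector with exactly two distinct values.
#' @return list with `statistic`, `p_value` and `group_sizes`.
#' @export
logRankTest <- function(timeDays, censored, group) {
    g <- as.factor(group)
    if (nlevels(g) != 2L || any(table(g) == 0L))
        stop("exactly two non-empty groups are required")
    if (!any(!censored)) stop("at least one event is required")
    sd <- survival::survdiff(
        survival::Surv(timeDays, !censored) ~ g,
        data = data.frame(timeDays = timeDays, censored = censored, g = g))
    stat <- unname(sd$chisq)
    list(statistic = stat,
         p_value = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
         group_sizes = as.integer(table(g)))
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function; censored samples leave
#' the risk set without causing a drop. Computed via
#' [survival::survfit()].
#'
#' @param timeDays positive survival times.
#' @param censored logical right-censoring indicator.
#' @return data.frame with columns `time`, `n_risk`, `n_event`, `surv`
#'   (one row per observed time point, survival right-continuous).
#' @export
kaplanMeier <- function(timeDays, censored) {
    if (length(timeDays) < 1L) stop("empty input")
    sf <- survival::survfit(survival::Surv(timeDays, !censored) ~ 1)
    data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
               surv = sf$surv)
}

#' Stratified k-fold split on the censoring indicator
#'
#' Censored and uncensored samples are shuffled within stratum and dealt
#' round-robin, so per-fold event counts differ from exact proportionality
#' by at most one.
#'
#' @param censored logical vector (the stratification variable).
#' @param k number of folds (>= 2); every stratum needs at least `k`
#'   members.
#' @param seed integer RNG seed.
#' @return integer vector of fold ids 1..k, one per sample.
#' @export
stratifiedKFold <- function(censored, k = 5L, seed = 1L) {
    stopifnot(k >= 2L)
    fold <- integer(length(censored))
    withr::with_seed(seed, {
        for (s in unique(censored)) {
            idx <- which(censored == s)
            if (length(idx) < k)
                stop("stratum with ", length(idx),
                     " samples is smaller than k = ", k)
            fold[idx] <- rep_len(seq_len(k), length(idx))[sample(length(idx))]
        }
    })
    fold
}

#' Merge per-fold gene rankings by gene ranking points
#'
#' Every gene collects `N - R_jk` points from each fold, where `R_jk` is
#' its rank in fold k and `N` the number of genes; the merged list sorts by
#' descending total points, ties broken by ascending gene id.
#'
#' @param rankings list of [FeatureRanking-class] objects over the same
#'   gene set.
#' @return data.frame with columns `rank`, `gene_id`, `points`.
#' @export
mergeRankings <- function(rankings) {
    stopifnot(length(rankings) >= 1L)
    genes <- sort(rankedGenes(rankings[[1L]]))
    N <- length(genes)
    pts <- stats::setNames(numeric(N), genes)
    for (r in rankings) {
        ids <- rankedGenes(r)
        if (!identical(sort(ids), genes))
            stop("rankings cover different gene sets")
        pts[ids] <- pts[ids] + (N - seq_len(N))
    }
    ord <- order(-pts, names(pts), method = "radix")
    data.frame(rank = seq_len(N), gene_id = names(pts)[ord],
               points = unname(pts[ord]), stringsAsFactors = FALSE)
}

#' Cross-validated c-index of cumulative top-k gene signatures
#'
#' For each requested signature size k and each fold, the survival network
#' is fitted on the training samples using the fold's top-k genes and
#' scored on the held-out fold by Harrell's c-index (plus, optionally, a
#' log-rank test of the test samples split at the median predicted risk).
#'
#' @param cohort a preprocessed [SurvivalCohort-class].
#' @param rankings either one [FeatureRanking-class] used for every fold or
#'   a list with one ranking per fold (leakage-free nested evaluation).
#' @param folds integer fold ids from [stratifiedKFold()].
#' @param ks integer vector of signature sizes to evaluate.
#' @param config survival fit settings ([survivalFitConfig()]); the seed is
#'   re-derived per fold and k from `seed`.
#' @param seed master seed.
#' @param logRank also compute the median-risk-split log-rank p per fold.
#' @return list with `perFold` (data.frame: k, fold, c_index, logrank_p)
#'   and `summary` (data.frame: k, mean_c_index).
#' @export
evaluateTopK <- function(cohort, rankings, folds, ks,
                         config = survivalFitConfig(), seed = 1L,
                         logRank = FALSE) {
    stopifnot(is(cohort, "SurvivalCohort"))
    nFolds <- max(folds)
    if (is(rankings, "FeatureRanking"))
        rankings <- rep(list(rankings), nFolds)
    stopifnot(length(rankings) == nFolds)
    X <- exprMatrix(cohort)
    tm <- survTime(cohort); cs <- isCensored(cohort)
    if (any(ks > ncol(X)))
        stop("signature size exceeds the number of genes (",
             ncol(X), ")")
    rows <- list()
    for (fold in seq_len(nFolds)) {
        genesRanked <- rankedGenes(rankings[[fold]])
        tr <- folds != fold; te <- !tr
        for (k in ks) {
            genes <- genesRanked[seq_len(k)]
            cfg <- config
            cfg$seed <- deriveSeed(seed, sprintf("topk_f%d_k%d", fold, k))
            model <- tryCatch(
                fitSurvivalModel(X[tr, genes, drop = FALSE], tm[tr], cs[tr],
                                 cfg),
                error = function(e) stop(sprintf("fold %d, k = %d: %s",
                                                 fold, k,
                                                 conditionMessage(e)),
                                         call. = FALSE))
            risk <- predictRisk(model, X[te, genes, drop = FALSE])
            ci <- harrellCIndex(risk, tm[te], cs[te])$value
            lrp <- NA_real_
            if (logRank) {
                split <- risk > stats::median(risk)
                lrp <- tryCatch(
                    logRankTest(tm[te], cs[te], split)$p_value,
                    error = function(e) NA_real_)
            }
            rows[[length(rows) + 1L]] <-
                data.frame(k = k, fold = fold, c_index = ci, logrank_p = lrp)
        }
    }
    perFold <- do.call(rbind, rows)
    agg <- stats::aggregate(c_index ~ k, perFold, mean)
    names(agg) <- c("k", "mean_c_index")
    list(perFold = perFold, summary = agg[order(agg$k), ])
}
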