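#' Cross-validated cascaded ranking with fold merging
#'
#' Runs the nested selection protocol: the cohort is split into `k`
#' stratified folds; for every fold the cascade is trained on the other
#' folds' samples only, yielding one full ranking per fold; the per-fold
#' rankings are merged by gene ranking points. Normalization is fitted on
#' the whole cohort by default (matching the published pipeline, which
#' normalizes before splitting); set `normalizeWithinTrain = TRUE` to fit
#' the per-gene min-max ranges on each fold's training samples instead.
#'
#' @param cohort a [SurvivalCohort-class] of raw (count-scale) expression.
#' @param config a [CascadeConfig-class].
#' @param k number of folds (default 5).
#' @param seed master seed; fold splitting and each fold's cascade draw
#'   stage-specific seeds via [deriveSeed()].
#' @param normalizeWithinTrain fit min-max ranges on training samples only.
#' @return list with `foldRankings` (list of [FeatureRanking-class]),
#'   `merged` (data.frame from [mergeRankings()]), `folds` (fold ids) and
#'   `cohortPreprocessed` (the preprocessed cohort, for evaluation).
#' @export
cwxCrossValidatedRanking <- function(cohort, config = cascadeConfig(),
                                     k = 5L, seed = 1L,
                                     normalizeWithinTrain = FALSE) {
    stopifnot(is(cohort, "SurvivalCohort"))
    base <- logTransform(dropZeroVariance(cohort))
    normAll <- minMaxNormalize(base)
    folds <- stratifiedKFold(isCensored(cohort), k = k,
                             seed = deriveSeed(seed, "fold_split"))
    foldRankings <- vector("list", k)
    for (fold in seq_len(k)) {
        trIdx <- which(folds != fold)
        if (normalizeWithinTrain) {
            fit <- minMaxFit(dropZeroVariance(
                exprMatrix(base)[trIdx, , drop = FALSE]))
            m <- exprMatrix(base)[trIdx, names(fit$min), drop = FALSE]
            trainCohort <- SurvivalCohort(
                minMaxNormalize(m, fit),
                timeDays = survTime(base)[trIdx],
                censored = isCensored(base)[trIdx])
        } else {
            trainCohort <- normAll[, trIdx]
        }
        foldRankings[[fold]] <- runCascade(
            trainCohort, config,
            seed = deriveSeed(seed, paste0("cascade_fold_", fold)))
    }
    if (normalizeWithinTrain) {
        common <- Reduce(intersect, lapply(foldRankings, rankedGenes))
        foldRankings <- lapply(foldRankings, function(r) {
            keep <- rankedGenes(r) %in% common
            new("FeatureRanking", geneIds = r@geneIds[keep],
                scores = r@scores[keep],
                eliminatedAtStep = r@eliminatedAtStep[keep])
        })
    }
    list(foldRankings = foldRankings,
         merged = mergeRankings(foldRankings),
         folds = folds,
         cohortPreprocessed = normAll)
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

.writeManifest <- function(path, seed, params) {
    jsonlite::write_json(
        list(package = "cascadeWx",
             version = as.character(utils::packageVersion("cascadeWx")),
             r_version = paste(R.version$major, R.version$minor, sep = "."),
             seed = seed, parameters = params),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' Read a run configuration from YAML
#'
#' Recognised top-level keys (all optional): `steps` (list of
#' `[death, survive]` year pairs), `keep_fraction`, `scorer`, `k_folds`,
#' `k_max`, `hidden_units`, `seed`, and a `synthetic:` block whose fields
#' mirror [syntheticConfig()] (`n_samples`, `n_genes`, `n_causal`,
#' `causal_beta`, `baseline_hazard`, `censor_rate_target`).
#'
#' @param path YAML file path.
#' @return list with elements `cascade` ([CascadeConfig-class]), `kFolds`,
#'   `kMax`, `fit` ([survivalFitConfig()]), `seed` and `synthetic`.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    steps <- if (is.null(y$steps)) {
        list(cutoffYears(3, 3), cutoffYears(2, 4), cutoffYears(1, 5))
    } else {
        lapply(y$steps, function(s) cutoffYears(s[[1L]], s[[2L]]))
    }
    seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
    syn <- NULL
    if (!is.null(y$synthetic)) {
        s <- y$synthetic
        g <- function(k, dflt) if (is.null(s[[k]])) dflt else s[[k]]
        syn <- syntheticConfig(
            nSamples = g("n_samples", 400L), nGenes = g("n_genes", 1000L),
            nCausal = g("n_causal", 20L), causalBeta = g("causal_beta", 1),
            baselineHazard = g("baseline_hazard", 0.15),
            censorRateTarget = g("censor_rate_target", 0.5),
            seed = deriveSeed(seed, "simulate"))
    }
    list(cascade = cascadeConfig(
             steps = steps,
             keepFraction = if (is.null(y$keep_fraction)) 0.25
                            else y$keep_fraction,
             scorerName = if (is.null(y$scorer)) "wx" else y$scorer),
         kFolds = if (is.null(y$k_folds)) 5L else as.integer(y$k_folds),
         kMax = if (is.null(y$k_max)) 50L else as.integer(y$k_max),
         fit = survivalFitConfig(
             hiddenUnits = if (is.null(y$hidden_units)) 8L
                           else as.integer(y$hidden_units)),
         seed = seed,
         synthetic = syn)
}

#' Simulate a cohort and write it to disk
#'
#' Writes `<prefix>expression.tsv` (genes in rows, firehose-like),
#' `<prefix>clinical.tsv`, `<prefix>truth.tsv` and `<prefix>manifest.json`.
#'
#' @param config list from [syntheticConfig()].
#' @param outPrefix path prefix for the output files.
#' @return invisibly, the list from [generateCohort()].
#' @export
runSimulateWorkflow <- function(config = syntheticConfig(), outPrefix) {
    sim <- generateCohort(config)
    writeExpressionTable(exprMatrix(sim$cohort),
                         paste0(outPrefix, "expression.tsv"))
    .writeTsv(data.frame(sample_id = colnames(sim$cohort),
                         time_days = survTime(sim$cohort),
                         censored = as.integer(isCensored(sim$cohort))),
              paste0(outPrefix, "clinical.tsv"))
    .writeTsv(sim$truth, paste0(outPrefix, "truth.tsv"))
    .writeManifest(paste0(outPrefix, "manifest.json"), config$seed,
                   config[setdiff(names(config), "seed")])
    invisible(sim)
}

#' Rank genes from expression + clinical files
#'
#' End-to-end: read tables, preprocess, run the cross-validated cascade,
#' write one ranking TSV per fold, the merged ranking, and a manifest.
#'
#' @param expressionPath,clinicalPath input TSVs (see
#'   [readExpressionTable()], [readClinicalTable()]).
#' @param outDir output directory (created if missing).
#' @param config a [CascadeConfig-class].
#' @param k folds.
#' @param seed master seed.
#' @param orientation expression-table layout.
#' @return invisibly, the list from [cwxCrossValidatedRanking()].
#' @export
runRankWorkflow <- function(expressionPath, clinicalPath, outDir,
                            config = cascadeConfig(), k = 5L, seed = 1L,
                            orientation = "genes_in_rows") {
    X <- readExpressionTable(expressionPath, orientation)
    clin <- readClinicalTable(clinicalPath)
    if (!setequal(rownames(X), clin$sample_id))
        stop("expression and clinical sample ids do not match")
    clin <- clin[match(rownames(X), clin$sample_id), ]
    cohort <- SurvivalCohort(X, clin$time_days, clin$censored)
    res <- cwxCrossValidatedRanking(cohort, config, k = k, seed = seed)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (fold in seq_len(k))
        .writeTsv(as.data.frame(res$foldRankings[[fold]]),
                  file.path(outDir, sprintf("ranking_fold%d.tsv", fold)))
    .writeTsv(res$merged, file.path(outDir, "ranking_merged.tsv"))
    .writeTsv(data.frame(sample_id = colnames(cohort), fold = res$folds),
              file.path(outDir, "folds.tsv"))
    .writeManifest(file.path(outDir, "manifest.json"), seed,
                   list(k = k, scorer = config@scorerName,
                        keep_fraction = config@keepFraction,
                        steps = lapply(config@steps, function(s)
                            c(s@deathCutYears, s@surviveCutYears))))
    invisible(res)
}

#' Evaluate ranked gene signatures by cross-validated c-index
#'
#' Fits the survival network per fold on the top-k genes of each fold's
#' ranking and writes a per-fold and a per-k summary table.
#'
#' @param cohort a raw-scale [SurvivalCohort-class].
#' @param rankResult result of [cwxCrossValidatedRanking()] (or compatible
#'   list with `foldRankings`, `folds`, `cohortPreprocessed`).
#' @param ks signature sizes to evaluate.
#' @param outDir output directory.
#' @param fitConfig survival fit settings.
#' @param seed master seed.
#' @return invisibly, the list from [evaluateTopK()].
#' @export
runEvaluateWorkflow <- function(cohort, rankResult, ks, outDir,
                                fitConfig = survivalFitConfig(),
                                seed = 1L) {
    ev <- evaluateTopK(rankResult$cohortPreprocessed,
                       rankResult$foldRankings, rankResult$folds, ks,
                       config = fitConfig,
                       seed = deriveSeed(seed, "evaluate"),
                       logRank = TRUE)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    .writeTsv(ev$perFold, file.path(outDir, "cindex_per_fold.tsv"))
    .writeTsv(ev$summary, file.path(outDir, "cindex_summary.tsv"))
    .writeManifest(file.path(outDir, "evaluate_manifest.json"), seed,
                   list(ks = ks, hidden_units = fitConfig$hiddenUnits))
    invisible(ev)
}
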