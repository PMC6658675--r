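# Small in-code fixtures shared across test files.

# Random survival instance for oracle comparisons.
randomSurvivalInstance <- function(n, censorProb = 0.3, tieTimes = FALSE,
                                   tieRisks = FALSE) {
    timeDays <- if (tieTimes) sample(1:max(3L, n %/% 2L), n, replace = TRUE)
                else sample(seq_len(10L * n), n)
    censored <- stats::runif(n) < censorProb
    if (!any(!censored)) censored[sample(n, 1L)] <- FALSE
    risk <- if (tieRisks) sample(seq_len(max(2L, n %/% 3L)), n, replace = TRUE)
            else stats::rnorm(n)
    list(time = as.numeric(timeDays), censored = censored,
         risk = as.numeric(risk))
}

# Tiny labeled expression matrix with both risk classes.
toyLabeledData <- function(nPerClass = 10L, nGenes = 5L, seed = 1L,
                           gap = 1) {
    withr::with_seed(seed, {
        n <- 2L * nPerClass
        X <- matrix(stats::runif(n * nGenes), n, nGenes,
                    dimnames = list(sprintf("s%02d", seq_len(n)),
                                    sprintf("g%02d", seq_len(nGenes))))
        X[seq_len(nPerClass), 1L] <- X[seq_len(nPerClass), 1L] + gap
        # HIGH = died within 1 year, LOW = alive beyond 6 years
        timeDays <- c(rep(200, nPerClass), rep(2400, nPerClass))
        censored <- rep(FALSE, n)
        labels <- assignRiskLabels(
            stats::setNames(timeDays, rownames(X)), cutoffYears(3, 3),
            censored = censored)
        list(X = X, labels = labels,
             isHigh = riskGroups(labels)[rownames(X)] == "HIGH")
    })
}

# Write a small expression/clinical TSV pair; returns the paths.
writeToyTables <- function(dir, nSamples = 6L, nGenes = 4L, seed = 1L) {
    sim <- generateCohort(syntheticConfig(
        nSamples = nSamples, nGenes = nGenes, nCausal = 0L,
        censorRateTarget = NA, seed = seed))
    ep <- file.path(dir, "expr.tsv")
    cp <- file.path(dir, "clin.tsv")
    writeExpressionTable(exprMatrix(sim$cohort), ep)
    utils::write.table(
        data.frame(sample_id = colnames(sim$cohort),
                   time_days = survTime(sim$cohort),
                   censored = as.integer(isCensored(sim$cohort))),
        cp, sep = "\t", quote = FALSE, row.names = FALSE)
    list(expression = ep, clinical = cp, cohort = sim$cohort)
}
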