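#' Configuration of the synthetic survival-transcriptome generator
#'
#' The generator emulates a bulk RNA-seq prognosis cohort: a few hundred
#' samples, thousands of genes with heavy-right-skewed non-negative
#' (log-normal) expression, a small set of causal genes acting on the event
#' hazard through a proportional-hazards model, and roughly half the
#' samples right-censored.
#'
#' @param nSamples number of patients (default 400).
#' @param nGenes number of genes (default 1000).
#' @param nCausal number of causal genes (default 20).
#' @param causalBeta log-hazard effect per normalized expression unit;
#'   causal genes alternate sign `+causalBeta`, `-causalBeta` (default 1).
#' @param baselineHazard events per year at the average expression profile
#'   (default 0.15, i.e. median survival near 4.6 years).
#' @param censorRateTarget desired right-censoring fraction in [0, 1)
#'   (default 0.5); the follow-up horizon is tuned by bisection to hit it.
#' @param followupMaxYears administrative follow-up cap used when
#'   `censorRateTarget` is `NA` (default 10).
#' @param seed integer RNG seed.
#' @return list of settings for [generateCohort()].
#' @export
syntheticConfig <- function(nSamples = 400L, nGenes = 1000L, nCausal = 20L,
                            causalBeta = 1, baselineHazard = 0.15,
                            censorRateTarget = 0.5, followupMaxYears = 10,
                            seed = 1L) {
    stopifnot(nSamples >= 2L, nGenes >= 1L, nCausal >= 0L,
              nCausal <= nGenes, baselineHazard > 0, followupMaxYears > 0,
              is.na(censorRateTarget) ||
                  (censorRateTarget >= 0 && censorRateTarget < 1))
    list(nSamples = as.integer(nSamples), nGenes = as.integer(nGenes),
         nCausal = as.integer(nCausal), causalBeta = causalBeta,
         baselineHazard = baselineHazard,
         censorRateTarget = censorRateTarget,
         followupMaxYears = followupMaxYears, seed = as.integer(seed))
}

#' Generate a synthetic survival-transcriptome cohort with known truth
#'
#' Expression is drawn per gene from a log-normal distribution with
#' gene-specific location and scale (right-skewed, non-negative, RSEM-like
#' magnitudes). The first `nCausal` genes are causal: event times are
#' exponential with rate `baselineHazard * exp(sum_g beta_g (z_g - mean))`
#' where `z_g` is the cohort min-max-normalized log2(x+1) value of causal
#' gene g — the same scale the selection pipeline operates on. Each sample
#' additionally draws an independent uniform censoring time on
#' `(0, followupMax)`; the recorded time is the minimum and the censoring
#' flag is set accordingly. When `censorRateTarget` is given, `followupMax`
#' is found by bisection so the realized censoring fraction matches the
#' target. Fully deterministic given the seed.
#'
#' @param config list from [syntheticConfig()].
#' @return list with `cohort` (a [SurvivalCohort-class] of raw counts-scale
#'   expression), and `truth` (data.frame: gene_id, beta) plus
#'   `censoringFraction` and `followupMaxYears` as attributes of the list.
#' @export
generateCohort <- function(config = syntheticConfig()) {
    n <- config$nSamples; d <- config$nGenes
    out <- withr::with_seed(config$seed, {
        geneMeanLog <- stats::runif(d, log(5), log(2000))
        geneSdLog <- stats::runif(d, 0.4, 1.2)
        X <- exp(sweep(sweep(matrix(stats::rnorm(n * d), n, d), 2L,
                             geneSdLog, "*"),
                       2L, geneMeanLog, "+"))
        dimnames(X) <- list(sprintf("sample%03d", seq_len(n)),
                            sprintf("gene%04d", seq_len(d)))
        betas <- numeric(0)
        lp <- numeric(n)
        if (config$nCausal > 0L) {
            betas <- config$causalBeta *
                rep_len(c(1, -1), config$nCausal)
            L <- log2(X[, seq_len(config$nCausal), drop = FALSE] + 1)
            rng <- apply(L, 2L, range)
            Z <- sweep(sweep(L, 2L, rng[1L, ]), 2L,
                       pmax(rng[2L, ] - rng[1L, ], .Machine$double.eps), "/")
            lp <- drop(sweep(Z, 2L, colMeans(Z)) %*% betas)
        }
        rate <- config$baselineHazard * exp(lp)       # events per year
        eventYears <- stats::rexp(n) / rate
        u <- stats::runif(n)                          # censor-time quantiles
        list(X = X, betas = betas, eventYears = eventYears, u = u)
    })

    censorFraction <- function(fmax) {
        censYears <- pmin(out$u * fmax, fmax)
        mean(censYears < out$eventYears)
    }
    fmax <- config$followupMaxYears
    if (!is.na(config$censorRateTarget)) {
        lo <- 1e-3; hi <- 1e4
        for (i in seq_len(60L)) {
            mid <- sqrt(lo * hi)
            # censoring fraction decreases as follow-up lengthens
            if (censorFraction(mid) > config$censorRateTarget) lo <- mid
            else hi <- mid
        }
        fmax <- sqrt(lo * hi)
    }
    censYears <- out$u * fmax
    timeYears <- pmin(out$eventYears, censYears)
    censored <- censYears < out$eventYears
    timeDays <- pmax(timeYears * DAYS_PER_YEAR, 0.5)

    cohort <- SurvivalCohort(out$X, timeDays = timeDays, censored = censored)
    truth <- data.frame(
        gene_id = colnames(out$X)[seq_len(config$nCausal)],
        beta = out$betas, stringsAsFactors = FALSE)
    list(cohort = cohort, truth = truth,
         censoringFraction = mean(censored),
         followupMaxYears = fmax)
}
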