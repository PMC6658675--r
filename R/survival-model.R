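#' Configuration for fitting the survival network
#'
#' @param maxEpochs maximum full-batch epochs (default 100).
#' @param earlyStopPatience epochs without validation c-index improvement
#'   before stopping (default 20).
#' @param learningRates candidate Adam learning rates; the one with the best
#'   validation c-index wins.
#' @param validationFraction fraction of the training samples held out for
#'   rate selection and early stopping (default 0.2), stratified on the
#'   censoring indicator.
#' @param hiddenUnits width of the single hidden layer (default 8).
#' @param seed RNG seed for the split and weight initialisation.
#' @return list of settings for [fitSurvivalModel()].
#' @export
survivalFitConfig <- function(maxEpochs = 100L, earlyStopPatience = 20L,
                              learningRates = c(1e-1, 1e-2, 1e-3, 1e-4),
                              validationFraction = 0.2, hiddenUnits = 8L,
                              seed = 1L) {
    cfg <- classifierHyperparams(maxEpochs, earlyStopPatience, learningRates,
                                 validationFraction, seed)
    cfg$hiddenUnits <- as.integer(hiddenUnits)
    stopifnot(cfg$hiddenUnits >= 1L)
    cfg
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.networkForward <- function(X, par) {
    H <- .sigmoid(sweep(X %*% par$W1, 2L, par$b1, "+"))
    list(H = H, f = drop(H %*% par$w2) + par$b2)
}

#' Fit the Faraggi-Simon survival network
#'
#' A feed-forward network with one hidden sigmoid layer and a scalar
#' log-hazard output, trained full-batch with Adam to minimise the negative
#' log partial likelihood. For each candidate learning rate the same
#' stratified validation split and initial weights are used; training stops
#' early when the validation concordance index has not improved for
#' `earlyStopPatience` epochs, weights are restored from the best epoch, and
#' the rate with the best validation c-index is kept. Deterministic given
#' the config seed.
#'
#' @param X samples x genes matrix of the selected genes (normalized scale).
#' @param timeDays positive survival times (days), one per row of `X`.
#' @param censored logical right-censoring indicator.
#' @param config list from [survivalFitConfig()].
#' @return a [SurvivalModel-class].
#' @export
fitSurvivalModel <- function(X, timeDays, censored,
                             config = survivalFitConfig()) {
    if (!is.matrix(X) || is.null(colnames(X)))
        stop("'X' must be a samples x genes matrix with gene column names")
    if (length(timeDays) != nrow(X) || length(censored) != nrow(X))
        stop("clinical vectors must match the rows of 'X'")
    if (sum(!censored) < 2L)
        stop("at least 2 uncensored samples are required to fit")
    d <- ncol(X); H <- config$hiddenUnits

    init <- withr::with_seed(config$seed, {
        val <- .stratifiedHoldout(ifelse(censored, "C", "E"),
                                  config$validationFraction)
        W1 <- matrix(stats::runif(d * H, -0.1, 0.1), d, H)
        b1 <- stats::runif(H, -0.1, 0.1)
        w2 <- stats::runif(H, -0.1, 0.1)
        b2 <- stats::runif(1L, -0.1, 0.1)
        list(val = val, par = list(W1 = W1, b1 = b1, w2 = w2, b2 = b2))
    })
    val <- init$val
    if (sum(!censored[!val]) < 2L)
        stop("too few uncensored samples left in the training split")
    Xtr <- X[!val, , drop = FALSE]
    ctlTr <- .riskSetControl(timeDays[!val], censored[!val])
    Xva <- X[val, , drop = FALSE]
    tVa <- timeDays[val]; cVa <- censored[val]
    canValidate <- sum(val) >= 2L && any(!cVa)
    nTr <- nrow(Xtr)

    valMetric <- function(par) {
        if (!canValidate) {
            # degenerate validation split: fall back to training loss
            fw <- .networkForward(Xtr, par)
            return(-.negLogPL(fw$f, ctlTr))
        }
        f <- .networkForward(Xva, par)$f
        ci <- tryCatch(harrellCIndex(f, tVa, cVa)$value,
                       error = function(e) NA_real_)
        if (is.na(ci)) -Inf else ci
    }

    best <- NULL
    perRate <- list()
    for (lr in config$learningRates) {
        par <- init$par
        state <- list()
        bestMetric <- -Inf; bestPar <- par; bestEpoch <- 0L
        sinceBest <- 0L; epochsRun <- 0L; diverged <- FALSE
        lossTrace <- numeric(0)
        for (epoch in seq_len(config$maxEpochs)) {
            fw <- .networkForward(Xtr, par)
            pl <- .negLogPL(fw$f, ctlTr, gradient = TRUE)
            if (!is.finite(pl$value)) { diverged <- TRUE; break }
            dH <- outer(pl$gradient, par$w2)          # n x H
            dZ <- dH * fw$H * (1 - fw$H)
            grad <- list(W1 = crossprod(Xtr, dZ) / nTr,
                         b1 = colSums(dZ) / nTr,
                         w2 = drop(crossprod(fw$H, pl$gradient)) / nTr,
                         b2 = sum(pl$gradient) / nTr)
            upd <- .adamStep(par, grad, state, lr)
            par <- upd$par; state <- upd$state
            if (any(!vapply(par, function(p) all(is.finite(p)), logical(1)))) {
                diverged <- TRUE; break
            }
            metric <- valMetric(par)
            epochsRun <- epoch
            lossTrace <- c(lossTrace, pl$value)
            if (metric > bestMetric + 1e-12) {
                bestMetric <- metric; bestPar <- par
                bestEpoch <- epoch; sinceBest <- 0L
            } else {
                sinceBest <- sinceBest + 1L
                if (sinceBest >= config$earlyStopPatience) break
            }
        }
        perRate[[as.character(lr)]] <-
            if (diverged) NA_real_ else bestMetric
        if (!diverged && (is.null(best) || bestMetric > best$metric)) {
            best <- list(par = bestPar, metric = bestMetric, lr = lr,
                         epochs = epochsRun, bestEpoch = bestEpoch,
                         lossTrace = lossTrace)
        }
    }
    if (is.null(best))
        stop("survival-model training diverged at every learning rate: ",
             paste(config$learningRates, collapse = ", "))
    new("SurvivalModel",
        W1 = unname(best$par$W1), b1 = unname(best$par$b1),
        w2 = unname(best$par$w2), b2 = unname(best$par$b2),
        geneIds = colnames(X),
        hiddenUnits = as.integer(H), activation = "sigmoid",
        trainingLog = list(learningRate = best$lr,
                           epochsRun = best$epochs,
                           bestEpoch = best$bestEpoch,
                           bestValidationCIndex = best$metric,
                           validationCIndexPerRate = perRate,
                           seed = config$seed))
}

#' Predict per-sample log-hazard risk
#'
#' Higher values mean higher predicted risk of death.
#'
#' @param model a [SurvivalModel-class].
#' @param X samples x genes matrix over exactly the genes the model was
#'   fitted on (same order).
#' @return named numeric vector of log-hazard scores.
#' @export
predictRisk <- function(model, X) {
    stopifnot(is(model, "SurvivalModel"))
    if (!identical(colnames(X), model@geneIds))
        stop("gene set/order of 'X' does not match the fitted model")
    par <- list(W1 = model@W1, b1 = model@b1, w2 = model@w2, b2 = model@b2)
    f <- .networkForward(X, par)$f
    stats::setNames(f, rownames(X))
}

#' @describeIn SurvivalModel-class training summary.
#' @param object a `SurvivalModel`.
#' @export
setMethod("show", "SurvivalModel", function(object) {
    cat(sprintf(
        "SurvivalModel: %d genes -> %d %s hidden units -> log-hazard; lr %g, val c-index %.3f\n",
        length(object@geneIds), object@hiddenUnits, object@activation,
        object@trainingLog$learningRate,
        object@trainingLog$bestValidationCIndex))
})

#' Save / load a fitted survival model as JSON
#'
#' The dump is a flat JSON document holding the architecture, weights and
#' training log; [readSurvivalModel()] restores an identical model.
#'
#' @param model a [SurvivalModel-class].
#' @param path file path.
#' @export
writeSurvivalModel <- function(model, path) {
    stopifnot(is(model, "SurvivalModel"))
    obj <- list(class = "SurvivalModel",
                geneIds = model@geneIds,
                hiddenUnits = model@hiddenUnits,
                activation = model@activation,
                W1 = as.numeric(model@W1),
                b1 = model@b1, w2 = model@w2, b2 = model@b2,
                trainingLog = model@trainingLog)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeSurvivalModel
#' @export
readSurvivalModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    H <- as.integer(obj$hiddenUnits)
    new("SurvivalModel",
        W1 = matrix(as.numeric(obj$W1), ncol = H),
        b1 = as.numeric(obj$b1), w2 = as.numeric(obj$w2),
        b2 = as.numeric(obj$b2), geneIds = as.character(obj$geneIds),
        hiddenUnits = H, activation = obj$activation,
        trainingLog = obj$trainingLog)
}
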