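#' Hyperparameters for the cascade's softmax classifier
#'
#' The training protocol mirrors the survival model's: full-batch Adam, at
#' most `maxEpochs` epochs with early stopping after `earlyStopPatience`
#' epochs without validation improvement, and the learning rate picked from
#' `learningRates` by best validation cross-entropy on a stratified
#' `validationFraction` holdout.
#'
#' @param maxEpochs maximum training epochs (default 100).
#' @param earlyStopPatience epochs without improvement before stopping
#'   (default 20).
#' @param learningRates candidate learning rates (default `10^-(1:4)`).
#' @param validationFraction fraction of labeled samples held out
#'   (default 0.2).
#' @param seed integer RNG seed for the split and the initialisation.
#' @return list of hyperparameters.
#' @export
classifierHyperparams <- function(maxEpochs = 100L, earlyStopPatience = 20L,
                                  learningRates = c(1e-1, 1e-2, 1e-3, 1e-4),
                                  validationFraction = 0.2, seed = 1L) {
    stopifnot(maxEpochs >= 1L, earlyStopPatience >= 1L,
              validationFraction > 0, validationFraction < 1,
              length(learningRates) >= 1L, all(learningRates > 0))
    list(maxEpochs = as.integer(maxEpochs),
         earlyStopPatience = as.integer(earlyStopPatience),
         learningRates = learningRates,
         validationFraction = validationFraction,
         seed = as.integer(seed))
}

.softmaxForward <- function(X, W, b) {
    Z <- sweep(X %*% W, 2L, b, "+")
    Z <- Z - apply(Z, 1L, max)
    E <- exp(Z)
    E / rowSums(E)
}

.crossEntropy <- function(P, Y) {
    -mean(rowSums(Y * log(pmax(P, 1e-300))))
}

#' Train a two-output softmax classifier on risk labels
#'
#' Fits softmax(XW + b) with classes (HIGH, LOW) by full-batch Adam on the
#' cross-entropy, restricted to the samples labeled HIGH or LOW. The
#' learning rate is selected from the candidate grid by the best validation
#' cross-entropy; weights are restored from the best epoch. Deterministic
#' given the seed in `hyperparams`.
#'
#' @param X samples x genes numeric matrix (min-max normalized); row names
#'   must cover the labeled sample ids.
#' @param labels a [RiskLabels-class].
#' @param hyperparams list from [classifierHyperparams()].
#' @return a [SoftmaxFit-class].
#' @export
trainSoftmaxClassifier <- function(X, labels,
                                   hyperparams = classifierHyperparams()) {
    stopifnot(is(labels, "RiskLabels"))
    grp <- riskGroups(labels)
    used <- names(grp)[grp %in% c("HIGH", "LOW")]
    if (!all(used %in% rownames(X)))
        stop("labeled samples missing from the expression matrix")
    nHigh <- sum(grp == "HIGH")
    nLow <- sum(grp == "LOW")
    if (nHigh == 0L || nLow == 0L)
        stop("both HIGH and LOW classes must be present")
    Xl <- X[used, , drop = FALSE]
    y <- grp[used] == "HIGH"
    Y <- cbind(HIGH = as.numeric(y), LOW = as.numeric(!y))
    d <- ncol(Xl)

    fit <- withr::with_seed(hyperparams$seed, {
        val <- .stratifiedHoldout(ifelse(y, "H", "L"),
                                  hyperparams$validationFraction)
        if (!any(val)) val[sample(length(y), 1L)] <- TRUE
        W0 <- matrix(stats::runif(d * 2L, -0.05, 0.05), d, 2L)
        b0 <- stats::runif(2L, -0.05, 0.05)
        list(val = val, W0 = W0, b0 = b0)
    })
    Xtr <- Xl[!fit$val, , drop = FALSE]; Ytr <- Y[!fit$val, , drop = FALSE]
    Xva <- Xl[fit$val, , drop = FALSE];  Yva <- Y[fit$val, , drop = FALSE]
    if (length(unique(Ytr[, 1L])) < 2L)
        stop("training split lost a class; too few labeled samples")
    nTr <- nrow(Xtr)

    best <- NULL
    perRate <- list()
    for (lr in hyperparams$learningRates) {
        W <- fit$W0; b <- fit$b0
        state <- list()
        bestVal <- Inf; bestW <- W; bestB <- b; bestEpoch <- 0L
        sinceBest <- 0L; epochsRun <- 0L; diverged <- FALSE
        for (epoch in seq_len(hyperparams$maxEpochs)) {
            P <- .softmaxForward(Xtr, W, b)
            G <- (P - Ytr) / nTr
            grad <- list(W = crossprod(Xtr, G), b = colSums(G))
            upd <- .adamStep(list(W = W, b = b), grad, state, lr)
            W <- upd$par$W; b <- upd$par$b; state <- upd$state
            if (any(!is.finite(W)) || any(!is.finite(b))) {
                diverged <- TRUE
                break
            }
            valLoss <- .crossEntropy(.softmaxForward(Xva, W, b), Yva)
            epochsRun <- epoch
            if (valLoss < bestVal - 1e-12) {
                bestVal <- valLoss; bestW <- W; bestB <- b
                bestEpoch <- epoch; sinceBest <- 0L
            } else {
                sinceBest <- sinceBest + 1L
                if (sinceBest >= hyperparams$earlyStopPatience) break
            }
        }
        perRate[[as.character(lr)]] <- if (diverged) NA_real_ else bestVal
        if (!diverged && (is.null(best) || bestVal < best$valLoss)) {
            best <- list(W = bestW, b = bestB, valLoss = bestVal,
                         lr = lr, epochs = epochsRun, bestEpoch = bestEpoch)
        }
    }
    if (is.null(best))
        stop("training diverged (non-finite loss) at every learning rate: ",
             paste(hyperparams$learningRates, collapse = ", "))
    gid <- colnames(Xl)
    new("SoftmaxFit",
        wHigh = stats::setNames(best$W[, 1L], gid),
        wLow = stats::setNames(best$W[, 2L], gid),
        biases = stats::setNames(best$b, c("HIGH", "LOW")),
        trainingLog = list(learningRate = best$lr,
                           epochsRun = best$epochs,
                           bestEpoch = best$bestEpoch,
                           bestValidationLoss = best$valLoss,
                           validationLossPerRate = perRate,
                           nHigh = nHigh, nLow = nLow,
                           seed = hyperparams$seed))
}

#' @describeIn SoftmaxFit-class training summary.
#' @param object a `SoftmaxFit`.
#' @export
setMethod("show", "SoftmaxFit", function(object) {
    cat(sprintf(
        "SoftmaxFit: %d genes; lr %g, %d epochs (best %d), val loss %.4f\n",
        length(object@wHigh), object@trainingLog$learningRate,
        object@trainingLog$epochsRun, object@trainingLog$bestEpoch,
        object@trainingLog$bestValidationLoss))
})
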