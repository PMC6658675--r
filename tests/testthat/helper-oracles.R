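# Independent brute-force oracles, deliberately written as plain double
# loops over the defining formulas so they share no code with the package
# implementations they check.

# Breslow Cox negative log partial likelihood, direct double loop.
oracleNegLogPL <- function(f, timeDays, censored) {
    total <- 0
    for (i in seq_along(f)) {
        if (censored[i]) next
        riskSum <- 0
        for (j in seq_along(f)) {
            if (timeDays[j] >= timeDays[i]) riskSum <- riskSum + exp(f[j])
        }
        total <- total + log(riskSum) - f[i]
    }
    total
}

# Harrell's c-index by exhaustive enumeration of ordered pairs.
oracleCIndex <- function(risk, timeDays, censored) {
    conc <- disc <- tied <- 0L
    n <- length(risk)
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (i == j) next
            if (censored[i] || timeDays[i] >= timeDays[j]) next
            if (risk[i] > risk[j]) conc <- conc + 1L
            else if (risk[i] < risk[j]) disc <- disc + 1L
            else tied <- tied + 1L
        }
    }
    list(value = (conc + 0.5 * tied) / (conc + disc + tied),
         concordant = conc, discordant = disc, tied_risk = tied)
}

# Discriminating power straight from its definition.
oracleDpScores <- function(wHigh, wLow, X, isHigh) {
    out <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
        out[j] <- abs(wHigh[j] * mean(X[isHigh, j]) -
                      wLow[j] * mean(X[!isHigh, j]))
    }
    stats::setNames(out, colnames(X))
}

# Two-class Fisher criterion straight from its definition.
oracleFisherScores <- function(X, isHigh) {
    out <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
        a <- X[isHigh, j]; b <- X[!isHigh, j]
        mu <- mean(X[, j])
        between <- length(a) * (mean(a) - mu)^2 + length(b) * (mean(b) - mu)^2
        within <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
        out[j] <- if (within == 0) Inf else between / within
    }
    stats::setNames(out, colnames(X))
}

# Gene-ranking-point merge: Point_j = sum_k (N - R_jk), direct summation.
oracleMergePoints <- function(rankLists) {
    genes <- sort(rankLists[[1L]])
    N <- length(genes)
    pts <- stats::setNames(numeric(N), genes)
    for (lst in rankLists) {
        for (r in seq_along(lst)) pts[lst[r]] <- pts[lst[r]] + (N - r)
    }
    pts
}
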