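# Precomputed risk-set bookkeeping shared by the loss and its gradient.
# Samples are sorted by decreasing time; tied times share a group, and the
# risk set of an event is every sample in its own or any earlier (longer
# surviving) group.
.riskSetControl <- function(timeDays, censored) {
    stopifnot(length(timeDays) == length(censored))
    if (any(!is.finite(timeDays)) || any(timeDays <= 0))
        stop("survival times must be positive and finite")
    if (!any(!censored)) stop("at least one uncensored sample is required")
    ord <- order(timeDays, decreasing = TRUE)
    ts <- timeDays[ord]
    grp <- cumsum(!duplicated(ts))            # group index along sorted order
    list(ord = ord, grp = grp, event = !censored[ord], nGroups = max(grp))
}

# Negative log partial likelihood given precomputed control; returns the
# value and, when gradient = TRUE, d(nll)/d(f) in the ORIGINAL sample order.
.negLogPL <- function(f, ctl, gradient = FALSE) {
    fs <- f[ctl$ord]
    m <- max(fs)
    ef <- exp(fs - m)
    groupSum <- rowsum(ef, ctl$grp)[, 1L]
    cumEf <- cumsum(groupSum)                 # risk-set sum per group
    nEvents <- rowsum(as.numeric(ctl$event), ctl$grp)[, 1L]
    value <- sum(nEvents * (log(cumEf) + m)) - sum(fs[ctl$event])
    if (!gradient) return(value)
    # d nll / d f_j = e^{f_j} * sum over events i with S_i <= S_j of
    # 1 / riskSum_i, minus 1 if j itself is an event.
    a <- nEvents / cumEf
    tailA <- rev(cumsum(rev(a)))              # events in group g or later
    g <- ef * tailA[ctl$grp] - as.numeric(ctl$event)
    grad <- numeric(length(f))
    grad[ctl$ord] <- g
    list(value = value, gradient = grad)
}

#' Negative log partial likelihood of a log-hazard vector
#'
#' The Cox/Faraggi-Simon cost: for every uncensored sample i,
#' `log( sum_{j : S_j >= S_i} exp(f_j) ) - f_i`, summed over events. Tied
#' times are handled Breslow-style — every sample with `S_j >= S_i` is in
#' the risk set. Numerically stabilised by max subtraction.
#'
#' @param f numeric vector of per-sample log-hazard values.
#' @param timeDays positive survival times.
#' @param censored logical right-censoring indicator (at least one `FALSE`).
#' @return single non-negative number.
#' @examples
#' negLogPartialLikelihood(c(0, 0), c(1, 2), c(FALSE, FALSE))  # log(2)
#' @export
negLogPartialLikelihood <- function(f, timeDays, censored) {
    if (any(!is.finite(f))) stop("non-finite log-hazard values")
    ctl <- .riskSetControl(timeDays, censored)
    .negLogPL(f, ctl)
}
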