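#' Derive a stage-specific seed from a master seed
#'
#' Deterministic 31-bit hash combining the master seed with a stage label,
#' so that every randomised stage of a pipeline (fold split, per-step
#' classifier init, simulation, ...) gets its own reproducible stream.
#'
#' @param seed integer master seed.
#' @param stage character label of the pipeline stage.
#' @return integer in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, stage) {
    mod <- 2147483647  # 2^31 - 1, prime
    h <- 17
    for (v in utf8ToInt(as.character(stage))) h <- (h * 31 + v) %% mod
    as.integer((h * 1103 + (as.numeric(seed) %% mod) * 30013) %% mod)
}

# Stratified index split: returns logical vector marking validation members.
# Guarantees >= 1 training member per stratum; validation may be empty for
# tiny strata.
.stratifiedHoldout <- function(strata, fraction) {
    val <- logical(length(strata))
    for (s in unique(strata)) {
        idx <- which(strata == s)
        nVal <- floor(length(idx) * fraction)
        if (nVal >= length(idx)) nVal <- length(idx) - 1L
        if (nVal > 0L) val[sample(idx, nVal)] <- TRUE
    }
    val
}

# One Adam update; state carries first/second moments and step count.
.adamStep <- function(par, grad, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
    if (is.null(state$m)) {
        state$m <- lapply(grad, function(g) g * 0)
        state$v <- lapply(grad, function(g) g * 0)
        state$t <- 0L
    }
    state$t <- state$t + 1L
    for (k in names(grad)) {
        state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grad[[k]]
        state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grad[[k]]^2
        mhat <- state$m[[k]] / (1 - beta1^state$t)
        vhat <- state$v[[k]] / (1 - beta2^state$t)
        par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
    }
    list(par = par, state = state)
}
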