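test_that("partial likelihood matches closed forms and the loop oracle", {
    # one uncensored sample: its risk set is itself
    expect_equal(negLogPartialLikelihood(5, 100, FALSE), 0)
    # two events, equal log-hazards: log 2
    expect_equal(negLogPartialLikelihood(c(0, 0), c(1, 2), c(FALSE, FALSE)),
                 log(2))
    withr::with_seed(21, {
        for (i in 1:20) {
            n <- 15L
            tm <- sample(1000:9999, n)     # distinct times
            cs <- stats::runif(n) < 0.4
            if (!any(!cs)) cs[1] <- FALSE
            f <- stats::rnorm(n)
            expect_equal(negLogPartialLikelihood(f, tm, cs),
                         oracleNegLogPL(f, tm, cs), tolerance = 1e-10)
        }
        # tied times: Breslow risk sets, still the same double loop
        tm <- sample(1:6, 12, replace = TRUE)
        cs <- rep(c(FALSE, TRUE), 6)
        f <- stats::rnorm(12)
        expect_equal(negLogPartialLikelihood(f, tm, cs),
                     oracleNegLogPL(f, tm, cs), tolerance = 1e-10)
    })
    expect_error(negLogPartialLikelihood(c(0, 0), c(1, 2), c(TRUE, TRUE)),
                 "uncensored")
    expect_error(negLogPartialLikelihood(c(Inf, 0), c(1, 2), c(FALSE, FALSE)),
                 "finite")
})

test_that("partial likelihood is shift-invariant and matches Cox/Breslow", {
    withr::with_seed(22, {
        tm <- sample(100:999, 12)
        cs <- stats::runif(12) < 0.3
        cs[1] <- FALSE
        f <- stats::rnorm(12)
        expect_equal(negLogPartialLikelihood(f + 17.3, tm, cs),
                     negLogPartialLikelihood(f, tm, cs), tolerance = 1e-9)

        # linear limit: f = X beta equals the Breslow Cox partial likelihood
        # evaluated by survival::coxph at that fixed beta
        X <- matrix(stats::rnorm(24), 12, 2)
        beta <- c(0.7, -0.4)
        fit <- survival::coxph(survival::Surv(tm, !cs) ~ X, ties = "breslow",
                               init = beta,
                               control = survival::coxph.control(iter.max = 0))
        expect_equal(negLogPartialLikelihood(drop(X %*% beta), tm, cs),
                     -fit$loglik[2], tolerance = 1e-8)
    })
})

test_that("the gradient of the partial likelihood is correct", {
    withr::with_seed(23, {
        tm <- sample(1:8, 10, replace = TRUE)
        cs <- stats::runif(10) < 0.3
        cs[2] <- FALSE
        f <- stats::rnorm(10)
        ctl <- cascadeWx:::.riskSetControl(tm, cs)
        g <- cascadeWx:::.negLogPL(f, ctl, gradient = TRUE)$gradient
        num <- vapply(seq_along(f), function(j) {
            h <- 1e-6
            fp <- f; fp[j] <- fp[j] + h
            fm <- f; fm[j] <- fm[j] - h
            (oracleNegLogPL(fp, tm, cs) - oracleNegLogPL(fm, tm, cs)) / (2 * h)
        }, numeric(1))
        expect_equal(g, num, tolerance = 1e-5)
    })
})

test_that("the network recovers signal from a linear-hazard cohort", {
    withr::with_seed(0, {
        n <- 450L
        X <- matrix(stats::rnorm(n * 5), n, 5,
                    dimnames = list(sprintf("s%03d", 1:n), paste0("g", 1:5)))
        beta <- c(1, -1, 0, 0, 0)
        lp <- drop(X %*% beta)
        eventY <- stats::rexp(n) / (0.4 * exp(lp))
        censY <- stats::runif(n, 0, 12)
        tm <- pmin(eventY, censY) * 365.25
        cs <- censY < eventY   # ~30% censored
        tr <- seq_len(300L); te <- 301:450
    })
    model <- fitSurvivalModel(X[tr, ], tm[tr], cs[tr],
                              survivalFitConfig(seed = 0))
    risk <- predictRisk(model, X[te, ])
    ciModel <- harrellCIndex(risk, tm[te], cs[te])$value
    ciTrue <- harrellCIndex(lp[te], tm[te], cs[te])$value
    expect_gte(ciModel, 0.65)
    expect_lte(ciModel, ciTrue + 0.02)  # true predictor is the ceiling
})

test_that("survival fitting is deterministic and validates its input", {
    d <- toyLabeledData(nPerClass = 30L, nGenes = 3L, seed = 30)
    withr::with_seed(31, {
        tm <- stats::runif(60, 100, 3000)
        cs <- stats::runif(60) < 0.3
    })
    cfg <- survivalFitConfig(seed = 5, hiddenUnits = 4L, maxEpochs = 30L)
    m1 <- fitSurvivalModel(d$X, tm, cs, cfg)
    m2 <- fitSurvivalModel(d$X, tm, cs, cfg)
    expect_identical(m1@W1, m2@W1)
    expect_identical(m1@trainingLog, m2@trainingLog)

    expect_error(fitSurvivalModel(d$X, tm, rep(TRUE, 60), cfg),
                 "uncensored")
})

test_that("risk prediction is consistent and guards the gene set", {
    d <- toyLabeledData(nPerClass = 10L, nGenes = 4L, seed = 32)
    # all-zero weights give a constant risk equal to the output bias
    zero <- new("SurvivalModel",
                W1 = matrix(0, 4, 2), b1 = c(0, 0), w2 = c(0, 0), b2 = 0.3,
                geneIds = colnames(d$X), hiddenUnits = 2L,
                activation = "sigmoid", trainingLog = list())
    expect_equal(unname(predictRisk(zero, d$X)), rep(0.3, nrow(d$X)))

    withr::with_seed(33, {
        model <- new("SurvivalModel",
                     W1 = matrix(stats::rnorm(8), 4, 2),
                     b1 = stats::rnorm(2), w2 = stats::rnorm(2),
                     b2 = stats::rnorm(1), geneIds = colnames(d$X),
                     hiddenUnits = 2L, activation = "sigmoid",
                     trainingLog = list())
    })
    batch <- predictRisk(model, d$X)
    oneByOne <- vapply(seq_len(nrow(d$X)), function(i)
        unname(predictRisk(model, d$X[i, , drop = FALSE])), numeric(1))
    expect_equal(unname(batch), oneByOne)
    expect_error(predictRisk(model, d$X[, c(2, 1, 3, 4)]), "gene")
})

test_that("models round-trip through the JSON dump", {
    d <- toyLabeledData(nPerClass = 15L, nGenes = 3L, seed = 34)
    withr::with_seed(35, {
        tm <- stats::runif(30, 100, 3000)
        cs <- stats::runif(30) < 0.3
    })
    m <- fitSurvivalModel(d$X, tm, cs,
                          survivalFitConfig(seed = 2, hiddenUnits = 3L,
                                            maxEpochs = 20L))
    p <- withr::local_tempfile(fileext = ".json")
    writeSurvivalModel(m, p)
    back <- readSurvivalModel(p)
    expect_equal(back@W1, m@W1)
    expect_equal(back@w2, m@w2)
    expect_identical(back@geneIds, m@geneIds)
    expect_equal(predictRisk(back, d$X), predictRisk(m, d$X))
})
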