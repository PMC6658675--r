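test_that("softmax classifier separates separable 1-D classes", {
    d <- toyLabeledData(nPerClass = 12L, nGenes = 1L, seed = 2, gap = 1)
    fit <- trainSoftmaxClassifier(d$X, d$labels,
                                  classifierHyperparams(seed = 3))
    # training accuracy: HIGH iff the HIGH logit wins
    logitHigh <- drop(d$X %*% fit@wHigh) + fit@biases["HIGH"]
    logitLow <- drop(d$X %*% fit@wLow) + fit@biases["LOW"]
    expect_identical(unname(logitHigh > logitLow), unname(d$isHigh))
})

test_that("softmax training is deterministic and rejects one-class input", {
    d <- toyLabeledData(seed = 4)
    f1 <- trainSoftmaxClassifier(d$X, d$labels,
                                 classifierHyperparams(seed = 9))
    f2 <- trainSoftmaxClassifier(d$X, d$labels,
                                 classifierHyperparams(seed = 9))
    expect_identical(f1@wHigh, f2@wHigh)
    expect_identical(f1@wLow, f2@wLow)
    expect_identical(f1@biases, f2@biases)

    allHigh <- assignRiskLabels(
        stats::setNames(rep(100, nrow(d$X)), rownames(d$X)),
        cutoffYears(3, 3), censored = rep(FALSE, nrow(d$X)),
        requireBothClasses = FALSE)
    expect_error(trainSoftmaxClassifier(d$X, allHigh),
                 "HIGH and LOW")
})

test_that("DP scores equal the defining formula", {
    # degenerate: zero weights -> all scores zero
    d <- toyLabeledData(seed = 5)
    zero <- new("SoftmaxFit",
                wHigh = stats::setNames(numeric(5), colnames(d$X)),
                wLow = stats::setNames(numeric(5), colnames(d$X)),
                biases = c(HIGH = 0, LOW = 0), trainingLog = list())
    expect_identical(unname(wxDpScores(zero, d$X, d$labels)), numeric(5))

    # single-gene arithmetic: |2 * 0.5 - 1 * 0.2| = 0.8
    X1 <- matrix(c(0.5, 0.5, 0.2, 0.2), 4, 1,
                 dimnames = list(paste0("s", 1:4), "g"))
    lab1 <- assignRiskLabels(
        stats::setNames(c(100, 100, 3000, 3000), rownames(X1)),
        cutoffYears(3, 3), censored = rep(FALSE, 4))
    one <- new("SoftmaxFit", wHigh = c(g = 2), wLow = c(g = 1),
               biases = c(HIGH = 0, LOW = 0), trainingLog = list())
    expect_equal(unname(wxDpScores(one, X1, lab1)), 0.8)

    # random instance vs the independent double-loop oracle
    withr::with_seed(6, {
        for (i in 1:10) {
            d <- toyLabeledData(nPerClass = 8L, nGenes = 5L,
                                seed = 100 + i)
            w <- new("SoftmaxFit",
                     wHigh = stats::setNames(stats::rnorm(5), colnames(d$X)),
                     wLow = stats::setNames(stats::rnorm(5), colnames(d$X)),
                     biases = stats::rnorm(2), trainingLog = list())
            expect_equal(wxDpScores(w, d$X, d$labels),
                         oracleDpScores(w@wHigh, w@wLow, d$X, d$isHigh),
                         tolerance = 1e-12)
        }
    })
    expect_true(all(wxDpScores(one, X1, lab1) >= 0))
})

test_that("Fisher scores match the two-class criterion", {
    d <- toyLabeledData(nPerClass = 6L, nGenes = 4L, seed = 7)
    # a gene with the same values in both classes has no separation
    Xc <- d$X; Xc[, 3] <- 0.7
    expect_equal(unname(fisherScores(Xc, d$labels)[3]), 0)

    # perfectly separating gene outranks every finite score
    Xp <- d$X; Xp[, 1] <- ifelse(d$isHigh, 1, 0)
    sp <- fisherScores(Xp, d$labels)
    expect_identical(names(which.max(sp)), colnames(Xp)[1])
    expect_true(sp[1] > max(sp[-1]))

    withr::with_seed(8, {
        for (i in 1:10) {
            d <- toyLabeledData(nPerClass = 7L, nGenes = 6L,
                                seed = 200 + i)
            expect_equal(fisherScores(d$X, d$labels),
                         oracleFisherScores(d$X, d$isHigh),
                         tolerance = 1e-12)
        }
    })

    tiny <- toyLabeledData(nPerClass = 1L, seed = 9)
    expect_error(fisherScores(tiny$X, tiny$labels), "at least 2")
})

test_that("rankFeatures orders by score then gene id", {
    r <- rankFeatures(c(A = 0.2, B = 0.9, C = 0.5))
    expect_identical(rankedGenes(r), c("B", "C", "A"))
    expect_identical(unname(featureScores(r)), c(0.9, 0.5, 0.2))

    tied <- rankFeatures(c(z = 1, a = 1, m = 1))
    expect_identical(rankedGenes(tied), c("a", "m", "z"))

    expect_identical(rankedGenes(rankFeatures(c(only = 3))), "only")
    expect_error(rankFeatures(c(a = NaN)), "NA|NaN")
})

test_that("both scorers honour the scorer contract", {
    d <- toyLabeledData(nPerClass = 8L, nGenes = 6L, seed = 10)
    for (nm in c("wx", "fisher")) {
        scorer <- getScorer(nm)
        s <- scorer(d$X, d$labels, classifierHyperparams(seed = 1))
        expect_identical(names(s), colnames(d$X))
        expect_true(all(is.finite(s)) && all(s >= 0))
    }
})

test_that("a planted class-mean gap is recovered as the top DP gene", {
    hits <- 0L
    for (run in 1:20) {
        withr::with_seed(3000 + run, {
            n <- 60L; dGenes <- 20L
            X <- matrix(stats::rnorm(n * dGenes), n, dGenes,
                        dimnames = list(sprintf("s%02d", 1:n),
                                        sprintf("g%02d", 1:dGenes)))
            isHigh <- rep(c(TRUE, FALSE), each = n / 2)
            X[isHigh, 7] <- X[isHigh, 7] + 2.0
            tm <- ifelse(isHigh, 300, 2500)
            labels <- assignRiskLabels(
                stats::setNames(tm, rownames(X)), cutoffYears(3, 3),
                censored = rep(FALSE, n))
        })
        scorer <- getScorer("wx")
        s <- scorer(X, labels, classifierHyperparams(seed = run))
        if (names(which.max(s)) == "g07") hits <- hits + 1L
    }
    expect_gte(hits, 19L)
})
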