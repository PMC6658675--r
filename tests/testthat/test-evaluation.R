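test_that("c-index hits the perfect and inverted extremes", {
    tm <- c(1, 2, 3); cs <- c(FALSE, FALSE, FALSE)
    expect_equal(harrellCIndex(c(3, 2, 1), tm, cs)$value, 1)
    expect_equal(harrellCIndex(c(1, 2, 3), tm, cs)$value, 0)
    expect_error(harrellCIndex(1, 5, TRUE), "comparable")
})

test_that("c-index equals exhaustive pair enumeration, ties included", {
    withr::with_seed(41, {
        for (i in 1:20) {
            inst <- randomSurvivalInstance(40L, tieTimes = i %% 2 == 0,
                                           tieRisks = TRUE)
            got <- harrellCIndex(inst$risk, inst$time, inst$censored)
            want <- oracleCIndex(inst$risk, inst$time, inst$censored)
            expect_identical(got$concordant, want$concordant)
            expect_identical(got$discordant, want$discordant)
            expect_identical(got$tied_risk, want$tied_risk)
            expect_identical(got$value, want$value)
        }
    })
})

test_that("c-index agrees with survival::concordance and is antisymmetric", {
    withr::with_seed(42, {
        for (i in 1:5) {
            inst <- randomSurvivalInstance(50L)
            got <- harrellCIndex(inst$risk, inst$time, inst$censored)
            ref <- survival::concordance(
                survival::Surv(inst$time, !inst$censored) ~ inst$risk,
                reverse = TRUE)$concordance
            expect_equal(got$value, unname(ref), tolerance = 1e-12)
            if (got$tied_risk == 0) {
                flipped <- harrellCIndex(-inst$risk, inst$time,
                                         inst$censored)$value
                expect_equal(got$value + flipped, 1)
            }
        }
    })
})

test_that("log-rank test matches a hand-worked table and the null", {
    # identical time/censoring multisets in both groups: O = E everywhere
    tm <- c(1, 2, 3, 1, 2, 3); cs <- rep(FALSE, 6)
    res <- logRankTest(tm, cs, rep(c("a", "b"), each = 3))
    expect_equal(res$statistic, 0, tolerance = 1e-12)
    expect_equal(res$p_value, 1)

    # hand computation, deaths at t=1,2 (group 1) and t=3,4 (group 2):
    # t=1: O1=1, E1=2/4, V=(2*2*1*3)/(16*3)=1/4
    # t=2: O1=1, E1=1/3, V=(1*2*1*2)/(9*2)=2/9
    # t=3: O1=0, E1=0,   V=0 ; t=4 last subject, V=0, E=0... group1 absent
    # sum(O-E) = 1-1/2 + 1-1/3 + 0-0 + 0-0 = 7/6; sum V = 1/4+2/9 = 17/36
    # statistic = (7/6)^2 / (17/36) = 49/17
    res <- logRankTest(c(1, 2, 3, 4), rep(FALSE, 4), c(1, 1, 2, 2))
    expect_equal(res$statistic, 49 / 17, tolerance = 1e-10)
    expect_identical(res$group_sizes, c(2L, 2L))

    # invariant under swapping the group labels
    withr::with_seed(43, {
        inst <- randomSurvivalInstance(30L)
        g <- rep(c(0, 1), 15)
        a <- logRankTest(inst$time, inst$censored, g)
        b <- logRankTest(inst$time, inst$censored, 1 - g)
        expect_equal(a$statistic, b$statistic)
        expect_true(a$p_value >= 0 && a$p_value <= 1)
    })
    expect_error(logRankTest(c(1, 2), c(FALSE, FALSE), c(1, 1)), "two")
    expect_error(logRankTest(c(1, 2), c(TRUE, TRUE), c(1, 2)), "event")
})

test_that("Kaplan-Meier reproduces hand product-limit curves", {
    km <- kaplanMeier(c(10, 20, 30, 40), rep(FALSE, 4))
    expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

    km <- kaplanMeier(c(10, 20, 30), rep(TRUE, 3))
    expect_true(all(km$surv == 1))

    # deaths at 1 and 3, censoring at 2: S(1) = 2/3, S(3) = 2/3 * 0 = 0
    km <- kaplanMeier(c(1, 2, 3), c(FALSE, TRUE, FALSE))
    expect_equal(km$surv[km$time == 1], 2 / 3)
    expect_equal(km$surv[km$time == 3], 0)

    # curve is non-increasing and starts at or below 1
    withr::with_seed(44, {
        inst <- randomSurvivalInstance(50L, tieTimes = TRUE)
        km <- kaplanMeier(inst$time, inst$censored)
        expect_true(all(diff(km$surv) <= 1e-12))
        expect_true(all(km$surv <= 1 & km$surv >= 0))
    })
})

test_that("stratified folds balance the censoring classes", {
    cs <- rep(c(TRUE, FALSE), each = 10)
    f <- stratifiedKFold(cs, k = 5, seed = 1)
    for (k in 1:5) {
        expect_identical(sum(f == k & cs), 2L)
        expect_identical(sum(f == k & !cs), 2L)
    }
    expect_identical(sort(unique(f)), 1:5)
    expect_identical(stratifiedKFold(cs, 5, seed = 1), f)
    expect_false(identical(stratifiedKFold(cs, 5, seed = 2), f))
    expect_error(stratifiedKFold(c(TRUE, rep(FALSE, 10)), k = 5), "stratum")
})

test_that("rank merging equals the direct gene-ranking-point sum", {
    mk <- function(ids) new("FeatureRanking", geneIds = ids,
                            scores = rev(seq_along(ids)) * 1.0,
                            eliminatedAtStep = integer(length(ids)))
    genes <- sprintf("g%02d", 1:20)
    withr::with_seed(45, {
        for (i in 1:10) {
            lists <- replicate(5, sample(genes), simplify = FALSE)
            merged <- mergeRankings(lapply(lists, mk))
            pts <- oracleMergePoints(lists)
            expect_equal(stats::setNames(merged$points, merged$gene_id),
                         pts[order(-pts, names(pts))])
        }
    })

    # a gene ranked first everywhere collects k * (N - 1) points
    always <- mergeRankings(replicate(5, mk(genes), simplify = FALSE))
    expect_identical(always$gene_id[1], "g01")
    expect_identical(always$points[1], 5 * (20 - 1))

    # symmetric ranks tie and break by gene id; fold order is irrelevant
    a <- mk(c("A", "B", "C")); b <- mk(c("B", "A", "C"))
    m1 <- mergeRankings(list(a, b)); m2 <- mergeRankings(list(b, a))
    expect_identical(m1, m2)
    expect_identical(m1$gene_id[1:2], c("A", "B"))
    expect_identical(m1$points[1], m1$points[2])

    expect_error(mergeRankings(list(mk(genes), mk(genes[-1]))), "gene set")
})

test_that("top-k evaluation has sound bookkeeping and a null at 0.5", {
    sim <- generateCohort(syntheticConfig(nSamples = 200, nGenes = 15,
                                          nCausal = 0, seed = 46))
    pc <- preprocessExpression(sim$cohort)
    folds <- stratifiedKFold(isCensored(pc), k = 5, seed = 46)
    ranking <- rankFeatures(stats::setNames(
        seq_len(ncol(exprMatrix(pc))), colnames(exprMatrix(pc))))
    ev <- evaluateTopK(pc, ranking, folds, ks = c(2, 5),
                       config = survivalFitConfig(hiddenUnits = 4L,
                                                  maxEpochs = 40L),
                       seed = 46)
    expect_identical(nrow(ev$summary), 2L)
    expect_identical(nrow(ev$perFold), 10L)
    expect_equal(ev$summary$mean_c_index[1],
                 mean(ev$perFold$c_index[ev$perFold$k == 2]))
    # pure-noise genes carry no prognostic signal
    expect_true(all(abs(ev$summary$mean_c_index - 0.5) <= 0.1))
    expect_error(evaluateTopK(pc, ranking, folds, ks = 99), "exceeds")
})
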