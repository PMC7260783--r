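# Conformal machinery: scores, error model, calibration, intervals.

test_that("nonconformity is the scaled absolute residual", {
    expect_equal(nonconformity(6, 5, 0.5), 2)
    expect_equal(nonconformity(5, 5, 0.3), 0)
    expect_equal(nonconformity(4, 7, 1.5), 2)   # symmetric in the sign
    expect_error(nonconformity(1, 2, 0), "positive")
})

test_that("conformal quantile follows the ceil(c(n+1)) convention", {
    tab <- new("CalibrationTable", scores = seq(0.5, 4.5, by = 0.5), n = 9L)
    expect_equal(conformalQuantile(tab, 0.9), 4.5)    # index ceil(9) = 9
    expect_identical(conformalQuantile(tab, 0.95), Inf)  # index 10 > n
    expect_equal(conformalQuantile(tab, 0.5), tab@scores[5])
    # monotone in confidence (Inf once the table is exhausted)
    cs <- seq(0.05, 0.95, by = 0.05)
    qs <- vapply(cs, function(cc) conformalQuantile(tab, cc), 0)
    fin <- is.finite(qs)
    expect_true(all(diff(qs[fin]) >= 0))
    expect_true(all(which(!fin) > max(which(fin))))
})

test_that("interval width and domain flags follow the stated arithmetic", {
    # lambda = 0.8, alpha* = 4.5 -> half-width 3.6, width 7.2 > 4 -> out
    tab <- new("CalibrationTable", scores = seq(0.5, 4.5, by = 0.5), n = 9L)
    a <- conformalQuantile(tab, 0.9)
    hw <- 0.8 * a
    expect_equal(hw, 3.6)
    expect_false(2 * hw <= 4.0)
    # all-zero calibration scores -> zero width, in domain
    tab0 <- new("CalibrationTable", scores = rep(0, 5), n = 5L)
    expect_equal(conformalQuantile(tab0, 0.8) * 0.8, 0)
    # raising maxWidth can only turn out-of-domain into in-domain
    for (mw in c(2, 4, 8, 16)) {
        inD1 <- 2 * hw <= mw
        inD2 <- 2 * hw <= mw * 2
        if (inD1) expect_true(inD2)
    }
})

test_that("error model tracks homoscedastic noise magnitude", {
    sigma <- 0.5
    ls1 <- generateLigandSet(nCompounds = 150L, noiseSigma = sigma,
                             seed = 21L, assayId = "ERR-1")
    pt <- trainPointModel(ls1, seed = 1L)
    er <- trainErrorModel(ls1, pt, seed = 2L)
    lam <- predictActivity(er, qaffp:::.ligandFingerprints(ls1))
    expect_true(all(lam >= er@floor))
    analytic <- sigma * sqrt(2 / pi)      # mean |N(0, sigma)|
    expect_lt(abs(mean(lam) - analytic), 0.5 * analytic)
})

test_that("noiseless data drives the error model toward its floor", {
    ls0 <- fixtureLigandSet()
    pt0 <- trainPointModel(ls0, seed = 1L)
    er0 <- trainErrorModel(ls0, pt0, seed = 2L)
    lam0 <- predictActivity(er0, qaffp:::.ligandFingerprints(ls0))
    expect_true(all(lam0 >= er0@floor))
    # same molecules, noisy activities: expected residuals clearly larger
    lsN <- generateLigandSet(nCompounds = 120L, noiseSigma = 0.8,
                             seed = 7L, assayId = "FIX-N")
    ptN <- trainPointModel(lsN, seed = 1L)
    erN <- trainErrorModel(lsN, ptN, seed = 2L)
    lamN <- predictActivity(erN, qaffp:::.ligandFingerprints(lsN))
    expect_lt(mean(lam0), mean(lamN))
    expect_lt(mean(lam0), 0.5)   # small relative to the ~4 log-unit range
})

test_that("ICP calibration recomputes hand-derived scores", {
    ls1 <- generateLigandSet(nCompounds = 60L, seed = 22L,
                             assayId = "ICP-1")
    ids <- compoundIds(ls1)
    proper <- ids[1:40]; calib <- ids[41:60]
    pt <- trainPointModel(ls1, ids = proper, seed = 5L)
    er <- trainErrorModel(ls1, pt, seed = 6L)
    tab <- icpCalibrate(pt, er, ls1, calib)
    expect_identical(tab@n, 20L)
    sub <- subsetLigands(ls1, calib)
    X <- qaffp:::.ligandFingerprints(sub)
    byHand <- sort(abs(activities(sub) - predictActivity(pt, X)) /
                   predictActivity(er, X))
    expect_equal(tab@scores, unname(byHand), tolerance = 1e-12)
    expect_error(icpCalibrate(pt, er, ls1, character(0)), "empty")
    expect_error(icpCalibrate(pt, er, ls1, proper[1]), "overlap")
})

test_that("CCP pools exactly one score per compound and matches LOO", {
    ls1 <- generateLigandSet(nCompounds = 12L, seed = 23L,
                             assayId = "CCP-1", nSignalBits = 5L)
    fit <- ccpTrain(ls1, k = 12L, seed = 4L)
    expect_identical(fit$table@n, 12L)
    # leave-one-out oracle: rebuild each singleton fold's score through
    # the public operations, given the recorded fold assignment
    scores <- numeric(0)
    for (f in seq_along(fit$folds)) {
        held <- fit$folds[[f]]
        pt <- trainPointModel(ls1, ids = setdiff(compoundIds(ls1), held),
                              seed = qaffp:::.deriveSeed(4L, f, 1L))
        er <- trainErrorModel(ls1, pt,
                              seed = qaffp:::.deriveSeed(4L, f, 2L))
        scores <- c(scores, icpCalibrate(pt, er, ls1, held)@scores)
    }
    expect_equal(fit$table@scores, sort(scores), tolerance = 1e-12)
    # partition property at smaller k
    fit5 <- ccpTrain(ls1, k = 4L, seed = 4L)
    expect_identical(fit5$table@n, 12L)
    expect_error(ccpTrain(ls1, k = 13L), "folds")
})

test_that("ICP intervals achieve close-to-nominal coverage", {
    # compact validity check; the acceptance suite runs the large version
    ls1 <- generateLigandSet(nCompounds = 600L, noiseSigma = 0.4,
                             seed = 24L, assayId = "COV-1")
    ids <- compoundIds(ls1)
    set.seed(1)
    proper <- sample(ids, 250L)
    calib <- sample(setdiff(ids, proper), 150L)
    test <- setdiff(ids, c(proper, calib))
    pt <- trainPointModel(ls1, ids = proper, seed = 1L)
    er <- trainErrorModel(ls1, pt, seed = 2L)
    tab <- icpCalibrate(pt, er, ls1, calib)
    sub <- subsetLigands(ls1, test)
    pi <- predictInterval(pt, er, tab, qaffp:::.ligandFingerprints(sub),
                          confidence = 0.9)
    cov <- mean(abs(activities(sub) - pi@midpoint) <= pi@halfWidth)
    se <- sqrt(0.9 * 0.1 / length(test))
    expect_gte(cov, 0.9 - 3 * se)
    # width grows with confidence for each molecule
    pi95 <- predictInterval(pt, er, tab,
                            qaffp:::.ligandFingerprints(sub),
                            confidence = 0.95)
    expect_true(all(pi95@halfWidth >= pi@halfWidth))
})

test_that("conformal bundles respect the ICP training separation", {
    ls1 <- generateLigandSet(nCompounds = 110L, noiseSigma = 0,
                             seed = 25L, assayId = "BND-1")
    bundle <- conformalQSAR(ls1, method = "icp", k = 5L, repeats = 1L,
                            seed = 3L)
    expect_s4_class(bundle, "ConformalQSARModel")
    # calibration compounds were never seen by the deployed point model
    expect_identical(bundle@calibration@n,
                     length(ls1) - length(bundle@point@trainIds) -
                         length(stratifiedSplit(ls1, seed = 3L)@testIds))
    expect_true(bundle@calibration@n > 0)
})
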