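# The three evaluation harnesses.

test_that("benchmark sets enforce disjoint classes", {
    expect_error(benchSet("t", c("CCO"), c("OCC")), "disjoint")
    bs <- benchSet("t", c("CCO", "CCC"), c("CCN"), kind = "HET")
    expect_length(smiles(actives(bs)), 2L)
    expect_length(smiles(inactives(bs)), 1L)
})

test_that("similarity searching separates a planted signal from noise", {
    # a homogeneous active series (one scaffold family) against a mixed
    # background: the textbook similarity-searching use case
    lib <- moleculeLibrary()
    set.seed(30)
    actSmi <- sample(lib$smiles[lib$family == "naphthalene"], 40L)
    inaSmi <- sample(lib$smiles[lib$family %in%
                                c("benzene", "thiophene", "biphenyl")],
                     80L)
    bs <- benchSet("SIM-1", actSmi, inaSmi, kind = "HET")
    scheme <- fingerprintScheme("morgan2")
    res <- runSimilarityBenchmark(bs, scheme, nRep = 10L, nQuery = 10L,
                                  inactiveHoldout = 0.2, seed = 5L)
    expect_identical(nrow(repetitions(res)), 10L)
    expect_gt(res@auc, 0.9)
    # determinism: same master seed, bitwise-identical repetitions
    res2 <- runSimilarityBenchmark(bs, scheme, nRep = 10L, nQuery = 10L,
                                   inactiveHoldout = 0.2, seed = 5L)
    expect_identical(repetitions(res), repetitions(res2))
    expect_error(runSimilarityBenchmark(
        benchSet("tiny", c("CCO", "CCC"), c("CCN"), kind = "HET"),
        scheme), "actives")
})

test_that("random fingerprints give chance-level retrieval", {
    set.seed(32)
    n <- 120L
    labels <- rep(c(1, 0), c(20, 100))
    aucs <- replicate(50, {
        X <- matrix(rbinom(n * 64, 1, 0.3), nrow = n)  # fresh draw per rep
        q <- sample(which(labels == 1), 5)
        pool <- setdiff(seq_len(n), q)
        rocAuc(maxFusionScores(X[q, ], X[pool, ], "tanimoto"),
               labels[pool])
    })
    expect_lt(abs(mean(aucs) - 0.5), 3 * sd(aucs) / sqrt(50))
})

test_that("balanced RF draws equal class counts per tree", {
    set.seed(33)
    X <- matrix(rnorm(200 * 5), ncol = 5)
    y <- rep(c(TRUE, FALSE), c(30, 170))     # imbalanced toy set
    model <- qaffp:::.balancedRF(X, y, nTrees = 25L, seed = 1L)
    inbag <- model$inbag                     # draws per compound per tree
    perTree <- t(vapply(seq_len(ncol(inbag)), function(t)
        c(pos = sum(inbag[y, t]), neg = sum(inbag[!y, t])), c(0, 0)))
    expect_true(all(perTree[, "pos"] == 30))
    expect_true(all(perTree[, "neg"] == 30))
})

test_that("classification benchmark learns separable sets, not permuted ones", {
    bs <- generateClassSet(nAct = 70L, nInact = 90L, nScaffolds = 3L,
                           seed = 34L, targetId = "CLS-1")
    scheme <- fingerprintScheme("morgan2")
    res <- runClassificationBenchmark(bs, scheme, repeats = 2L, seed = 6L)
    expect_identical(nrow(repetitions(res)), 10L)   # 5 folds x 2 repeats
    expect_gte(res@auc, 0.9)
    # permuting the labels reduces performance to chance
    set.seed(35)
    perm <- sample(length(bs@active))
    bsPerm <- new("BenchSet", targetId = "CLS-null",
                  molecules = bs@molecules[perm], active = bs@active,
                  activity = bs@activity, kind = "CLASS",
                  metadata = list())
    resPerm <- runClassificationBenchmark(bsPerm, scheme, repeats = 2L,
                                          seed = 6L)
    expect_lt(abs(resPerm@auc - 0.5), 0.1)
    # the CLASS size rule is strict
    small <- benchSet("small", smiles(actives(bs))[1:10],
                      smiles(inactives(bs))[1:10], kind = "CLASS")
    expect_error(runClassificationBenchmark(small, scheme), "more than 60")
})

test_that("scaffold hopping counts planted ground truth exactly", {
    lib <- moleculeLibrary()
    fam <- function(name, n) head(lib$smiles[lib$family == name], n)
    # CSK A: 6 actives (the only RACSK); B: 2 actives; C: 1 active
    actSmi <- c(fam("benzene", 6), fam("naphthalene", 2),
                fam("cycloheptane", 1))
    inaSmi <- c(fam("thiophene", 8), fam("biphenyl", 8))
    bs <- benchSet("HOP-1", actSmi, inaSmi, kind = "CLASS",
                   activity = c(rep(7, 9), rep(4, 16)))
    scheme <- fingerprintScheme("morgan2")
    csks <- cskSmiles(cyclicSkeleton(bs@molecules, onAcyclic = "na"))
    cskB <- unique(csks[7:8]); cskC <- csks[9]
    # oracle classifier flags exactly one naphthalene-family compound
    target <- smiles(bs@molecules)[7]
    fpTarget <- morganFingerprint(target)
    oracle <- function(trainX, trainY, testX)
        as.numeric(apply(testX, 1, function(r)
            all(r == as.numeric(fpTarget))))
    res <- runScaffoldHopping(bs, scheme, classifier = oracle, seed = 1L)
    expect_identical(res@nRacsk, 1L)
    expect_identical(res@nAcskTotal, 3L)
    expect_identical(res@retrievedCsk, cskB)
    expect_identical(nRetrieved(res), 1L)
    # a classifier that rejects everything retrieves nothing
    nihilist <- function(trainX, trainY, testX) rep(0, nrow(testX))
    res0 <- runScaffoldHopping(bs, scheme, classifier = nihilist)
    expect_identical(nRetrieved(res0), 0L)
    # pooling rv and b retrievals is a set union
    resC <- new("HoppingResult", assayId = "HOP-1", nAcskTotal = 3L,
                nRacsk = 1L, retrievedCsk = cskC)
    pooled <- poolHoppingResults(res, resC)
    expect_setequal(pooled@retrievedCsk, c(cskB, cskC))
    expect_gte(nRetrieved(pooled), max(nRetrieved(res), nRetrieved(resC)))
})

test_that("assays without a rich scaffold are skipped with a notice", {
    lib <- moleculeLibrary()
    bs <- benchSet("NORACSK",
                   head(lib$smiles[lib$family == "benzene"], 3),
                   head(lib$smiles[lib$family == "thiophene"], 10),
                   kind = "CLASS", activity = c(rep(7, 3), rep(4, 10)))
    expect_message(res <- runScaffoldHopping(
        bs, fingerprintScheme("morgan2")), "no rich")
    expect_identical(res@nRacsk, 0L)
    expect_identical(nRetrieved(res), 0L)
})
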