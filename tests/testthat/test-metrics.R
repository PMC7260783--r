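# Similarity indices, fusion, AUC and enrichment.

test_that("Rogot-Goldberg matches hand values and its invariants", {
    x <- c(1, 1, 0, 0, 1); y <- x
    expect_equal(rogotGoldberg(x, y), 1)
    expect_equal(rogotGoldberg(x, 1 - x), 0)
    # a=2, b=1, c=1, d=4
    a <- c(1, 1, 1, 0, 0, 0, 0, 0)
    b <- c(1, 1, 0, 1, 0, 0, 0, 0)
    expect_equal(rogotGoldberg(a, b), 2 / 6 + 4 / 10)
    expect_error(rogotGoldberg(c(1, 0), c(1, 0, 1)), "length")
    # identical degenerate vectors still score 1
    expect_equal(rogotGoldberg(c(1, 1), c(1, 1)), 1)
    expect_equal(rogotGoldberg(c(0, 0), c(0, 0)), 1)
    set.seed(5)
    for (i in 1:200) {
        u <- rbinom(32, 1, runif(1)); v <- rbinom(32, 1, runif(1))
        s <- rogotGoldberg(u, v)
        expect_equal(s, rogotGoldberg(v, u))            # symmetric
        expect_gte(s, 0); expect_lte(s, 1)
        expect_equal(s, oracleRogot(u, v), tolerance = 1e-12)
        if (!identical(u, v)) expect_lt(s, 1)           # 1 iff identical
    }
})

test_that("Tanimoto matches hand values", {
    expect_equal(tanimoto(c(1, 0, 1), c(1, 0, 1)), 1)
    expect_equal(tanimoto(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
    # a=1, b=1, c=2
    expect_equal(tanimoto(c(1, 1, 0, 0), c(1, 0, 1, 1)), 0.25)
    expect_warning(z <- tanimoto(c(0, 0), c(0, 0)), "all-zero")
    expect_equal(z, 0)
})

test_that("MAX fusion equals the brute-force double loop", {
    set.seed(6)
    Q <- matrix(rbinom(3 * 64, 1, 0.3), nrow = 3)
    P <- matrix(rbinom(5 * 64, 1, 0.3), nrow = 5)
    for (sim in c("tanimoto", "rogot_goldberg")) {
        f <- if (sim == "tanimoto") oracleTanimoto else oracleRogot
        want <- apply(P, 1, function(p) max(apply(Q, 1, f, p)))
        expect_equal(maxFusionScores(Q, P, sim = sim), want,
                     tolerance = 1e-12)
    }
    expect_equal(maxFusionScores(Q, matrix(0, 0, 64)), numeric(0))
    expect_error(maxFusionScores(matrix(0, 0, 64), P), "query")
    # single query reduces to the plain similarity
    expect_equal(maxFusionScores(Q[1, , drop = FALSE], P, "tanimoto"),
                 apply(P, 1, oracleTanimoto, Q[1, ]))
})

test_that("AUC is the tie-aware Mann-Whitney probability", {
    expect_equal(rocAuc(c(3, 4, 1, 2), c(1, 1, 0, 0)), 1)
    expect_equal(rocAuc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
    expect_equal(rocAuc(c(0.8, 0.5, 0.5, 0.2), c(1, 1, 0, 0)), 0.875)
    expect_error(rocAuc(1:3, c(1, 1, 1)), "undefined")
    set.seed(7)
    for (i in 1:200) {
        sc <- sample(1:10, 30, replace = TRUE)   # force ties
        lb <- rbinom(30, 1, 0.4)
        if (sum(lb) == 0 || sum(lb) == 30) next
        expect_equal(rocAuc(sc, lb), oracleAuc(sc, lb),
                     tolerance = 1e-12)
    }
})

test_that("enrichment factor matches its definition and edge cases", {
    # 1000 compounds, 10 actives all in the top 50 -> EF5 = 20
    scores <- c(seq(1000, 991), runif(990, 0, 900))
    labels <- c(rep(1, 10), rep(0, 990))
    expect_equal(enrichmentFactor(scores, labels, chi = 0.05), 20)
    # no actives in the top fraction
    expect_equal(enrichmentFactor(rev(seq_len(100)),
                                  c(rep(0, 95), rep(1, 5)), chi = 0.05), 0)
    # chi = 1 is always 1
    set.seed(8)
    expect_equal(enrichmentFactor(runif(50), rbinom(50, 1, 0.3), chi = 1),
                 1)
    # oracle agreement on tie-free continuous scores
    for (i in 1:200) {
        sc <- runif(40); lb <- rbinom(40, 1, 0.3)
        if (sum(lb) == 0) next
        expect_equal(enrichmentFactor(sc, lb, chi = 0.1),
                     oracleEf(sc, lb, chi = 0.1), tolerance = 1e-12)
    }
})

test_that("moving an active up the ranking never decreases EF5", {
    set.seed(9)
    for (i in 1:30) {
        sc <- runif(60); lb <- rbinom(60, 1, 0.2)
        if (sum(lb) == 0) next
        ef1 <- enrichmentFactor(sc, lb, chi = 0.05)
        j <- sample(which(lb == 1), 1)
        sc2 <- sc; sc2[j] <- max(sc) + 1   # promote one active to the top
        ef2 <- enrichmentFactor(sc2, lb, chi = 0.05)
        expect_gte(ef2, ef1 - 1e-12)
    }
})
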