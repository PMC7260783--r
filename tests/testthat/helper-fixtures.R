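# Shared fixtures, built once per test session. Fingerprints are memoised
# inside the package, so repeated use across test files is cheap.

# small noiseless ligand set: the workhorse for model/conformal tests
fixtureLigandSet <- local({
    cache <- NULL
    function() {
        if (is.null(cache))
            cache <<- generateLigandSet(nCompounds = 120L,
                                        noiseSigma = 0, seed = 7L,
                                        assayId = "FIX-1")
        cache
    }
})

# a small gated panel of three noiseless assays (ICP conformal bundles)
fixturePanel <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            bundles <- lapply(1:3, function(i) {
                ls <- generateLigandSet(nCompounds = 110L, noiseSigma = 0,
                                        seed = 100L + i,
                                        assayId = sprintf("PNL-%d", i))
                conformalQSAR(ls, method = "icp", k = 5L, repeats = 1L,
                              seed = i)
            })
            cache <<- assemblePanel(bundles)
        }
        cache
    }
})

# molecules disjoint from most fixture training draws, for prediction
fixtureQueryMolecules <- function(n = 20L, seed = 999L) {
    lib <- moleculeLibrary()
    set.seed(seed)
    parseMolecules(sample(lib$smiles, n))
}

# brute-force oracles, deliberately naive re-implementations
oracleAuc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg)
        tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
}

oracleEf <- function(scores, labels, chi = 0.05) {
    # assumes no ties at the boundary (callers draw continuous scores)
    n <- length(scores)
    nChi <- ceiling(chi * n)
    top <- order(scores, decreasing = TRUE)[seq_len(nChi)]
    (sum(labels[top]) / nChi) / (sum(labels) / n)
}

oracleRogot <- function(x, y) {
    a <- sum(x & y); d <- sum(!x & !y)
    b <- sum(x & !y); c <- sum(!x & y)
    t1 <- if (2 * a + b + c == 0) 0.5 else a / (2 * a + b + c)
    t2 <- if (2 * d + b + c == 0) 0.5 else d / (2 * d + b + c)
    t1 + t2
}

oracleTanimoto <- function(x, y) {
    a <- sum(x & y)
    u <- sum(x | y)
    if (u == 0) 0 else a / u
}

# exact Wilcoxon by literal enumeration of all 2^n sign assignments
oracleWilcoxon <- function(d, alternative) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    w <- sum(r[d > 0])
    signs <- expand.grid(rep(list(c(0, 1)), n))
    ws <- as.matrix(signs) %*% r
    pGE <- mean(ws >= w - 1e-9)
    pLE <- mean(ws <= w + 1e-9)
    switch(alternative,
           greater = pGE, less = pLE,
           two_sided = min(1, 2 * min(pGE, pLE)))
}
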