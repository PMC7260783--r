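# Panel assembly and rv/b fingerprint emission.

test_that("panel assembly keeps only gated models and rejects duplicates", {
    panel <- fixturePanel()
    expect_s4_class(panel, "AffinityPanel")
    expect_true(all(vapply(panel@assays, gatePassed, TRUE)))
    expect_identical(assayIds(panel), sort(assayIds(panel)))
    # a failing bundle is dropped
    failing <- panel@assays[[1]]
    failing@assayId <- "ZZZ-FAIL"
    failing@gate <- gateMetricsFrom(0.1, 0.1)
    expect_length(assemblePanel(c(panel@assays, failing)), length(panel))
    expect_error(assemblePanel(list(failing)), "no bundle passed")
    expect_error(assemblePanel(c(panel@assays, panel@assays[[1]])),
                 "duplicate")
})

test_that("imputation replaces unreliable components by the reliable mean", {
    vals <- rbind(c(6, 8, 4), c(5, 5, 5))
    rel <- rbind(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, TRUE))
    out <- qaffp:::.imputeUnreliable(vals, rel)
    expect_equal(out$values[1, 3], 7)            # mean of 6 and 8
    expect_equal(out$values[2, ], c(5, 5, 5))    # untouched
    expect_identical(out$imputed, !rel)
    relNone <- rbind(c(FALSE, FALSE, FALSE), c(TRUE, TRUE, TRUE))
    expect_error(qaffp:::.imputeUnreliable(vals, relNone), "no reliable")
})

test_that("binarization follows the cutoff and domain rules", {
    vals <- rbind(c(6.2, 4.2, 9.0))
    rel <- rbind(c(TRUE, TRUE, FALSE))
    expect_identical(qaffp:::.binarize(vals, rel, 5, adUsed = TRUE),
                     rbind(c(1L, 0L, 0L)))   # out-of-domain -> 0
    expect_identical(qaffp:::.binarize(vals, rel, 5, adUsed = FALSE),
                     rbind(c(1L, 0L, 1L)))
})

test_that("rv fingerprints have panel geometry and policy contracts hold", {
    panel <- fixturePanel()
    mols <- fixtureQueryMolecules(12L)
    rv <- rvQaffp(panel, mols)
    expect_identical(dim(rv@values), c(12L, length(panel)))
    expect_identical(assayIds(rv), assayIds(panel))
    expect_false(any(rv@imputed))
    # ignore-policy values are invariant to the AD parameters
    rv2 <- rvQaffp(panel, mols, confidence = 0.5, maxWidth = 0.01)
    expect_identical(rv@values, rv2@values)
    # impute policy: reliable components keep their raw predictions and
    # imputed components are exactly the unreliable ones
    rvImp <- rvQaffp(panel, mols, adPolicy = "impute", maxWidth = 6)
    expect_identical(rvImp@imputed, !rvImp@reliable)
    expect_identical(rvImp@values[rvImp@reliable],
                     rv@values[rvImp@reliable])
})

test_that("bit density is non-increasing in the cutoff", {
    panel <- fixturePanel()
    mols <- fixtureQueryMolecules(15L)
    dens <- vapply(c(5, 6, 7, 8), function(cut)
        mean(fingerprintValues(bQaffp(panel, mols, cutoff = cut))), 0)
    expect_true(all(diff(dens) <= 0))
})

test_that("masking removes positions and warns on unknown ids", {
    panel <- fixturePanel()
    mols <- fixtureQueryMolecules(5L)
    bfp <- bQaffp(panel, mols)
    keep <- assayIds(panel)[1]
    masked <- maskAssays(bfp, setdiff(assayIds(panel), keep))
    expect_identical(assayIds(masked), keep)
    expect_identical(ncol(fingerprintValues(masked)), 1L)
    expect_warning(m2 <- maskAssays(bfp, "NOT-AN-ASSAY"), "unknown")
    expect_identical(assayIds(m2), assayIds(bfp))   # identity
    p2 <- maskAssays(panel, assayIds(panel)[2])
    expect_identical(length(p2), length(panel) - 1L)
    expect_error(maskAssays(panel, assayIds(panel)), "empty")
})

test_that("Z-standardization centers, scales and is idempotent", {
    m <- cbind(a = c(5, 6, 7), b = c(1, 1, 2))
    z <- zStandardize(m)
    expect_equal(z[, "a"], c(-1, 0, 1) * sqrt(3 / 2),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(colMeans(z), c(a = 0, b = 0), tolerance = 1e-12)
    expect_equal(zStandardize(z), z, tolerance = 1e-12)
    expect_warning(zc <- zStandardize(cbind(c(2, 2, 2))), "constant")
    expect_true(all(zc == 0))
    expect_error(zStandardize(matrix(1, 1, 3)), "2 rows")
})
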