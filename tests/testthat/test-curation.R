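# Record filtering, replicate aggregation and ligand-set assembly.

rec <- function(cid = "c1", aid = "a1", type = "IC50", rel = "=",
                val = 6, conf = 9L, smi = "CCO") {
    data.frame(compoundId = cid, smiles = smi, assayId = aid,
               activityType = type, relation = rel, value = val,
               confidence = conf, stringsAsFactors = FALSE)
}

test_that("filters enforce activity type, relation and confidence", {
    records <- rbind(rec(cid = "keep"),
                     rec(cid = "censored", rel = ">"),
                     rec(cid = "lowconf", conf = 8L),
                     rec(cid = "wrongtype", type = "AC50"),
                     rec(cid = "keep2", type = "Kd", conf = 7L))
    out <- filterActivityRecords(records)
    expect_identical(out$compoundId, c("keep", "keep2"))  # order preserved
    expect_identical(nrow(filterActivityRecords(records[2:4, ])), 0L)
})

test_that("replicates aggregate to the mean below the SD cutoff", {
    records <- rbind(rec(val = 6.0), rec(val = 6.2),           # sd 0.141
                     rec(cid = "c2", val = 5.0),
                     rec(cid = "c2", val = 6.5),               # sd 1.06
                     rec(cid = "c3", val = 7.3))
    out <- aggregateDuplicates(records)
    expect_equal(nrow(out), 2L)
    expect_equal(out$value[out$compoundId == "c1"], 6.1)
    expect_equal(out$value[out$compoundId == "c3"], 7.3)
    # discard is per compound-assay pair: c2 survives in another assay
    records2 <- rbind(records, rec(cid = "c2", aid = "a2", val = 5.5))
    out2 <- aggregateDuplicates(records2)
    expect_identical(out2$assayId[out2$compoundId == "c2"], "a2")
})

test_that("ligand sets require strictly more than minSize compounds", {
    mk <- function(n, aid) do.call(rbind, lapply(seq_len(n), function(i)
        rec(cid = paste0("c", i), aid = aid,
            smi = c("CCO", "CCC", "CCN", "CCCl", "CCF")[1 + i %% 5],
            val = 5 + i / 10)))
    agg <- aggregateDuplicates(rbind(mk(4, "small"), mk(6, "big")))
    sets <- buildLigandSets(agg, minSize = 5L)
    expect_length(sets, 1L)
    expect_identical(assayId(sets[[1]]), "big")
    expect_identical(length(sets[[1]]), 6L)
    expect_length(buildLigandSets(agg[0, ], minSize = 5L), 0L)
})

test_that("unparseable compounds are dropped with a warning, not fatal", {
    agg <- data.frame(
        compoundId = paste0("c", 1:7),
        assayId = "a1",
        smiles = c("CCO", "junk(", "CCC", "CCN", "CCF", "CCCl", "CCCC"),
        value = 5 + (1:7) / 10, stringsAsFactors = FALSE)
    expect_warning(sets <- buildLigandSets(agg, minSize = 5L),
                   "unparseable")
    expect_identical(length(sets[[1]]), 6L)
})

test_that("curation is order-insensitive at the set level", {
    tab <- generateActivityTable(nAssays = 2L, nCompounds = 30L, seed = 3L)
    a <- buildLigandSets(aggregateDuplicates(filterActivityRecords(tab)),
                         minSize = 10L)
    set.seed(1)
    tabShuffled <- tab[sample(nrow(tab)), ]
    b <- buildLigandSets(
        aggregateDuplicates(filterActivityRecords(tabShuffled)),
        minSize = 10L)
    expect_identical(names(a), names(b))
    for (i in seq_along(a)) {
        expect_identical(compoundIds(a[[i]]), compoundIds(b[[i]]))
        expect_equal(activities(a[[i]]), activities(b[[i]]))
    }
})

test_that("activity tables round-trip with configurable column names", {
    tab <- generateActivityTable(nAssays = 1L, nCompounds = 10L, seed = 4L)
    f <- tempfile(fileext = ".tsv")
    names(tab)[names(tab) == "smiles"] <- "canonical_smiles"
    write.table(tab, f, sep = "\t", row.names = FALSE, quote = FALSE)
    got <- readActivityTable(f, columns = c(smiles = "canonical_smiles"))
    expect_true(all(c("compoundId", "smiles", "value") %in% names(got)))
    expect_identical(nrow(got), nrow(tab))
    expect_error(readActivityTable(f, columns = c(smiles = "nope")),
                 "not in file")
    expect_error(readActivityTable(f), "lacks columns")
})

test_that("concentration conversion hits the canonical potency anchors", {
    expect_identical(potencyFromConcentration(10, "uM"), 5)
    expect_identical(potencyFromConcentration(1, "uM"), 6)
    expect_identical(potencyFromConcentration(100, "nM"), 7)
    expect_identical(potencyFromConcentration(10, "nM"), 8)
    expect_error(potencyFromConcentration(-1, "nM"), "positive")
    expect_error(potencyFromConcentration(1, "furlong"), "unit")
})
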