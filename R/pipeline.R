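# End-to-end orchestration: resolved run configuration, the build pipeline
# (curation -> gating -> conformal calibration -> serialized panel) and the
# evaluation pipeline (benchmark harnesses + scheme comparisons). One
# master seed determines every stochastic choice; reruns with an equal
# configuration produce byte-identical reports.

#' Run configuration
#'
#' Collects every tunable of the pipeline with the recommended defaults:
#' conformal confidence 0.90, applicability-domain width 4.0, binary
#' cutoff 5 (-log10 M), rv fingerprints from raw predictions, b
#' fingerprints zeroed outside the domain, gate thresholds
#' \code{q2 >= 0.5} and \code{R'0^2 >= 0.6}, minimum ligand-set size 50
#' (exclusive), 80:20 split, 10x10 cross-validation.
#'
#' @param seed master seed.
#' @param confidence,maxWidth conformal settings.
#' @param cutoff binary-fingerprint activity cutoff.
#' @param adPolicyRv,adPolicyB applicability-domain policies per mode.
#' @param q2Min,r2Min,minSetSize gate and curation thresholds.
#' @param ratio,cvFolds,cvRepeats split and cross-validation settings.
#' @param calibFraction ICP calibration fraction of the training set.
#' @param method conformal scheme ("icp" or "ccp").
#' @param nTrees forest size.
#' @return An object of class \code{qaffpConfig} (a validated list).
#' @export
qaffpConfig <- function(seed = 1L, confidence = 0.90, maxWidth = 4.0,
                        cutoff = 5, adPolicyRv = "ignore",
                        adPolicyB = "zero_outside", q2Min = 0.5,
                        r2Min = 0.6, minSetSize = 50L, ratio = 0.8,
                        cvFolds = 10L, cvRepeats = 10L,
                        calibFraction = 1 / 3, method = "icp",
                        nTrees = 100L) {
    cfg <- list(seed = as.integer(seed), confidence = confidence,
                maxWidth = maxWidth, cutoff = cutoff,
                adPolicyRv = adPolicyRv, adPolicyB = adPolicyB,
                q2Min = q2Min, r2Min = r2Min,
                minSetSize = as.integer(minSetSize), ratio = ratio,
                cvFolds = as.integer(cvFolds),
                cvRepeats = as.integer(cvRepeats),
                calibFraction = calibFraction, method = method,
                nTrees = as.integer(nTrees))
    stopifnot(cfg$confidence > 0, cfg$confidence < 1, cfg$maxWidth > 0,
              cfg$ratio > 0, cfg$ratio < 1,
              cfg$method %in% c("icp", "ccp"),
              cfg$adPolicyRv %in% c("ignore", "impute"),
              cfg$adPolicyB %in% c("zero_outside", "none"))
    class(cfg) <- "qaffpConfig"
    cfg
}

#' @rdname qaffpConfig
#' @param file YAML file path.
#' @export
readConfig <- function(file) {
    vals <- yaml::read_yaml(file)
    do.call(qaffpConfig, vals)
}

#' @rdname qaffpConfig
#' @param cfg a \code{qaffpConfig}.
#' @export
writeConfig <- function(cfg, file) {
    stopifnot(inherits(cfg, "qaffpConfig"))
    yaml::write_yaml(unclass(cfg), file, precision = 12L)
    invisible(file)
}

#' @export
print.qaffpConfig <- function(x, ...) {
    cat("qaffp run configuration:\n")
    for (k in names(x)) cat(sprintf("  %-14s %s\n", k, x[[k]]))
    invisible(x)
}

## ---- build --------------------------------------------------------------

#' Build an affinity panel from an activity table
#'
#' The full construction workflow: filter records, aggregate replicates,
#' assemble per-assay ligand sets, train and gate a conformal QSAR model
#' per assay, and serialize the passing models as an affinity panel. A
#' machine-readable build report (per-assay compound counts, q2, R'0^2 and
#' pass flags) plus an audit copy of the resolved configuration are always
#' written, even when no assay passes (which is an error after writing).
#'
#' @param activityTable a data.frame of activity records or a path to a
#'   delimited file (see \code{\link{readActivityTable}}).
#' @param outDir output directory (created if needed).
#' @param config a \code{\link{qaffpConfig}}.
#' @param sep field separator when \code{activityTable} is a path.
#' @return Invisibly, the \code{\linkS4class{AffinityPanel}}.
#' @export
runBuild <- function(activityTable, outDir, config = qaffpConfig(),
                     sep = "\t") {
    if (is.character(activityTable)) {
        if (!file.exists(activityTable))
            stop("activity table not found: ", activityTable)
        activityTable <- readActivityTable(activityTable, sep = sep)
    }
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeConfig(config, file.path(outDir, "config.yaml"))
    nRaw <- nrow(activityTable)
    filtered <- filterActivityRecords(activityTable)
    aggregated <- aggregateDuplicates(filtered)
    sets <- buildLigandSets(aggregated, minSize = config$minSetSize)
    message(sprintf(
        "curation: %d records -> %d after filters -> %d compound-assay pairs -> %d ligand sets",
        nRaw, nrow(filtered), nrow(aggregated), length(sets)))
    if (length(sets) == 0L) stop("no ligand set survived curation")
    report <- vector("list", length(sets))
    bundles <- vector("list", length(sets))
    for (i in seq_along(sets)) {
        ls <- sets[[i]]
        bundle <- conformalQSAR(
            ls, method = config$method, ratio = config$ratio,
            k = config$cvFolds, repeats = config$cvRepeats,
            q2Min = config$q2Min, r2Min = config$r2Min,
            calibFraction = config$calibFraction,
            nTrees = config$nTrees,
            seed = .deriveSeed(config$seed, i))
        bundles[[i]] <- bundle
        g <- bundle@gate
        report[[i]] <- list(assayId = assayId(ls), n = length(ls),
                            q2 = round(g@q2, 6), r0Squared = round(g@r0Squared, 6),
                            passed = g@passed)
        message(sprintf("assay %s: n = %d, q2 = %.3f, R'0^2 = %.3f -> %s",
                        assayId(ls), length(ls), g@q2, g@r0Squared,
                        if (g@passed) "pass" else "fail"))
    }
    reportPath <- file.path(outDir, "build_report.json")
    jsonlite::write_json(
        list(seed = config$seed, method = config$method,
             assays = report),
        reportPath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    passed <- vapply(bundles, gatePassed, TRUE)
    if (!any(passed))
        stop("no assay passed the gate; report written to ", reportPath)
    panel <- assemblePanel(bundles)
    modelDir <- file.path(outDir, "models")
    dir.create(modelDir, showWarnings = FALSE)
    meta <- list(assayIds = assayIds(panel), seed = config$seed,
                 method = config$method, confidence = config$confidence,
                 maxWidth = config$maxWidth)
    jsonlite::write_json(meta, file.path(outDir, "panel.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    for (b in panel@assays)
        saveRDS(b, file.path(modelDir, paste0(b@assayId, ".rds")))
    invisible(panel)
}

#' Load a serialized affinity panel
#'
#' @param dir a directory written by \code{\link{runBuild}}.
#' @return An \code{\linkS4class{AffinityPanel}}.
#' @export
readPanel <- function(dir) {
    metaPath <- file.path(dir, "panel.json")
    if (!file.exists(metaPath)) stop("not a panel directory: ", dir)
    meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
    bundles <- lapply(meta$assayIds, function(a)
        readRDS(file.path(dir, "models", paste0(a, ".rds"))))
    assemblePanel(bundles)
}

## ---- evaluation ---------------------------------------------------------

.schemeFromName <- function(name, panel, config) {
    switch(name,
        morgan2 = fingerprintScheme("morgan2"),
        rv = fingerprintScheme("rv", panel = panel,
                               adPolicy = config$adPolicyRv,
                               confidence = config$confidence,
                               maxWidth = config$maxWidth),
        b = fingerprintScheme("b", panel = panel,
                              adPolicy = config$adPolicyB,
                              confidence = config$confidence,
                              maxWidth = config$maxWidth,
                              cutoff = config$cutoff),
        stop("unknown scheme: ", name))
}

#' Evaluate fingerprint schemes on benchmark sets
#'
#' Runs the requested harnesses for every benchmark set and scheme, writes
#' a tidy CSV of per-repetition results and a summary JSON that includes
#' exact paired Wilcoxon comparisons between schemes (paired over
#' benchmark sets) when at least two sets are available. Benchmark targets
#' whose assays appear in the panel are masked from the affinity schemes
#' via \code{maskTargets}.
#'
#' @param panel an \code{\linkS4class{AffinityPanel}} or a panel
#'   directory.
#' @param benchSets list of \code{\linkS4class{BenchSet}}.
#' @param outDir output directory.
#' @param tasks subset of \code{c("sim", "class", "hop")}.
#' @param schemes subset of \code{c("morgan2", "rv", "b")}.
#' @param config a \code{\link{qaffpConfig}}.
#' @param maskTargets optional character vector of assay ids to remove
#'   from the panel before fingerprinting.
#' @return Invisibly, a list with the tidy results data.frame and the
#'   summary list.
#' @export
runEval <- function(panel, benchSets, outDir,
                    tasks = c("sim", "class", "hop"),
                    schemes = c("morgan2", "b"),
                    config = qaffpConfig(), maskTargets = NULL) {
    if (is.character(panel)) panel <- readPanel(panel)
    if (length(benchSets) == 0L) stop("no benchmark sets supplied")
    tasks <- match.arg(tasks, several.ok = TRUE)
    if (!is.null(maskTargets)) panel <- maskAssays(panel, maskTargets)
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeConfig(config, file.path(outDir, "config.yaml"))
    tidy <- list(); summary <- list()
    means <- list()  # scheme x set mean AUC/EF5 for paired comparisons
    for (sc in schemes) {
        scheme <- .schemeFromName(sc, panel, config)
        for (bs in benchSets) {
            base <- list(scheme = sc, target = bs@targetId)
            if ("sim" %in% tasks && bs@kind %in% c("HET", "HOM", "CLASS")) {
                res <- runSimilarityBenchmark(
                    bs, scheme, seed = .deriveSeed(config$seed, 1L))
                tidy[[length(tidy) + 1L]] <- data.frame(
                    task = "sim", scheme = sc, target = bs@targetId,
                    repetitions(res))
                means$sim[[sc]][[bs@targetId]] <-
                    c(auc = res@auc, ef5 = res@ef5)
            }
            if ("class" %in% tasks && bs@kind == "CLASS") {
                res <- runClassificationBenchmark(
                    bs, scheme, folds = 5L, repeats = config$cvRepeats,
                    nTrees = config$nTrees,
                    seed = .deriveSeed(config$seed, 2L))
                tidy[[length(tidy) + 1L]] <- data.frame(
                    task = "class", scheme = sc, target = bs@targetId,
                    repetitions(res))
                means$class[[sc]][[bs@targetId]] <-
                    c(auc = res@auc, ef5 = res@ef5)
            }
            if ("hop" %in% tasks && bs@kind == "CLASS") {
                res <- runScaffoldHopping(
                    bs, scheme, nTrees = config$nTrees,
                    seed = .deriveSeed(config$seed, 3L))
                summary$hop[[sc]][[bs@targetId]] <- list(
                    nAcskTotal = res@nAcskTotal, nRacsk = res@nRacsk,
                    nRetrieved = nRetrieved(res),
                    retrievedCsk = res@retrievedCsk)
            }
        }
    }
    tidyDf <- if (length(tidy) > 0L) do.call(rbind, tidy) else
        data.frame()
    utils::write.csv(tidyDf, file.path(outDir, "results.csv"),
                     row.names = FALSE, quote = FALSE)
    # paired scheme comparisons over benchmark sets
    for (task in names(means)) {
        ms <- means[[task]]
        if (length(ms) < 2L) next
        prs <- utils::combn(names(ms), 2L, simplify = FALSE)
        for (pr in prs) {
            shared <- intersect(names(ms[[pr[1L]]]), names(ms[[pr[2L]]]))
            if (length(shared) < 2L) next
            for (metric in c("auc", "ef5")) {
                a <- vapply(ms[[pr[1L]]][shared], `[[`, 0, metric)
                b <- vapply(ms[[pr[2L]]][shared], `[[`, 0, metric)
                w <- tryCatch(wilcoxonExactPaired(a, b, "two_sided"),
                              error = function(e) NULL)
                summary$wilcoxon[[task]][[paste(pr, collapse = "_vs_")]][[metric]] <-
                    if (is.null(w)) NA else w$pValue
            }
        }
    }
    summary$meanPerformance <- means
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(results = tidyDf, summary = summary))
}

## ---- benchmark-set IO ---------------------------------------------------

#' Write or read a benchmark set as plain text
#'
#' One SMILES-per-line file per class plus a JSON manifest declaring the
#' target, kind and (when known) activities; the same formats the loaders
#' consume for real benchmark data.
#'
#' @param bs a \code{\linkS4class{BenchSet}}.
#' @param dir directory to write to / read from.
#' @return \code{writeBenchSet}: invisibly, \code{dir};
#'   \code{readBenchSet}: a \code{BenchSet}.
#' @export
writeBenchSet <- function(bs, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(smiles(actives(bs)), file.path(dir, "actives.smi"))
    writeLines(smiles(inactives(bs)), file.path(dir, "inactives.smi"))
    jsonlite::write_json(
        list(targetId = bs@targetId, kind = bs@kind,
             activity = bs@activity),
        file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
        pretty = TRUE)
    invisible(dir)
}

#' @rdname writeBenchSet
#' @export
readBenchSet <- function(dir) {
    man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                               simplifyVector = TRUE)
    act <- readLines(file.path(dir, "actives.smi"))
    ina <- readLines(file.path(dir, "inactives.smi"))
    activity <- man$activity
    if (length(activity) == 0L) activity <- NULL
    benchSet(man$targetId, act, ina, kind = man$kind,
             activity = activity)
}
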