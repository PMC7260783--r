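# Per-assay random forest QSAR regression: activity-stratified splitting,
# the q2 / R'0^2 validation statistics, and the quality gate that decides
# panel admission.

#' Activity-stratified train/test split with cross-validation folds
#'
#' Continuous activities are stratified by sorting compounds by activity
#' and partitioning them into consecutive blocks; test compounds (one per
#' block of \code{round(1/(1 - ratio))}) and fold labels (one per fold from
#' each block of \code{k}) are then drawn at random within blocks, so both
#' sides of the split track the full activity distribution.
#'
#' @param ligandSet a \code{\linkS4class{LigandSet}}.
#' @param ratio training fraction (default 0.8 for an 80:20 split).
#' @param k number of cross-validation folds over the training portion.
#' @param seed integer seed; a fixed seed reproduces the plan exactly.
#' @return A \code{\linkS4class{SplitPlan}}.
#' @export
stratifiedSplit <- function(ligandSet, ratio = 0.8, k = 10L, seed = 1L) {
    stopifnot(is(ligandSet, "LigandSet"), ratio > 0, ratio < 1)
    n <- length(ligandSet)
    if (n < k) stop("ligand set smaller than the number of folds")
    set.seed(as.integer(seed))
    ord <- order(ligandSet@activity, ligandSet@compoundId)
    idsSorted <- ligandSet@compoundId[ord]
    blockSize <- max(2L, round(1 / (1 - ratio)))
    testSel <- logical(n)
    for (start in seq(1L, n, by = blockSize)) {
        block <- start:min(start + blockSize - 1L, n)
        # partial trailing blocks contribute proportionally (0 when tiny)
        nTest <- if (length(block) == blockSize) 1L
                 else round(length(block) * (1 - ratio))
        if (nTest > 0L)
            testSel[sample(block, nTest)] <- TRUE
    }
    trainIds <- idsSorted[!testSel]
    testIds <- idsSorted[testSel]
    # fold labels: one member per fold from each consecutive activity block
    nTrain <- length(trainIds)
    foldOf <- integer(nTrain)
    for (start in seq(1L, nTrain, by = k)) {
        block <- start:min(start + k - 1L, nTrain)
        foldOf[block] <- sample(k, length(block))
    }
    folds <- lapply(seq_len(k), function(f) trainIds[foldOf == f])
    new("SplitPlan", trainIds = trainIds, testIds = testIds,
        folds = folds, ratio = ratio, seed = as.integer(seed))
}

#' Cross-validation correlation coefficient q2
#'
#' \eqn{q^2 = 1 - \sum_i (y_i - \hat y_i)^2 / \sum_i (y_i - \bar y)^2}.
#' Equals 1 for exact predictions, 0 for predicting the mean, and may be
#' negative for predictions worse than the mean.
#'
#' @param y observed activities.
#' @param yHat predicted activities.
#' @return The statistic.
#' @export
qSquared <- function(y, yHat) {
    stopifnot(length(y) == length(yHat), length(y) >= 2L)
    ssTot <- sum((y - mean(y))^2)
    if (ssTot == 0) stop("q2 undefined: observed activities are constant")
    1 - sum((y - yHat)^2) / ssTot
}

#' Through-origin coefficient of determination R'0^2
#'
#' Coefficient of determination of the predicted-vs-observed regression
#' constrained to pass through the origin: with slope
#' \eqn{k' = \sum y_i \hat y_i / \sum \hat y_i^2},
#' \eqn{R'^2_0 = 1 - \sum (y_i - k' \hat y_i)^2 / \sum (y_i - \bar y)^2}.
#' Used as the external (test-set) predictivity measure.
#'
#' @inheritParams qSquared
#' @return The statistic.
#' @export
r0Squared <- function(y, yHat) {
    stopifnot(length(y) == length(yHat), length(y) >= 2L)
    ssHat <- sum(yHat^2)
    if (ssHat == 0) stop("R'0^2 undefined: predictions are all zero")
    ssTot <- sum((y - mean(y))^2)
    if (ssTot == 0) stop("R'0^2 undefined: observed activities are constant")
    kPrime <- sum(y * yHat) / ssHat
    1 - sum((y - kPrime * yHat)^2) / ssTot
}

#' Train the per-assay point prediction model
#'
#' A random forest regressor of 100 trees over 1024-bit Morgan
#' fingerprints, with every (varying) feature considered at each split.
#' Deterministic for a fixed seed.
#'
#' @param ligandSet a \code{\linkS4class{LigandSet}}.
#' @param ids compound ids to train on (default: all).
#' @param nTrees forest size.
#' @param seed integer seed.
#' @return A \code{\linkS4class{PointModel}}.
#' @export
trainPointModel <- function(ligandSet, ids = NULL, nTrees = 100L,
                            seed = 1L) {
    if (is.null(ids)) ids <- ligandSet@compoundId
    if (length(ids) < 2L) stop("cannot train on fewer than 2 compounds")
    sub <- subsetLigands(ligandSet, ids)
    X <- .ligandFingerprints(sub)
    featureIdx <- which(.colVar(X) > 0)
    if (length(featureIdx) == 0L)
        stop("degenerate feature matrix: all fingerprint bits constant")
    fit <- ranger::ranger(x = X[, featureIdx, drop = FALSE],
                          y = sub@activity,
                          num.trees = as.integer(nTrees),
                          mtry = length(featureIdx),
                          num.threads = 1L, seed = as.integer(seed),
                          verbose = FALSE)
    new("PointModel", assayId = ligandSet@assayId, forest = fit,
        featureIdx = featureIdx, nTrees = as.integer(nTrees),
        seed = as.integer(seed), trainIds = ids,
        oobPrediction = setNames(fit$predictions, ids))
}

# column variances without a matrixStats dependency
.colVar <- function(X) {
    mu <- colMeans(X)
    colMeans(X^2) - mu^2
}

#' Predict activities with a point (or error) model
#'
#' @param model a \code{PointModel} or \code{ErrorModel}.
#' @param x a \code{MoleculeSet}, SMILES character vector, or a
#'   precomputed 1024-column fingerprint matrix.
#' @return Numeric predictions (-log10 M); for error models, floored
#'   expected absolute residuals.
#' @export
predictActivity <- function(model, x) {
    X <- if (is.matrix(x)) x else morganFingerprint(x)
    p <- stats::predict(model@forest,
                        data = X[, model@featureIdx, drop = FALSE],
                        num.threads = 1L, verbose = FALSE)$predictions
    if (is(model, "ErrorModel")) pmax(p, model@floor) else p
}

#' Repeated k-fold cross-validated q2
#'
#' For each repeat and each fold of the plan, a model is trained on the
#' other folds and evaluated on the held-out fold; the statistic is the
#' mean per-fold \eqn{q^2} over all folds in all repeats. Fold membership
#' is fixed by the plan; repeats re-randomize only the forest (the source
#' of run-to-run variation in bagged models). Folds with constant observed
#' activity are excluded with a warning. Test-set compounds are never
#' touched.
#'
#' @param ligandSet a \code{\linkS4class{LigandSet}}.
#' @param plan a \code{\linkS4class{SplitPlan}} on the set.
#' @param repeats number of cross-validation repetitions.
#' @param nTrees forest size.
#' @param seed integer master seed for the fold models.
#' @return Mean per-fold q2.
#' @export
crossValidatedQ2 <- function(ligandSet, plan, repeats = 10L, nTrees = 100L,
                             seed = 1L) {
    stopifnot(is(plan, "SplitPlan"))
    folds <- plan@folds
    acts <- activities(ligandSet)
    vals <- c()
    for (r in seq_len(repeats)) {
        for (f in seq_along(folds)) {
            heldOut <- folds[[f]]
            if (length(heldOut) == 0L) next
            yObs <- acts[heldOut]
            if (length(unique(yObs)) < 2L || stats::sd(yObs) == 0) {
                warning("fold with constant activity excluded from q2")
                next
            }
            trainIds <- setdiff(plan@trainIds, heldOut)
            m <- trainPointModel(ligandSet, ids = trainIds,
                                 nTrees = nTrees,
                                 seed = .deriveSeed(seed, r, f))
            yHat <- predictActivity(m, .ligandFingerprints(
                subsetLigands(ligandSet, heldOut)))
            vals <- c(vals, qSquared(yObs, yHat))
        }
    }
    mean(vals)
}

#' Gate metrics constructor
#'
#' @param q2 cross-validated q2.
#' @param r0Squared test-set through-origin R'0^2.
#' @param q2Min,r2Min inclusive admission thresholds.
#' @return A \code{\linkS4class{GateMetrics}} with the \code{passed} flag
#'   set by the conjunction \code{q2 >= q2Min && r0Squared >= r2Min}.
#' @export
gateMetricsFrom <- function(q2, r0Squared, q2Min = 0.5, r2Min = 0.6) {
    new("GateMetrics", q2 = q2, r0Squared = r0Squared,
        q2Min = q2Min, r2Min = r2Min,
        passed = q2 >= q2Min && r0Squared >= r2Min)
}

#' Validate a ligand set's model and decide panel admission
#'
#' Computes the cross-validated \eqn{q^2} on the training portion, refits
#' the final model on the entire training set, scores the held-out test
#' set with \eqn{R'^2_0}, and admits the model iff \code{q2 >= q2Min} and
#' \code{r0Squared >= r2Min} (both inclusive).
#'
#' @inheritParams crossValidatedQ2
#' @param q2Min,r2Min admission thresholds.
#' @return A \code{\linkS4class{GateMetrics}}.
#' @export
evaluateAndGate <- function(ligandSet, plan = NULL, q2Min = 0.5,
                            r2Min = 0.6, repeats = 10L, nTrees = 100L,
                            seed = 1L) {
    if (is.null(plan))
        plan <- stratifiedSplit(ligandSet, seed = seed)
    q2 <- crossValidatedQ2(ligandSet, plan, repeats = repeats,
                           nTrees = nTrees, seed = seed)
    final <- trainPointModel(ligandSet, ids = plan@trainIds,
                             nTrees = nTrees, seed = .deriveSeed(seed, 0L))
    testSet <- subsetLigands(ligandSet, plan@testIds)
    yHat <- predictActivity(final, .ligandFingerprints(testSet))
    gateMetricsFrom(q2, r0Squared(testSet@activity, yHat),
                    q2Min = q2Min, r2Min = r2Min)
}

#' @rdname gateMetrics
#' @export
setMethod("gateMetrics", "GateMetrics", function(x) x)

#' @rdname gateMetrics
#' @export
setMethod("gatePassed", "GateMetrics", function(x) x@passed)

setMethod("show", "GateMetrics", function(object) {
    cat(sprintf("GateMetrics: q2 = %.3f (min %.2f), R'0^2 = %.3f (min %.2f) -> %s\n",
                object@q2, object@q2Min, object@r0Squared, object@r2Min,
                if (object@passed) "PASSED" else "failed"))
})

setMethod("show", "SplitPlan", function(object) {
    cat("SplitPlan:", length(object@trainIds), "train /",
        length(object@testIds), "test;", length(object@folds),
        "folds; seed", object@seed, "\n")
})

setMethod("show", "PointModel", function(object) {
    cat("PointModel for assay '", object@assayId, "': ", object@nTrees,
        " trees, ", length(object@featureIdx), " active bits, ",
        length(object@trainIds), " training compounds\n", sep = "")
})
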