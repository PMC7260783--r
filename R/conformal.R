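# Normalized conformal regression around each point model: an error model
# predicting the expected absolute residual supplies the scaling factor
# lambda, calibration scores alpha = |y - yhat| / lambda rank new compounds
# against calibrated ones, and the resulting interval width at a fixed
# confidence defines the applicability domain.

#' Normalized nonconformity score
#'
#' \eqn{\alpha = |y - \hat y| / \lambda}: the absolute residual scaled by
#' the error model's expected residual, measuring how unusual a compound's
#' error is relative to what the error model anticipates for it.
#'
#' @param y observed activity.
#' @param yHat predicted activity.
#' @param lam scaling factor \eqn{\lambda > 0}.
#' @return Non-negative score (vectorized).
#' @export
nonconformity <- function(y, yHat, lam) {
    if (any(lam <= 0)) stop("lambda must be positive")
    abs(y - yHat) / lam
}

#' Train the error prediction model
#'
#' A second random forest trained to predict the absolute residual of the
#' point model. Residual targets are taken from the point model's
#' out-of-bag predictions on its own training compounds, so in-sample
#' optimism does not leak into the scaling factors. Predictions are
#' floored at \code{floor} to keep nonconformity scores defined.
#'
#' @param ligandSet a \code{\linkS4class{LigandSet}}.
#' @param point the fitted \code{\linkS4class{PointModel}} whose residuals
#'   are modelled; its training ids define the error model's training set.
#' @param floor minimum emitted \eqn{\lambda} (-log10 M units).
#' @param nTrees forest size.
#' @param seed integer seed.
#' @return An \code{\linkS4class{ErrorModel}}.
#' @export
trainErrorModel <- function(ligandSet, point, floor = 0.01, nTrees = 100L,
                            seed = 1L) {
    ids <- point@trainIds
    sub <- subsetLigands(ligandSet, ids)
    resid <- abs(sub@activity - point@oobPrediction[ids])
    X <- .ligandFingerprints(sub)
    featureIdx <- which(.colVar(X) > 0)
    if (length(featureIdx) == 0L)
        stop("degenerate feature matrix: all fingerprint bits constant")
    fit <- ranger::ranger(x = X[, featureIdx, drop = FALSE], y = resid,
                          num.trees = as.integer(nTrees),
                          mtry = length(featureIdx), num.threads = 1L,
                          seed = as.integer(seed), verbose = FALSE)
    new("ErrorModel", forest = fit, featureIdx = featureIdx,
        floor = floor, seed = as.integer(seed))
}

#' Inductive conformal calibration
#'
#' Scores a calibration set (disjoint from the proper training set) with
#' the point and error models and collects the sorted nonconformity
#' scores.
#'
#' @param point a \code{\linkS4class{PointModel}}.
#' @param error an \code{\linkS4class{ErrorModel}}.
#' @param ligandSet the \code{\linkS4class{LigandSet}}.
#' @param calibIds compound ids of the calibration set; must not overlap
#'   the point model's training ids.
#' @return A \code{\linkS4class{CalibrationTable}}.
#' @export
icpCalibrate <- function(point, error, ligandSet, calibIds) {
    if (length(calibIds) == 0L) stop("empty calibration set")
    if (length(intersect(calibIds, point@trainIds)) > 0L)
        stop("calibration compounds overlap the proper training set")
    sub <- subsetLigands(ligandSet, calibIds)
    X <- .ligandFingerprints(sub)
    yHat <- predictActivity(point, X)
    lam <- predictActivity(error, X)
    scores <- nonconformity(sub@activity, yHat, lam)
    new("CalibrationTable", scores = sort(scores),
        n = length(scores))
}

#' Cross-conformal training
#'
#' The set is divided into \code{k} activity-stratified folds; for each
#' fold, point and error models trained on the complement score the held
#' fold, and all scores are pooled into one calibration table (every
#' compound contributes exactly one score). Final point and error models
#' are refit on all compounds.
#'
#' @param ligandSet a \code{\linkS4class{LigandSet}}.
#' @param k number of folds (default 10).
#' @param floor,nTrees as in \code{\link{trainErrorModel}}.
#' @param seed integer seed (fold assignment and forests).
#' @return list with elements \code{point}, \code{error}, \code{table} and
#'   \code{folds} (the fold assignment used, for reproduction).
#' @export
ccpTrain <- function(ligandSet, k = 10L, floor = 0.01, nTrees = 100L,
                     seed = 1L) {
    n <- length(ligandSet)
    if (n < k) stop("ligand set smaller than the number of folds")
    set.seed(as.integer(seed))
    ord <- order(ligandSet@activity, ligandSet@compoundId)
    idsSorted <- ligandSet@compoundId[ord]
    foldOf <- integer(n)
    for (start in seq(1L, n, by = k)) {
        block <- start:min(start + k - 1L, n)
        foldOf[block] <- sample(k, length(block))
    }
    folds <- lapply(seq_len(k), function(f) idsSorted[foldOf == f])
    scores <- numeric(0)
    for (f in seq_len(k)) {
        heldOut <- folds[[f]]
        if (length(heldOut) == 0L) next
        trainIds <- setdiff(ligandSet@compoundId, heldOut)
        pt <- trainPointModel(ligandSet, ids = trainIds, nTrees = nTrees,
                              seed = .deriveSeed(seed, f, 1L))
        er <- trainErrorModel(ligandSet, pt, floor = floor,
                              nTrees = nTrees,
                              seed = .deriveSeed(seed, f, 2L))
        tab <- icpCalibrate(pt, er, ligandSet, heldOut)
        scores <- c(scores, tab@scores)
    }
    point <- trainPointModel(ligandSet, nTrees = nTrees,
                             seed = .deriveSeed(seed, 0L, 1L))
    error <- trainErrorModel(ligandSet, point, floor = floor,
                             nTrees = nTrees,
                             seed = .deriveSeed(seed, 0L, 2L))
    list(point = point, error = error,
         table = new("CalibrationTable", scores = sort(scores),
                     n = length(scores)),
         folds = folds)
}

#' Conformal quantile of a calibration table
#'
#' The order-statistic quantile with the finite-sample correction: the
#' \eqn{\lceil c (n + 1) \rceil}-th smallest calibration score at
#' confidence \eqn{c}, or \code{Inf} when that index exceeds \eqn{n}
#' (the calibration set is too small to support the confidence level).
#'
#' @param table a \code{\linkS4class{CalibrationTable}}.
#' @param confidence confidence level in (0, 1).
#' @return The score quantile \eqn{\alpha^*}.
#' @export
conformalQuantile <- function(table, confidence) {
    stopifnot(confidence > 0, confidence < 1)
    idx <- ceiling(confidence * (table@n + 1))
    if (idx > table@n) Inf else table@scores[idx]
}

#' Conformal prediction intervals and applicability-domain flags
#'
#' For each molecule the interval is the point prediction plus/minus
#' \eqn{\lambda \alpha^*}, where \eqn{\alpha^*} is the calibration-table
#' quantile at the requested confidence. A molecule is inside the
#' applicability domain when the full interval width does not exceed
#' \code{maxWidth}.
#'
#' @param point a \code{\linkS4class{PointModel}}.
#' @param error an \code{\linkS4class{ErrorModel}}.
#' @param table a \code{\linkS4class{CalibrationTable}}.
#' @param x molecules (\code{MoleculeSet}, SMILES, or fingerprint matrix).
#' @param confidence confidence level (default 0.90).
#' @param maxWidth applicability-domain width threshold in -log10 M units
#'   (default 4.0, i.e. predicted value plus/minus 2.0).
#' @return A \code{\linkS4class{PredictionIntervalSet}}.
#' @export
predictInterval <- function(point, error, table, x, confidence = 0.90,
                            maxWidth = 4.0) {
    X <- if (is.matrix(x)) x else morganFingerprint(x)
    mid <- predictActivity(point, X)
    lam <- predictActivity(error, X)
    aStar <- conformalQuantile(table, confidence)
    halfWidth <- lam * aStar
    new("PredictionIntervalSet", midpoint = mid, halfWidth = halfWidth,
        confidence = confidence, maxWidth = maxWidth,
        inDomain = 2 * halfWidth <= maxWidth)
}

#' Train the full conformal bundle for one assay
#'
#' Runs the whole per-assay protocol: activity-stratified 80:20 split,
#' repeated k-fold cross-validated \eqn{q^2}, final-model \eqn{R'^2_0} on
#' the test set, the quality gate, and conformal calibration. With
#' \code{method = "icp"} the training portion is further divided into a
#' proper training set and a calibration set (fraction
#' \code{calibFraction}, activity-stratified) and the deployed point/error
#' models are fit on the proper training set, keeping the conformal
#' guarantee exact. With \code{method = "ccp"} all training compounds
#' rotate through the calibration role and the deployed models are refit
#' on the full training set.
#'
#' @param ligandSet a \code{\linkS4class{LigandSet}}.
#' @param method \code{"icp"} (default) or \code{"ccp"}.
#' @param ratio training fraction of the initial split.
#' @param k cross-validation folds (gate and CCP).
#' @param repeats cross-validation repetitions for q2.
#' @param q2Min,r2Min gate thresholds.
#' @param calibFraction fraction of the training set used for ICP
#'   calibration.
#' @param floor error-model floor.
#' @param nTrees forest size.
#' @param seed integer master seed.
#' @return A \code{\linkS4class{ConformalQSARModel}} (whether or not the
#'   gate passed; inspect \code{gatePassed(gateMetrics(x))}).
#' @export
conformalQSAR <- function(ligandSet, method = c("icp", "ccp"), ratio = 0.8,
                          k = 10L, repeats = 10L, q2Min = 0.5, r2Min = 0.6,
                          calibFraction = 1 / 3, floor = 0.01,
                          nTrees = 100L, seed = 1L) {
    method <- match.arg(method)
    plan <- stratifiedSplit(ligandSet, ratio = ratio, k = k, seed = seed)
    gate <- evaluateAndGate(ligandSet, plan, q2Min = q2Min, r2Min = r2Min,
                            repeats = repeats, nTrees = nTrees, seed = seed)
    trainSet <- subsetLigands(ligandSet, plan@trainIds)
    if (method == "icp") {
        # activity-stratified proper/calibration division of the train set
        calPlan <- stratifiedSplit(trainSet, ratio = 1 - calibFraction,
                                   k = 2L, seed = .deriveSeed(seed, 11L))
        properIds <- calPlan@trainIds
        calibIds <- calPlan@testIds
        point <- trainPointModel(ligandSet, ids = properIds,
                                 nTrees = nTrees,
                                 seed = .deriveSeed(seed, 1L))
        error <- trainErrorModel(ligandSet, point, floor = floor,
                                 nTrees = nTrees,
                                 seed = .deriveSeed(seed, 2L))
        table <- icpCalibrate(point, error, ligandSet, calibIds)
    } else {
        fit <- ccpTrain(trainSet, k = k, floor = floor, nTrees = nTrees,
                        seed = .deriveSeed(seed, 21L))
        point <- fit$point; error <- fit$error; table <- fit$table
    }
    new("ConformalQSARModel", assayId = ligandSet@assayId, point = point,
        error = error, calibration = table, gate = gate, method = method)
}

#' @rdname gateMetrics
#' @export
setMethod("gateMetrics", "ConformalQSARModel", function(x) x@gate)

#' @rdname gateMetrics
#' @export
setMethod("gatePassed", "ConformalQSARModel", function(x) x@gate@passed)

#' @rdname AffinityPanel-class
#' @export
setMethod("assayIds", "ConformalQSARModel", function(x) x@assayId)

setMethod("show", "ConformalQSARModel", function(object) {
    cat("ConformalQSARModel '", object@assayId, "' (", object@method,
        "): ", object@calibration@n, " calibration scores; ", sep = "")
    show(object@gate)
})

setMethod("show", "CalibrationTable", function(object) {
    cat("CalibrationTable of", object@n, "scores, median",
        sprintf("%.3f", stats::median(object@scores)), "\n")
})

setMethod("show", "PredictionIntervalSet", function(object) {
    cat(sprintf(
        "PredictionIntervalSet: %d molecules at %.0f%% confidence; %d in domain (max width %.1f)\n",
        length(object@midpoint), 100 * object@confidence,
        sum(object@inDomain), object@maxWidth))
})
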