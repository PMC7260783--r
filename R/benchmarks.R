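# The three evaluation harnesses: similarity searching (MAX fusion over
# query actives), bioactivity classification (balanced random forest under
# cross-validation) and scaffold hopping (per-RACSK training with unique
# retrieved-CSK counting).

#' Construct a benchmark set
#'
#' @param targetId target identifier.
#' @param activeSmiles,inactiveSmiles SMILES of actives and inactives.
#' @param kind \code{"HET"}, \code{"HOM"} or \code{"CLASS"}.
#' @param activity optional activities (-log10 M), actives first then
#'   inactives; \code{NA} when unknown.
#' @param metadata optional provenance list.
#' @return A \code{\linkS4class{BenchSet}}.
#' @export
benchSet <- function(targetId, activeSmiles, inactiveSmiles,
                     kind = c("CLASS", "HET", "HOM"), activity = NULL,
                     metadata = list()) {
    kind <- match.arg(kind)
    mols <- parseMolecules(c(activeSmiles, inactiveSmiles))
    nA <- length(activeSmiles); nI <- length(inactiveSmiles)
    if (is.null(activity)) activity <- rep(NA_real_, nA + nI)
    new("BenchSet", targetId = targetId, molecules = mols,
        active = rep(c(TRUE, FALSE), c(nA, nI)), activity = activity,
        kind = kind, metadata = metadata)
}

#' @rdname BenchSet-class
#' @param x a \code{BenchSet}.
#' @export
actives <- function(x) x@molecules[x@active]

#' @rdname BenchSet-class
#' @export
inactives <- function(x) x@molecules[!x@active]

setMethod("show", "BenchSet", function(object) {
    cat("BenchSet '", object@targetId, "' (", object@kind, "): ",
        sum(object@active), " actives / ", sum(!object@active),
        " inactives\n", sep = "")
})

## ---- fingerprint schemes ------------------------------------------------

#' Define how molecules are encoded for a benchmark
#'
#' A scheme bundles the feature computation (structural Morgan bits, or
#' affinity fingerprints against a panel) with the similarity index used
#' in searching: Tanimoto for substructure bits, Rogot-Goldberg for binary
#' affinity bits (where shared inactivity is as meaningful as shared
#' activity).
#'
#' @param type \code{"morgan2"}, \code{"rv"} or \code{"b"}.
#' @param panel an \code{\linkS4class{AffinityPanel}} (required for
#'   \code{"rv"} and \code{"b"}).
#' @param adPolicy,confidence,maxWidth,cutoff fingerprint parameters (see
#'   \code{\link{rvQaffp}} and \code{\link{bQaffp}}); defaults follow the
#'   recommended settings (rv: raw values; b: cutoff 5, domain zeroing at
#'   confidence 0.90, width 4.0).
#' @param zScore standardize rv features column-wise (optional).
#' @return A \code{\linkS4class{FingerprintScheme}}.
#' @export
fingerprintScheme <- function(type = c("morgan2", "rv", "b"), panel = NULL,
                              adPolicy = NULL, confidence = 0.90,
                              maxWidth = 4.0, cutoff = 5,
                              zScore = FALSE) {
    type <- match.arg(type)
    if (type != "morgan2" && is.null(panel))
        stop("affinity schemes need a panel")
    fun <- switch(type,
        morgan2 = function(mols) morganFingerprint(mols),
        rv = function(mols) {
            v <- fingerprintValues(rvQaffp(panel, mols,
                adPolicy = adPolicy %||% "ignore",
                confidence = confidence, maxWidth = maxWidth))
            if (zScore) zStandardize(v) else v
        },
        b = function(mols) fingerprintValues(bQaffp(panel, mols,
                cutoff = cutoff, adPolicy = adPolicy %||% "zero_outside",
                confidence = confidence, maxWidth = maxWidth)))
    new("FingerprintScheme", name = type, fun = fun,
        sim = if (type == "morgan2") "tanimoto" else "rogot_goldberg")
}

setMethod("show", "FingerprintScheme", function(object) {
    cat("FingerprintScheme '", object@name, "' (similarity: ",
        object@sim, ")\n", sep = "")
})

.schemeFeatures <- function(scheme, mols) {
    X <- scheme@fun(mols)
    storage.mode(X) <- "double"
    X
}

.semOf <- function(v) {
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
}

.benchResult <- function(reps) {
    new("BenchResult", repetitions = reps, auc = mean(reps$auc),
        ef5 = mean(reps$ef5), aucSem = .semOf(reps$auc),
        ef5Sem = .semOf(reps$ef5))
}

#' @rdname BenchResult-class
#' @param x a \code{BenchResult}.
#' @export
repetitions <- function(x) x@repetitions

setMethod("show", "BenchResult", function(object) {
    cat(sprintf("BenchResult over %d repetitions: AUC %.3f +/- %.3f, EF5 %.2f +/- %.2f\n",
                nrow(object@repetitions), object@auc,
                object@aucSem %||% NA, object@ef5, object@ef5Sem))
})

## ---- similarity searching -----------------------------------------------

#' Similarity-searching benchmark
#'
#' Per repetition: a training set of query actives plus a fraction of the
#' inactives is drawn at random and removed from the pool; the remaining
#' actives and inactives are scored by MAX fusion over the queries and
#' evaluated by AUC and EF5. The heterogeneous-set protocol (kind
#' \code{"HET"}) uses 10 query actives, 20\% of inactives and 50
#' repetitions; the homogeneous protocol (\code{"HOM"}) uses a larger
#' query series and 10\% of inactives.
#'
#' @param bench a \code{\linkS4class{BenchSet}}.
#' @param scheme a \code{\linkS4class{FingerprintScheme}}.
#' @param nRep repetitions (default by kind: 50 for HET, 10 for HOM).
#' @param nQuery query actives per repetition (default 10 for HET, 20 for
#'   HOM).
#' @param inactiveHoldout fraction of inactives withheld with the training
#'   set (default 0.2 for HET, 0.1 for HOM).
#' @param activesCap optional cap on the number of held-out actives kept
#'   in the test pool.
#' @param chi EF top fraction.
#' @param seed integer master seed.
#' @return A \code{\linkS4class{BenchResult}}.
#' @export
runSimilarityBenchmark <- function(bench, scheme, nRep = NULL,
                                   nQuery = NULL, inactiveHoldout = NULL,
                                   activesCap = NULL, chi = 0.05,
                                   seed = 1L) {
    hom <- bench@kind == "HOM"
    nRep <- nRep %||% if (hom) 10L else 50L
    nQuery <- nQuery %||% if (hom) 20L else 10L
    inactiveHoldout <- inactiveHoldout %||% if (hom) 0.1 else 0.2
    actIdx <- which(bench@active); inaIdx <- which(!bench@active)
    if (length(actIdx) <= nQuery)
        stop("similarity protocol needs more than ", nQuery,
             " actives (have ", length(actIdx), ")")
    X <- .schemeFeatures(scheme, bench@molecules)
    reps <- data.frame(rep = seq_len(nRep), auc = NA_real_,
                       ef5 = NA_real_)
    for (r in seq_len(nRep)) {
        set.seed(.deriveSeed(seed, r))
        queries <- sample(actIdx, nQuery)
        heldIna <- sample(inaIdx, floor(inactiveHoldout * length(inaIdx)))
        testAct <- setdiff(actIdx, queries)
        if (!is.null(activesCap) && length(testAct) > activesCap)
            testAct <- sample(testAct, activesCap)
        pool <- c(testAct, setdiff(inaIdx, heldIna))
        scores <- maxFusionScores(X[queries, , drop = FALSE],
                                  X[pool, , drop = FALSE],
                                  sim = scheme@sim)
        labels <- pool %in% testAct
        reps$auc[r] <- rocAuc(scores, labels)
        reps$ef5[r] <- enrichmentFactor(scores, labels, chi = chi)
    }
    .benchResult(reps)
}

## ---- balanced random forest ---------------------------------------------

# Balanced RF: each tree's bootstrap draws an equal-size sample (with
# replacement) from every class, undersampling the majority; 100 trees,
# GINI splits.
.balancedRF <- function(X, y, nTrees = 100L, seed = 1L) {
    y <- factor(y, levels = c("FALSE", "TRUE"))
    nMin <- min(table(y))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    set.seed(as.integer(seed))
    randomForest::randomForest(x = as.data.frame(X), y = y,
                               ntree = as.integer(nTrees),
                               strata = y, sampsize = rep(nMin, 2L),
                               replace = TRUE, keep.inbag = TRUE)
}

.balancedRFProb <- function(model, X) {
    colnames(X) <- paste0("f", seq_len(ncol(X)))
    stats::predict(model, newdata = as.data.frame(X),
                   type = "prob")[, "TRUE"]
}

#' Bioactivity classification benchmark
#'
#' Repeated stratified 5-fold cross-validation of a balanced random
#' forest (100 trees, GINI, equal per-class bootstraps) over the scheme's
#' features, scored by AUC and EF5 per fold. Requires a CLASS-style set
#' with strictly more than \code{minClassSize} compounds in each class.
#'
#' @param bench a \code{\linkS4class{BenchSet}} of kind \code{"CLASS"}.
#' @param scheme a \code{\linkS4class{FingerprintScheme}}.
#' @param folds cross-validation folds (default 5).
#' @param repeats repetitions (default 10).
#' @param minClassSize exclusive minimum class size (default 60).
#' @param nTrees forest size.
#' @param chi EF top fraction.
#' @param seed integer master seed.
#' @return A \code{\linkS4class{BenchResult}} with one repetition row per
#'   fold evaluation.
#' @export
runClassificationBenchmark <- function(bench, scheme, folds = 5L,
                                       repeats = 10L, minClassSize = 60L,
                                       nTrees = 100L, chi = 0.05,
                                       seed = 1L) {
    nAct <- sum(bench@active); nIna <- sum(!bench@active)
    if (nAct <= minClassSize || nIna <= minClassSize)
        stop("classification sets need more than ", minClassSize,
             " actives and more than ", minClassSize, " inactives (have ",
             nAct, "/", nIna, ")")
    X <- .schemeFeatures(scheme, bench@molecules)
    y <- bench@active
    n <- length(y)
    reps <- data.frame(rep = integer(0), auc = numeric(0),
                       ef5 = numeric(0))
    row <- 0L
    for (r in seq_len(repeats)) {
        set.seed(.deriveSeed(seed, r))
        foldOf <- integer(n)
        for (cls in c(TRUE, FALSE)) {   # class-stratified fold labels
            idx <- which(y == cls)
            foldOf[idx] <- sample(rep_len(seq_len(folds), length(idx)))
        }
        for (f in seq_len(folds)) {
            test <- foldOf == f
            model <- .balancedRF(X[!test, , drop = FALSE], y[!test],
                                 nTrees = nTrees,
                                 seed = .deriveSeed(seed, r, f))
            prob <- .balancedRFProb(model, X[test, , drop = FALSE])
            row <- row + 1L
            reps[row, ] <- list((r - 1L) * folds + f,
                                rocAuc(prob, y[test]),
                                enrichmentFactor(prob, y[test], chi = chi))
        }
    }
    .benchResult(reps)
}

## ---- scaffold hopping ---------------------------------------------------

#' Scaffold-hopping benchmark
#'
#' Compounds with activity strictly above 6 (-log10 M) count as active.
#' Each rich active cyclic skeleton (RACSK: a CSK with at least
#' \code{minRacsk} actives) seeds one training set consisting of that
#' RACSK's actives plus all inactives; a balanced random forest (or a
#' plug-in classifier) then labels the remaining actives, and the CSKs of
#' compounds classified active (probability >= 0.5) are collected. The
#' result reports the union of retrieved CSKs over all training sets.
#' Acyclic compounds are excluded from the analysis; an assay without any
#' RACSK yields an empty result with a message.
#'
#' @param bench a \code{\linkS4class{BenchSet}} of kind \code{"CLASS"}
#'   with activities.
#' @param scheme a \code{\linkS4class{FingerprintScheme}}.
#' @param minRacsk minimum actives per CSK for a RACSK (default 5).
#' @param probThreshold classification threshold (default 0.5).
#' @param classifier optional plug-in: \code{function(trainX, trainY,
#'   testX) -> probability vector} replacing the balanced random forest.
#' @param nTrees forest size for the default classifier.
#' @param seed integer master seed.
#' @return A \code{\linkS4class{HoppingResult}}.
#' @export
runScaffoldHopping <- function(bench, scheme, minRacsk = 5L,
                               probThreshold = 0.5, classifier = NULL,
                               nTrees = 100L, seed = 1L) {
    if (all(is.na(bench@activity)))
        stop("scaffold hopping needs activities")
    act <- !is.na(bench@activity) & bench@activity > 6
    ina <- !act
    csk <- cskSmiles(cyclicSkeleton(bench@molecules, onAcyclic = "na"))
    usable <- !is.na(csk)
    actIdx <- which(act & usable)
    acsk <- unique(csk[actIdx])
    cskCounts <- table(csk[actIdx])
    racsk <- names(cskCounts)[cskCounts >= minRacsk]
    if (length(racsk) == 0L) {
        message("assay '", bench@targetId,
                "' has no rich active CSK; skipped")
        return(new("HoppingResult", assayId = bench@targetId,
                   nAcskTotal = length(acsk), nRacsk = 0L,
                   retrievedCsk = character(0)))
    }
    X <- .schemeFeatures(scheme, bench@molecules)
    retrieved <- character(0)
    for (s in seq_along(racsk)) {
        trainAct <- actIdx[csk[actIdx] == racsk[s]]
        trainIdx <- c(trainAct, which(ina))
        testIdx <- setdiff(actIdx, trainAct)
        if (length(testIdx) == 0L) next
        trainY <- c(rep(TRUE, length(trainAct)),
                    rep(FALSE, sum(ina)))
        prob <- if (is.null(classifier)) {
            model <- .balancedRF(X[trainIdx, , drop = FALSE], trainY,
                                 nTrees = nTrees,
                                 seed = .deriveSeed(seed, s))
            .balancedRFProb(model, X[testIdx, , drop = FALSE])
        } else {
            classifier(X[trainIdx, , drop = FALSE], trainY,
                       X[testIdx, , drop = FALSE])
        }
        hits <- testIdx[prob >= probThreshold]
        retrieved <- union(retrieved, unique(csk[hits]))
    }
    new("HoppingResult", assayId = bench@targetId,
        nAcskTotal = length(acsk), nRacsk = length(racsk),
        retrievedCsk = sort(retrieved))
}

#' Pool scaffold-hopping results from two fingerprint schemes
#'
#' The union of the retrieved-CSK sets (as reported for combined
#' rv+b fingerprints).
#'
#' @param a,b \code{\linkS4class{HoppingResult}} objects for the same
#'   assay.
#' @return A pooled \code{HoppingResult}.
#' @export
poolHoppingResults <- function(a, b) {
    stopifnot(a@assayId == b@assayId)
    new("HoppingResult", assayId = a@assayId,
        nAcskTotal = max(a@nAcskTotal, b@nAcskTotal),
        nRacsk = max(a@nRacsk, b@nRacsk),
        retrievedCsk = sort(union(a@retrievedCsk, b@retrievedCsk)))
}

#' @rdname HoppingResult-class
#' @param x a \code{HoppingResult}.
#' @export
nRetrieved <- function(x) length(x@retrievedCsk)

setMethod("show", "HoppingResult", function(object) {
    cat("HoppingResult '", object@assayId, "': ", nRetrieved(object),
        " of ", object@nAcskTotal, " active CSKs retrieved (",
        object@nRacsk, " RACSK training sets)\n", sep = "")
})
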