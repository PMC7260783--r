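#' MoleculeSet: parsed, canonicalized molecules
#'
#' A vectorized container of molecules identified by their OpenBabel
#' canonical SMILES. Construct with \code{\link{parseMolecules}}.
#'
#' @slot smiles canonical SMILES, one per molecule.
#' @slot molId molecule identifiers (defaults to the canonical SMILES).
#' @slot atomCount heavy-atom counts.
#' @slot ringFlag \code{TRUE} when the molecule contains at least one ring.
#' @exportClass MoleculeSet
setClass("MoleculeSet",
    representation(smiles = "character", molId = "character",
                   atomCount = "integer", ringFlag = "logical"))

setValidity("MoleculeSet", function(object) {
    n <- length(object@smiles)
    if (length(object@molId) != n || length(object@atomCount) != n ||
        length(object@ringFlag) != n)
        return("slot lengths differ")
    if (any(object@atomCount <= 0L))
        return("atomCount must be positive")
    TRUE
})

#' CyclicSkeletonSet: Bemis-Murcko scaffolds reduced to cyclic skeletons
#'
#' One entry per input molecule. The cyclic skeleton (CSK) is the
#' Bemis-Murcko ring-and-linker framework with every heavy atom replaced by
#' carbon and every bond order set to one; its canonical SMILES is the
#' chemotype identity key (string equality = skeleton equality). Entries are
#' \code{NA} for acyclic molecules when they are tolerated.
#'
#' @slot cskSmiles canonical SMILES of the all-carbon single-bond skeleton.
#' @slot scaffoldSmiles canonical SMILES of the Bemis-Murcko scaffold the
#'   skeleton was derived from.
#' @exportClass CyclicSkeletonSet
setClass("CyclicSkeletonSet",
    representation(cskSmiles = "character", scaffoldSmiles = "character"))

setValidity("CyclicSkeletonSet", function(object) {
    if (length(object@cskSmiles) != length(object@scaffoldSmiles))
        return("slot lengths differ")
    TRUE
})

#' LigandSet: curated compounds and activities for a single assay
#'
#' The unit of QSAR modelling: unique compounds measured in one assay, with
#' activities on the -log10 molar (pChEMBL-like) scale.
#'
#' @slot assayId assay identifier (organism/target/activity-type).
#' @slot compoundId unique compound identifiers.
#' @slot smiles canonical SMILES, parallel to \code{compoundId}.
#' @slot activity activities, -log10 M.
#' @slot metadata free-form provenance list (e.g. planted synthetic signal).
#' @exportClass LigandSet
setClass("LigandSet",
    representation(assayId = "character", compoundId = "character",
                   smiles = "character", activity = "numeric",
                   metadata = "list"),
    prototype(metadata = list()))

setValidity("LigandSet", function(object) {
    if (length(object@assayId) != 1L) return("assayId must be length 1")
    n <- length(object@compoundId)
    if (length(object@smiles) != n || length(object@activity) != n)
        return("slot lengths differ")
    if (anyDuplicated(object@compoundId))
        return("compound ids must be unique within a ligand set")
    if (any(!is.finite(object@activity)))
        return("activities must be finite")
    TRUE
})

#' SplitPlan: stratified train/test split with cross-validation folds
#'
#' @slot trainIds,testIds disjoint compound-id vectors covering the set.
#' @slot folds list of disjoint id vectors partitioning \code{trainIds}.
#' @slot ratio training fraction.
#' @slot seed integer seed the plan was drawn with.
#' @exportClass SplitPlan
setClass("SplitPlan",
    representation(trainIds = "character", testIds = "character",
                   folds = "list", ratio = "numeric", seed = "integer"))

setValidity("SplitPlan", function(object) {
    if (length(intersect(object@trainIds, object@testIds)) > 0L)
        return("train and test ids overlap")
    fall <- unlist(object@folds, use.names = FALSE)
    if (anyDuplicated(fall) || !setequal(fall, object@trainIds))
        return("folds must partition the training ids")
    sz <- lengths(object@folds)
    if (length(sz) > 1L && diff(range(sz)) > 1L)
        return("fold sizes may differ by at most one")
    TRUE
})

#' PointModel: per-assay random forest activity regressor
#'
#' 100 bagged trees (every feature considered at each split) over 1024-bit
#' Morgan fingerprints, predicting activity on the -log10 M scale.
#'
#' @slot assayId assay the model belongs to.
#' @slot forest fitted \code{ranger} object.
#' @slot featureIdx columns of the 1024-bit fingerprint that vary in the
#'   training data (constant bits can never split and are dropped).
#' @slot nTrees number of trees.
#' @slot seed RNG seed used for fitting.
#' @slot trainIds compound ids the forest was fitted on.
#' @slot oobPrediction out-of-bag predictions, named by compound id.
#' @exportClass PointModel
setClass("PointModel",
    representation(assayId = "character", forest = "ANY",
                   featureIdx = "integer", nTrees = "integer",
                   seed = "integer", trainIds = "character",
                   oobPrediction = "numeric"))

#' ErrorModel: random forest predictor of the expected absolute residual
#'
#' Supplies the scaling factor \eqn{\lambda} of the normalized
#' nonconformity score; predictions are floored at a small positive
#' constant so the score is always defined.
#'
#' @slot forest fitted \code{ranger} object.
#' @slot featureIdx fingerprint columns used.
#' @slot floor lower bound applied to predicted \eqn{\lambda} (-log10 M).
#' @slot seed RNG seed used for fitting.
#' @exportClass ErrorModel
setClass("ErrorModel",
    representation(forest = "ANY", featureIdx = "integer",
                   floor = "numeric", seed = "integer"))

setValidity("ErrorModel", function(object) {
    if (object@floor <= 0) return("floor must be positive")
    TRUE
})

#' CalibrationTable: sorted conformal nonconformity scores
#'
#' @slot scores nonconformity scores, ascending.
#' @slot n number of calibration compounds.
#' @exportClass CalibrationTable
setClass("CalibrationTable",
    representation(scores = "numeric", n = "integer"))

setValidity("CalibrationTable", function(object) {
    if (object@n < 1L) return("calibration table must hold >= 1 score")
    if (length(object@scores) != object@n) return("n must match scores")
    if (is.unsorted(object@scores)) return("scores must be sorted ascending")
    if (any(object@scores < 0)) return("scores must be non-negative")
    TRUE
})

#' GateMetrics: model-quality statistics and the panel admission flag
#'
#' @slot q2 mean cross-validated \eqn{q^2} over all folds in all repeats.
#' @slot r0Squared through-origin \eqn{R'^2_0} on the held-out test set.
#' @slot q2Min,r2Min thresholds the model was gated at.
#' @slot passed \code{TRUE} iff \code{q2 >= q2Min} and
#'   \code{r0Squared >= r2Min}.
#' @exportClass GateMetrics
setClass("GateMetrics",
    representation(q2 = "numeric", r0Squared = "numeric",
                   q2Min = "numeric", r2Min = "numeric", passed = "logical"))

setValidity("GateMetrics", function(object) {
    ok <- object@q2 >= object@q2Min && object@r0Squared >= object@r2Min
    if (!identical(object@passed, ok))
        return("passed flag inconsistent with thresholds")
    TRUE
})

#' PredictionIntervalSet: conformal prediction intervals for molecules
#'
#' @slot midpoint point predictions (-log10 M).
#' @slot halfWidth interval half-widths (may be \code{Inf} when the
#'   requested confidence exceeds what the calibration set supports).
#' @slot confidence confidence level in (0, 1).
#' @slot maxWidth full-width threshold defining the applicability domain.
#' @slot inDomain \code{TRUE} iff \code{2 * halfWidth <= maxWidth}.
#' @exportClass PredictionIntervalSet
setClass("PredictionIntervalSet",
    representation(midpoint = "numeric", halfWidth = "numeric",
                   confidence = "numeric", maxWidth = "numeric",
                   inDomain = "logical"))

setValidity("PredictionIntervalSet", function(object) {
    n <- length(object@midpoint)
    if (length(object@halfWidth) != n || length(object@inDomain) != n)
        return("slot lengths differ")
    if (any(object@halfWidth < 0)) return("halfWidth must be >= 0")
    if (object@confidence <= 0 || object@confidence >= 1)
        return("confidence must lie in (0, 1)")
    if (!identical(object@inDomain,
                   2 * object@halfWidth <= object@maxWidth))
        return("inDomain inconsistent with maxWidth")
    TRUE
})

#' ConformalQSARModel: conformal bundle for one assay
#'
#' Point model, error model and calibration table plus the gate metrics the
#' assay was admitted (or refused) with.
#'
#' @slot assayId assay identifier.
#' @slot point \code{\linkS4class{PointModel}}.
#' @slot error \code{\linkS4class{ErrorModel}}.
#' @slot calibration \code{\linkS4class{CalibrationTable}}.
#' @slot gate \code{\linkS4class{GateMetrics}}.
#' @slot method calibration scheme, \code{"icp"} or \code{"ccp"}.
#' @exportClass ConformalQSARModel
setClass("ConformalQSARModel",
    representation(assayId = "character", point = "PointModel",
                   error = "ErrorModel", calibration = "CalibrationTable",
                   gate = "GateMetrics", method = "character"))

#' AffinityPanel: ordered collection of gated conformal QSAR models
#'
#' The panel order is fixed (sorted by assay id) and defines the fingerprint
#' positions.
#'
#' @slot assays list of \code{\linkS4class{ConformalQSARModel}}, all with
#'   \code{passed = TRUE}, sorted by assay id.
#' @exportClass AffinityPanel
setClass("AffinityPanel", representation(assays = "list"))

setValidity("AffinityPanel", function(object) {
    if (length(object@assays) == 0L) return("panel must not be empty")
    if (!all(vapply(object@assays, is, TRUE, "ConformalQSARModel")))
        return("assays must be ConformalQSARModel objects")
    aid <- vapply(object@assays, function(a) a@assayId, "")
    if (anyDuplicated(aid)) return("assay ids must be unique")
    if (is.unsorted(aid)) return("assays must be sorted by assay id")
    if (!all(vapply(object@assays, function(a) a@gate@passed, TRUE)))
        return("all panel members must have passed the gate")
    TRUE
})

#' RvFingerprint: real-valued affinity fingerprints
#'
#' Rows are molecules, columns are panel assays; values are predicted
#' activities on the -log10 M scale.
#'
#' @slot values predicted-activity matrix.
#' @slot reliable logical matrix of applicability-domain flags.
#' @slot imputed logical matrix marking values replaced by the molecule's
#'   mean reliable prediction.
#' @slot assayIds column identities.
#' @exportClass RvFingerprint
setClass("RvFingerprint",
    representation(values = "matrix", reliable = "matrix",
                   imputed = "matrix", assayIds = "character"))

setValidity("RvFingerprint", function(object) {
    d <- dim(object@values)
    if (!identical(d, dim(object@reliable)) ||
        !identical(d, dim(object@imputed)))
        return("matrix dimensions differ")
    if (length(object@assayIds) != d[2L])
        return("assayIds must match the number of columns")
    if (any(object@imputed & object@reliable))
        return("imputed values cannot be flagged reliable")
    TRUE
})

#' BitFingerprint: binarized affinity fingerprints
#'
#' @slot bits 0/1 matrix (rows molecules, columns panel assays).
#' @slot cutoff activity cutoff (-log10 M) used for binarization.
#' @slot adUsed whether out-of-domain predictions were zeroed.
#' @slot assayIds column identities.
#' @exportClass BitFingerprint
setClass("BitFingerprint",
    representation(bits = "matrix", cutoff = "numeric", adUsed = "logical",
                   assayIds = "character"))

setValidity("BitFingerprint", function(object) {
    if (length(object@assayIds) != ncol(object@bits))
        return("assayIds must match the number of columns")
    if (!all(object@bits %in% c(0L, 1L))) return("bits must be 0/1")
    TRUE
})

#' BenchSet: one target's actives and inactives for benchmarking
#'
#' @slot targetId target identifier.
#' @slot molecules \code{\linkS4class{MoleculeSet}} of all compounds.
#' @slot active logical label per compound.
#' @slot activity activity (-log10 M) per compound; may be \code{NA} for
#'   similarity-search sets where only the label is known.
#' @slot kind one of \code{"HET"}, \code{"HOM"}, \code{"CLASS"}.
#' @slot metadata provenance (e.g. planted scaffold families).
#' @exportClass BenchSet
setClass("BenchSet",
    representation(targetId = "character", molecules = "MoleculeSet",
                   active = "logical", activity = "numeric",
                   kind = "character", metadata = "list"),
    prototype(metadata = list()))

setValidity("BenchSet", function(object) {
    n <- length(object@molecules@smiles)
    if (length(object@active) != n || length(object@activity) != n)
        return("slot lengths differ")
    if (!object@kind %in% c("HET", "HOM", "CLASS"))
        return("kind must be HET, HOM or CLASS")
    act <- object@molecules@smiles[object@active]
    ina <- object@molecules@smiles[!object@active]
    if (length(intersect(act, ina)) > 0L)
        return("actives and inactives must be disjoint by canonical SMILES")
    TRUE
})

#' BenchResult: AUC/EF5 evaluations with repetition structure
#'
#' @slot repetitions data.frame with one row per repetition (or fold) and
#'   columns \code{rep}, \code{auc}, \code{ef5}.
#' @slot auc,ef5 means over repetitions.
#' @slot aucSem,ef5Sem standard errors of those means.
#' @exportClass BenchResult
setClass("BenchResult",
    representation(repetitions = "data.frame", auc = "numeric",
                   ef5 = "numeric", aucSem = "numeric", ef5Sem = "numeric"))

setValidity("BenchResult", function(object) {
    r <- object@repetitions
    if (!all(c("rep", "auc", "ef5") %in% names(r)))
        return("repetitions needs rep/auc/ef5 columns")
    if (abs(object@auc - mean(r$auc)) > 1e-8 ||
        abs(object@ef5 - mean(r$ef5)) > 1e-8)
        return("summary must equal recomputation from repetitions")
    TRUE
})

#' HoppingResult: scaffold-hopping retrieval counts for one assay
#'
#' @slot assayId assay/target identifier.
#' @slot nAcskTotal number of distinct active cyclic skeletons (ACSKs).
#' @slot nRacsk number of rich ACSKs (>= 5 active members).
#' @slot retrievedCsk canonical CSK strings of hops retrieved over all
#'   per-RACSK training sets.
#' @exportClass HoppingResult
setClass("HoppingResult",
    representation(assayId = "character", nAcskTotal = "integer",
                   nRacsk = "integer", retrievedCsk = "character"))

setValidity("HoppingResult", function(object) {
    if (anyDuplicated(object@retrievedCsk))
        return("retrieved CSKs must be unique")
    if (length(object@retrievedCsk) > object@nAcskTotal)
        return("cannot retrieve more CSKs than exist")
    TRUE
})

#' FingerprintScheme: a named molecule-to-feature-matrix encoder
#'
#' Wraps the function used by the benchmark harnesses to turn molecules
#' into feature rows, together with the binary similarity index the scheme
#' is searched with. Construct with \code{\link{fingerprintScheme}}.
#'
#' @slot name scheme label (\code{"morgan2"}, \code{"rv"}, \code{"b"}, ...).
#' @slot fun function mapping a \code{MoleculeSet} to a numeric matrix.
#' @slot sim similarity index for searching: \code{"tanimoto"} or
#'   \code{"rogot_goldberg"}.
#' @exportClass FingerprintScheme
setClass("FingerprintScheme",
    representation(name = "character", fun = "function", sim = "character"))
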