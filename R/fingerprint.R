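# Panel assembly and fingerprint emission. The affinity fingerprint of a
# molecule is the vector of activities predicted across the panel of gated
# assays; the binary variant thresholds those values at an activity cutoff
# with optional zeroing of out-of-domain components.

#' Assemble gated conformal models into an affinity panel
#'
#' Retains only bundles whose gate passed and fixes the fingerprint
#' positions by sorting on assay id. Duplicate assay ids are an error;
#' zero passing bundles is an error.
#'
#' @param bundles list of \code{\linkS4class{ConformalQSARModel}}.
#' @return An \code{\linkS4class{AffinityPanel}}.
#' @export
assemblePanel <- function(bundles) {
    stopifnot(length(bundles) > 0L)
    aid <- vapply(bundles, function(b) b@assayId, "")
    if (anyDuplicated(aid))
        stop("duplicate assay id(s): ",
             paste(unique(aid[duplicated(aid)]), collapse = ", "))
    passed <- vapply(bundles, gatePassed, TRUE)
    if (!any(passed))
        stop("no bundle passed the quality gate; panel would be empty")
    kept <- bundles[passed]
    kept <- kept[order(vapply(kept, function(b) b@assayId, ""))]
    new("AffinityPanel", assays = kept)
}

#' @rdname AffinityPanel-class
#' @export
setMethod("assayIds", "AffinityPanel", function(x) {
    vapply(x@assays, function(a) a@assayId, "")
})

#' @rdname AffinityPanel-class
#' @param x an \code{AffinityPanel}.
#' @export
setMethod("length", "AffinityPanel", function(x) length(x@assays))

setMethod("show", "AffinityPanel", function(object) {
    cat("AffinityPanel of", length(object), "gated assays:",
        paste(head(assayIds(object), 5L), collapse = ", "),
        if (length(object) > 5L) "..." else "", "\n")
})

# midpoints and in-domain flags for all molecules across all panel assays
.panelPredict <- function(panel, X, confidence, maxWidth) {
    L <- length(panel)
    values <- matrix(NA_real_, nrow = nrow(X), ncol = L)
    reliable <- matrix(NA, nrow = nrow(X), ncol = L)
    for (j in seq_len(L)) {
        b <- panel@assays[[j]]
        pi <- predictInterval(b@point, b@error, b@calibration, X,
                              confidence = confidence, maxWidth = maxWidth)
        values[, j] <- pi@midpoint
        reliable[, j] <- pi@inDomain
    }
    colnames(values) <- colnames(reliable) <- assayIds(panel)
    rownames(values) <- rownames(reliable) <- rownames(X)
    list(values = values, reliable = reliable)
}

# per-molecule imputation: unreliable components replaced by the mean of
# the molecule's reliable components
.imputeUnreliable <- function(values, reliable) {
    imputed <- !reliable
    for (i in seq_len(nrow(values))) {
        if (all(reliable[i, ])) next
        if (!any(reliable[i, ]))
            stop("molecule ", rownames(values)[i] %||% i,
                 ": no reliable prediction; fingerprint undefined")
        values[i, !reliable[i, ]] <- mean(values[i, reliable[i, ]])
    }
    list(values = values, imputed = imputed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# binarization rule: >= cutoff inside the domain -> 1; < cutoff inside the
# domain -> 0; outside the domain -> 0 when the domain is enforced (an
# out-of-domain compound is taken to be more likely inactive)
.binarize <- function(values, reliable, cutoff, adUsed) {
    bits <- (values >= cutoff) * 1L
    if (adUsed) bits[!reliable] <- 0L
    storage.mode(bits) <- "integer"
    bits
}

#' Real-valued affinity fingerprint (rv)
#'
#' Predicted activities across the panel, one column per assay. With
#' \code{adPolicy = "impute"}, components whose prediction interval at the
#' given confidence is wider than \code{maxWidth} are replaced by the mean
#' of the molecule's reliable components and flagged; with
#' \code{"ignore"} (the recommended default) raw predictions are kept and
#' the reliability flags are still recorded.
#'
#' @param panel an \code{\linkS4class{AffinityPanel}}.
#' @param x molecules (\code{MoleculeSet}, SMILES, or fingerprint matrix).
#' @param adPolicy \code{"ignore"} or \code{"impute"}.
#' @param confidence conformal confidence level (default 0.90).
#' @param maxWidth applicability-domain width threshold (default 4.0).
#' @return An \code{\linkS4class{RvFingerprint}}.
#' @export
rvQaffp <- function(panel, x, adPolicy = c("ignore", "impute"),
                    confidence = 0.90, maxWidth = 4.0) {
    adPolicy <- match.arg(adPolicy)
    X <- if (is.matrix(x)) x else morganFingerprint(x)
    pred <- .panelPredict(panel, X, confidence, maxWidth)
    imputed <- matrix(FALSE, nrow(pred$values), ncol(pred$values),
                      dimnames = dimnames(pred$values))
    values <- pred$values
    if (adPolicy == "impute") {
        imp <- .imputeUnreliable(values, pred$reliable)
        values <- imp$values
        imputed <- imp$imputed
    }
    new("RvFingerprint", values = values, reliable = pred$reliable,
        imputed = imputed, assayIds = assayIds(panel))
}

#' Binary affinity fingerprint (b)
#'
#' Binarizes panel predictions at an activity cutoff on the -log10 M scale
#' (the recommended cutoff is 5, i.e. 10 uM). With
#' \code{adPolicy = "zero_outside"} (recommended), out-of-domain
#' components are set to 0; with \code{"none"} raw predictions are
#' thresholded regardless of the domain.
#'
#' @inheritParams rvQaffp
#' @param cutoff activity cutoff, -log10 M (5, 6, 7 and 8 correspond to
#'   10 uM, 1 uM, 100 nM and 10 nM).
#' @param adPolicy \code{"zero_outside"} or \code{"none"}.
#' @return A \code{\linkS4class{BitFingerprint}}.
#' @export
bQaffp <- function(panel, x, cutoff = 5,
                   adPolicy = c("zero_outside", "none"),
                   confidence = 0.90, maxWidth = 4.0) {
    adPolicy <- match.arg(adPolicy)
    X <- if (is.matrix(x)) x else morganFingerprint(x)
    pred <- .panelPredict(panel, X, confidence, maxWidth)
    bits <- .binarize(pred$values, pred$reliable, cutoff,
                      adUsed = adPolicy == "zero_outside")
    new("BitFingerprint", bits = bits, cutoff = cutoff,
        adUsed = adPolicy == "zero_outside", assayIds = assayIds(panel))
}

## ---- masking ------------------------------------------------------------

.maskIdx <- function(have, targetIds) {
    unknown <- setdiff(targetIds, have)
    if (length(unknown) > 0L)
        warning("unknown assay id(s) ignored: ",
                paste(unknown, collapse = ", "))
    which(!have %in% targetIds)
}

#' @rdname maskAssays
#' @export
setMethod("maskAssays", "AffinityPanel", function(x, targetIds) {
    keep <- .maskIdx(assayIds(x), targetIds)
    if (length(keep) == 0L) stop("masking would empty the panel")
    new("AffinityPanel", assays = x@assays[keep])
})

#' @rdname maskAssays
#' @export
setMethod("maskAssays", "RvFingerprint", function(x, targetIds) {
    keep <- .maskIdx(x@assayIds, targetIds)
    new("RvFingerprint", values = x@values[, keep, drop = FALSE],
        reliable = x@reliable[, keep, drop = FALSE],
        imputed = x@imputed[, keep, drop = FALSE],
        assayIds = x@assayIds[keep])
})

#' @rdname maskAssays
#' @export
setMethod("maskAssays", "BitFingerprint", function(x, targetIds) {
    keep <- .maskIdx(x@assayIds, targetIds)
    new("BitFingerprint", bits = x@bits[, keep, drop = FALSE],
        cutoff = x@cutoff, adUsed = x@adUsed,
        assayIds = x@assayIds[keep])
})

## ---- Z-standardization --------------------------------------------------

#' Z-standardize a compounds-by-assays matrix
#'
#' Centers and scales each column to mean 0 and (population) standard
#' deviation 1. Constant columns are left as zeros with a warning. The
#' transformation is idempotent on already-standardized input. Offered as
#' an option for real-valued fingerprints used as classifier features.
#'
#' @param m numeric matrix with at least 2 rows.
#' @return The standardized matrix.
#' @export
zStandardize <- function(m) {
    stopifnot(is.matrix(m))
    if (nrow(m) < 2L) stop("need at least 2 rows to standardize")
    mu <- colMeans(m)
    sdev <- sqrt(.colVar(m))
    out <- sweep(m, 2L, mu)
    zero <- sdev == 0
    if (any(zero)) {
        warning(sum(zero), " constant column(s) left as zeros")
        sdev[zero] <- 1
    }
    sweep(out, 2L, sdev, "/")
}

## ---- fingerprint accessors ----------------------------------------------

#' @rdname RvFingerprint-class
#' @param x an \code{RvFingerprint} or \code{BitFingerprint}.
#' @return \code{fingerprintValues} returns the numeric (or bit) matrix.
#' @export
fingerprintValues <- function(x) {
    if (is(x, "RvFingerprint")) x@values
    else if (is(x, "BitFingerprint")) x@bits
    else stop("not a fingerprint object")
}

#' @rdname AffinityPanel-class
#' @export
setMethod("assayIds", "RvFingerprint", function(x) x@assayIds)

#' @rdname AffinityPanel-class
#' @export
setMethod("assayIds", "BitFingerprint", function(x) x@assayIds)

setMethod("show", "RvFingerprint", function(object) {
    cat("RvFingerprint:", nrow(object@values), "molecules x",
        ncol(object@values), "assays;",
        sprintf("%.1f%%", 100 * mean(object@reliable)), "in domain\n")
})

setMethod("show", "BitFingerprint", function(object) {
    cat("BitFingerprint:", nrow(object@bits), "molecules x",
        ncol(object@bits), "assays; cutoff", object@cutoff,
        if (object@adUsed) "(AD-zeroed);" else "(no AD);",
        "density", sprintf("%.3f", mean(object@bits)), "\n")
})

#' Write fingerprints as a delimited table
#'
#' One row per molecule (id column first), one column per assay.
#'
#' @param x an \code{RvFingerprint} or \code{BitFingerprint}.
#' @param file output path.
#' @return Invisibly, the written data.frame.
#' @export
writeFingerprints <- function(x, file) {
    m <- fingerprintValues(x)
    df <- data.frame(compoundId = rownames(m) %||%
                         as.character(seq_len(nrow(m))),
                     m, check.names = FALSE)
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
    invisible(df)
}
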