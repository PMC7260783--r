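# Curation: filter raw activity records and assemble per-assay ligand sets.
#
# An "assay" is one organism/target/activity-type combination; a record is
# one measured compound-assay activity with the provenance fields the
# filters act on. Records are plain data.frames with the columns documented
# in readActivityTable(); activities are on the -log10 molar scale
# throughout (5 = 10 uM, 6 = 1 uM, ...).

.recordCols <- c("compoundId", "smiles", "assayId", "activityType",
                 "relation", "value", "confidence")

.checkRecords <- function(records) {
    miss <- setdiff(.recordCols, names(records))
    if (length(miss) > 0L)
        stop("activity table lacks columns: ", paste(miss, collapse = ", "))
    if (any(!is.finite(records$value)))
        stop("activity values must be finite")
    invisible(records)
}

#' Read a delimited activity table
#'
#' Reads compound-assay activity records from CSV/TSV. Column names can be
#' remapped via \code{columns}, a named character vector from the canonical
#' names (\code{compoundId}, \code{smiles}, \code{assayId},
#' \code{activityType}, \code{relation}, \code{value}, \code{confidence})
#' to the names used in the file. Values must already be on the -log10
#' molar scale; use \code{\link{potencyFromConcentration}} first when the
#' source reports concentrations.
#'
#' @param file path to a delimited text file with a header.
#' @param sep field separator (default tab; use "," for CSV).
#' @param columns optional canonical-to-file column-name mapping.
#' @return data.frame of activity records with canonical column names.
#' @export
readActivityTable <- function(file, sep = "\t", columns = NULL) {
    df <- utils::read.delim(file, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE)
    if (!is.null(columns)) {
        for (canon in names(columns)) {
            if (!columns[[canon]] %in% names(df))
                stop("mapped column '", columns[[canon]], "' not in file")
            names(df)[names(df) == columns[[canon]]] <- canon
        }
    }
    .checkRecords(df[, intersect(c(.recordCols,
                                   setdiff(names(df), .recordCols)),
                                 names(df)), drop = FALSE])
}

#' Convert concentrations to the -log10 molar potency scale
#'
#' \code{potencyFromConcentration(10, "uM")} is exactly 5;
#' 1 uM is 6, 100 nM is 7, 10 nM is 8. Computed as the unit's decimal
#' exponent minus \code{log10(value)} so that powers of ten stay exact.
#'
#' @param value numeric concentrations (> 0).
#' @param unit one of "M", "mM", "uM", "nM", "pM" (recycled).
#' @return Potency on the -log10 molar scale.
#' @export
potencyFromConcentration <- function(value, unit = "nM") {
    expo <- c(M = 0, mM = 3, uM = 6, nM = 9, pM = 12)
    if (any(!unit %in% names(expo)))
        stop("unknown unit; use one of ", paste(names(expo), collapse = ", "))
    if (any(value <= 0)) stop("concentrations must be positive")
    unname(expo[unit] - log10(value))
}

#' Filter activity records for QSAR-grade data
#'
#' Keeps records with (i) activity type IC50, EC50, Ki or Kd, (ii) the
#' relation exactly \code{"="} (no censored values), and (iii) a curation
#' confidence score of 7 or 9 (direct binding to a single protein or a
#' complex subunit). Order is preserved; an empty result is allowed.
#'
#' @param records activity-record data.frame.
#' @param activityTypes,relation,confidence the admissible values.
#' @return The filtered data.frame.
#' @export
filterActivityRecords <- function(records,
                                  activityTypes = c("IC50", "EC50",
                                                    "Ki", "Kd"),
                                  relation = "=",
                                  confidence = c(7L, 9L)) {
    .checkRecords(records)
    keep <- records$activityType %in% activityTypes &
        records$relation %in% relation &
        records$confidence %in% confidence
    records[keep, , drop = FALSE]
}

#' Aggregate replicate measurements per compound-assay pair
#'
#' Multiple measurements for the same compound-assay pair are replaced by
#' their mean when the (sample) standard deviation of all annotated values
#' is below \code{sdCutoff}; otherwise the pair is discarded entirely.
#' Pairs discarded in one assay do not affect the same compound elsewhere.
#'
#' @param records filtered activity-record data.frame.
#' @param sdCutoff replicate standard-deviation cutoff (-log10 M units).
#' @return data.frame with one row per surviving (compoundId, assayId)
#'   pair: columns compoundId, assayId, smiles, value.
#' @export
aggregateDuplicates <- function(records, sdCutoff = 0.5) {
    .checkRecords(records)
    if (nrow(records) == 0L)
        return(data.frame(compoundId = character(0),
                          assayId = character(0),
                          smiles = character(0), value = numeric(0),
                          stringsAsFactors = FALSE))
    key <- paste(records$assayId, records$compoundId, sep = "\r")
    grp <- split(seq_len(nrow(records)), key)
    keep <- lapply(grp, function(idx) {
        v <- records$value[idx]
        if (length(v) > 1L && stats::sd(v) >= sdCutoff) return(NULL)
        data.frame(compoundId = records$compoundId[idx[1L]],
                   assayId = records$assayId[idx[1L]],
                   smiles = records$smiles[idx[1L]],
                   value = mean(v), stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, keep[!vapply(keep, is.null, TRUE)])
    if (is.null(out))
        out <- data.frame(compoundId = character(0), assayId = character(0),
                          smiles = character(0), value = numeric(0),
                          stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out[order(out$assayId, out$compoundId), , drop = FALSE]
}

#' Group aggregated records into per-assay ligand sets
#'
#' Groups by assay, parses SMILES (compounds whose SMILES cannot be parsed
#' are dropped with a warning, not an error) and emits a
#' \code{\linkS4class{LigandSet}} for each assay with strictly more than
#' \code{minSize} distinct compounds.
#'
#' @param aggregated output of \code{\link{aggregateDuplicates}}.
#' @param minSize minimum exclusive set size (default 50: a set qualifies
#'   with 51+ compounds).
#' @return list of \code{LigandSet}, sorted by assay id.
#' @export
buildLigandSets <- function(aggregated, minSize = 50L) {
    stopifnot(all(c("compoundId", "assayId", "smiles", "value") %in%
                  names(aggregated)))
    sets <- lapply(split(aggregated, aggregated$assayId), function(df) {
        df <- df[order(df$compoundId), , drop = FALSE]
        parsed <- rep(NA_character_, nrow(df))
        for (i in seq_len(nrow(df))) {
            can <- tryCatch(
                suppressWarnings(smiles(parseMolecules(df$smiles[i]))),
                error = function(e) NA_character_)
            parsed[i] <- can
        }
        if (anyNA(parsed))
            warning("assay ", df$assayId[1L], ": dropped ",
                    sum(is.na(parsed)), " unparseable compound(s)")
        df <- df[!is.na(parsed), , drop = FALSE]
        can <- parsed[!is.na(parsed)]
        if (nrow(df) <= minSize) return(NULL)
        new("LigandSet", assayId = df$assayId[1L],
            compoundId = df$compoundId, smiles = can,
            activity = df$value)
    })
    sets <- sets[!vapply(sets, is.null, TRUE)]
    sets[order(names(sets))]
}

## ---- LigandSet accessors ------------------------------------------------

#' @rdname LigandSet-class
#' @export
setMethod("assayId", "LigandSet", function(x) x@assayId)

#' @rdname LigandSet-class
#' @export
setMethod("compoundIds", "LigandSet", function(x) x@compoundId)

#' @rdname LigandSet-class
#' @export
setMethod("activities", "LigandSet", function(x) {
    setNames(x@activity, x@compoundId)
})

#' @rdname LigandSet-class
#' @param x,object a \code{LigandSet}.
#' @param ... unused.
#' @export
setMethod("smiles", "LigandSet", function(x, ...) {
    setNames(x@smiles, x@compoundId)
})

#' @rdname LigandSet-class
#' @export
setMethod("length", "LigandSet", function(x) length(x@compoundId))

setMethod("show", "LigandSet", function(object) {
    cat("LigandSet '", object@assayId, "': ", length(object),
        " compounds, activity range [",
        sprintf("%.2f", min(object@activity)), ", ",
        sprintf("%.2f", max(object@activity)), "] (-log10 M)\n", sep = "")
})

# Fingerprint matrix for a ligand set (rows named by compound id); cached
# globally by canonical SMILES, so repeated calls are cheap.
.ligandFingerprints <- function(ls) {
    mols <- new("MoleculeSet", smiles = ls@smiles, molId = ls@compoundId,
                atomCount = rep(1L, length(ls)),
                ringFlag = rep(TRUE, length(ls)))
    morganFingerprint(mols)
}

#' Subset a ligand set by compound ids
#' @param x a \code{LigandSet}.
#' @param ids compound ids to keep.
#' @return The reduced \code{LigandSet}.
#' @export
subsetLigands <- function(x, ids) {
    idx <- match(ids, x@compoundId)
    if (anyNA(idx)) stop("unknown compound id(s)")
    new("LigandSet", assayId = x@assayId, compoundId = x@compoundId[idx],
        smiles = x@smiles[idx], activity = x@activity[idx],
        metadata = x@metadata)
}
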