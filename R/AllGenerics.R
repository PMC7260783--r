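#' @rdname MoleculeSet-class
#' @param x,object an object.
#' @param ... unused.
#' @export
setGeneric("smiles", function(x, ...) standardGeneric("smiles"))

#' @rdname MoleculeSet-class
#' @export
setGeneric("atomCount", function(x) standardGeneric("atomCount"))

#' @rdname MoleculeSet-class
#' @export
setGeneric("ringFlag", function(x) standardGeneric("ringFlag"))

#' @rdname CyclicSkeletonSet-class
#' @param x an object.
#' @export
setGeneric("cskSmiles", function(x) standardGeneric("cskSmiles"))

#' @rdname LigandSet-class
#' @param x an object.
#' @export
setGeneric("assayId", function(x) standardGeneric("assayId"))

#' @rdname LigandSet-class
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname LigandSet-class
#' @export
setGeneric("activities", function(x) standardGeneric("activities"))

#' Accessors for gate metrics
#' @param x an object carrying gate metrics.
#' @export
setGeneric("gateMetrics", function(x) standardGeneric("gateMetrics"))

#' @rdname gateMetrics
#' @export
setGeneric("gatePassed", function(x) standardGeneric("gatePassed"))

#' @rdname AffinityPanel-class
#' @param x an object with assay positions.
#' @export
setGeneric("assayIds", function(x) standardGeneric("assayIds"))

#' Remove assay positions from a panel or fingerprint
#'
#' Benchmark targets that are themselves part of the panel must be excluded
#' before the panel is evaluated on them; this removes the corresponding
#' positions. Unknown ids are ignored with a warning.
#'
#' @param x an \code{AffinityPanel}, \code{RvFingerprint} or
#'   \code{BitFingerprint}.
#' @param targetIds character vector of assay ids to drop.
#' @return An object of the same class with those positions removed.
#' @export
setGeneric("maskAssays", function(x, targetIds) standardGeneric("maskAssays"))
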