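#' @include AllGenerics.R
NULL

#' Accessor generics
#'
#' Small accessor generics used across the package's S4 classes.
#'
#' @param x An object of the relevant class.
#' @param object An object of the relevant class.
#' @return The slot content (see the class documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname accessors
#' @export
setGeneric("regionCentroids", function(x) standardGeneric("regionCentroids"))

#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("connMatrix", function(x) standardGeneric("connMatrix"))

#' @rdname accessors
#' @export
setGeneric("connKind", function(x) standardGeneric("connKind"))

#' @rdname accessors
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' @rdname accessors
#' @export
setGeneric("coefficient", function(x) standardGeneric("coefficient"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))

#' @rdname accessors
#' @export
setGeneric("nEdges", function(x) standardGeneric("nEdges"))

#' @rdname accessors
#' @export
setGeneric("assocMethod", function(x) standardGeneric("assocMethod"))

#' @rdname accessors
#' @export
setGeneric("detectionSummary", function(x) standardGeneric("detectionSummary"))

#' @rdname accessors
#' @export
setGeneric("detectionPoints", function(x) standardGeneric("detectionPoints"))

#' Symmetrize a connectome by averaging reciprocal weights
#'
#' @param x A [Connectome-class] (or plain square matrix).
#' @param ... Unused, for future methods.
#' @return An object of the same class with `w[i,j]` replaced by
#'   `(w[i,j] + w[j,i]) / 2`. Idempotent.
#' @export
setGeneric("symmetrize", function(x, ...) standardGeneric("symmetrize"))
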