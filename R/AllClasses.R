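#' @include AllGenerics.R
NULL

.CONN_KINDS <- c("count", "fln", "fs", "log", "weight")

# ---------------------------------------------------------------------------
# RegionSet
# ---------------------------------------------------------------------------

#' RegionSet: an ordered cortical parcellation with optional centroids
#'
#' A `RegionSet` fixes the ordered set of region labels that indexes every
#' connectivity matrix in an analysis, together with (optionally) one 3-D
#' centroid per region in millimetres. Centroid coordinates live in an
#' arbitrary but shared space; only relative Euclidean distances between
#' centroids are ever used.
#'
#' @slot labels Character vector of unique, non-empty region names. Their
#'   order defines row/column indexing everywhere in the package.
#' @slot centroids Numeric matrix with one row per region and columns
#'   `x`, `y`, `z` (mm), or a 0-row matrix when centroids are absent.
#'   Individual regions may carry `NA` coordinates (centroid unknown).
#'
#' @seealso [readRegionSet()], [euclideanDistances()]
#' @export
setClass("RegionSet",
  representation(labels = "character", centroids = "matrix"))

setValidity("RegionSet", function(object) {
  lab <- object@labels
  if (length(lab) == 0L) return("RegionSet must contain at least one region")
  if (anyNA(lab) || any(!nzchar(lab)))
    return("region labels must be non-empty and non-NA")
  if (anyDuplicated(lab)) {
    dup <- unique(lab[duplicated(lab)])
    return(sprintf("duplicate region label(s): %s",
                   paste(dup, collapse = ", ")))
  }
  ctr <- object@centroids
  if (nrow(ctr) > 0L) {
    if (nrow(ctr) != length(lab))
      return("centroids must have one row per region")
    if (ncol(ctr) != 3L)
      return("centroids must have exactly 3 columns (x, y, z)")
    if (!is.numeric(ctr))
      return("centroids must be numeric")
    if (any(is.infinite(ctr)))
      return("centroid coordinates must be finite")
  }
  TRUE
})

#' Construct a RegionSet
#'
#' @param labels Character vector of unique region names.
#' @param centroids Optional numeric matrix or data.frame with 3 columns
#'   (x, y, z in mm) and one row per label.
#' @return A [RegionSet-class] object.
#' @examples
#' rs <- RegionSet(c("17", "18", "19"),
#'                 centroids = rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1)))
#' euclideanDistances(rs)
#' @export
RegionSet <- function(labels, centroids = NULL) {
  labels <- as.character(labels)
  if (is.null(centroids)) {
    centroids <- matrix(numeric(0), nrow = 0L, ncol = 3L,
                        dimnames = list(NULL, c("x", "y", "z")))
  } else {
    centroids <- as.matrix(centroids)
    storage.mode(centroids) <- "double"
    colnames(centroids) <- c("x", "y", "z")
    rownames(centroids) <- labels
  }
  new("RegionSet", labels = labels, centroids = centroids)
}

#' @rdname accessors
#' @export
setMethod("regionLabels", "RegionSet", function(x) x@labels)

#' @rdname accessors
#' @export
setMethod("regionCentroids", "RegionSet", function(x) {
  if (nrow(x@centroids) == 0L) NULL else x@centroids
})

#' @rdname accessors
#' @export
setMethod("nRegions", "RegionSet", function(x) length(x@labels))

setMethod("show", "RegionSet", function(object) {
  cat(sprintf("RegionSet with %d regions%s\n", length(object@labels),
              if (nrow(object@centroids) > 0L) " (centroids in mm)" else ""))
  cat("  labels:", paste(utils::head(object@labels, 8L), collapse = ", "),
      if (length(object@labels) > 8L) "..." else "", "\n")
})

# ---------------------------------------------------------------------------
# Connectome
# ---------------------------------------------------------------------------

#' Connectome: a weighted adjacency matrix over a RegionSet
#'
#' Holds an `n x n` weight matrix aligned to a [RegionSet-class], tagged with
#' the kind of weight it carries and whether it is directed. Rows are source
#' regions and columns are target (injected) regions throughout the package.
#'
#' Weight kinds:
#' \describe{
#'   \item{count}{raw integer counts (streamlines or labeled neurons)}
#'   \item{fln}{fraction of labeled neurons: each injected column normalized
#'     to sum to 1 over extrinsic sources}
#'   \item{fs}{fraction of streamlines (fractional scaling)}
#'   \item{log}{natural-log-transformed normalized weights (may be negative)}
#'   \item{weight}{arbitrary nonnegative weights (e.g. synthetic ground truth)}
#' }
#'
#' Self-connections are excluded: the diagonal is always zero.
#'
#' @slot regions A [RegionSet-class].
#' @slot weights Numeric `n x n` matrix, dimnames = region labels.
#' @slot directed Logical scalar; if `FALSE` the matrix is symmetric.
#' @slot kind One of `"count"`, `"fln"`, `"fs"`, `"log"`, `"weight"`.
#'
#' @seealso [readConnectome()], [computeFLN()], [fractionalScaling()]
#' @export
setClass("Connectome",
  representation(regions = "RegionSet", weights = "matrix",
                 directed = "logical", kind = "character"))

setValidity("Connectome", function(object) {
  W <- object@weights
  n <- length(object@regions@labels)
  if (!is.numeric(W)) return("weights must be numeric")
  if (nrow(W) != n || ncol(W) != n)
    return(sprintf("weights must be %d x %d to match the RegionSet", n, n))
  if (length(object@kind) != 1L || !object@kind %in% .CONN_KINDS)
    return(sprintf("kind must be one of: %s",
                   paste(.CONN_KINDS, collapse = ", ")))
  if (length(object@directed) != 1L || is.na(object@directed))
    return("directed must be TRUE or FALSE")
  if (any(!is.finite(W))) return("all weights must be finite")
  if (any(diag(W) != 0))
    return("diagonal must be zero (self-connections are excluded)")
  if (object@kind != "log" && any(W < 0))
    return(sprintf("negative weights are not allowed for kind '%s'",
                   object@kind))
  if (object@kind == "count" && any(W != round(W)))
    return("kind 'count' requires integer-valued entries")
  if (!object@directed && any(W != t(W)))
    return("directed = FALSE requires a symmetric weight matrix")
  # column stochasticity is an invariant of *directed* FLN only;
  # symmetrization (averaging both directions) deliberately breaks it
  if (object@kind == "fln" && object@directed) {
    cs <- colSums(W)
    bad <- which(cs > 0 & abs(cs - 1) > 1e-8)
    if (length(bad))
      return(sprintf("FLN columns with labels must sum to 1 (violated at: %s)",
                     paste(object@regions@labels[bad], collapse = ", ")))
  }
  TRUE
})

#' Construct a Connectome
#'
#' @param weights Square numeric matrix (rows = source, columns = target).
#' @param regions A [RegionSet-class] whose labels index `weights`.
#' @param kind Weight kind; see [Connectome-class].
#' @param directed Logical; `FALSE` requires `weights` symmetric.
#' @return A [Connectome-class] object.
#' @export
Connectome <- function(weights, regions, kind, directed) {
  weights <- as.matrix(weights)
  storage.mode(weights) <- "double"
  dimnames(weights) <- list(regions@labels, regions@labels)
  new("Connectome", regions = regions, weights = weights,
      kind = kind, directed = directed)
}

#' @rdname accessors
#' @export
setMethod("regions", "Connectome", function(x) x@regions)

#' @rdname accessors
#' @export
setMethod("connMatrix", "Connectome", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("connKind", "Connectome", function(x) x@kind)

#' @rdname accessors
#' @export
setMethod("isDirected", "Connectome", function(x) x@directed)

#' @rdname accessors
#' @export
setMethod("nRegions", "Connectome", function(x) length(x@regions@labels))

setMethod("show", "Connectome", function(object) {
  W <- object@weights
  off <- W[row(W) != col(W)]
  cat(sprintf("Connectome: %d regions, kind '%s', %s\n",
              nrow(W), object@kind,
              if (object@directed) "directed" else "symmetric"))
  cat(sprintf("  nonzero off-diagonal entries: %d / %d\n",
              sum(off != 0), length(off)))
  if (length(off))
    cat(sprintf("  weight range: [%g, %g]\n", min(off), max(off)))
})

# ---------------------------------------------------------------------------
# AssociationResult
# ---------------------------------------------------------------------------

#' AssociationResult: one association estimate between paired edge weights
#'
#' @slot method One of `"spearman"`, `"pearson_log"`, `"partial_spearman"`.
#' @slot coefficient Correlation coefficient in `[-1, 1]`.
#' @slot pValue Two-sided p-value in `(0, 1]`.
#' @slot ciLow,ciHigh Percentile bootstrap confidence bounds (`NA` when no
#'   bootstrap has been run).
#' @slot ciLevel Confidence level of the interval (`NA` when absent).
#' @slot nEdges Number of edges the coefficient was computed on.
#'
#' @export
setClass("AssociationResult",
  representation(method = "character", coefficient = "numeric",
                 pValue = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 ciLevel = "numeric", nEdges = "integer"))

setValidity("AssociationResult", function(object) {
  if (!object@method %in% c("spearman", "pearson_log", "partial_spearman"))
    return("unknown association method")
  r <- object@coefficient
  if (!is.finite(r) || r < -1 - 1e-12 || r > 1 + 1e-12)
    return("coefficient must lie in [-1, 1]")
  if (!is.na(object@ciLow) && !is.na(object@ciHigh)) {
    if (object@ciLow > r + 1e-12 || object@ciHigh < r - 1e-12)
      return("confidence interval must bracket the coefficient")
  }
  TRUE
})

.AssociationResult <- function(method, coefficient, pValue, nEdges,
                               ciLow = NA_real_, ciHigh = NA_real_,
                               ciLevel = NA_real_) {
  new("AssociationResult", method = method, coefficient = coefficient,
      pValue = pValue, ciLow = ciLow, ciHigh = ciHigh, ciLevel = ciLevel,
      nEdges = as.integer(nEdges))
}

#' @rdname accessors
#' @export
setMethod("coefficient", "AssociationResult", function(x) x@coefficient)

#' @rdname accessors
#' @export
setMethod("pValue", "AssociationResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setMethod("confInt", "AssociationResult",
          function(x) c(low = x@ciLow, high = x@ciHigh))

#' @rdname accessors
#' @export
setMethod("nEdges", "AssociationResult", function(x) x@nEdges)

#' @rdname accessors
#' @export
setMethod("assocMethod", "AssociationResult", function(x) x@method)

setMethod("show", "AssociationResult", function(object) {
  lab <- switch(object@method,
                spearman = "Spearman's rho",
                pearson_log = "Pearson's r (log values)",
                partial_spearman = "partial Spearman's rho (distance removed)")
  cat(sprintf("%s = %.4f  (n = %d edges, p = %.3g)\n",
              lab, object@coefficient, object@nEdges, object@pValue))
  if (!is.na(object@ciLow))
    cat(sprintf("  %g%% bootstrap CI: [%.4f, %.4f]\n",
                100 * object@ciLevel, object@ciLow, object@ciHigh))
})

# ---------------------------------------------------------------------------
# DetectionResult
# ---------------------------------------------------------------------------

#' DetectionResult: detection performance across ground-truth densities
#'
#' Produced by [detectionSweep()]. `summary` has one row per ground-truth
#' density and evaluation mode with sensitivity, specificity and precision;
#' `points` stores every underlying confusion tuple (one per operating point)
#' so the defining identities sensitivity = TP/(TP+FN), specificity =
#' TN/(TN+FP) and precision = TP/(TP+FP) can be verified exactly.
#'
#' @slot densities Numeric vector of ground-truth densities evaluated.
#' @slot summary data.frame: density, densityRealized, mode, sensitivity,
#'   specificity, precision.
#' @slot points data.frame of per-operating-point confusion tuples:
#'   density, mode, threshold, TP, FP, TN, FN, sensitivity, specificity,
#'   precision.
#' @export
setClass("DetectionResult",
  representation(densities = "numeric", summary = "data.frame",
                 points = "data.frame"))

setValidity("DetectionResult", function(object) {
  p <- object@points
  if (nrow(p)) {
    tot <- p$TP + p$FP + p$TN + p$FN
    if (length(unique(tot)) != 1L)
      return("confusion tuples must all cover the same number of pairs")
    if (any(abs(p$sensitivity - p$TP / (p$TP + p$FN)) > 1e-12, na.rm = TRUE))
      return("sensitivity != TP/(TP+FN) in stored confusion tuples")
  }
  TRUE
})

#' @rdname accessors
#' @export
setMethod("detectionSummary", "DetectionResult", function(x) x@summary)

#' @rdname accessors
#' @export
setMethod("detectionPoints", "DetectionResult", function(x) x@points)

setMethod("show", "DetectionResult", function(object) {
  cat(sprintf("DetectionResult over %d ground-truth densities\n",
              length(object@densities)))
  m <- object@summary[object@summary$mode == "matched", , drop = FALSE]
  if (nrow(m))
    cat(sprintf("  matched-density means: sens %.3f, spec %.3f, prec %.3f\n",
                mean(m$sensitivity), mean(m$specificity), mean(m$precision)))
  s <- object@summary[object@summary$mode == "sweep", , drop = FALSE]
  if (nrow(s))
    cat(sprintf("  sweep-averaged means:  sens %.3f, spec %.3f, prec %.3f\n",
                mean(s$sensitivity), mean(s$specificity), mean(s$precision)))
})
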