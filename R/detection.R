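#' @include AllClasses.R
NULL

# Extract upper-triangle weights in stable lexicographic pair order.
.pairWeights <- function(W) {
  n <- nrow(W)
  pr <- t(utils::combn(n, 2L))
  list(pairs = pr, w = W[cbind(pr[, 1L], pr[, 2L])])
}

#' Threshold and binarize a symmetric connectome at a target density
#'
#' Keeps exactly `ceiling(density * E)` of the strongest off-diagonal
#' unordered edges (E = n(n-1)/2 candidate pairs) and sets them to 1, the
#' rest to 0. Ties at the cut are resolved deterministically by sorted
#' region-label pair (falling back to index pair order for unlabeled
#' matrices), so the result is invariant to the region order of the inputs;
#' a warning reports when tied weights straddle the cut. The realized
#' density `k / E` is attached as attribute `"realizedDensity"`.
#'
#' @param w A symmetric [Connectome-class] or symmetric numeric matrix.
#' @param density Proportion of pairs to keep, in (0, 1].
#' @return Binary symmetric integer matrix with zero diagonal.
#' @export
thresholdBinarize <- function(w, density) {
  if (is(w, "Connectome")) {
    if (isDirected(w)) stop("thresholdBinarize needs a symmetric connectome")
    w <- connMatrix(w)
  }
  if (!is.matrix(w) || nrow(w) != ncol(w)) stop("w must be a square matrix")
  if (any(w != t(w))) stop("w must be symmetric")
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1)
    stop("density must lie in (0, 1]")
  pw <- .pairWeights(w)
  E <- length(pw$w)
  k <- ceiling(density * E)
  labs <- rownames(w)
  ord <- if (is.null(labs)) {
    .orderDecreasingStable(pw$w)
  } else {
    # label-keyed tie-break: invariant to region reordering of the inputs
    lo <- pmin(labs[pw$pairs[, 1L]], labs[pw$pairs[, 2L]])
    hi <- pmax(labs[pw$pairs[, 1L]], labs[pw$pairs[, 2L]])
    order(-pw$w, lo, hi, method = "radix")
  }
  if (k < E && pw$w[ord[k]] == pw$w[ord[k + 1L]])
    warning(sprintf(
      "tied weights straddle the density cut at %g; kept by stable pair order",
      density))
  B <- matrix(0L, nrow(w), ncol(w), dimnames = dimnames(w))
  keep <- pw$pairs[ord[seq_len(k)], , drop = FALSE]
  B[cbind(keep[, 1L], keep[, 2L])] <- 1L
  B[cbind(keep[, 2L], keep[, 1L])] <- 1L
  attr(B, "realizedDensity") <- k / E
  B
}

#' Confusion counts between binary symmetric networks
#'
#' Counts true/false positives/negatives over off-diagonal unordered pairs
#' of a predicted binary network against a ground-truth binary network.
#'
#' @param gt,pred Binary symmetric matrices of equal dimension (0/1 entries,
#'   zero diagonal).
#' @return Named integer vector `c(TP, FP, TN, FN)`;
#'   `TP + FP + TN + FN = n(n-1)/2`.
#' @export
confusionCounts <- function(gt, pred) {
  for (nm in c("gt", "pred")) {
    M <- get(nm)
    if (!is.matrix(M) || nrow(M) != ncol(M)) stop(nm, " must be square")
    if (any(M != t(M))) stop(nm, " must be symmetric")
    if (!all(M %in% c(0, 1))) stop(nm, " must be binary (0/1)")
  }
  if (!all(dim(gt) == dim(pred))) stop("gt and pred differ in dimension")
  up <- upper.tri(gt)
  g <- gt[up] == 1
  p <- pred[up] == 1
  c(TP = sum(g & p), FP = sum(!g & p), TN = sum(!g & !p), FN = sum(g & !p))
}

.measures <- function(cc) {
  sens <- if (cc[["TP"]] + cc[["FN"]] > 0)
    cc[["TP"]] / (cc[["TP"]] + cc[["FN"]]) else NA_real_
  spec <- if (cc[["TN"]] + cc[["FP"]] > 0)
    cc[["TN"]] / (cc[["TN"]] + cc[["FP"]]) else NA_real_
  prec <- if (cc[["TP"]] + cc[["FP"]] > 0)
    cc[["TP"]] / (cc[["TP"]] + cc[["FP"]]) else NA_real_
  c(sensitivity = sens, specificity = spec, precision = prec)
}

#' Detection performance of tractography against thresholded tracing truth
#'
#' For each ground-truth density `p`, the tract-tracing weight matrix is
#' thresholded and binarized keeping the proportion `p` of its strongest
#' pairs; detection of those "true" connections by tractography is then
#' scored two ways:
#' \describe{
#'   \item{matched}{the prediction is binarized at the *same* density `p`,
#'     giving one confusion tuple per density;}
#'   \item{sweep}{the prediction is thresholded at every distinct predicted
#'     weight (predicted positive = weight >= threshold), producing the full
#'     ROC / precision-recall point series, whose sensitivity, specificity
#'     and precision are then averaged per density.}
#' }
#' Both modes are reported; neither is privileged, as they answer slightly
#' different questions (operating-point match vs threshold-free detection).
#'
#' @param gt A symmetric tract-tracing [Connectome-class] or matrix
#'   (weights, e.g. symmetrized FLN).
#' @param pred A symmetric tractography [Connectome-class] or matrix
#'   (weights, e.g. FS or streamline counts); must not be all zero.
#' @param densities Ground-truth densities to evaluate; default
#'   `seq(0.1, 0.9, by = 0.1)`.
#' @return A [DetectionResult-class].
#' @export
detectionSweep <- function(gt, pred, densities = seq(0.1, 0.9, by = 0.1)) {
  toMat <- function(w, nm) {
    if (is(w, "Connectome")) {
      if (isDirected(w)) stop(nm, " must be symmetric")
      w <- connMatrix(w)
    }
    w
  }
  gtW <- toMat(gt, "gt")
  predW <- toMat(pred, "pred")
  if (!all(dim(gtW) == dim(predW)))
    stop("gt and pred differ in dimension")
  if (any(densities <= 0 | densities > 1))
    stop("densities must lie in (0, 1]")
  pw <- .pairWeights(predW)
  if (all(pw$w == 0))
    stop("prediction matrix is all zero; detection is undefined")
  thresholds <- sort(unique(pw$w), decreasing = TRUE)
  sumRows <- list()
  ptRows <- list()
  for (p in densities) {
    gtBin <- suppressWarnings(thresholdBinarize(gtW, p))
    # matched-density operating point
    predBin <- suppressWarnings(thresholdBinarize(predW, p))
    cc <- confusionCounts(gtBin, predBin)
    ms <- .measures(cc)
    sumRows[[length(sumRows) + 1L]] <- data.frame(
      density = p, densityRealized = attr(gtBin, "realizedDensity"),
      mode = "matched", t(ms))
    ptRows[[length(ptRows) + 1L]] <- data.frame(
      density = p, mode = "matched", threshold = NA_real_,
      t(cc), t(ms))
    # threshold sweep over every distinct predicted weight
    sweep <- vapply(thresholds, function(th) {
      predPos <- (predW >= th) * 1
      diag(predPos) <- 0
      cc <- confusionCounts(gtBin, predPos)
      c(cc, .measures(cc))
    }, numeric(7L))
    swDf <- data.frame(density = p, mode = "sweep",
                       threshold = thresholds, t(sweep))
    ptRows[[length(ptRows) + 1L]] <- swDf
    sumRows[[length(sumRows) + 1L]] <- data.frame(
      density = p, densityRealized = attr(gtBin, "realizedDensity"),
      mode = "sweep",
      sensitivity = mean(swDf$sensitivity, na.rm = TRUE),
      specificity = mean(swDf$specificity, na.rm = TRUE),
      precision = mean(swDf$precision, na.rm = TRUE))
  }
  summary <- do.call(rbind, sumRows)
  points <- do.call(rbind, ptRows)
  rownames(summary) <- rownames(points) <- NULL
  new("DetectionResult", densities = as.numeric(densities),
      summary = summary, points = points)
}
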