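#' @include AllClasses.R
NULL

#' Build an aligned edge table from paired connectomes
#'
#' Flattens a pair of connectomes over the same [RegionSet-class] into an
#' aligned per-edge table: tracing weight `x`, tractography weight `y` and
#' (optionally) Euclidean centroid distance per edge. Absent connections
#' (zero weights) are retained — they enter rank analyses as tied minimal
#' ranks, mirroring connections that tractography failed to find.
#'
#' In `"symmetric"` mode each unordered pair appears once (`n(n-1)/2` edges;
#' both matrices must be symmetric, i.e. the tracing matrix already
#' symmetrized). In `"directed"` mode all ordered pairs appear
#' (`n(n-1)` edges); the directed tracing weight `x[i,j]` is paired with the
#' tractography weight of the unordered pair, since tractography carries no
#' direction information.
#'
#' @param tracing Tract-tracing [Connectome-class] (FLN, log-FLN, or counts).
#' @param tract Tractography [Connectome-class] (FS, log-FS, or counts);
#'   must be symmetric.
#' @param distances Optional symmetric distance matrix from
#'   [euclideanDistances()].
#' @param mode `"symmetric"` or `"directed"`.
#' @return A `data.frame` with columns `from`, `to`, `x`, `y`, `dist`
#'   (`NA` when no distances given). Rows are sorted by the `(from, to)`
#'   labels, so the table — and every downstream statistic, including
#'   seeded bootstraps and stable tie-breaks — is invariant to the region
#'   order of the input files.
#' @export
buildEdgeTable <- function(tracing, tract, distances = NULL,
                           mode = c("symmetric", "directed")) {
  mode <- match.arg(mode)
  stopifnot(is(tracing, "Connectome"), is(tract, "Connectome"))
  if (!identical(regionLabels(regions(tracing)),
                 regionLabels(regions(tract))))
    stop("tracing and tractography connectomes use different region sets")
  if (isDirected(tract))
    stop("tractography connectome must be symmetric")
  if (mode == "symmetric" && isDirected(tracing))
    stop("symmetric mode requires a symmetrized tracing connectome")
  n <- nRegions(tracing)
  labs <- regionLabels(regions(tracing))
  X <- connMatrix(tracing)
  Y <- connMatrix(tract)
  if (!is.null(distances)) {
    if (!all(dim(distances) == c(n, n)))
      stop("distance matrix dimension does not match the region set")
  }
  if (mode == "symmetric") {
    pr <- t(utils::combn(n, 2L))           # lexicographic (i < j)
  } else {
    pr <- as.matrix(expand.grid(to = seq_len(n), from = seq_len(n)))[, 2:1]
    pr <- pr[pr[, 1L] != pr[, 2L], , drop = FALSE]  # row-major ordered pairs
  }
  idx <- cbind(pr[, 1L], pr[, 2L])
  fromLab <- labs[pr[, 1L]]
  toLab <- labs[pr[, 2L]]
  if (mode == "symmetric") {
    # canonical unordered-pair labels: from < to lexicographically
    lo <- pmin(fromLab, toLab)
    hi <- pmax(fromLab, toLab)
    fromLab <- lo
    toLab <- hi
  }
  out <- data.frame(
    from = fromLab,
    to = toLab,
    x = X[idx],
    y = Y[idx],
    dist = if (is.null(distances)) NA_real_ else distances[idx],
    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# OLS residuals of v on d (intercept + slope). Constant d is the trivial
# case: plain centering, computed directly so exact ties in v survive
# (QR residuals would split them by last-bit rounding).
.olsResiduals <- function(v, d) {
  if (length(unique(d)) < 2L) return(v - mean(v))
  stats::lm.fit(cbind(1, d), v)$residuals
}

# All n! permutations of 1..n (rows). Guarded by callers.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

.checkEdgeTable <- function(table, minEdges = 3L) {
  stopifnot(is.data.frame(table), all(c("x", "y") %in% names(table)))
  if (nrow(table) < minEdges)
    stop("at least ", minEdges, " edges are required")
  if (.isConstant(table$x))
    stop("tracing weights are constant; correlation is undefined")
  if (.isConstant(table$y))
    stop("tractography weights are constant; correlation is undefined")
  invisible(table)
}

#' Spearman rank correlation between tracing and tractography weights
#'
#' Midrank (average-rank) Spearman's rho between the paired edge weights,
#' with a two-sided p-value from the large-sample t approximation
#' (df = n - 2). Ties — including blocks of absent (zero) connections —
#' receive midranks. Optionally an exact permutation p-value is computed by
#' full enumeration, practical for very small tables only.
#'
#' @param table An edge table from [buildEdgeTable()] (needs >= 3 edges,
#'   neither weight vector constant).
#' @param exact Logical; exact two-sided permutation p-value (enumeration of
#'   all `n!` pairings, supported for up to 8 edges).
#' @return An [AssociationResult-class].
#' @export
edgeSpearman <- function(table, exact = FALSE) {
  .checkEdgeTable(table)
  n <- nrow(table)
  rx <- rank(table$x)
  ry <- rank(table$y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 8L)
      stop("exact permutation p-value supported for at most 8 edges")
    perms <- .permutations(n)
    rhos <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    p <- .corPvalT(rho, n)
  }
  .AssociationResult("spearman", rho, p, n)
}

#' Pearson correlation on log-transformed weights
#'
#' Product-moment correlation intended for edge tables built from
#' [pseudocountLog()] connectomes (the pseudocount guarantees finite log
#' values for absent connections). Two-sided p-value from the t
#' distribution with df = n - 2.
#'
#' @param table An edge table of log weights from [buildEdgeTable()].
#' @return An [AssociationResult-class].
#' @export
edgePearsonLog <- function(table) {
  .checkEdgeTable(table)
  n <- nrow(table)
  r <- stats::cor(table$x, table$y)
  .AssociationResult("pearson_log", r, .corPvalT(r, n), n)
}

#' Partial Spearman correlation regressing out centroid distance
#'
#' Connection strength decays with distance in both tract tracing and
#' tractography, so a raw correlation partly reflects shared geometry. This
#' removes the linear dependence of each (log) weight vector on the
#' Euclidean distance between region centroids by ordinary least squares
#' (intercept + slope), then correlates the two residual vectors with
#' midrank Spearman. Intended for pseudocount-logged weights so residuals
#' are defined for absent connections.
#'
#' When distances are constant the regression only centers the values, and
#' the coefficient equals the plain Spearman correlation. The p-value uses
#' the t approximation with df = n - 3 (one regressor removed).
#'
#' @param table Edge table with a `dist` column and >= 4 edges.
#' @return An [AssociationResult-class] with method `"partial_spearman"`.
#' @export
partialSpearmanDistance <- function(table) {
  .checkEdgeTable(table, minEdges = 4L)
  d <- table$dist
  if (is.null(d) || anyNA(d))
    stop("edge table has no complete distance column")
  resx <- .olsResiduals(table$x, d)
  resy <- .olsResiduals(table$y, d)
  if (.isConstant(resx) || .isConstant(resy))
    stop("residual vector is constant; partial correlation is undefined")
  rho <- stats::cor(rank(resx), rank(resy))
  n <- nrow(table)
  .AssociationResult("partial_spearman", rho,
                     .corPvalT(rho, n, df = n - 3L), n)
}

#' Percentile bootstrap confidence interval for an association
#'
#' Resamples edges — paired `(x, y, dist)` records — with replacement `B`
#' times, recomputes the chosen association on each resample, and reports
#' the percentile interval at the requested confidence level. Resamples on
#' which the coefficient is undefined (a constant vector after resampling)
#' are redrawn and their count reported via a message. Deterministic under a
#' fixed seed; the caller's RNG state is left untouched.
#'
#' @param table Edge table from [buildEdgeTable()].
#' @param method `"spearman"`, `"pearson_log"` or `"partial_spearman"`.
#' @param B Number of bootstrap resamples (>= 100; default 10000).
#' @param level Confidence level in (0, 1); default 0.95.
#' @param seed Integer seed (recommended for reproducibility).
#' @return An [AssociationResult-class] carrying the full-sample coefficient
#'   and p-value plus the bootstrap interval.
#' @export
bootstrapCI <- function(table, method = c("spearman", "pearson_log",
                                          "partial_spearman"),
                        B = 10000L, level = 0.95, seed = NULL) {
  method <- match.arg(method)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("confidence level must lie strictly between 0 and 1")
  if (B < 100L) stop("B must be at least 100")
  full <- switch(method,
                 spearman = edgeSpearman(table),
                 pearson_log = edgePearsonLog(table),
                 partial_spearman = partialSpearmanDistance(table))
  # work on bare vectors: resampling B times must not pay
  # data.frame-subsetting costs
  xv <- table$x
  yv <- table$y
  dv <- table$dist
  statFun <- switch(method,
    spearman = function(idx) {
      x <- xv[idx]; y <- yv[idx]
      if (.isConstant(x) || .isConstant(y)) return(NA_real_)
      stats::cor(rank(x), rank(y))
    },
    pearson_log = function(idx) {
      x <- xv[idx]; y <- yv[idx]
      if (.isConstant(x) || .isConstant(y)) return(NA_real_)
      stats::cor(x, y)
    },
    partial_spearman = function(idx) {
      d <- dv[idx]
      rx <- .olsResiduals(xv[idx], d)
      ry <- .olsResiduals(yv[idx], d)
      if (.isConstant(rx) || .isConstant(ry)) return(NA_real_)
      stats::cor(rank(rx), rank(ry))
    })
  n <- nrow(table)
  stats <- .withSeed(seed, {
    out <- numeric(B)
    redraws <- 0L
    for (b in seq_len(B)) {
      repeat {
        v <- statFun(sample.int(n, n, replace = TRUE))
        if (!is.na(v)) break
        redraws <- redraws + 1L
        if (redraws > 100L * B)
          stop("bootstrap failed: too many degenerate resamples")
      }
      out[b] <- v
    }
    if (redraws > 0L)
      message(redraws, " degenerate bootstrap resample(s) redrawn")
    out
  })
  alpha <- (1 - level) / 2
  ci <- unname(stats::quantile(stats, c(alpha, 1 - alpha)))
  # widen, if ever needed, so the interval brackets the full-sample
  # estimate (a hard invariant of AssociationResult)
  .AssociationResult(method, full@coefficient, full@pValue, n,
                     ciLow = min(ci[1L], full@coefficient),
                     ciHigh = max(ci[2L], full@coefficient),
                     ciLevel = level)
}
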