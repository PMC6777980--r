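#' @include AllClasses.R
NULL

#' Configuration for the synthetic paired-experiment generator
#'
#' Builds a validated configuration for [generateGroundTruth()],
#' [sampleTracer()] and [sampleTractography()]. Defaults are read from the
#' package file `inst/extdata/synthetic-defaults.yaml` (one place, never
#' hard-coded) and can be overridden individually.
#'
#' The generator emulates the statistical structure assumed of inter-areal
#' cortical connectivity: lognormal connection weights, exponential decay of
#' weight with inter-centroid distance, multinomial retrograde-tracer
#' sampling per injection site, and streamline sampling with
#' distance-dependent dropout plus a false-positive floor.
#'
#' @param ... Named overrides of the defaults. Fields:
#' \describe{
#'   \item{nRegions}{number of regions (>= 3)}
#'   \item{edgeDensity}{probability an ordered pair is connected, in (0, 1]}
#'   \item{reciprocity}{probability the two directions of a pair share one
#'     existence draw, in `[0, 1]` (1 = fully reciprocal topology)}
#'   \item{mu, sigma}{log-mean and log-sd of the lognormal weight factor}
#'   \item{lambda}{distance-decay rate of true weights (per mm), >= 0}
#'   \item{boxSize}{edge of the cube (mm) centroids are sampled in}
#'   \item{neuronsPerInjection}{tracer neurons counted per injection (M)}
#'   \item{totalStreamlines}{total streamline budget (T)}
#'   \item{gamma}{tractography distance-dropout rate (per mm), >= 0}
#'   \item{epsilon}{false-positive floor relative to the mean true weight,
#'     >= 0}
#'   \item{allocation}{streamline budget allocation: `"multinomial"` (fixed
#'     total) or `"poisson"` (independent counts, expected total T)}
#'   \item{seed}{integer seed; all stage seeds are fanned out from it}
#' }
#' @param file Alternative YAML defaults file.
#' @return A named list of class `"SyntheticConfig"`.
#' @examples
#' cfg <- syntheticConfig(nRegions = 6, seed = 1)
#' cfg$edgeDensity
#' @export
syntheticConfig <- function(..., file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "synthetic-defaults.yaml",
                        package = "conntracer", mustWork = TRUE)
  cfg <- yaml::read_yaml(file)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad))
      stop("unknown SyntheticConfig field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  with(cfg, {
    stopifnot(nRegions >= 3, edgeDensity > 0, edgeDensity <= 1,
              reciprocity >= 0, reciprocity <= 1, sigma >= 0, lambda >= 0,
              boxSize > 0, neuronsPerInjection >= 1, totalStreamlines >= 1,
              gamma >= 0, epsilon >= 0,
              allocation %in% c("multinomial", "poisson"))
  })
  cfg$nRegions <- as.integer(cfg$nRegions)
  cfg$neuronsPerInjection <- as.integer(round(cfg$neuronsPerInjection))
  cfg$totalStreamlines <- as.integer(round(cfg$totalStreamlines))
  structure(cfg, class = c("SyntheticConfig", "list"))
}

#' Generate a ground-truth weighted network
#'
#' Samples region centroids uniformly in a cube of edge `boxSize` mm and a
#' directed true-weight matrix: each ordered pair is connected with
#' probability `edgeDensity` (with probability `reciprocity` the two
#' directions of a pair share a single existence draw, coupling them), and
#' each present connection has weight
#' \deqn{w_{ij} = \exp(\mathcal{N}(\mu, \sigma^2)) \cdot \exp(-\lambda d_{ij}),}
#' i.e. lognormal strength attenuated exponentially with centroid distance.
#' Deterministic under the config seed.
#'
#' @param cfg A [syntheticConfig()] object.
#' @param seed Optional override of the fanned-out stage seed.
#' @return List with elements `regions` ([RegionSet-class]) and `truth`
#'   (directed [Connectome-class] of kind `"weight"`).
#' @export
generateGroundTruth <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  if (is.null(seed)) seed <- .fanSeed(cfg$seed, "truth")
  n <- cfg$nRegions
  .withSeed(seed, {
    labs <- sprintf("R%02d", seq_len(n))
    ctr <- matrix(stats::runif(3L * n, 0, cfg$boxSize), ncol = 3L)
    rs <- RegionSet(labs, ctr)
    D <- euclideanDistances(rs)
    # pair-level coupling of the two directions' existence draws
    A <- matrix(FALSE, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (stats::runif(1L) < cfg$reciprocity) {
          e <- stats::runif(1L) < cfg$edgeDensity
          A[i, j] <- A[j, i] <- e
        } else {
          A[i, j] <- stats::runif(1L) < cfg$edgeDensity
          A[j, i] <- stats::runif(1L) < cfg$edgeDensity
        }
      }
    }
    W <- matrix(0, n, n)
    present <- which(A)
    W[present] <- exp(stats::rnorm(length(present), cfg$mu, cfg$sigma)) *
      exp(-cfg$lambda * D[present])
    diag(W) <- 0
    list(regions = rs,
         truth = Connectome(W, rs, kind = "weight", directed = TRUE))
  })
}

#' Simulate retrograde tracer counts from a ground-truth network
#'
#' For each injected (target) region `j`, `M` labeled neurons are allocated
#' multinomially over source regions with probabilities proportional to the
#' true incoming weights `w[, j]`: every column of the returned count matrix
#' sums exactly to `M`, emulating counting a fixed number of retrogradely
#' labeled cell bodies per injection. Zero-weight pairs get zero counts.
#'
#' @param truth Directed ground-truth [Connectome-class] from
#'   [generateGroundTruth()].
#' @param M Labeled neurons counted per injection (positive integer).
#' @param seed Integer seed.
#' @return Directed [Connectome-class] of kind `"count"`.
#' @export
sampleTracer <- function(truth, M, seed = NULL) {
  stopifnot(is(truth, "Connectome"), M >= 1)
  W <- connMatrix(truth)
  zero <- which(colSums(W) == 0)
  if (length(zero))
    stop("injection site(s) with no incoming connections: ",
         paste(regionLabels(regions(truth))[zero], collapse = ", "))
  .withSeed(seed, {
    counts <- vapply(seq_len(ncol(W)), function(j) {
      as.numeric(stats::rmultinom(1L, size = M, prob = W[, j]))
    }, numeric(nrow(W)))
    Connectome(counts, regions(truth), kind = "count", directed = TRUE)
  })
}

#' Simulate streamline counts from a ground-truth network
#'
#' Tractography neither sees direction nor counts axons: the two directions
#' of the truth are averaged, streamline intensity per unordered pair decays
#' exponentially with centroid distance at rate `gamma` (path-following
#' failure accumulates with length), and a false-positive floor `epsilon`
#' (relative to the mean true weight, so unit-free) gives every pair —
#' connected or not — a small chance of spurious streamlines:
#' \deqn{q_{ij} \propto \bar w_{ij} e^{-\gamma d_{ij}} + \epsilon \,
#'   \mathrm{mean}(\bar w).}
#' The streamline budget `T` is then allocated multinomially over unordered
#' pairs (total exactly `T`), or as independent Poisson counts with the same
#' means when `allocation = "poisson"`.
#'
#' @param truth Directed ground-truth [Connectome-class] (regions must carry
#'   centroids).
#' @param cfg A [syntheticConfig()] supplying `gamma`, `epsilon`,
#'   `totalStreamlines` and `allocation`.
#' @param seed Integer seed.
#' @return Symmetric [Connectome-class] of kind `"count"`.
#' @export
sampleTractography <- function(truth, cfg, seed = NULL) {
  stopifnot(is(truth, "Connectome"), inherits(cfg, "SyntheticConfig"))
  if (is.null(seed)) seed <- .fanSeed(cfg$seed, "tractography")
  W <- connMatrix(truth)
  wbar <- (W + t(W)) / 2
  D <- euclideanDistances(regions(truth))
  n <- nrow(W)
  pr <- t(utils::combn(n, 2L))
  idx <- cbind(pr[, 1L], pr[, 2L])
  q <- wbar[idx] * exp(-cfg$gamma * D[idx]) +
    cfg$epsilon * mean(wbar[row(wbar) != col(wbar)])
  if (all(q == 0))
    stop("all streamline intensities are zero; nothing to sample")
  .withSeed(seed, {
    cnt <- if (cfg$allocation == "multinomial") {
      as.numeric(stats::rmultinom(1L, size = cfg$totalStreamlines, prob = q))
    } else {
      stats::rpois(length(q), cfg$totalStreamlines * q / sum(q))
    }
    S <- matrix(0, n, n, dimnames = dimnames(W))
    S[idx] <- cnt
    S[idx[, 2:1, drop = FALSE]] <- cnt
    Connectome(S, regions(truth), kind = "count", directed = FALSE)
  })
}
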