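#' @include AllClasses.R
NULL

#' Fraction of labeled neurons (FLN) normalization
#'
#' Converts a directed matrix of retrograde labeled-neuron counts into FLN
#' values: the count of labeled neurons in a source region divided by the
#' total labeled neurons for that injection (column), excluding
#' self-connections. Every injected column with a nonzero total sums to 1.
#'
#' @param counts A directed [Connectome-class] of kind `"count"` whose
#'   columns are injection (target) sites.
#' @return A [Connectome-class] of kind `"fln"`, same directedness.
#' @examples
#' rs <- RegionSet(c("a", "b", "c"))
#' cc <- Connectome(rbind(c(0, 20, 5), c(10, 0, 5), c(30, 30, 0)),
#'                  rs, kind = "count", directed = TRUE)
#' colSums(connMatrix(computeFLN(cc)))
#' @export
computeFLN <- function(counts) {
  stopifnot(is(counts, "Connectome"))
  if (connKind(counts) != "count")
    stop("computeFLN expects kind 'count', got '", connKind(counts), "'")
  N <- connMatrix(counts)
  tot <- colSums(N)
  zero <- which(tot == 0)
  if (length(zero))
    stop("injection(s) with no labeled neurons: ",
         paste(regionLabels(regions(counts))[zero], collapse = ", "))
  FLN <- sweep(N, 2L, tot, "/")
  Connectome(FLN, regions(counts), kind = "fln",
             directed = isDirected(counts))
}

#' Fractional scaling (FS) normalization of streamline counts
#'
#' Normalizes a symmetric streamline-count matrix so each weight is the
#' streamline count of a region pair divided by the sum of the streamline
#' counts attached to both regions, excluding self-connections:
#' \deqn{FS_{ij} = S_{ij} / (\sum_{k \ne i} S_{ik} + \sum_{k \ne j} S_{jk}).}
#' With this denominator the pair's own count enters both totals, so it is
#' counted twice; set `subtractShared = TRUE` for the variant that removes
#' one copy of \eqn{S_{ij}} from the denominator (used by some fractional
#' scaling implementations). FS is symmetric and invariant under rescaling
#' of the raw counts.
#'
#' @param counts A symmetric [Connectome-class] of kind `"count"`.
#' @param subtractShared Logical; subtract the shared count once from the
#'   denominator (default `FALSE`).
#' @return A symmetric [Connectome-class] of kind `"fs"`. An isolated pair
#'   (zero denominator) yields 0 with a warning.
#' @export
fractionalScaling <- function(counts, subtractShared = FALSE) {
  stopifnot(is(counts, "Connectome"))
  if (connKind(counts) != "count")
    stop("fractionalScaling expects kind 'count', got '",
         connKind(counts), "'")
  if (isDirected(counts))
    stop("fractionalScaling expects a symmetric streamline matrix; ",
         "symmetrize() it first")
  S <- connMatrix(counts)
  tot <- rowSums(S)                      # diagonal is zero already
  den <- outer(tot, tot, "+")
  if (subtractShared) den <- den - S
  FS <- matrix(0, nrow(S), ncol(S), dimnames = dimnames(S))
  pos <- den > 0
  FS[pos] <- S[pos] / den[pos]
  if (any(!pos & row(S) != col(S) & S == 0))
    warning("isolated region pair(s): FS set to 0 where both totals are 0")
  diag(FS) <- 0
  FS <- (FS + t(FS)) / 2                 # exact symmetry against fp noise
  Connectome(FS, regions(counts), kind = "fs", directed = FALSE)
}

#' @describeIn symmetrize Average reciprocal weights of a directed
#'   connectome: `out[i,j] = (w[i,j] + w[j,i]) / 2`.
#' @export
setMethod("symmetrize", "Connectome", function(x, ...) {
  W <- (connMatrix(x) + t(connMatrix(x))) / 2
  Connectome(W, regions(x), kind = connKind(x), directed = FALSE)
})

#' @describeIn symmetrize Plain matrix method.
#' @export
setMethod("symmetrize", "matrix", function(x, ...) (x + t(x)) / 2)

#' Pseudocount, normalize, then log-transform
#'
#' For log-scale (Pearson) analyses absent connections would map to
#' \eqn{-\infty}; to cope, every off-diagonal raw count is incremented by 1
#' *before* normalization, the chosen normalization (FLN or FS) is applied,
#' and the natural logarithm is taken. All outputs are finite.
#'
#' @param counts A [Connectome-class] of kind `"count"`. FLN requires a
#'   directed matrix (injection semantics); FS requires a symmetric one.
#' @param normalizer `"fln"` or `"fs"`.
#' @param symmetrizeAfter Logical; average the normalized values in both
#'   directions before taking logs (only meaningful for FLN).
#' @param subtractShared Passed to [fractionalScaling()] when
#'   `normalizer = "fs"`.
#' @return A [Connectome-class] of kind `"log"` (entries may be negative;
#'   the diagonal is kept at 0 and is never analyzed).
#' @export
pseudocountLog <- function(counts, normalizer = c("fln", "fs"),
                           symmetrizeAfter = FALSE, subtractShared = FALSE) {
  stopifnot(is(counts, "Connectome"))
  normalizer <- match.arg(normalizer)
  if (connKind(counts) != "count")
    stop("pseudocountLog expects kind 'count', got '", connKind(counts), "'")
  if (normalizer == "fln" && !isDirected(counts))
    stop("FLN normalization needs a directed count matrix ",
         "(injection-site columns); direction information is lost here")
  N <- connMatrix(counts)
  N1 <- N + 1
  diag(N1) <- 0
  inc <- Connectome(N1, regions(counts), kind = "count",
                    directed = isDirected(counts))
  norm <- switch(normalizer,
                 fln = computeFLN(inc),
                 fs = fractionalScaling(inc, subtractShared = subtractShared))
  if (symmetrizeAfter) norm <- symmetrize(norm)
  V <- connMatrix(norm)
  L <- matrix(0, nrow(V), ncol(V), dimnames = dimnames(V))
  off <- row(V) != col(V)
  L[off] <- log(V[off])
  if (any(!is.finite(L)))
    stop("internal error: pseudocount log produced non-finite values")
  Connectome(L, regions(counts), kind = "log",
             directed = isDirected(norm))
}
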