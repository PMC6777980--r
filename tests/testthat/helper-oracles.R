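# Independent brute-force oracles and fixture builders. These deliberately
# avoid the code paths they check: ranks by pairwise counting, correlations
# by the textbook covariance formulas, OLS by the normal equations.

# Midranks by counting: rank of v[i] = #(v < v[i]) + (#(v == v[i]) + 1)/2.
oracleRanks <- function(v) {
  vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
}

# Pearson r from raw sums (textbook covariance formula).
oraclePearson <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  sxy / sqrt(sxx * syy)
}

# Spearman rho = Pearson on counted midranks.
oracleSpearman <- function(x, y) {
  oraclePearson(oracleRanks(x), oracleRanks(y))
}

# OLS residuals of v on d (intercept + slope) via the 2x2 normal equations.
oracleResiduals <- function(v, d) {
  n <- length(v)
  XtX <- rbind(c(n, sum(d)), c(sum(d), sum(d^2)))
  Xty <- c(sum(v), sum(d * v))
  beta <- solve(XtX, Xty)
  v - (beta[1] + beta[2] * d)
}

# Brute-force sweep averages: threshold the prediction at every distinct
# pair weight and average the three measures against a fixed binary truth.
oracleSweepAverages <- function(gtBin, predW) {
  up <- upper.tri(predW)
  g <- gtBin[up] == 1
  w <- predW[up]
  ms <- vapply(sort(unique(w), decreasing = TRUE), function(th) {
    p <- w >= th
    tp <- sum(g & p); fp <- sum(!g & p)
    tn <- sum(!g & !p); fn <- sum(g & !p)
    c(if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  }, numeric(3))
  c(sensitivity = mean(ms[1, ], na.rm = TRUE),
    specificity = mean(ms[2, ], na.rm = TRUE),
    precision = mean(ms[3, ], na.rm = TRUE))
}

# --- fixture builders -------------------------------------------------------

randRegionSet <- function(n, seed = NULL, centroids = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  labs <- sprintf("A%02d", seq_len(n))
  if (centroids)
    RegionSet(labs, matrix(runif(3 * n, 0, 20), ncol = 3))
  else
    RegionSet(labs)
}

randCountConnectome <- function(rs, directed = TRUE, seed = NULL,
                                maxCount = 50, zeroFrac = 0.25) {
  if (!is.null(seed)) set.seed(seed)
  n <- nRegions(rs)
  M <- matrix(rpois(n * n, maxCount / 2), n, n)
  M[runif(n * n) < zeroFrac] <- 0
  diag(M) <- 0
  if (!directed) M <- pmax(M, t(M))
  M <- M + diag(0, n)
  # guard degenerate all-zero columns for FLN paths
  for (j in seq_len(n)) if (sum(M[, j]) == 0) M[(j %% n) + 1L, j] <- 1
  if (!directed) { M <- pmax(M, t(M)); diag(M) <- 0 }
  Connectome(M, rs, kind = "count", directed = directed)
}

# A random aligned edge table (no connectome needed).
randEdgeTable <- function(n = 28, seed = NULL, tieFrac = 0.2,
                          withDist = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  x <- rlnorm(n, 0, 1.5)
  y <- x * rlnorm(n, 0, 1)
  x[runif(n) < tieFrac] <- 0   # tied absent connections, as in real tables
  y[runif(n) < tieFrac] <- 0
  data.frame(from = paste0("e", seq_len(n)), to = paste0("f", seq_len(n)),
             x = x, y = y,
             dist = if (withDist) runif(n, 1, 30) else NA_real_,
             stringsAsFactors = FALSE)
}
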