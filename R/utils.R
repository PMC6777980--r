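# Internal helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched (draws advance it).
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one top-level seed to named sub-stages;
# keeps derived seeds within 32-bit integer range.
.fanSeed <- function(seed, stage) {
  offsets <- c(truth = 11L, tracer = 23L, tractography = 37L,
               bootstrap = 53L, analysis = 71L)
  if (!stage %in% names(offsets))
    stop("unknown seed stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

# Indices of unordered off-diagonal pairs (i < j), in stable
# row-major order of the upper triangle.
.upperPairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

# Midrank (average-rank) Spearman coefficient.
.spearmanRho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Two-sided p-value for a correlation via the t approximation.
# df defaults to n - 2 (plain correlation); partial correlations pass
# n - 2 - #controls. Exact-1 correlations give the smallest positive double.
.corPvalT <- function(r, n, df = n - 2) {
  if (df < 1) return(NA_real_)
  if (abs(r) >= 1) return(.Machine$double.xmin)
  tstat <- r * sqrt(df / (1 - r^2))
  min(1, 2 * stats::pt(-abs(tstat), df = df))
}

.isConstant <- function(v) {
  length(unique(v)) < 2L
}

# Stable decreasing order: ties broken by original position.
.orderDecreasingStable <- function(x) {
  order(-x, seq_along(x), method = "radix")
}

# Stable increasing order.
.orderIncreasingStable <- function(x) {
  order(x, seq_along(x), method = "radix")
}
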