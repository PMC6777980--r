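#' @include association.R
NULL

#' Association after progressive removal of strongest/weakest connections
#'
#' Probes whether an association between tracing and tractography weights is
#' driven by the strongest connections (short-range, easiest to track) or
#' degraded by the weakest ones (most prone to false positives). Edges are
#' ranked by the tract-tracing weight `x` only; for each removal fraction
#' `f`, the `ceiling(f * E)` top (direction `"strongest"`) or bottom
#' (`"weakest"`) edges are dropped from both sources — each edge's `x` and
#' `y` leave together — and the chosen association is recomputed on the
#' remaining edges. `f = 0` reproduces the full-table coefficient exactly.
#'
#' Ties among equal tracing weights are broken by the stable edge order of
#' the table (row index, then column index).
#'
#' @param table Edge table from [buildEdgeTable()].
#' @param direction `"strongest"` or `"weakest"`: which end of the tracing
#'   weight ranking to remove.
#' @param fractions Increasing removal proportions in `[0, 1)`, starting
#'   at 0. Default `seq(0, 0.5, by = 0.05)`.
#' @param method Association recomputed on each reduced table:
#'   `"spearman"` or `"pearson_log"`.
#' @return A `data.frame` of class `"RemovalCurve"` with columns
#'   `direction`, `fraction`, `nRemaining`, `coefficient`, `p`.
#' @export
removalCurve <- function(table, direction = c("strongest", "weakest"),
                         fractions = seq(0, 0.5, by = 0.05),
                         method = c("spearman", "pearson_log")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  .checkEdgeTable(table)
  if (any(fractions < 0 | fractions >= 1))
    stop("removal fractions must lie in [0, 1)")
  if (is.unsorted(fractions, strictly = TRUE))
    stop("removal fractions must be strictly increasing")
  if (fractions[1L] != 0)
    stop("removal fractions must start at 0 (the full table)")
  E <- nrow(table)
  ord <- if (direction == "strongest") .orderDecreasingStable(table$x)
         else .orderIncreasingStable(table$x)
  nDrop <- ceiling(fractions * E)
  short <- fractions[E - nDrop < 3L]
  if (length(short))
    stop("fraction(s) leaving fewer than 3 edges: ",
         paste(short, collapse = ", "))
  assoc <- function(tb) switch(method,
                               spearman = edgeSpearman(tb),
                               pearson_log = edgePearsonLog(tb))
  rows <- lapply(seq_along(fractions), function(k) {
    keep <- if (nDrop[k] == 0L) seq_len(E) else ord[-seq_len(nDrop[k])]
    res <- assoc(table[sort(keep), , drop = FALSE])
    data.frame(direction = direction, fraction = fractions[k],
               nRemaining = E - nDrop[k],
               coefficient = res@coefficient, p = res@pValue)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("RemovalCurve", "data.frame")
  out
}
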