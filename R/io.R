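#' @include AllClasses.R
NULL

# Guess the field separator of a delimited text file: comma by default,
# tab accepted.
.guessSep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

#' Read a region table (labels and centroid coordinates)
#'
#' Reads a delimited text file with a header containing a `label` column and,
#' optionally, numeric `x`, `y`, `z` centroid columns in millimetres. The row
#' order of the file defines the canonical region order of the analysis.
#'
#' @param path Path to a CSV (or TSV) file.
#' @param sep Field separator; `NULL` (default) autodetects comma vs tab.
#' @return A [RegionSet-class]; centroids are `NULL` when the coordinate
#'   columns are absent.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("label,x,y,z", "17,0,0,0", "18,3,4,0"), f)
#' readRegionSet(f)
#' @export
readRegionSet <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("region file not found: ", path)
  if (is.null(sep)) sep <- .guessSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (!"label" %in% names(df))
    stop("region file must have a 'label' column: ", path)
  labels <- df$label
  if (anyDuplicated(labels))
    stop("duplicate region label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  coordCols <- c("x", "y", "z")
  if (all(coordCols %in% names(df))) {
    coords <- matrix(NA_real_, nrow(df), 3L,
                     dimnames = list(labels, coordCols))
    for (cc in coordCols) {
      raw <- df[[cc]]
      val <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(val) & !is.na(raw) & nzchar(raw) &
                     !toupper(raw) %in% "NA")
      if (length(bad))
        stop(sprintf("non-numeric coordinate '%s' in column %s at row %d",
                     raw[bad[1L]], cc, bad[1L]))
      coords[, cc] <- val
    }
    RegionSet(labels, coords)
  } else {
    RegionSet(labels)
  }
}

#' Write a region table
#'
#' Inverse of [readRegionSet()]: writes `label,x,y,z` (or labels only when
#' centroids are absent).
#'
#' @param regions A [RegionSet-class].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return Invisibly, `path`.
#' @export
writeRegionSet <- function(regions, path, sep = ",") {
  stopifnot(is(regions, "RegionSet"))
  ctr <- regionCentroids(regions)
  df <- if (is.null(ctr)) {
    data.frame(label = regionLabels(regions))
  } else {
    data.frame(label = regionLabels(regions),
               x = ctr[, 1L], y = ctr[, 2L], z = ctr[, 3L])
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read a labeled connectivity matrix
#'
#' Reads a square delimited matrix whose header row and first column carry
#' region labels (a superset or exact match of `regions`), reorders rows and
#' columns into the canonical [RegionSet-class] order, and subsets to it.
#' Subsetting an edge-complete measurement to the shared region set yields
#' the edge-complete subnetwork the analyses operate on. Rows are source
#' regions and columns are target (injected) regions.
#'
#' A nonzero diagonal is zeroed with a warning (self-connections are excluded
#' by both normalizations).
#'
#' @param path Path to a labeled square CSV/TSV matrix. Lines starting with
#'   `#` are ignored.
#' @param regions A [RegionSet-class] giving the canonical order.
#' @param kind Weight kind tag; see [Connectome-class].
#' @param directed Logical; `FALSE` asserts symmetry.
#' @param sep Field separator; `NULL` autodetects comma vs tab.
#' @return A [Connectome-class] in canonical region order.
#' @export
readConnectome <- function(path, regions, kind = "count", directed = TRUE,
                           sep = NULL) {
  stopifnot(is(regions, "RegionSet"))
  if (!file.exists(path)) stop("connectome file not found: ", path)
  if (is.null(sep)) sep <- .guessSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  M <- as.matrix(df)
  if (nrow(M) != ncol(M))
    stop(sprintf("matrix in %s is not square (%d rows, %d columns)",
                 path, nrow(M), ncol(M)))
  if (!is.numeric(M))
    stop("matrix in ", path, " contains non-numeric entries")
  if (!setequal(rownames(M), colnames(M)))
    stop("row and column labels differ in ", path)
  missing <- setdiff(regionLabels(regions), rownames(M))
  if (length(missing))
    stop("region label(s) missing from ", path, ": ",
         paste(missing, collapse = ", "))
  M <- M[regionLabels(regions), regionLabels(regions), drop = FALSE]
  if (any(M < 0, na.rm = TRUE))
    stop("negative weight(s) in ", path)
  if (any(diag(M) != 0)) {
    warning("nonzero diagonal in ", path,
            "; self-connections set to zero")
    diag(M) <- 0
  }
  Connectome(M, regions, kind = kind, directed = directed)
}

#' Write a labeled connectivity matrix
#'
#' Writes the matrix as labeled CSV with a header comment recording the
#' weight kind, directedness and orientation (rows = source, columns =
#' target), so files are self-describing and round-trip through
#' [readConnectome()].
#'
#' @param conn A [Connectome-class].
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return Invisibly, `path`.
#' @export
writeConnectome <- function(conn, path, sep = ",") {
  stopifnot(is(conn, "Connectome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# conntracer connectome; kind: %s; directed: %s; rows = source, columns = target",
    connKind(conn), isDirected(conn)), con)
  W <- connMatrix(conn)
  writeLines(paste(c("region", colnames(W)), collapse = sep), con)
  for (i in seq_len(nrow(W))) {
    writeLines(paste(c(rownames(W)[i], sprintf("%.17g", W[i, ])),
                     collapse = sep), con)
  }
  invisible(path)
}

#' Pairwise Euclidean distances between region centroids
#'
#' Computes the full symmetric matrix of Euclidean distances (mm) between
#' region centroids, the distance covariate of the distance-regressed
#' partial correlation.
#'
#' @param regions A [RegionSet-class] with centroids.
#' @return Symmetric `n x n` numeric matrix with zero diagonal, dimnames =
#'   region labels.
#' @export
euclideanDistances <- function(regions) {
  stopifnot(is(regions, "RegionSet"))
  ctr <- regionCentroids(regions)
  if (is.null(ctr))
    stop("RegionSet has no centroids; distances are undefined")
  bad <- which(apply(ctr, 1L, anyNA))
  if (length(bad))
    stop("missing centroid for region(s): ",
         paste(regionLabels(regions)[bad], collapse = ", "))
  D <- as.matrix(stats::dist(ctr, method = "euclidean"))
  dimnames(D) <- list(regionLabels(regions), regionLabels(regions))
  D
}
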