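#' @include association.R robustness.R detection.R synthetic.R
NULL

.analysisDefaults <- function() {
  list(modes = c("symmetric", "directed"), B = 10000L, level = 0.95,
       fractions = seq(0, 0.5, by = 0.05),
       densities = seq(0.1, 0.9, by = 0.1), seed = 1L)
}

# Core of the validation pipeline, shared by runValidation() (file inputs)
# and simulateAndValidate() (in-memory synthetic inputs).
.validateCore <- function(tracingCounts, tractCounts, distances, opts,
                          hashes = character(0)) {
  stopifnot(isDirected(tracingCounts), !isDirected(tractCounts))
  FLN <- computeFLN(tracingCounts)
  FLNsym <- symmetrize(FLN)
  FS <- fractionalScaling(tractCounts)
  logFS <- pseudocountLog(tractCounts, "fs")
  bootSeed <- .fanSeed(opts$seed, "bootstrap")
  assocRows <- list()
  removalRows <- list()
  k <- 0L
  addAssoc <- function(res, mode) {
    assocRows[[length(assocRows) + 1L]] <<- data.frame(
      method = res@method, mode = mode, coefficient = res@coefficient,
      p = res@pValue, ciLow = res@ciLow, ciHigh = res@ciHigh,
      nEdges = res@nEdges, seed = opts$seed)
  }
  for (mode in opts$modes) {
    if (mode == "symmetric") {
      tracingW <- FLNsym
      tracingLog <- pseudocountLog(tracingCounts, "fln",
                                   symmetrizeAfter = TRUE)
    } else {
      tracingW <- FLN
      tracingLog <- pseudocountLog(tracingCounts, "fln")
    }
    tblRank <- buildEdgeTable(tracingW, FS, distances, mode)
    tblLog <- buildEdgeTable(tracingLog, logFS, distances, mode)
    addAssoc(bootstrapCI(tblRank, "spearman", B = opts$B,
                         level = opts$level, seed = bootSeed + (k <- k + 1L)),
             mode)
    addAssoc(bootstrapCI(tblLog, "pearson_log", B = opts$B,
                         level = opts$level, seed = bootSeed + (k <- k + 1L)),
             mode)
    if (!is.null(distances))
      addAssoc(partialSpearmanDistance(tblLog), mode)
    for (dir in c("strongest", "weakest")) {
      rc <- removalCurve(tblRank, dir, opts$fractions, "spearman")
      rc$mode <- mode
      removalRows[[length(removalRows) + 1L]] <- rc
    }
  }
  det <- detectionSweep(FLNsym, FS, opts$densities)
  removal <- do.call(rbind, removalRows)
  class(removal) <- "data.frame"
  structure(list(
    associations = do.call(rbind, assocRows),
    removal = removal,
    detection = det,
    meta = list(seed = opts$seed, B = opts$B, level = opts$level,
                modes = opts$modes, nRegions = nRegions(tracingCounts),
                inputHashes = as.list(hashes),
                package = as.character(utils::packageVersion("conntracer")))),
    class = "ValidationReport")
}

#' Run the full tracing-vs-tractography validation from a config file
#'
#' Orchestrates the complete validation: read region metadata and the two
#' raw count matrices, normalize (FLN with symmetrization; fractional
#' scaling), then per requested mode compute Spearman and log-Pearson
#' associations with percentile bootstrap confidence intervals, the
#' distance-regressed partial Spearman correlation (when centroids are
#' available), strongest/weakest removal curves, and the detection sweep.
#' All randomness is fanned out deterministically from the single top-level
#' seed, so a rerun with the same config is bit-identical.
#'
#' The config (YAML file or named list) names the inputs and parameters:
#' `regions`, `tracing`, `tractography` (file paths), and optionally
#' `modes`, `seed`, `B`, `level`, `fractions`, `densities`, `outputDir`.
#'
#' @param config Path to a YAML config file, or an equivalent named list.
#' @return A `ValidationReport`: list with `associations` (tidy data.frame),
#'   `removal` (removal curves), `detection` ([DetectionResult-class]) and
#'   `meta` (seed, parameters, md5 input hashes). Written to
#'   `config$outputDir` via [writeValidationReport()] when set.
#' @export
runValidation <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    base <- dirname(normalizePath(config))
    config <- yaml::read_yaml(config)
    for (f in c("regions", "tracing", "tractography")) {
      if (!is.null(config[[f]]) && !file.exists(config[[f]]))
        config[[f]] <- file.path(base, config[[f]])   # paths relative to config
    }
  }
  stopifnot(is.list(config))
  for (f in c("regions", "tracing", "tractography")) {
    if (is.null(config[[f]]))
      stop("config is missing required input: ", f)
    if (!file.exists(config[[f]]))
      stop("input file not found: ", config[[f]])
  }
  opts <- .analysisDefaults()
  for (nm in intersect(names(config), names(opts))) opts[[nm]] <- config[[nm]]
  opts$B <- as.integer(opts$B)
  opts$seed <- as.integer(opts$seed)
  opts$fractions <- as.numeric(opts$fractions)
  opts$densities <- as.numeric(opts$densities)
  rs <- readRegionSet(config$regions)
  tracing <- readConnectome(config$tracing, rs, kind = "count",
                            directed = TRUE)
  tract <- readConnectome(config$tractography, rs, kind = "count",
                          directed = FALSE)
  distances <- if (!is.null(regionCentroids(rs))) euclideanDistances(rs)
               else NULL
  hashes <- tools::md5sum(c(regions = config$regions,
                            tracing = config$tracing,
                            tractography = config$tractography))
  names(hashes) <- c("regions", "tracing", "tractography")
  report <- .validateCore(tracing, tract, distances, opts, hashes)
  if (!is.null(config$outputDir))
    writeValidationReport(report, config$outputDir)
  report
}

#' Simulate a paired experiment and validate it end to end
#'
#' Chains the synthetic generator into the validation pipeline: generate a
#' ground-truth network, sample tracer and tractography observations from
#' it, and run the full validation. The ground truth is returned alongside
#' the report for parameter-recovery checks.
#'
#' @param cfg A [syntheticConfig()].
#' @param ... Analysis option overrides (`modes`, `B`, `level`, `fractions`,
#'   `densities`). The analysis seed is the config seed.
#' @return List with `report` (`ValidationReport`), `truth`, `regions`,
#'   `tracer` and `tractography` (the sampled count connectomes).
#' @export
simulateAndValidate <- function(cfg, ...) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  opts <- .analysisDefaults()
  over <- list(...)
  bad <- setdiff(names(over), names(opts))
  if (length(bad))
    stop("unknown analysis option(s): ", paste(bad, collapse = ", "))
  opts[names(over)] <- over
  opts$seed <- as.integer(cfg$seed)
  gt <- generateGroundTruth(cfg)
  tracer <- sampleTracer(gt$truth, cfg$neuronsPerInjection,
                         seed = .fanSeed(cfg$seed, "tracer"))
  tract <- sampleTractography(gt$truth, cfg)
  distances <- euclideanDistances(gt$regions)
  report <- .validateCore(tracer, tract, distances, opts)
  list(report = report, truth = gt$truth, regions = gt$regions,
       tracer = tracer, tractography = tract)
}

#' Write a ValidationReport as CSV tables plus a JSON summary
#'
#' Emits `associations.csv`, `removal.csv`, `detection_summary.csv`,
#' `detection_points.csv` and `summary.json` (associations + metadata) into
#' a directory. Rerunning the pipeline with the same config reproduces the
#' files byte for byte.
#'
#' @param report A `ValidationReport` from [runValidation()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
writeValidationReport <- function(report, dir) {
  stopifnot(inherits(report, "ValidationReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, f) utils::write.csv(df, file.path(dir, f),
                                         row.names = FALSE)
  wr(report$associations, "associations.csv")
  wr(report$removal, "removal.csv")
  wr(detectionSummary(report$detection), "detection_summary.csv")
  wr(detectionPoints(report$detection), "detection_points.csv")
  jsonlite::write_json(
    list(associations = report$associations,
         detection = detectionSummary(report$detection),
         meta = report$meta),
    file.path(dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.ValidationReport <- function(x, ...) {
  cat("ValidationReport (seed", x$meta$seed, ")\n")
  a <- x$associations
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-17s %-9s  coef = %6.3f  [%6.3f, %6.3f]  p = %.3g\n",
                a$method[i], a$mode[i], a$coefficient[i],
                a$ciLow[i], a$ciHigh[i], a$p[i]))
  show(x$detection)
  invisible(x)
}
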