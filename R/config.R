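#' Pipeline configuration
#'
#' Collects every tunable parameter of the TAD-disruption pipeline in one
#' validated list. Defaults follow the analysis conventions this package
#' implements: 25-kb bins, a 1-Mb insulation square with a 200-kb delta span,
#' mean aggregation, a 1-bin merge margin and a 0.1 noise threshold for
#' boundary calling; 50-kb consensus tolerance; 75-kb (3-bin) boundary
#' intervals; a 2-Mb short-range SV cutoff; 10,000 shuffles for null models;
#' a 75-250-kb germline deletion length window; a strict 10% recurrence
#' fraction; k = 5 domain classes; 0.1-FPKM expression, copy-number 4 and
#' 1-Mb distance filters for fold changes; a 2-Mb fusion window and a 0.1
#' scaling-factor exclusion threshold.
#'
#' @param ... Named overrides of the defaults. Unknown names are an error.
#' @return A list of class \code{tadsv_config}.
#' @examples
#' cfg <- pipelineConfig(nShuffles = 500)
#' cfg$insulationSquare / cfg$binSize  # 40 bins
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    binSize = 25000,
    tadSignalWindow = 2e6,
    insulationSquare = 1e6,
    deltaSpan = 2e5,
    insulationMean = "mean",
    boundaryMargin = 1,
    noiseThreshold = 0.1,
    consensusTol = 5e4,
    boundaryWidth = 75000,
    shortRangeCutoff = 2e6,
    nShuffles = 10000,
    germlineLenRange = c(75000, 250000),
    recurrenceFrac = 0.10,
    kmeansK = 5,
    fpkmMin = 0.1,
    cnMax = 4,
    maxGeneDistance = 1e6,
    fusionWindow = 2e6,
    scalingMin = 0.1,
    rngSeed = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown configuration key(s): ",
           paste(if (length(bad)) bad else "<unnamed>", collapse = ", "),
           call. = FALSE)
    }
    cfg[names(dots)] <- dots
  }
  binMult <- c("tadSignalWindow", "insulationSquare", "deltaSpan",
               "boundaryWidth", "fusionWindow")
  for (key in binMult) {
    if (cfg[[key]] <= 0 || cfg[[key]] %% cfg$binSize != 0) {
      stop(sprintf("'%s' must be a positive multiple of binSize", key),
           call. = FALSE)
    }
  }
  for (key in c("binSize", "shortRangeCutoff", "nShuffles", "kmeansK")) {
    .assertScalarNumber(cfg[[key]], key, positive = TRUE)
  }
  if (cfg$recurrenceFrac < 0 || cfg$recurrenceFrac > 1) {
    stop("'recurrenceFrac' must lie in [0, 1]", call. = FALSE)
  }
  structure(cfg, class = "tadsv_config")
}

#' @export
print.tadsv_config <- function(x, ...) {
  cat("tadsv pipeline configuration:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}
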