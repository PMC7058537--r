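# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Sets the seed, runs `code`, and restores the caller's RNG stream so that
#' seeded operations do not perturb surrounding randomness.
#' @noRd
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(seed)
  }
  code
}

#' Derive a named sub-seed from a root seed
#'
#' Stage-specific RNG streams are derived deterministically from one root
#' seed so that a single `--seed` reproduces every stage. Kept below 2^31.
#' @noRd
.deriveSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647L)
}

.assertScalarNumber <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  }
  invisible(x)
}

#' Bin index (1-based) containing a 0-based bp position
#' @noRd
.bpToBin <- function(pos, binSize) {
  as.integer(floor(pos / binSize)) + 1L
}

#' Convert a GRanges of boundaries to 0-based half-open coordinates
#' @noRd
.grToBed <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

#' Interval centers (bp, 0-based continuous) of a GRanges
#' @noRd
.grCenters <- function(gr) {
  (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
}
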