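#' @import methods
#' @importFrom stats kmeans median p.adjust pnorm quantile rgamma rnorm rpois
#'   runif sd wilcox.test setNames rmultinom
#' @importFrom utils read.table write.table head
NULL

#' ContactMatrix: a binned intra-chromosomal Hi-C contact map
#'
#' Symmetric non-negative contact frequencies for one chromosome at a fixed
#' bin size (default 25 kb). Unmappable or low-coverage bins are flagged in
#' the per-bin mask; masked rows/columns hold \code{NA}, never a silent zero,
#' and are excluded from every downstream statistic.
#'
#' @slot chrom Chromosome name.
#' @slot binSize Bin width in bp.
#' @slot values Symmetric numeric matrix of contact frequencies; \code{NA}
#'   on masked rows/columns.
#' @slot mask Logical per-bin vector; \code{TRUE} marks an excluded bin.
#'
#' @examples
#' m <- matrix(1, 4, 4)
#' cm <- ContactMatrix("chr1", 25000L, m)
#' nBins(cm)
#' @export
setClass("ContactMatrix", representation(
  chrom = "character",
  binSize = "integer",
  values = "matrix",
  mask = "logical"
))

setValidity("ContactMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("'values' must be square")
  if (length(object@mask) != nrow(v)) return("mask length must equal n_bins")
  if (length(object@chrom) != 1L) return("'chrom' must be a single name")
  if (object@binSize <= 0L) return("'binSize' must be positive")
  ok <- !object@mask
  sub <- v[ok, ok, drop = FALSE]
  if (any(sub < 0, na.rm = TRUE)) return("unmasked contacts must be >= 0")
  if (length(sub) && !isTRUE(all.equal(sub, t(sub), tolerance = 1e-8,
                                       check.attributes = FALSE))) {
    return("'values' must be symmetric")
  }
  TRUE
})

#' Construct a ContactMatrix
#'
#' @param chrom Chromosome name.
#' @param binSize Bin width in bp.
#' @param values Square symmetric numeric matrix.
#' @param mask Optional logical vector of bins to exclude; defaults to bins
#'   whose row is entirely zero or \code{NA}.
#' @return A \linkS4class{ContactMatrix}.
#' @export
ContactMatrix <- function(chrom, binSize, values, mask = NULL) {
  values <- as.matrix(values)
  if (is.null(mask)) {
    # auto-mask: bins with no signal at all (all-zero or all-NA rows)
    rs <- rowSums(values, na.rm = TRUE)
    allNA <- apply(values, 1L, function(r) all(is.na(r)))
    mask <- allNA | rs == 0
  }
  values[mask, ] <- NA_real_
  values[, mask] <- NA_real_
  new("ContactMatrix", chrom = as.character(chrom),
      binSize = as.integer(binSize), values = values,
      mask = as.logical(mask))
}

#' @rdname ContactMatrix-class
#' @param object,x A \code{ContactMatrix}.
#' @export
setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix: %s, %d bins @ %d bp (%d masked)\n",
              object@chrom, nrow(object@values), object@binSize,
              sum(object@mask)))
})

#' @export
setGeneric("chromName", function(x) standardGeneric("chromName"))
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))
#' @export
setGeneric("contactValues", function(x) standardGeneric("contactValues"))
#' @export
setGeneric("binMask", function(x) standardGeneric("binMask"))

#' @rdname ContactMatrix-class
#' @export
setMethod("chromName", "ContactMatrix", function(x) x@chrom)
#' @rdname ContactMatrix-class
#' @export
setMethod("binSize", "ContactMatrix", function(x) x@binSize)
#' @rdname ContactMatrix-class
#' @export
setMethod("nBins", "ContactMatrix", function(x) nrow(x@values))
#' @rdname ContactMatrix-class
#' @export
setMethod("contactValues", "ContactMatrix", function(x) x@values)
#' @rdname ContactMatrix-class
#' @export
setMethod("binMask", "ContactMatrix", function(x) x@mask)

#' InsulationProfile: per-bin insulation scores for one chromosome
#'
#' Holds the log2-normalized insulation score, the delta track used for
#' boundary detection, and the window parameters that produced them. Bins
#' within one square of the chromosome end, and masked bins, are \code{NA}.
#'
#' @slot chrom Chromosome name.
#' @slot binSize Bin width in bp.
#' @slot score Per-bin log2-normalized insulation.
#' @slot delta Per-bin delta (downstream minus upstream mean of score).
#' @slot squareBins Insulation square half-width in bins.
#' @slot deltaBins Delta span in bins.
#' @export
setClass("InsulationProfile", representation(
  chrom = "character",
  binSize = "integer",
  score = "numeric",
  delta = "numeric",
  squareBins = "integer",
  deltaBins = "integer"
))

setValidity("InsulationProfile", function(object) {
  if (length(object@score) != length(object@delta)) {
    return("score and delta must have equal length")
  }
  TRUE
})

#' @rdname InsulationProfile-class
#' @param object An \code{InsulationProfile}.
#' @export
setMethod("show", "InsulationProfile", function(object) {
  cat(sprintf(
    "InsulationProfile: %s, %d bins @ %d bp (square %d bins, delta %d bins)\n",
    object@chrom, length(object@score), object@binSize,
    object@squareBins, object@deltaBins))
})

#' @rdname InsulationProfile-class
#' @param x An \code{InsulationProfile}.
#' @export
setMethod("chromName", "InsulationProfile", function(x) x@chrom)
#' @rdname InsulationProfile-class
#' @export
setMethod("binSize", "InsulationProfile", function(x) x@binSize)
#' @rdname InsulationProfile-class
#' @export
setMethod("nBins", "InsulationProfile", function(x) length(x@score))

#' @export
setGeneric("insulationScore", function(x) standardGeneric("insulationScore"))
#' @export
setGeneric("insulationDelta", function(x) standardGeneric("insulationDelta"))
#' @rdname InsulationProfile-class
#' @export
setMethod("insulationScore", "InsulationProfile", function(x) x@score)
#' @rdname InsulationProfile-class
#' @export
setMethod("insulationDelta", "InsulationProfile", function(x) x@delta)

#' ShuffleNull: an observed statistic against a boundary-shuffle null
#'
#' Summarizes a bootstrap shuffle test: the observed value, the null mean and
#' standard deviation, the z-score, a two-sided normal-approximation p-value,
#' and the empirical (upper-tail) p-value. The empirical p is never smaller
#' than 1/(n_shuffles + 1).
#'
#' @slot observed Observed statistic.
#' @slot nullMean,nullSd Moments of the shuffle null.
#' @slot z Standardized observed value; \code{NA} when the null is degenerate.
#' @slot pNormal Two-sided p from the normal approximation.
#' @slot pEmpirical Upper-tail empirical p, \code{(1 + #null >= obs)/(n + 1)}.
#' @slot nShuffles Number of shuffles.
#' @slot seed RNG seed used for the shuffles.
#' @export
setClass("ShuffleNull", representation(
  observed = "numeric",
  nullMean = "numeric",
  nullSd = "numeric",
  z = "numeric",
  pNormal = "numeric",
  pEmpirical = "numeric",
  nShuffles = "integer",
  seed = "integer"
))

setValidity("ShuffleNull", function(object) {
  if (length(object@observed) != 1L) return("'observed' must be scalar")
  if (!is.na(object@pEmpirical) &&
      object@pEmpirical < 1 / (object@nShuffles + 1) - 1e-12) {
    return("empirical p below 1/(n_shuffles + 1)")
  }
  TRUE
})

#' Summarize shuffle-null draws into a ShuffleNull object
#'
#' @param observed Observed statistic.
#' @param nulls Numeric vector of null draws.
#' @param seed Integer seed used to generate the shuffles.
#' @return A \linkS4class{ShuffleNull}.
#' @examples
#' shuffleNull(10, rpois(200, 4), seed = 1L)
#' @export
shuffleNull <- function(observed, nulls, seed = NA_integer_) {
  m <- mean(nulls)
  s <- sd(nulls)
  z <- if (!is.na(s) && s > 0) (observed - m) / s else NA_real_
  new("ShuffleNull",
      observed = as.numeric(observed), nullMean = m, nullSd = s, z = z,
      pNormal = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
      pEmpirical = (1 + sum(nulls >= observed)) / (length(nulls) + 1),
      nShuffles = length(nulls), seed = as.integer(seed))
}

#' @rdname ShuffleNull-class
#' @param object A \code{ShuffleNull}.
#' @export
setMethod("show", "ShuffleNull", function(object) {
  cat(sprintf(
    "ShuffleNull: observed %.4g vs null %.4g +/- %.4g (n=%d)\n  z = %.3f, p_normal = %.3g, p_empirical = %.3g\n",
    object@observed, object@nullMean, object@nullSd, object@nShuffles,
    object@z, object@pNormal, object@pEmpirical))
})

#' @export
setGeneric("observedValue", function(x) standardGeneric("observedValue"))
#' @export
setGeneric("nullMean", function(x) standardGeneric("nullMean"))
#' @export
setGeneric("nullSd", function(x) standardGeneric("nullSd"))
#' @export
setGeneric("zScore", function(x) standardGeneric("zScore"))
#' @export
setGeneric("pNormal", function(x) standardGeneric("pNormal"))
#' @export
setGeneric("pEmpirical", function(x) standardGeneric("pEmpirical"))

#' @rdname ShuffleNull-class
#' @param x A \code{ShuffleNull}.
#' @export
setMethod("observedValue", "ShuffleNull", function(x) x@observed)
#' @rdname ShuffleNull-class
#' @export
setMethod("nullMean", "ShuffleNull", function(x) x@nullMean)
#' @rdname ShuffleNull-class
#' @export
setMethod("nullSd", "ShuffleNull", function(x) x@nullSd)
#' @rdname ShuffleNull-class
#' @export
setMethod("zScore", "ShuffleNull", function(x) x@z)
#' @rdname ShuffleNull-class
#' @export
setMethod("pNormal", "ShuffleNull", function(x) x@pNormal)
#' @rdname ShuffleNull-class
#' @export
setMethod("pEmpirical", "ShuffleNull", function(x) x@pEmpirical)
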