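# TAD-fusion statistics on rearranged contact maps: distance-decay expected
# model, SV scaling factors, intra/inter-TAD-SV classification and breakend
# aggregate enrichment.

#' Expected contact frequency by genomic distance
#'
#' Empirical mean contact over all unmasked bin pairs at each separation,
#' per chromosome and genome-wide (weighted by pair counts). Distances
#' with fewer than `minPairs` unmasked pairs are pooled with following
#' neighbors; a distance with no pairs at all is NA.
#'
#' @param mats A \linkS4class{ContactMatrix} or list of them (one per
#'   chromosome).
#' @param minPairs Minimum pairs per distance before pooling.
#' @return A list of class `tadsv_decay` with `distance` (bins), `mean`,
#'   `n` (pair counts) and `perChrom` (same three, per chromosome).
#' @export
expectedByDistance <- function(mats, minPairs = 10L) {
  if (is(mats, "ContactMatrix")) mats <- list(mats)
  perChrom <- lapply(mats, function(m) {
    v <- contactValues(m)
    n <- nBins(m)
    if (all(is.na(v))) {
      message("chromosome ", chromName(m), " fully masked; empty curve")
      return(list(chrom = chromName(m), sum = numeric(0), n = numeric(0)))
    }
    sums <- numeric(n - 1L)
    cnts <- numeric(n - 1L)
    for (d in seq_len(n - 1L)) {
      band <- v[cbind(seq_len(n - d), seq_len(n - d) + d)]
      cnts[d] <- sum(!is.na(band))
      sums[d] <- sum(band, na.rm = TRUE)
    }
    list(chrom = chromName(m), sum = sums, n = cnts)
  })
  maxD <- max(vapply(perChrom, function(x) length(x$sum), integer(1)))
  gsum <- numeric(maxD)
  gcnt <- numeric(maxD)
  for (x in perChrom) {
    if (!length(x$sum)) next
    idx <- seq_along(x$sum)
    gsum[idx] <- gsum[idx] + x$sum
    gcnt[idx] <- gcnt[idx] + x$n
  }
  pool <- function(sums, cnts) {
    means <- rep(NA_real_, length(sums))
    d <- 1L
    while (d <= length(sums)) {
      e <- d
      while (sum(cnts[d:e]) < minPairs && e < length(sums)) e <- e + 1L
      tot <- sum(cnts[d:e])
      if (tot > 0) means[d:e] <- sum(sums[d:e]) / tot
      d <- e + 1L
    }
    means
  }
  structure(list(
    distance = seq_len(maxD), mean = pool(gsum, gcnt), n = gcnt,
    perChrom = lapply(perChrom, function(x) {
      list(chrom = x$chrom, distance = seq_along(x$sum),
           mean = pool(x$sum, x$n), n = x$n)
    })), class = "tadsv_decay")
}

#' @export
print.tadsv_decay <- function(x, ...) {
  cat(sprintf("Distance-decay curve: %d distances, %d chromosome(s)\n",
              length(x$distance), length(x$perChrom)))
  invisible(x)
}

# Expected value lookup for bin separations d >= 1
.decayAt <- function(decay, d) {
  out <- rep(NA_real_, length(d))
  okk <- d >= 1L & d <= length(decay$mean)
  out[okk] <- decay$mean[d[okk]]
  out
}

# Window of an SV in bins: footprint symmetric-extended to `window` bp
# total span, truncated per side at the nearest other-SV breakend.
.svWindowBins <- function(mat, sv, window, otherSVs = NULL) {
  bs <- binSize(mat)
  n <- nBins(mat)
  s <- GenomicRanges::start(sv) - 1
  e <- GenomicRanges::end(sv)
  ext <- max(0, (window - (e - s)) / 2)
  lo <- s - ext
  hi <- e + ext
  if (!is.null(otherSVs) && length(otherSVs)) {
    ends <- sort(c(GenomicRanges::start(otherSVs) - 1,
                   GenomicRanges::end(otherSVs)))
    leftCut <- ends[ends <= s]
    if (length(leftCut)) lo <- max(lo, max(leftCut))
    rightCut <- ends[ends >= e]
    if (length(rightCut)) hi <- min(hi, min(rightCut))
  }
  c(max(1L, .bpToBin(lo, bs)), min(n, .bpToBin(hi - 1, bs)))
}

#' Scaling factor of an SV region relative to the expected model
#'
#' Mean observed contact over all unmasked bin pairs inside the SV's
#' window (the footprint extended to a 2-Mb total span, truncated at the
#' nearest other-SV breakend per side), divided by the mean distance-
#' matched expectation over the same pairs. Regions scaling below
#' `scalingMin` (default 0.1) are flagged excluded — in WGS-vs-Hi-C
#' integration these are likely false-positive SV calls.
#'
#' @param mat \linkS4class{ContactMatrix} (normalized).
#' @param sv Single-event GRanges on the matrix's chromosome.
#' @param decay `tadsv_decay` from \code{\link{expectedByDistance}} on the
#'   same normalization.
#' @param window Total window span in bp (default 2 Mb).
#' @param otherSVs GRanges of the sample's other SVs (window truncation).
#' @param scalingMin Exclusion threshold.
#' @return A list with `scalingFactor`, `windowUsed` (bin range),
#'   `excluded`, `reason`.
#' @export
svScalingFactor <- function(mat, sv, decay, window = 2e6, otherSVs = NULL,
                            scalingMin = 0.1) {
  wb <- .svWindowBins(mat, sv, window, otherSVs)
  if (wb[2] - wb[1] + 1L < 4L) {
    return(list(scalingFactor = NA_real_, windowUsed = wb, excluded = TRUE,
                reason = "window-too-small"))
  }
  bins <- wb[1]:wb[2]
  v <- contactValues(mat)[bins, bins, drop = FALSE]
  nb <- length(bins)
  ut <- which(upper.tri(v), arr.ind = TRUE)
  dists <- ut[, 2L] - ut[, 1L]
  obs <- v[ut]
  expv <- .decayAt(decay, dists)
  okk <- !is.na(obs) & !is.na(expv)
  if (!any(okk) || mean(expv[okk]) <= 0) {
    return(list(scalingFactor = NA_real_, windowUsed = wb, excluded = TRUE,
                reason = "no-informative-pairs"))
  }
  sf <- mean(obs[okk]) / mean(expv[okk])
  list(scalingFactor = sf, windowUsed = wb, excluded = sf < scalingMin,
       reason = if (sf < scalingMin) "low-scaling" else "")
}

#' Classify cross-SV bin pairs as intra- or inter-TAD/SV
#'
#' For each breakend, finds the nearest boundary beyond it (away from the
#' SV). Bin pairs spanning the SV with both bins between a breakend and its
#' nearest boundary are "intra" (the putative fused domain); cross-SV pairs
#' reaching past a nearest boundary are "inter"; everything else in the
#' window is "other".
#'
#' @param mat \linkS4class{ContactMatrix} (provides bin geometry).
#' @param sv Single-event GRanges.
#' @param boundaries Boundary GRanges on the same chromosome.
#' @param windowUsed Bin range from \code{\link{svScalingFactor}} (or NULL
#'   to use the full 2-Mb window).
#' @param window Window span in bp when `windowUsed` is NULL.
#' @return Character matrix (window x window, upper triangle filled) with
#'   entries "intra", "inter", "other"; attribute `bins` holds the bin
#'   range.
#' @export
classifyFusionBins <- function(mat, sv, boundaries, windowUsed = NULL,
                               window = 2e6) {
  bs <- binSize(mat)
  if (is.null(windowUsed)) windowUsed <- .svWindowBins(mat, sv, window)
  bins <- windowUsed[1]:windowUsed[2]
  sBin <- .bpToBin(GenomicRanges::start(sv) - 1, bs)
  eBin <- .bpToBin(GenomicRanges::end(sv) - 1, bs)
  bChrom <- as.character(GenomicRanges::seqnames(boundaries)) ==
    chromName(mat)
  bnd <- boundaries[bChrom]
  # nearest boundary beyond each breakend, away from the SV
  bStartBin <- .bpToBin(GenomicRanges::start(bnd) - 1, bs)
  bEndBin <- .bpToBin(GenomicRanges::end(bnd) - 1, bs)
  leftB <- bEndBin[bEndBin < sBin]
  leftEdge <- if (length(leftB)) max(leftB) else NA_integer_
  rightB <- bStartBin[bStartBin > eBin]
  rightEdge <- if (length(rightB)) min(rightB) else NA_integer_
  if (is.na(leftEdge) || is.na(rightEdge)) {
    message("no boundary within the window on one side; that side ",
            "contributes only inter labels")
  }
  nb <- length(bins)
  lab <- matrix("", nb, nb, dimnames = NULL)
  for (a in seq_len(nb - 1L)) {
    for (b in (a + 1L):nb) {
      i <- bins[a]
      j <- bins[b]
      if (i < sBin && j > eBin) {
        intraLeft <- !is.na(leftEdge) && i > leftEdge
        intraRight <- !is.na(rightEdge) && j < rightEdge
        lab[a, b] <- if (intraLeft && intraRight) "intra" else "inter"
      } else {
        lab[a, b] <- "other"
      }
    }
  }
  attr(lab, "bins") <- windowUsed
  attr(lab, "breakendBins") <- c(sBin, eBin)
  lab
}

#' Compare contact decay of intra- vs inter-TAD/SV pairs
#'
#' For each class, the per-distance and overall mean of observed/expected
#' contact; the summary statistic is intraMean / interMean. A class with no
#' pairs is flagged undefined.
#'
#' @param mat \linkS4class{ContactMatrix}.
#' @param labels Label matrix from \code{\link{classifyFusionBins}}.
#' @param decay `tadsv_decay` expected model.
#' @return A list with `intraMean`, `interMean`, `ratio`, `undefined`
#'   (character vector of empty classes) and `perDistance` (data.frame:
#'   distance, class, ratio, n).
#' @export
fusionDecayCompare <- function(mat, labels, decay) {
  wb <- attr(labels, "bins")
  bins <- wb[1]:wb[2]
  v <- contactValues(mat)[bins, bins, drop = FALSE]
  ut <- which(upper.tri(v), arr.ind = TRUE)
  cls <- labels[ut]
  dists <- ut[, 2L] - ut[, 1L]
  obs <- v[ut]
  expv <- .decayAt(decay, dists)
  okk <- !is.na(obs) & !is.na(expv) & expv > 0
  ratio <- obs[okk] / expv[okk]
  cls <- cls[okk]
  dists <- dists[okk]
  meanOf <- function(cc) {
    if (!any(cls == cc)) return(NA_real_)
    mean(ratio[cls == cc])
  }
  intraMean <- meanOf("intra")
  interMean <- meanOf("inter")
  undefined <- c("intra", "inter")[c(!any(cls == "intra"),
                                     !any(cls == "inter"))]
  perD <- do.call(rbind, lapply(c("intra", "inter"), function(cc) {
    sel <- cls == cc
    if (!any(sel)) return(NULL)
    agg <- tapply(ratio[sel], dists[sel], mean)
    data.frame(distance = as.integer(names(agg)), class = cc,
               ratio = as.numeric(agg),
               n = as.integer(table(dists[sel])))
  }))
  list(intraMean = intraMean, interMean = interMean,
       ratio = intraMean / interMean, undefined = undefined,
       perDistance = perD)
}

#' Aggregate observed/expected contact enrichment at SV breakend pixels
#'
#' For each SV, extracts the (2h+1)^2 observed/expected submatrix centered
#' on the (start-bin, end-bin) pixel of its sample's matrix and reports the
#' center-pixel fold; the aggregate is the element-wise mean over SVs. SVs
#' whose breakend bin is masked are skipped and counted.
#'
#' @param mats Named list of \linkS4class{ContactMatrix} per sample, or a
#'   single matrix used for all SVs.
#' @param svs GRanges of SV events (metadata `sample_id` indexes `mats`
#'   when it is a named list).
#' @param halfWidth h, half-width in bins of the aggregate window.
#' @param decay Optional shared `tadsv_decay`; computed per matrix when
#'   NULL.
#' @return A list with `aggregate` ((2h+1)^2 mean fold matrix),
#'   `centerFold` (mean over SVs of the center-pixel fold), `perSV`
#'   (numeric vector), `nUsed`, `nSkipped`.
#' @export
breakendAggregate <- function(mats, svs, halfWidth = 2L, decay = NULL) {
  single <- is(mats, "ContactMatrix")
  if (single && is.null(decay)) decay <- expectedByDistance(mats)
  decayCache <- list()
  h <- as.integer(halfWidth)
  size <- 2L * h + 1L
  acc <- matrix(0, size, size)
  accN <- matrix(0, size, size)
  perSV <- rep(NA_real_, length(svs))
  nSkipped <- 0L
  for (k in seq_along(svs)) {
    m <- if (single) mats else mats[[S4Vectors::mcols(svs)$sample_id[k]]]
    if (is.null(m)) {
      nSkipped <- nSkipped + 1L
      next
    }
    dk <- if (!is.null(decay)) {
      decay
    } else {
      key <- S4Vectors::mcols(svs)$sample_id[k]
      if (is.null(decayCache[[key]])) {
        decayCache[[key]] <- expectedByDistance(m)
      }
      decayCache[[key]]
    }
    bs <- binSize(m)
    n <- nBins(m)
    # pixels flanking the junction: last bin left of the start breakend,
    # first bin at/after the end breakend (for a bin-aligned deletion the
    # footprint bins themselves carry no contacts)
    i <- .bpToBin(max(0, GenomicRanges::start(svs[k]) - 2), bs)
    j <- .bpToBin(GenomicRanges::end(svs[k]), bs)
    if (i < 1L || j > n || binMask(m)[i] || binMask(m)[j]) {
      nSkipped <- nSkipped + 1L
      next
    }
    v <- contactValues(m)
    for (a in -h:h) {
      for (b in -h:h) {
        ii <- i + a
        jj <- j + b
        if (ii < 1L || jj < 1L || ii > n || jj > n || ii >= jj) next
        ev <- .decayAt(dk, jj - ii)
        ov <- v[ii, jj]
        if (is.na(ov) || is.na(ev) || ev <= 0) next
        acc[a + h + 1L, b + h + 1L] <- acc[a + h + 1L, b + h + 1L] + ov / ev
        accN[a + h + 1L, b + h + 1L] <- accN[a + h + 1L, b + h + 1L] + 1
      }
    }
    ev0 <- .decayAt(dk, j - i)
    if (!is.na(v[i, j]) && !is.na(ev0) && ev0 > 0 && i < j) {
      perSV[k] <- v[i, j] / ev0
    }
  }
  used <- which(!is.na(perSV))
  list(aggregate = ifelse(accN > 0, acc / accN, NA_real_),
       centerFold = mean(perSV[used]), perSV = perSV,
       nUsed = length(used), nSkipped = nSkipped)
}
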