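# Boundary-affecting SV detection, enrichment against shuffled boundaries,
# germline comparison, cohort recurrence and loop-anchor disruption.

#' Classify SVs as short- or long-range
#'
#' Short-range events have breakend span strictly less than the cutoff
#' (2 Mb by default).
#'
#' @param svs GRanges of SV events (see \code{\link{svEvents}}).
#' @param cutoff Length cutoff in bp.
#' @return Character vector, "short" or "long", one per event.
#' @examples
#' sv <- svEvents("chr1", 0, 1999999, "s1")
#' classifySVRange(sv)  # "short"
#' @export
classifySVRange <- function(svs, cutoff = 2e6) {
  len <- GenomicRanges::width(svs)
  if (any(len <= 0)) stop("SV length must be positive", call. = FALSE)
  ifelse(len < cutoff, "short", "long")
}

#' Annotate SVs as boundary-affecting (BA)
#'
#' An SV is boundary-affecting when its footprint fully contains at least
#' one TAD boundary interval (containment inclusive at both ends: the SV
#' must span the whole length of the boundary; partial overlap does not
#' qualify).
#'
#' @param svs GRanges of SV events.
#' @param boundaries GRanges of boundaries.
#' @return A list of class `tadsv_ba` with elements `sv` (the input, with
#'   added metadata columns `isBA` and `nBoundaries`), `boundaries`, and
#'   `hits` (a Hits object: which boundary is spanned by which SV).
#' @export
annotateBA <- function(svs, boundaries) {
  hits <- GenomicRanges::findOverlaps(boundaries, svs, type = "within")
  nB <- tabulate(S4Vectors::subjectHits(hits), nbins = length(svs))
  out <- svs
  S4Vectors::mcols(out)$isBA <- nB > 0L
  S4Vectors::mcols(out)$nBoundaries <- nB
  structure(list(sv = out, boundaries = boundaries, hits = hits),
            class = "tadsv_ba")
}

#' @export
print.tadsv_ba <- function(x, ...) {
  cat(sprintf("BA annotation: %d SV(s), %d boundary-affecting (%.1f%%)\n",
              length(x$sv), sum(S4Vectors::mcols(x$sv)$isBA),
              100 * mean(S4Vectors::mcols(x$sv)$isBA)))
  invisible(x)
}

#' Boundaries spanned by one SV
#' @param ba A `tadsv_ba` object from \code{\link{annotateBA}}.
#' @param i SV index.
#' @return GRanges of the boundaries fully contained in SV `i`.
#' @export
spannedBoundaries <- function(ba, i) {
  ba$boundaries[S4Vectors::queryHits(ba$hits)[
    S4Vectors::subjectHits(ba$hits) == i]]
}

# Fast BA counting used inside shuffle loops. Boundaries grouped by width;
# an SV [s, e) contains a width-w boundary starting at b iff
# b >= s and b + w <= e, i.e. b in [s, e - w].
.countBAFast <- function(svStart, svEnd, bStart, bWidth) {
  contained <- rep(FALSE, length(svStart))
  for (w in unique(bWidth)) {
    bs <- sort(bStart[bWidth == w])
    hi <- findInterval(svEnd - w, bs)
    lo <- findInterval(svStart - 1e-9, bs)
    contained <- contained | hi > lo
  }
  contained
}

#' BA-SV enrichment against shuffled boundaries, per SV type
#'
#' Restricts to short-range events, counts boundary-affecting SVs per type,
#' and compares the observed count with the distribution obtained by
#' shuffling the boundary set (default 10,000 times). The fold change is
#' observed / null mean.
#'
#' @param svs GRanges of SV events.
#' @param boundaries GRanges of boundaries.
#' @param chromSizes Named numeric vector of chromosome sizes (bp).
#' @param nShuffles Number of boundary shuffles.
#' @param binSize Bin width in bp (shuffles are bin-grid placements).
#' @param cutoff Short-range cutoff in bp.
#' @param seed Integer seed.
#' @return Named list per SV type, each with elements `n` (short-range
#'   events of that type), `baCount`, `baFraction`, `fold` and `null`
#'   (a \linkS4class{ShuffleNull}). Types with no events are omitted with
#'   a message.
#' @export
baEnrichment <- function(svs, boundaries, chromSizes, nShuffles = 10000,
                         binSize = 25000, cutoff = 2e6, seed = NULL) {
  short <- svs[classifySVRange(svs, cutoff) == "short"]
  types <- c("DEL", "DUP", "INV", "COMPLEX")
  present <- intersect(types, unique(S4Vectors::mcols(short)$sv_type))
  absent <- setdiff(unique(S4Vectors::mcols(svs)$sv_type), present)
  if (length(absent)) {
    message("no short-range events for type(s): ",
            paste(absent, collapse = ", "))
  }
  chroms <- as.character(GenomicRanges::seqnames(short))
  typeOf <- S4Vectors::mcols(short)$sv_type
  svS <- GenomicRanges::start(short) - 1
  svE <- GenomicRanges::end(short)
  bChrom <- as.character(GenomicRanges::seqnames(boundaries))
  bW <- GenomicRanges::width(boundaries)

  svIdxByChrom <- split(seq_along(short), chroms)
  typeIdx <- match(typeOf, present)
  countByType <- function(bStartByChrom) {
    contained <- rep(FALSE, length(short))
    for (ch in names(bStartByChrom)) {
      ix <- svIdxByChrom[[ch]]
      if (is.null(ix)) next
      contained[ix] <- .countBAFast(svS[ix], svE[ix],
                                    bStartByChrom[[ch]]$start,
                                    bStartByChrom[[ch]]$width)
    }
    as.numeric(tabulate(typeIdx[contained], nbins = length(present)))
  }
  obsStarts <- lapply(split(seq_along(boundaries), bChrom), function(ix) {
    list(start = GenomicRanges::start(boundaries)[ix] - 1, width = bW[ix])
  })
  observed <- countByType(obsStarts)

  # shuffle loop: re-place boundaries per chromosome on the bin grid
  perChromK <- vapply(obsStarts, function(x) length(x$start), integer(1))
  perChromW <- lapply(obsStarts, function(x)
    as.integer(round(x$width / binSize)))
  nbins <- vapply(names(obsStarts), function(ch)
    as.integer(floor(chromSizes[[ch]] / binSize)), integer(1))
  nulls <- .withSeed(seed, {
    vapply(seq_len(nShuffles), function(s) {
      sh <- lapply(names(obsStarts), function(ch) {
        wb <- perChromW[[ch]]
        st <- .placeNonOverlapping(perChromK[[ch]], wb[1L], nbins[[ch]])
        list(start = st * binSize, width = wb * binSize)
      })
      names(sh) <- names(obsStarts)
      countByType(sh)
    }, numeric(length(present)))
  })
  if (length(present) == 1L) nulls <- matrix(nulls, nrow = 1L)
  res <- lapply(seq_along(present), function(k) {
    tp <- present[k]
    nTp <- sum(typeOf == tp)
    nullK <- nulls[k, ]
    sn <- shuffleNull(observed[k], nullK,
                      seed = if (is.null(seed)) NA_integer_ else seed)
    list(type = tp, n = nTp, baCount = unname(observed[k]),
         baFraction = unname(observed[k]) / nTp,
         fold = unname(observed[k]) / mean(nullK), null = sn)
  })
  names(res) <- present
  res
}

#' Germline versus somatic BA deletion rates
#'
#' Filters both deletion sets to lengths within `lenRange` (inclusive at
#' both ends, 75-250 kb by default), then reports the fraction of filtered
#' events that fully span a boundary, and the fraction of all boundaries
#' hit by each set.
#'
#' @param somaticDels,germlineDels GRanges of deletion events.
#' @param boundaries GRanges of boundaries.
#' @param lenRange Two-element numeric, closed length interval in bp.
#' @return A list with `rateSomatic`, `rateGermline` (NA with a flag when a
#'   filtered set is empty), per-set filtered counts, and the fraction of
#'   boundaries hit by each set.
#' @export
germlineSomaticRates <- function(somaticDels, germlineDels, boundaries,
                                 lenRange = c(75000, 250000)) {
  filt <- function(gr) {
    len <- GenomicRanges::width(gr)
    gr[len >= lenRange[1] & len <= lenRange[2]]
  }
  rateOf <- function(gr) {
    if (!length(gr)) return(list(rate = NA_real_, n = 0L, nBA = 0L,
                                 boundariesHit = 0L, flagged = TRUE))
    ba <- annotateBA(gr, boundaries)
    list(rate = mean(S4Vectors::mcols(ba$sv)$isBA), n = length(gr),
         nBA = sum(S4Vectors::mcols(ba$sv)$isBA),
         boundariesHit = length(unique(S4Vectors::queryHits(ba$hits))),
         flagged = FALSE)
  }
  som <- rateOf(filt(somaticDels))
  ger <- rateOf(filt(germlineDels))
  list(rateSomatic = som$rate, rateGermline = ger$rate,
       counts = data.frame(
         set = c("somatic", "germline"),
         nFiltered = c(som$n, ger$n), nBA = c(som$nBA, ger$nBA),
         fracBoundariesHit = c(som$boundariesHit, ger$boundariesHit) /
           max(1L, length(boundaries))),
       flagged = som$flagged || ger$flagged)
}

#' Recurrently affected boundaries in a cohort
#'
#' Builds the binary sample-by-boundary matrix (1 when the boundary is
#' affected by at least one BA-SV of that sample) and flags boundaries
#' affected in strictly more than `frac` of the samples.
#'
#' @param svs GRanges of SV events for one cohort (metadata `sample_id`).
#' @param boundaries GRanges of boundaries.
#' @param frac Recurrence fraction (strict inequality; default 0.10).
#' @return A list with `matrix` (samples x boundaries, binary),
#'   `recurrent` (GRanges of recurrent boundaries) and `fraction`
#'   (per-boundary affected-sample fraction).
#' @export
boundaryRecurrence <- function(svs, boundaries, frac = 0.10) {
  if (!length(svs)) stop("empty cohort", call. = FALSE)
  samples <- sort(unique(S4Vectors::mcols(svs)$sample_id))
  ba <- annotateBA(svs, boundaries)
  m <- matrix(0L, nrow = length(samples), ncol = length(boundaries),
              dimnames = list(samples, NULL))
  if (length(ba$hits)) {
    svSample <- S4Vectors::mcols(svs)$sample_id[
      S4Vectors::subjectHits(ba$hits)]
    bIdx <- S4Vectors::queryHits(ba$hits)
    m[cbind(match(svSample, samples), bIdx)] <- 1L
  }
  fraction <- colMeans(m)
  list(matrix = m, recurrent = boundaries[fraction > frac],
       fraction = fraction)
}

#' SVs disrupting exactly one anchor of an insulated neighborhood
#'
#' An insulated neighborhood is a CTCF-CTCF loop; a loop-disrupting SV
#' overlaps exactly one of the two anchors (events spanning both anchors,
#' or touching neither, are not reported).
#'
#' @param svs GRanges of SV events.
#' @param anchor1,anchor2 Parallel GRanges of the loops' two anchors
#'   (anchor1 precedes anchor2).
#' @return data.frame with columns svIndex, loopIndex, anchor ("anchor1" or
#'   "anchor2").
#' @export
loopDisruption <- function(svs, anchor1, anchor2) {
  if (length(anchor1) != length(anchor2)) {
    stop("anchor1 and anchor2 must be parallel", call. = FALSE)
  }
  h1 <- GenomicRanges::findOverlaps(svs, anchor1)
  h2 <- GenomicRanges::findOverlaps(svs, anchor2)
  k1 <- paste(S4Vectors::queryHits(h1), S4Vectors::subjectHits(h1))
  k2 <- paste(S4Vectors::queryHits(h2), S4Vectors::subjectHits(h2))
  only1 <- !(k1 %in% k2)
  only2 <- !(k2 %in% k1)
  out <- rbind(
    data.frame(svIndex = S4Vectors::queryHits(h1)[only1],
               loopIndex = S4Vectors::subjectHits(h1)[only1],
               anchor = rep("anchor1", sum(only1))),
    data.frame(svIndex = S4Vectors::queryHits(h2)[only2],
               loopIndex = S4Vectors::subjectHits(h2)[only2],
               anchor = rep("anchor2", sum(only2))))
  out[order(out$svIndex, out$loopIndex), , drop = FALSE]
}

#' Distribution of spanned-boundary counts per BA-SV
#'
#' For each SV type and each minimum-length threshold, tabulates how many
#' boundaries each boundary-affecting SV spans; fractions sum to 1 within
#' each (type, threshold) stratum.
#'
#' @param ba A `tadsv_ba` object from \code{\link{annotateBA}}.
#' @param thresholds Numeric vector of minimum SV lengths (bp).
#' @return data.frame with columns sv_type, min_length, k, count, fraction.
#' @export
boundariesPerSV <- function(ba, thresholds = c(0, 5e5, 1e6)) {
  mc <- S4Vectors::mcols(ba$sv)
  len <- GenomicRanges::width(ba$sv)
  rows <- list()
  for (tp in unique(mc$sv_type)) {
    for (th in thresholds) {
      sel <- mc$sv_type == tp & len >= th & mc$isBA
      if (!any(sel)) next
      tab <- table(mc$nBoundaries[sel])
      rows[[length(rows) + 1L]] <- data.frame(
        sv_type = tp, min_length = th,
        k = as.integer(names(tab)), count = as.integer(tab),
        fraction = as.integer(tab) / sum(tab))
    }
  }
  if (!length(rows)) {
    return(data.frame(sv_type = character(0), min_length = numeric(0),
                      k = integer(0), count = integer(0),
                      fraction = numeric(0)))
  }
  do.call(rbind, rows)
}
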