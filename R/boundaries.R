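# Consensus boundaries across cell types, boundary shuffling, shuffle-null
# overlap tests and feature profiles around boundaries.

# Uniform non-overlapping placement of k intervals of w bins in n bins
# (0-based start bins). Combinatorial bijection onto sorted k-subsets keeps
# the draw exactly uniform over all valid placements.
.placeNonOverlapping <- function(k, w, n, allowedStart = NULL) {
  if (k == 0L) return(integer(0))
  if (n < k * w) {
    stop("chromosome too short to host ", k, " boundaries of ", w,
         " bins without overlap", call. = FALSE)
  }
  if (is.null(allowedStart)) {
    x <- sort(sample.int(n - k * w + k, k) - 1L)
    x + (seq_len(k) - 1L) * (w - 1L)
  } else {
    # masked genome: rejection sampling on the allowed start bins
    for (try in seq_len(1000L)) {
      s <- sort(sample(allowedStart, k))
      if (all(diff(s) >= w)) return(s)
    }
    stop("could not place ", k, " non-overlapping boundaries on the ",
         "allowed bins in 1000 attempts", call. = FALSE)
  }
}

#' Shuffle a boundary set, preserving per-chromosome counts and widths
#'
#' Boundaries are re-placed uniformly at random on the bin grid of their own
#' chromosome, keeping the number of boundaries per chromosome and each
#' boundary's width; shuffled boundaries never overlap each other. This is
#' the null model used by every enrichment test in the package.
#'
#' @param bset GRanges of boundaries (bin-aligned).
#' @param chromSizes Named numeric vector of chromosome sizes (bp).
#' @param seed Integer seed (same seed, same output).
#' @param binSize Bin width in bp.
#' @param mask Optional named list of per-chromosome logical vectors marking
#'   excluded bins; shuffled boundaries avoid starting in a masked bin.
#' @return GRanges of shuffled boundaries, `source` set to "shuffle".
#' @export
shuffleBoundaries <- function(bset, chromSizes, seed = NULL,
                              binSize = 25000, mask = NULL) {
  if (!length(bset)) return(bset)
  chroms <- as.character(GenomicRanges::seqnames(bset))
  missing <- setdiff(unique(chroms), names(chromSizes))
  if (length(missing)) {
    stop("chromSizes lacks: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  .withSeed(seed, {
    out <- lapply(unique(chroms), function(ch) {
      sub <- bset[chroms == ch]
      wBins <- as.integer(round(GenomicRanges::width(sub) / binSize))
      nbins <- as.integer(floor(chromSizes[[ch]] / binSize))
      allowed <- if (!is.null(mask) && !is.null(mask[[ch]])) {
        which(!mask[[ch]]) - 1L
      } else NULL
      if (length(unique(wBins)) == 1L && is.null(allowed)) {
        starts <- .placeNonOverlapping(length(sub), wBins[1L], nbins)
        starts <- sample(starts)  # decouple width order from position order
      } else {
        # mixed widths: rejection sampling
        maxW <- max(wBins)
        starts <- NULL
        for (try in seq_len(1000L)) {
          cand <- if (is.null(allowed)) {
            sample.int(nbins - maxW + 1L, length(sub), replace = TRUE) - 1L
          } else {
            sample(allowed, length(sub), replace = TRUE)
          }
          ord <- order(cand)
          if (all(diff(cand[ord]) >= wBins[ord][-length(sub)]) &&
              max(cand + wBins) <= nbins) {
            starts <- cand
            break
          }
        }
        if (is.null(starts)) {
          stop("could not place shuffled boundaries without overlap",
               call. = FALSE)
        }
      }
      gr <- GenomicRanges::GRanges(
        ch, IRanges::IRanges(starts * binSize + 1L,
                             (starts + wBins) * binSize))
      S4Vectors::mcols(gr)$strength <- S4Vectors::mcols(sub)$strength
      S4Vectors::mcols(gr)$source <- "shuffle"
      gr
    })
    suppressWarnings(sort(do.call(c, out)))
  })
}

#' Cross-cell-type consensus boundaries
#'
#' Pools boundaries from two or more cell types and groups them greedily
#' left to right: a boundary joins the current group when its center lies
#' within `tol` of the previous member's center (50 kb = two 25-kb bins by
#' default). Groups containing at least one boundary from every input set
#' become consensus boundaries, re-emitted as a 3-bin interval centered on
#' the bin holding the median member center; groups missing any set are
#' dropped.
#'
#' @param sets List of two or more boundary GRanges.
#' @param tol Center-to-center tolerance in bp.
#' @param binSize Bin width in bp.
#' @return GRanges of consensus boundaries (`source` = "consensus",
#'   `strength` = mean member strength, `nMembers` = group size).
#' @export
consensusBoundaries <- function(sets, tol = 5e4, binSize = 25000) {
  if (!is.list(sets) || length(sets) < 2L) {
    stop("need at least 2 boundary sets for a consensus", call. = FALSE)
  }
  nSets <- length(sets)
  df <- do.call(rbind, lapply(seq_along(sets), function(k) {
    gr <- sets[[k]]
    if (!length(gr)) return(NULL)
    st <- S4Vectors::mcols(gr)$strength
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               center = .grCenters(gr),
               strength = if (is.null(st)) NA_real_ else st,
               set = k, stringsAsFactors = FALSE)
  }))
  emptySet <- function() {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$strength <- numeric(0)
    S4Vectors::mcols(gr)$source <- character(0)
    S4Vectors::mcols(gr)$nMembers <- integer(0)
    gr
  }
  if (is.null(df) || !nrow(df)) return(emptySet())
  df <- df[order(df$chrom, df$center), , drop = FALSE]
  newGrp <- c(TRUE, df$chrom[-1L] != df$chrom[-nrow(df)] |
                diff(df$center) > tol)
  df$group <- cumsum(newGrp)
  out <- lapply(split(df, df$group), function(g) {
    if (length(unique(g$set)) < nSets) return(NULL)
    med <- median(g$center)
    centerBin <- as.integer(floor(med / binSize))  # 0-based
    data.frame(chrom = g$chrom[1L],
               start = (centerBin - 1L) * binSize,
               end = (centerBin + 2L) * binSize,
               strength = mean(g$strength),
               nMembers = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(emptySet())
  gr <- GenomicRanges::GRanges(out$chrom,
                               IRanges::IRanges(out$start + 1L, out$end))
  S4Vectors::mcols(gr)$strength <- out$strength
  S4Vectors::mcols(gr)$source <- "consensus"
  S4Vectors::mcols(gr)$nMembers <- out$nMembers
  sort(gr)
}

# Encode boundary-covered bins as numeric keys chrom*stride + bin.
.boundaryBinKeys <- function(gr, chromIndex, binSize, stride) {
  if (!length(gr)) return(numeric(0))
  s <- GenomicRanges::start(gr) - 1L
  e <- GenomicRanges::end(gr)
  ci <- chromIndex[as.character(GenomicRanges::seqnames(gr))]
  keys <- unlist(lapply(seq_along(gr), function(k) {
    bins <- seq.int(floor(s[k] / binSize), ceiling(e[k] / binSize) - 1L)
    ci[k] * stride + bins
  }))
  unique(keys)
}

#' Shuffle-null test for the overlap of two boundary sets
#'
#' Discretizes the genome into bins, marks bins covered by each set, and
#' counts bins where both sets have a boundary (logical AND). The null
#' distribution comes from re-placing set `b` with
#' \code{\link{shuffleBoundaries}} `nShuffles` times; the z-score, a
#' two-sided normal-approximation p and the upper-tail empirical p are all
#' reported.
#'
#' @param a,b Boundary GRanges on the same assembly.
#' @param chromSizes Named numeric vector of chromosome sizes (bp).
#' @param nShuffles Number of shuffles (default 10,000).
#' @param binSize Bin width in bp.
#' @param seed Integer seed.
#' @return A \linkS4class{ShuffleNull}.
#' @export
boundaryOverlapTest <- function(a, b, chromSizes, nShuffles = 10000,
                                binSize = 25000, seed = NULL) {
  if (!length(a) || !length(b)) {
    return(new("ShuffleNull", observed = 0, nullMean = 0, nullSd = 0,
               z = NA_real_, pNormal = NA_real_, pEmpirical = 1,
               nShuffles = as.integer(nShuffles),
               seed = as.integer(if (is.null(seed)) NA else seed)))
  }
  chromIndex <- setNames(seq_along(chromSizes), names(chromSizes))
  stride <- 2^31
  aKeys <- .boundaryBinKeys(a, chromIndex, binSize, stride)
  observed <- sum(.boundaryBinKeys(b, chromIndex, binSize, stride) %in% aKeys)
  # per-chromosome geometry of b for the bin-level shuffle loop
  bChrom <- as.character(GenomicRanges::seqnames(b))
  geo <- lapply(split(seq_along(b), bChrom), function(ix) {
    wb <- as.integer(round(GenomicRanges::width(b)[ix] / binSize))
    list(k = length(ix), w = wb,
         off = sequence(wb) - 1L,
         rep = rep.int(seq_along(ix), wb))
  })
  nbins <- vapply(names(geo), function(ch) {
    as.integer(floor(chromSizes[[ch]] / binSize))
  }, integer(1))
  ci <- chromIndex[names(geo)]
  nulls <- .withSeed(seed, {
    vapply(seq_len(nShuffles), function(i) {
      keys <- unlist(lapply(seq_along(geo), function(g) {
        gg <- geo[[g]]
        starts <- if (length(unique(gg$w)) == 1L) {
          .placeNonOverlapping(gg$k, gg$w[1L], nbins[g])
        } else {
          .bpToBin(GenomicRanges::start(shuffleBoundaries(
            b[bChrom == names(geo)[g]], chromSizes, seed = NULL,
            binSize = binSize)) - 1, binSize) - 1L
        }
        ci[g] * stride + starts[gg$rep] + gg$off
      }), use.names = FALSE)
      sum(keys %in% aKeys)
    }, numeric(1))
  })
  shuffleNull(observed, nulls,
              seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Average feature profile around boundary centers
#'
#' Bins the feature per chromosome, then averages its per-bin level at
#' offsets \code{-flank..+flank} bins around each boundary center; an
#' analogous baseline from shuffled boundaries is computed when
#' `shuffles > 0`. Boundaries nearer than the flank to a chromosome end
#' contribute only where the offset is defined.
#'
#' @param bset Boundary GRanges.
#' @param feat Feature GRanges (e.g., CTCF or DNase sites); each interval
#'   counts once per bin it overlaps.
#' @param chromSizes Named numeric vector of chromosome sizes (bp).
#' @param flankBp Flank width in bp; multiple of `binSize`.
#' @param binSize Bin width in bp.
#' @param shuffles Number of shuffled boundary sets for the baseline.
#' @param seed Integer seed for the shuffles.
#' @return data.frame with columns offset (bp), observed, shuffled (NA when
#'   `shuffles = 0`).
#' @export
profileAroundBoundaries <- function(bset, feat, chromSizes, flankBp = 5e5,
                                    binSize = 25000, shuffles = 0L,
                                    seed = NULL) {
  if (flankBp %% binSize != 0) {
    stop("'flankBp' must be a multiple of binSize", call. = FALSE)
  }
  f <- as.integer(flankBp / binSize)
  counts <- lapply(names(chromSizes), function(ch) {
    nbins <- as.integer(floor(chromSizes[[ch]] / binSize))
    tiles <- GenomicRanges::GRanges(
      ch, IRanges::IRanges((seq_len(nbins) - 1L) * binSize + 1L,
                           seq_len(nbins) * binSize))
    GenomicRanges::countOverlaps(tiles, feat)
  })
  names(counts) <- names(chromSizes)
  profileOf <- function(gr) {
    sums <- numeric(2L * f + 1L)
    ns <- numeric(2L * f + 1L)
    ch <- as.character(GenomicRanges::seqnames(gr))
    centerBin <- .bpToBin(.grCenters(gr), binSize)
    for (k in seq_along(gr)) {
      vec <- counts[[ch[k]]]
      if (is.null(vec)) next
      off <- (-f):f
      pos <- centerBin[k] + off
      okk <- pos >= 1L & pos <= length(vec)
      sums[okk] <- sums[okk] + vec[pos[okk]]
      ns[okk] <- ns[okk] + 1L
    }
    ifelse(ns > 0, sums / ns, NA_real_)
  }
  observed <- profileOf(bset)
  shuffled <- rep(NA_real_, 2L * f + 1L)
  if (shuffles > 0L && length(bset)) {
    mats <- .withSeed(seed, {
      vapply(seq_len(shuffles), function(i) {
        profileOf(shuffleBoundaries(bset, chromSizes, seed = NULL,
                                    binSize = binSize))
      }, numeric(2L * f + 1L))
    })
    shuffled <- rowMeans(mats, na.rm = TRUE)
  }
  data.frame(offset = ((-f):f) * binSize, observed = observed,
             shuffled = shuffled)
}
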