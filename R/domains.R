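# Domains between consensus boundaries: chromatin-state coverage, k-means
# classification into five activity classes, flanking-domain pairs of
# BA-SVs, LAD overlap tests and per-class expression summaries.

#' The five domain classes, in increasing transcriptional activity
#' @return Character vector of the class names (activity ranks 0-4).
#' @export
domainClassNames <- function() {
  c("heterochromatin", "low", "repressed", "low-active", "active")
}

#' Default 15-state dictionary
#'
#' Maps each chromatin state (1..15, Roadmap-style numbering: promoter /
#' transcription / enhancer states first, heterochromatin 9, Polycomb 13-14,
#' quiescent 15) to one of \{active, quiescent, neutral\}. Used to name
#' k-means clusters by centroid composition. A custom dictionary can be
#' supplied to \code{\link{classifyDomains}} as a character vector of length
#' 15, or loaded from a two-column TSV (state, category) via
#' \code{\link{readStateDictionary}}.
#'
#' @return Character vector of length 15 with values in
#'   \{"active", "quiescent", "neutral"\}.
#' @export
defaultStateDictionary <- function() {
  readStateDictionary(system.file("extdata", "state_dictionary.tsv",
                                  package = "tadsv", mustWork = TRUE))
}

#' Read a state dictionary from TSV
#' @param path Two-column TSV (state index, category), with header.
#' @return Character vector indexed by state.
#' @export
readStateDictionary <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  out <- rep("neutral", max(df[[1]]))
  out[df[[1]]] <- df[[2]]
  bad <- setdiff(unique(out), c("active", "quiescent", "neutral"))
  if (length(bad)) {
    stop("state dictionary categories must be active/quiescent/neutral",
         call. = FALSE)
  }
  out
}

#' Domains between adjacent boundaries
#'
#' One domain per gap between two adjacent boundaries on the same
#' chromosome; the boundary intervals themselves are excluded, as are the
#' chromosome-terminal segments outside the first/last boundary.
#' Zero-length gaps (touching boundaries) are dropped.
#'
#' @param bset Boundary GRanges.
#' @param chromSizes Named numeric vector of chromosome sizes (bp); used
#'   only to note chromosomes with fewer than two boundaries.
#' @return GRanges of domains.
#' @export
domainsFromBoundaries <- function(bset, chromSizes = NULL) {
  bset <- sort(bset)
  chroms <- as.character(GenomicRanges::seqnames(bset))
  out <- lapply(unique(chroms), function(ch) {
    sub <- bset[chroms == ch]
    if (length(sub) < 2L) {
      message("chromosome ", ch, " has fewer than 2 boundaries; no domains")
      return(NULL)
    }
    s <- GenomicRanges::end(sub)[-length(sub)] + 1L
    e <- GenomicRanges::start(sub)[-1L] - 1L
    keep <- e >= s
    if (!any(keep)) return(NULL)
    GenomicRanges::GRanges(ch, IRanges::IRanges(s[keep], e[keep]))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(GenomicRanges::GRanges())
  suppressWarnings(sort(do.call(c, out)))
}

#' Chromatin-state coverage of domains
#'
#' For each domain, the fraction of its length covered by each of the 15
#' states. Gaps in the track are allowed (rows may sum to less than 1);
#' overlapping intervals of different states are a malformed track and an
#' error.
#'
#' @param domains GRanges of domains.
#' @param stateTrack GRanges with integer metadata column `state` (1..15).
#' @param nStates Number of states (default 15).
#' @return Numeric matrix, domains x states.
#' @export
stateCoverage <- function(domains, stateTrack, nStates = 15L) {
  st <- S4Vectors::mcols(stateTrack)$state
  if (is.null(st)) stop("stateTrack needs a 'state' column", call. = FALSE)
  if (any(st < 1L | st > nStates)) {
    stop("states must lie in 1..", nStates, call. = FALSE)
  }
  self <- GenomicRanges::findOverlaps(stateTrack, drop.self = TRUE,
                                      drop.redundant = TRUE)
  if (length(self) &&
      any(st[S4Vectors::queryHits(self)] !=
          st[S4Vectors::subjectHits(self)])) {
    stop("malformed state track: overlapping intervals of different states",
         call. = FALSE)
  }
  cov <- matrix(0, nrow = length(domains), ncol = nStates)
  hits <- GenomicRanges::findOverlaps(domains, stateTrack)
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(
      domains[S4Vectors::queryHits(hits)],
      stateTrack[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    dIdx <- S4Vectors::queryHits(hits)
    sIdx <- st[S4Vectors::subjectHits(hits)]
    for (k in seq_along(w)) {
      cov[dIdx[k], sIdx[k]] <- cov[dIdx[k], sIdx[k]] + w[k]
    }
  }
  cov / GenomicRanges::width(domains)
}

#' Classify domains into five activity classes by k-means
#'
#' Runs k-means (50 random restarts, best inertia, fixed seed) on the
#' state-coverage matrix, then names the k clusters by centroid
#' composition: centroids are ranked by (active-state mass minus
#' quiescent-state mass) under the state dictionary and assigned, in
#' increasing order, the names heterochromatin, low, repressed, low-active,
#' active (activity ranks 0-4). Naming is therefore invariant to cluster
#' index permutation.
#'
#' @param coverage Domains x states coverage matrix.
#' @param k Number of clusters (default 5; the class naming assumes 5).
#' @param seed Integer seed.
#' @param dictionary Character vector mapping state index to
#'   active/quiescent/neutral; default \code{\link{defaultStateDictionary}}.
#' @param nstart Number of k-means restarts.
#' @return A list of class `tadsv_domain_classes` with `class` (factor of
#'   class names per domain), `activityRank` (integer 0-4), `centers`
#'   (named centroid matrix), `clusterNames`, and `withinss`.
#' @export
classifyDomains <- function(coverage, k = 5L, seed = NULL,
                            dictionary = defaultStateDictionary(),
                            nstart = 50L) {
  coverage <- as.matrix(coverage)
  if (nrow(coverage) < k) {
    stop("need at least k domains to form k clusters", call. = FALSE)
  }
  if (nrow(unique(coverage)) < k) {
    stop("fewer than k distinct coverage rows; cannot form k clusters",
         call. = FALSE)
  }
  km <- if (nrow(coverage) == k) {
    # exactly k distinct rows: each is its own cluster
    list(cluster = seq_len(k), centers = coverage, tot.withinss = 0)
  } else {
    .withSeed(seed, kmeans(coverage, centers = k, nstart = nstart,
                           iter.max = 100L))
  }
  active <- which(dictionary[seq_len(ncol(coverage))] == "active")
  quies <- which(dictionary[seq_len(ncol(coverage))] == "quiescent")
  scoreOf <- rowSums(km$centers[, active, drop = FALSE]) -
    rowSums(km$centers[, quies, drop = FALSE])
  ord <- order(scoreOf)
  if (k == 5L) {
    nm <- domainClassNames()
  } else {
    nm <- paste0("class", seq_len(k))
  }
  clusterNames <- character(k)
  clusterNames[ord] <- nm
  cls <- factor(clusterNames[km$cluster], levels = nm)
  rank <- setNames(seq_along(nm) - 1L, nm)
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- nm
  structure(list(class = cls,
                 activityRank = unname(rank[as.character(cls)]),
                 centers = centers, clusterNames = clusterNames,
                 withinss = km$tot.withinss),
            class = "tadsv_domain_classes")
}

#' @export
print.tadsv_domain_classes <- function(x, ...) {
  cat("Domain classification (k-means):\n")
  print(table(x$class))
  invisible(x)
}

#' Assign coverage rows to the nearest existing centroid
#'
#' Used for shuffle nulls: domains re-derived from shuffled boundaries are
#' assigned to the observed centroids so the class definitions stay fixed
#' under the null.
#' @param coverage Domains x states matrix.
#' @param classes A `tadsv_domain_classes` object.
#' @return Factor of class names.
#' @export
assignToCentroids <- function(coverage, classes) {
  cen <- classes$centers
  d <- vapply(seq_len(nrow(cen)), function(k) {
    rowSums(sweep(coverage, 2L, cen[k, ], "-")^2)
  }, numeric(nrow(coverage)))
  if (nrow(coverage) == 1L) d <- matrix(d, nrow = 1L)
  factor(rownames(cen)[max.col(-d, ties.method = "first")],
         levels = rownames(cen))
}

# Nearest domain (by center, ties to the left) for bp positions.
.nearestDomainClass <- function(pos, chrom, domains, classVec) {
  dChrom <- as.character(GenomicRanges::seqnames(domains))
  dStart <- GenomicRanges::start(domains) - 1
  dEnd <- GenomicRanges::end(domains)
  dCenter <- (dStart + dEnd) / 2
  out <- rep(NA_character_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    dd <- which(dChrom == ch)
    if (!length(dd)) next
    for (i in sel) {
      p <- pos[i]
      inside <- dd[dStart[dd] <= p & dEnd[dd] > p]
      if (length(inside)) {
        out[i] <- as.character(classVec[inside[1L]])
      } else {
        dist <- abs(dCenter[dd] - p)
        best <- dd[which(dist == min(dist))]
        out[i] <- as.character(classVec[best[1L]])  # tie: leftmost
      }
    }
  }
  out
}

#' Flanking-domain class pairs of BA-SVs
#'
#' For each boundary-affecting SV, takes the class of the domain containing
#' (or nearest to, by center, ties left) each breakend and counts the
#' unordered class pair in a half-matrix. When `nShuffles > 0`, the
#' same-class diagonal count is compared against a null in which the
#' boundary set is shuffled, domains are re-derived, their state coverage
#' recomputed, and classes assigned to the observed centroids.
#'
#' @param ba A `tadsv_ba` object (see \code{\link{annotateBA}}).
#' @param boundaries Boundary GRanges that produced `domains`.
#' @param domains GRanges of domains.
#' @param classes `tadsv_domain_classes` for `domains`.
#' @param stateTrack State GRanges (needed when `nShuffles > 0`).
#' @param chromSizes Named chromosome sizes (bp).
#' @param nShuffles Number of boundary shuffles for the null (0 = skip).
#' @param seed Integer seed.
#' @return A list with `pairs` (5x5 symmetric count matrix), `nUsed`,
#'   `nSkipped` (SVs lacking a flank), and `sameClassNull`
#'   (\linkS4class{ShuffleNull} or NULL).
#' @export
flankingPairCounts <- function(ba, boundaries, domains, classes,
                               stateTrack = NULL, chromSizes = NULL,
                               nShuffles = 0L, seed = NULL) {
  nm <- levels(classes$class)
  svs <- ba$sv[S4Vectors::mcols(ba$sv)$isBA]
  countPairs <- function(doms, classVec) {
    m <- matrix(0L, length(nm), length(nm), dimnames = list(nm, nm))
    if (!length(svs)) return(list(pairs = m, used = 0L, skipped = 0L))
    ch <- as.character(GenomicRanges::seqnames(svs))
    left <- .nearestDomainClass(GenomicRanges::start(svs) - 1, ch,
                                doms, classVec)
    right <- .nearestDomainClass(GenomicRanges::end(svs), ch,
                                 doms, classVec)
    ok <- !is.na(left) & !is.na(right)
    for (i in which(ok)) {
      a <- match(left[i], nm)
      b <- match(right[i], nm)
      lo <- min(a, b)
      hi <- max(a, b)
      m[lo, hi] <- m[lo, hi] + 1L
      if (lo != hi) m[hi, lo] <- m[hi, lo] + 1L
    }
    list(pairs = m, used = sum(ok), skipped = sum(!ok))
  }
  obs <- countPairs(domains, classes$class)
  sameClassNull <- NULL
  if (nShuffles > 0L) {
    if (is.null(stateTrack) || is.null(chromSizes)) {
      stop("stateTrack and chromSizes are required for the shuffle null",
           call. = FALSE)
    }
    observedSame <- sum(diag(obs$pairs))
    nulls <- .withSeed(seed, {
      vapply(seq_len(nShuffles), function(s) {
        shb <- shuffleBoundaries(boundaries, chromSizes, seed = NULL)
        doms <- suppressMessages(domainsFromBoundaries(shb))
        if (!length(doms)) return(NA_real_)
        cv <- stateCoverage(doms, stateTrack, ncol(classes$centers))
        sum(diag(countPairs(doms, assignToCentroids(cv, classes))$pairs))
      }, numeric(1))
    })
    sameClassNull <- shuffleNull(observedSame, nulls[!is.na(nulls)],
                                 seed = if (is.null(seed)) NA_integer_
                                 else seed)
  }
  list(pairs = obs$pairs, nUsed = obs$used, nSkipped = obs$skipped,
       sameClassNull = sameClassNull)
}

#' LAD / inter-LAD overlap test for SV breakends
#'
#' Each SV is categorized by where its two breakends fall: both inside
#' constitutive LADs ("withinLAD"), both inside constitutive inter-LADs
#' ("withinInterLAD"), or one in each ("crossing"). SVs with a breakend in
#' a track gap, or on a chromosome absent from the track, are skipped with
#' a message. The null re-places each event uniformly on its own
#' chromosome, preserving its length, `nShuffles` times.
#'
#' @param svs GRanges of SV events.
#' @param lads GRanges with metadata `label` in \{"LAD", "interLAD"\}.
#' @param chromSizes Named chromosome sizes (bp).
#' @param nShuffles Number of shuffles (default 10,000).
#' @param seed Integer seed.
#' @return Nested list: per SV type, per category, a
#'   \linkS4class{ShuffleNull}; plus `counts`, the observed type x category
#'   table.
#' @export
ladOverlapTest <- function(svs, lads, chromSizes, nShuffles = 10000,
                           seed = NULL) {
  labs <- S4Vectors::mcols(lads)$label
  if (is.null(labs)) stop("LAD track needs a 'label' column", call. = FALSE)
  # per-chromosome breakpoint lookup: label of the interval containing a bp
  lookup <- lapply(names(chromSizes), function(ch) {
    sub <- lads[as.character(GenomicRanges::seqnames(lads)) == ch]
    if (!length(sub)) return(NULL)
    o <- order(GenomicRanges::start(sub))
    list(start = GenomicRanges::start(sub)[o] - 1,
         end = GenomicRanges::end(sub)[o],
         label = S4Vectors::mcols(sub)$label[o])
  })
  names(lookup) <- names(chromSizes)
  labelAt <- function(ch, pos) {
    lk <- lookup[[ch]]
    if (is.null(lk)) return(rep(NA_character_, length(pos)))
    i <- findInterval(pos, lk$start)
    out <- rep(NA_character_, length(pos))
    okk <- i >= 1L & i <= length(lk$start)
    okk[okk] <- pos[okk] < lk$end[i[okk]]
    out[okk] <- lk$label[i[okk]]
    out
  }
  categorize <- function(chrom, s, e) {
    a <- rep(NA_character_, length(s))
    for (ch in unique(chrom)) {
      sel <- chrom == ch
      la <- labelAt(ch, s[sel])
      lb <- labelAt(ch, e[sel] - 1)  # last bp inside the event
      cat <- rep(NA_character_, sum(sel))
      both <- !is.na(la) & !is.na(lb)
      cat[both & la == "LAD" & lb == "LAD"] <- "withinLAD"
      cat[both & la == "interLAD" & lb == "interLAD"] <- "withinInterLAD"
      cat[both & la != lb] <- "crossing"
      a[sel] <- cat
    }
    a
  }
  chrom <- as.character(GenomicRanges::seqnames(svs))
  s <- GenomicRanges::start(svs) - 1
  e <- GenomicRanges::end(svs)
  onTrack <- chrom %in% names(lookup)[
    !vapply(lookup, is.null, logical(1))]
  if (any(!onTrack)) {
    message("skipping ", sum(!onTrack), " SV(s) on chromosomes without ",
            "LAD calls")
  }
  types <- unique(S4Vectors::mcols(svs)$sv_type)
  cats <- c("withinLAD", "withinInterLAD", "crossing")
  obsCat <- categorize(chrom, s, e)
  counts <- table(factor(S4Vectors::mcols(svs)$sv_type, levels = types),
                  factor(obsCat, levels = cats))
  len <- e - s
  sizes <- unname(chromSizes[chrom])
  nullCounts <- .withSeed(seed, {
    lapply(seq_len(nShuffles), function(k) {
      ns <- floor(runif(length(svs)) * (sizes - len))
      table(factor(S4Vectors::mcols(svs)$sv_type, levels = types),
            factor(categorize(chrom, ns, ns + len), levels = cats))
    })
  })
  res <- lapply(types, function(tp) {
    perCat <- lapply(cats, function(cc) {
      nulls <- vapply(nullCounts, function(m) m[tp, cc], numeric(1))
      shuffleNull(counts[tp, cc], nulls,
                  seed = if (is.null(seed)) NA_integer_ else seed)
    })
    names(perCat) <- cats
    perCat
  })
  names(res) <- types
  c(res, list(counts = counts))
}

#' Per-class expression summary of domain-resident genes
#'
#' Assigns each gene to the domain containing its start, computes
#' log2 mean expression per gene across samples, and reports the median per
#' domain class plus a one-tailed Mann-Whitney test of each non-active
#' class against the active class (alternative: lower expression). Classes
#' with fewer than 3 genes are reported without a test.
#'
#' @param domains GRanges of domains.
#' @param classes `tadsv_domain_classes` for `domains`.
#' @param genes GRanges with `gene_id` metadata.
#' @param expression Gene x sample matrix (rownames = gene ids).
#' @return data.frame with columns class, nGenes, medianLog2, pVsActive.
#' @export
domainExpressionSummary <- function(domains, classes, genes, expression) {
  starts <- GenomicRanges::resize(genes, width = 1L, fix = "start",
                                  ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(starts, domains, select = "first")
  keep <- !is.na(hits) &
    S4Vectors::mcols(genes)$gene_id %in% rownames(expression)
  gid <- S4Vectors::mcols(genes)$gene_id[keep]
  cls <- classes$class[hits[keep]]
  expr <- log2(rowMeans(expression[gid, , drop = FALSE]))
  expr[!is.finite(expr)] <- NA_real_
  activeVals <- expr[!is.na(expr) & cls == "active"]
  out <- lapply(levels(classes$class), function(cn) {
    vals <- expr[!is.na(expr) & cls == cn]
    p <- NA_real_
    if (cn != "active" && length(vals) >= 3L && length(activeVals) >= 3L) {
      p <- wilcox.test(vals, activeVals, alternative = "less",
                       exact = FALSE)$p.value
    }
    data.frame(class = cn, nGenes = length(vals),
               medianLog2 = if (length(vals)) median(vals) else NA_real_,
               pVsActive = p)
  })
  do.call(rbind, out)
}
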