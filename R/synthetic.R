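# Generators for every pipeline input with known ground truth: block-TAD
# contact maps (optionally rearranged), cohort SV catalogs, chromatin-state
# and LAD tracks, gene models and expression/copy-number tables. All
# generators are pure functions of (parameters, seed).

#' Evenly spaced planted TAD boundaries
#'
#' Places `nPerChrom` 3-bin boundaries at even spacing (optionally
#' jittered) on each chromosome; these are the ground truth junctions the
#' contact-map generator builds TAD blocks between.
#'
#' @param chromSizes Named numeric vector of chromosome sizes (bp).
#' @param nPerChrom Boundaries per chromosome.
#' @param binSize Bin width in bp.
#' @param jitterBins Uniform jitter (+/- bins) applied to each center.
#' @param seed Integer seed (only used when `jitterBins > 0`).
#' @return GRanges of boundaries (`source` = "planted").
#' @export
plantedBoundaries <- function(chromSizes, nPerChrom = 9L, binSize = 25000,
                              jitterBins = 0L, seed = NULL) {
  .withSeed(seed, {
    out <- lapply(names(chromSizes), function(ch) {
      nbins <- as.integer(floor(chromSizes[[ch]] / binSize))
      centers <- round(nbins * seq_len(nPerChrom) / (nPerChrom + 1))
      if (jitterBins > 0L) {
        centers <- centers + sample(-jitterBins:jitterBins, nPerChrom,
                                    replace = TRUE)
      }
      centers <- pmin(pmax(centers, 2L), nbins - 1L)
      gr <- GenomicRanges::GRanges(
        ch, IRanges::IRanges((centers - 2L) * binSize + 1L,
                             (centers + 1L) * binSize))
      S4Vectors::mcols(gr)$strength <- 1
      S4Vectors::mcols(gr)$source <- "planted"
      gr
    })
    suppressWarnings(sort(do.call(c, out)))
  })
}

# TAD id per bin given boundary center bins
.tadIds <- function(nbins, centerBins) {
  findInterval(seq_len(nbins), sort(centerBins)) + 1L
}

# boundary center bins on one chromosome
.centerBins <- function(boundaries, ch, binSize) {
  sub <- boundaries[as.character(GenomicRanges::seqnames(boundaries)) == ch]
  .bpToBin(.grCenters(sub), binSize)
}

#' Simulate a block-TAD Hi-C contact map
#'
#' Expected contacts follow a power-law distance decay
#' \code{depth * d^(-alpha)} (d in bins) with a within-TAD enrichment
#' factor \code{1 + tau} for bin pairs in the same planted TAD; counts are
#' Poisson draws, symmetrized. The diagonal carries the d = 1 expectation
#' (it is excluded from all downstream statistics).
#'
#' @param chromSizes Named numeric vector of chromosome sizes (bp).
#' @param boundaries GRanges of planted boundaries (TAD junctions).
#' @param binSize Bin width in bp.
#' @param alpha Decay exponent (> 0).
#' @param tau Within-TAD enrichment (>= 0; 0 = no TAD structure).
#' @param depth Expected d = 1 background count.
#' @param maskFraction Fraction of bins randomly masked.
#' @param boostRegion Optional GRanges; bin pairs with both bins inside it
#'   have their expectation multiplied by `boostFactor`. This emulates the
#'   distance-matched contact elevation of a copy-number gain (a tandem
#'   duplication of copy ratio `boostFactor`).
#' @param boostFactor Multiplier for `boostRegion` pairs.
#' @param seed Integer seed; same seed gives a bit-identical map.
#' @return Named list of \linkS4class{ContactMatrix}, one per chromosome.
#' @export
simulateHiC <- function(chromSizes, boundaries, binSize = 25000,
                        alpha = 1, tau = 1, depth = 50,
                        maskFraction = 0, boostRegion = NULL,
                        boostFactor = 2, seed = NULL) {
  stopifnot(alpha > 0, tau >= 0, depth > 0)
  .withSeed(seed, {
    out <- lapply(names(chromSizes), function(ch) {
      n <- as.integer(floor(chromSizes[[ch]] / binSize))
      tad <- .tadIds(n, .centerBins(boundaries, ch, binSize))
      D <- abs(outer(seq_len(n), seq_len(n), "-"))
      D[D == 0L] <- 1L
      E <- depth * D^(-alpha) * (1 + tau * outer(tad, tad, "=="))
      if (!is.null(boostRegion)) {
        sel <- boostRegion[
          as.character(GenomicRanges::seqnames(boostRegion)) == ch]
        if (length(sel)) {
          inReg <- rep(FALSE, n)
          fpb <- .svFootprintBins(sel, binSize)
          for (r in seq_len(nrow(fpb))) {
            inReg[fpb[r, 1L]:min(n, fpb[r, 2L])] <- TRUE
          }
          both <- outer(inReg, inReg, "&")
          E[both] <- E[both] * boostFactor
        }
      }
      ut <- upper.tri(E, diag = TRUE)
      v <- matrix(0, n, n)
      v[ut] <- rpois(sum(ut), E[ut])
      v <- v + t(v)
      diag(v) <- diag(v) / 2
      mask <- rep(FALSE, n)
      if (maskFraction > 0) {
        mask[sample.int(n, round(maskFraction * n))] <- TRUE
      }
      ContactMatrix(ch, binSize, v, mask = mask)
    })
    names(out) <- names(chromSizes)
    out
  })
}

# bin footprint of an SV (bins overlapping [start, end), 1-based)
.svFootprintBins <- function(sv, binSize) {
  s <- GenomicRanges::start(sv) - 1
  e <- GenomicRanges::end(sv)
  cbind(floor(s / binSize) + 1L, floor((e - 1) / binSize) + 1L)
}

#' Simulate a rearranged Hi-C map in reference coordinates
#'
#' Builds the derived-chromosome bin map implied by the SVs (deletion
#' removes bins, tandem duplication repeats them, inversion reverses
#' them), re-derives TADs from the surviving planted boundaries, simulates
#' contacts on the derived genome with the same decay/TAD model as
#' \code{\link{simulateHiC}}, and projects every derived contact back to
#' reference bins, summing over duplicated copies. SVs must be
#' intra-chromosomal and non-overlapping.
#'
#' @param chromSize Length (bp) of the single chromosome simulated.
#' @param chrom Chromosome name.
#' @param boundaries GRanges of planted boundaries.
#' @param svs GRanges of DEL/DUP/INV events on `chrom`, non-overlapping.
#' @param binSize,alpha,tau,depth As in \code{\link{simulateHiC}}.
#' @param seed Integer seed.
#' @return A list with `matrix` (reference-coordinate
#'   \linkS4class{ContactMatrix}), `refMap` (derived bin -> reference bin)
#'   and `survivingCenters` (reference center bins of boundaries present
#'   on the derived chromosome).
#' @export
simulateRearrangedHiC <- function(chromSize, chrom = "chr1", boundaries,
                                  svs, binSize = 25000, alpha = 1,
                                  tau = 1, depth = 50, seed = NULL) {
  n <- as.integer(floor(chromSize / binSize))
  if (length(svs)) {
    if (any(as.character(GenomicRanges::seqnames(svs)) != chrom)) {
      stop("all SVs must lie on ", chrom, call. = FALSE)
    }
    o <- order(GenomicRanges::start(svs))
    svs <- svs[o]
    if (length(svs) > 1L &&
        any(GenomicRanges::start(svs)[-1L] <=
            GenomicRanges::end(svs)[-length(svs)])) {
      stop("nested or overlapping SVs are not supported", call. = FALSE)
    }
  }
  fp <- if (length(svs)) .svFootprintBins(svs, binSize) else
    matrix(integer(0), 0, 2)
  types <- if (length(svs)) S4Vectors::mcols(svs)$sv_type else character(0)
  if (any(!types %in% c("DEL", "DUP", "INV"))) {
    stop("rearranged-map simulation supports DEL, DUP and INV only",
         call. = FALSE)
  }
  refMap <- integer(0)
  pos <- 1L
  for (k in seq_along(types)) {
    lo <- fp[k, 1L]
    hi <- fp[k, 2L]
    if (pos < lo) refMap <- c(refMap, pos:(lo - 1L))
    seg <- lo:hi
    refMap <- c(refMap, switch(types[k],
                               DEL = integer(0),
                               DUP = c(seg, seg),
                               INV = rev(seg)))
    pos <- hi + 1L
  }
  if (pos <= n) refMap <- c(refMap, pos:n)
  m <- length(refMap)
  centers <- .centerBins(boundaries, chrom, binSize)
  derivedCenters <- which(refMap %in% centers)
  tad <- findInterval(seq_len(m), sort(derivedCenters)) + 1L
  .withSeed(seed, {
    D <- abs(outer(seq_len(m), seq_len(m), "-"))
    D[D == 0L] <- 1L
    E <- depth * D^(-alpha) * (1 + tau * outer(tad, tad, "=="))
    ut <- which(upper.tri(E, diag = TRUE), arr.ind = TRUE)
    counts <- rpois(nrow(ut), E[ut])
    ri <- refMap[ut[, 1L]]
    rj <- refMap[ut[, 2L]]
    lo <- pmin(ri, rj)
    hi <- pmax(ri, rj)
    key <- (lo - 1) * n + hi
    agg <- rowsum(counts, key)
    keys <- as.numeric(rownames(agg))
    v <- matrix(0, n, n)
    ii <- as.integer((keys - 1) %/% n) + 1L
    jj <- as.integer((keys - 1) %% n) + 1L
    v[cbind(ii, jj)] <- agg[, 1L]
    v[cbind(jj, ii)] <- agg[, 1L]
    # deleted bins have no contacts on the derived chromosome: masked
    list(matrix = ContactMatrix(chrom, binSize, v),
         refMap = refMap,
         survivingCenters = sort(unique(refMap[derivedCenters])))
  })
}

#' Closed-form chance that a uniformly placed SV spans a boundary
#'
#' For an event of length L placed uniformly on a chromosome chosen with
#' probability proportional to (size - L), the probability that its
#' footprint fully contains at least one boundary equals the length of the
#' union of the per-boundary valid-start intervals \code{[bEnd - L,
#' bStart]} divided by the number of possible starts.
#'
#' @param lengths Numeric vector of SV lengths (bp).
#' @param boundaries GRanges of boundaries.
#' @param chromSizes Named numeric vector of chromosome sizes (bp).
#' @return Numeric vector of probabilities, one per length.
#' @export
baChanceProbability <- function(lengths, boundaries, chromSizes) {
  bChrom <- as.character(GenomicRanges::seqnames(boundaries))
  vapply(lengths, function(L) {
    w <- pmax(0, unname(chromSizes) - L)
    if (sum(w) == 0) return(0)
    p <- vapply(seq_along(chromSizes), function(ci) {
      ch <- names(chromSizes)[ci]
      if (w[ci] <= 0) return(0)
      sub <- boundaries[bChrom == ch]
      if (!length(sub)) return(0)
      lo <- pmax(0, GenomicRanges::end(sub) - L)
      hi <- pmin(w[ci], GenomicRanges::start(sub) - 1)
      keep <- hi >= lo
      if (!any(keep)) return(0)
      ir <- IRanges::reduce(IRanges::IRanges(lo[keep] + 1, hi[keep] + 1))
      sum(IRanges::width(ir)) / w[ci]
    }, numeric(1))
    sum(p * w / sum(w))
  }, numeric(1))
}

#' Simulate a cohort SV catalog with controllable boundary enrichment
#'
#' Event counts per sample are Poisson, types follow `typeMix`, lengths
#' are log-uniform on `lenRange`, and placement is uniform except that a
#' fraction `enrichmentKnob` of events is forced to span a boundary
#' (negative values force avoidance instead). Ground-truth BA flags are
#' recorded.
#'
#' @param chromSizes Named numeric vector of chromosome sizes (bp).
#' @param boundaries GRanges of boundaries.
#' @param nSamples Number of samples.
#' @param meanPerSample Mean events per sample (Poisson).
#' @param typeMix Named probabilities over DEL/DUP/INV/COMPLEX.
#' @param lenRange Length range in bp (log-uniform).
#' @param enrichmentKnob In [-1, 1]: fraction of events forced to span
#'   (positive) or avoid (negative) boundaries; 0 = fully uniform.
#' @param targetFold Alternative to `enrichmentKnob`: plant a BA rate of
#'   `targetFold` times the geometric chance. The per-event forcing
#'   probability is derived from the closed form
#'   \code{\link{baChanceProbability}}: with chance p, forcing with
#'   probability p(f-1)/(1-p) yields rate f*p.
#' @param cohort Cohort label.
#' @param origin Event origin label ("somatic" or "germline").
#' @param seed Integer seed.
#' @return GRanges of events with metadata sample_id, cohort, sv_type,
#'   origin, forcedBA (placement mode) and isBA (ground truth).
#' @export
simulateSVCatalog <- function(chromSizes, boundaries, nSamples = 30L,
                              meanPerSample = 8,
                              typeMix = c(DEL = 0.4, DUP = 0.3, INV = 0.3),
                              lenRange = c(5e4, 2e6), enrichmentKnob = 0,
                              targetFold = NULL,
                              cohort = "cohort", origin = "somatic",
                              seed = NULL) {
  stopifnot(enrichmentKnob >= -1, enrichmentKnob <= 1)
  if (!is.null(targetFold) && targetFold < 1) {
    stop("'targetFold' must be >= 1", call. = FALSE)
  }
  bChrom <- as.character(GenomicRanges::seqnames(boundaries))
  bStart <- GenomicRanges::start(boundaries) - 1
  bEnd <- GenomicRanges::end(boundaries)
  isBAOf <- function(ch, s, e) {
    sel <- bChrom == ch
    any(bStart[sel] >= s & bEnd[sel] <= e)
  }
  .withSeed(seed, {
    rows <- list()
    for (smp in seq_len(nSamples)) {
      nEv <- rpois(1L, meanPerSample)
      if (!nEv) next
      for (ev in seq_len(nEv)) {
        tp <- sample(names(typeMix), 1L, prob = typeMix)
        L <- round(exp(runif(1L, log(lenRange[1]), log(lenRange[2]))))
        wts <- pmax(0, unname(chromSizes) - L)
        ch <- sample(names(chromSizes), 1L, prob = wts)
        G <- chromSizes[[ch]]
        u <- runif(1L)
        forceProb <- if (!is.null(targetFold)) {
          p <- baChanceProbability(L, boundaries, chromSizes)
          min(1, p * (targetFold - 1) / max(1e-12, 1 - p))
        } else {
          enrichmentKnob
        }
        forced <- if (forceProb > 0 && u < forceProb) {
          "span"
        } else if (forceProb < 0 && u < -forceProb) {
          "avoid"
        } else "uniform"
        s <- NA_real_
        if (forced == "span") {
          sel <- which(bChrom == ch & bEnd - bStart <= L &
                         pmax(0, bEnd - L) <= pmin(G - L, bStart))
          if (length(sel)) {
            b <- if (length(sel) == 1L) sel else sample(sel, 1L)
            s <- floor(runif(1L, max(0, bEnd[b] - L),
                             min(G - L, bStart[b]) + 1))
          } else {
            forced <- "uniform"
          }
        }
        if (forced == "avoid") {
          placed <- FALSE
          for (try in seq_len(1000L)) {
            s <- floor(runif(1L, 0, G - L + 1))
            if (!isBAOf(ch, s, s + L)) {
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            stop("could not place a boundary-avoiding event after 1000 ",
                 "attempts", call. = FALSE)
          }
        }
        if (forced == "uniform" && is.na(s)) {
          s <- floor(runif(1L, 0, G - L + 1))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = s, end = s + L,
          sample_id = sprintf("s%03d", smp), sv_type = tp,
          forcedBA = forced, isBA = isBAOf(ch, s, s + L),
          stringsAsFactors = FALSE)
      }
    }
    df <- do.call(rbind, rows)
    gr <- svEvents(df$chrom, df$start, df$end, df$sample_id,
                   cohort = cohort, sv_type = df$sv_type, origin = origin)
    S4Vectors::mcols(gr)$forcedBA <- df$forcedBA
    S4Vectors::mcols(gr)$isBA <- df$isBA
    gr
  })
}

#' State-composition archetypes of the five domain classes
#'
#' Rows are the classes in activity order; columns the 15 chromatin states
#' (active promoter/transcription/enhancer states 1-7, heterochromatin 9,
#' Polycomb 13-14, quiescent 15). Used as multinomial frequencies by
#' \code{\link{simulateStateTrack}}.
#' @return 5 x 15 numeric matrix, rows summing to 1.
#' @export
classArchetypes <- function() {
  a <- matrix(0, 5, 15, dimnames = list(domainClassNames(), NULL))
  a["heterochromatin", c(9, 15, 14)] <- c(0.65, 0.30, 0.05)
  a["low", c(15, 5, 14)] <- c(0.80, 0.05, 0.15)
  a["repressed", c(13, 14, 15, 1, 10)] <- c(0.45, 0.30, 0.15, 0.05, 0.05)
  a["low-active", c(5, 7, 15, 14, 4, 9)] <-
    c(0.30, 0.10, 0.25, 0.25, 0.05, 0.05)
  a["active", c(1, 2, 4, 5, 6, 7, 15, 8)] <-
    c(0.15, 0.05, 0.30, 0.20, 0.05, 0.15, 0.05, 0.05)
  a
}

#' Simulate a 15-state chromatin track over planted domains
#'
#' Each domain is tiled into `segmentBp` segments whose states are drawn
#' from a Dirichlet-perturbed copy of its class archetype; regions outside
#' domains (boundaries, chromosome ends) are quiescent (state 15).
#'
#' @param domains GRanges of domains.
#' @param classVec Factor/character of planted class per domain.
#' @param chromSizes Named numeric vector of chromosome sizes (bp).
#' @param archetypes Class x state frequency matrix.
#' @param segmentBp Segment size in bp.
#' @param concentration Dirichlet concentration (higher = closer to the
#'   archetype).
#' @param seed Integer seed.
#' @return GRanges with integer metadata `state`.
#' @export
simulateStateTrack <- function(domains, classVec, chromSizes,
                               archetypes = classArchetypes(),
                               segmentBp = 25000, concentration = 60,
                               seed = NULL) {
  classVec <- as.character(classVec)
  .withSeed(seed, {
    rows <- list()
    for (k in seq_along(domains)) {
      ch <- as.character(GenomicRanges::seqnames(domains))[k]
      s <- GenomicRanges::start(domains)[k] - 1
      e <- GenomicRanges::end(domains)[k]
      arch <- archetypes[classVec[k], ]
      g <- rgamma(length(arch), shape = concentration * arch + 1e-6)
      p <- g / sum(g)
      cuts <- unique(c(seq(s, e, by = segmentBp), e))
      nSeg <- length(cuts) - 1L
      st <- sample.int(length(p), nSeg, replace = TRUE, prob = p)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = cuts[-length(cuts)], end = cuts[-1L],
        state = st, stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    # fill non-domain genome with quiescent state
    gapRows <- list()
    for (ch in names(chromSizes)) {
      sub <- df[df$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      edges <- c(0, as.vector(rbind(sub$start, sub$end)),
                 unname(chromSizes[[ch]]))
      gs <- edges[seq(1, length(edges), by = 2)]
      ge <- edges[seq(2, length(edges), by = 2)]
      keep <- ge > gs
      if (any(keep)) {
        gapRows[[length(gapRows) + 1L]] <- data.frame(
          chrom = ch, start = gs[keep], end = ge[keep], state = 15L,
          stringsAsFactors = FALSE)
      }
    }
    df <- rbind(df, do.call(rbind, gapRows))
    out <- GenomicRanges::GRanges(df$chrom,
                                  IRanges::IRanges(df$start + 1, df$end))
    S4Vectors::mcols(out)$state <- as.integer(df$state)
    sort(out)
  })
}

#' Simulate a constitutive LAD / inter-LAD track
#'
#' Alternating LAD and inter-LAD intervals with log-normal-ish lengths
#' covering each chromosome end to end.
#'
#' @param chromSizes Named numeric vector of chromosome sizes (bp).
#' @param meanLen Mean interval length in bp.
#' @param seed Integer seed.
#' @return GRanges with metadata `label` in \{"LAD", "interLAD"\}.
#' @export
simulateLADTrack <- function(chromSizes, meanLen = 2e6, seed = NULL) {
  .withSeed(seed, {
    rows <- list()
    for (ch in names(chromSizes)) {
      pos <- 0
      lab <- sample(c("LAD", "interLAD"), 1L)
      while (pos < chromSizes[[ch]]) {
        len <- round(runif(1L, 0.5, 1.5) * meanLen)
        e <- min(pos + len, chromSizes[[ch]])
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = pos, end = e, label = lab,
          stringsAsFactors = FALSE)
        pos <- e
        lab <- if (lab == "LAD") "interLAD" else "LAD"
      }
    }
    df <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$start + 1, df$end))
    S4Vectors::mcols(gr)$label <- df$label
    gr
  })
}

#' Simulate gene models
#'
#' Genes placed uniformly with uniform lengths; identifiers g0001, ...
#'
#' @param chromSizes Named numeric vector of chromosome sizes (bp).
#' @param nGenes Number of genes.
#' @param lenRange Gene length range in bp.
#' @param seed Integer seed.
#' @return GRanges with metadata `gene_id`.
#' @export
simulateGenes <- function(chromSizes, nGenes = 300L,
                          lenRange = c(5e3, 1e5), seed = NULL) {
  .withSeed(seed, {
    wts <- unname(chromSizes) / sum(chromSizes)
    ch <- sample(names(chromSizes), nGenes, replace = TRUE, prob = wts)
    len <- round(runif(nGenes, lenRange[1], lenRange[2]))
    maxS <- unname(chromSizes[ch]) - len
    s <- floor(runif(nGenes, 0, maxS + 1))
    o <- order(ch, s)
    gr <- GenomicRanges::GRanges(
      ch[o], IRanges::IRanges(s[o] + 1, s[o] + len[o]),
      strand = sample(c("+", "-"), nGenes, replace = TRUE))
    S4Vectors::mcols(gr)$gene_id <- sprintf("g%04d", seq_len(nGenes))
    gr
  })
}

#' Simulate expression and copy-number tables
#'
#' Each gene's baseline is the median expression of its domain class
#' (genes outside domains use the "low" baseline); per-sample values are
#' log-normal around the baseline with coefficient of variation `cv`.
#' Planted effects multiply specific (gene, sample) cells by their fold.
#' Copy numbers are 2 except for a random aberrant fraction.
#'
#' @param genes GRanges with `gene_id`.
#' @param samples Character vector of sample ids.
#' @param domains,classVec Optional domain GRanges and planted classes for
#'   class-dependent baselines.
#' @param classMeans Named baseline expression per class (RPKM-like).
#' @param cv Log-normal coefficient of variation.
#' @param effects Optional data.frame(gene, sample, fold) of planted
#'   effects.
#' @param aberrantCNFrac Fraction of CN entries drawn from \{0,1,3,5,6\}.
#' @param seed Integer seed.
#' @return A list with `expression` and `cn` (gene x sample matrices).
#' @export
simulateExpression <- function(genes, samples, domains = NULL,
                               classVec = NULL,
                               classMeans = c(heterochromatin = 0.5,
                                              low = 1, repressed = 2,
                                              `low-active` = 8,
                                              active = 32),
                               cv = 0.3, effects = NULL,
                               aberrantCNFrac = 0.02, seed = NULL) {
  gid <- S4Vectors::mcols(genes)$gene_id
  base <- rep(classMeans[["low"]], length(genes))
  if (!is.null(domains) && !is.null(classVec)) {
    starts <- GenomicRanges::resize(genes, width = 1L, fix = "start",
                                    ignore.strand = TRUE)
    hit <- GenomicRanges::findOverlaps(starts, domains, select = "first")
    okk <- !is.na(hit)
    base[okk] <- classMeans[as.character(classVec)[hit[okk]]]
  }
  sdlog <- sqrt(log(1 + cv^2))
  .withSeed(seed, {
    expr <- matrix(
      base * exp(rnorm(length(genes) * length(samples), 0, sdlog)),
      nrow = length(genes), dimnames = list(gid, samples))
    if (!is.null(effects) && nrow(effects)) {
      for (k in seq_len(nrow(effects))) {
        expr[effects$gene[k], effects$sample[k]] <-
          expr[effects$gene[k], effects$sample[k]] * effects$fold[k]
      }
    }
    cn <- matrix(2, nrow = length(genes), ncol = length(samples),
                 dimnames = list(gid, samples))
    nAb <- round(aberrantCNFrac * length(cn))
    if (nAb > 0) {
      cn[sample.int(length(cn), nAb)] <-
        sample(c(0, 1, 3, 5, 6), nAb, replace = TRUE)
    }
    list(expression = expr, cn = cn)
  })
}
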