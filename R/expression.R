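# Breakend-flanking gene identification, cohort-relative expression fold
# changes with filtering, and group comparisons.

#' Nearest non-overlapping genes flanking each SV
#'
#' The upstream gene is the nearest gene lying wholly left of the SV start;
#' the downstream gene is the nearest lying wholly right of the SV end.
#' Genes overlapping either breakend are excluded from candidacy (a gene
#' straddling a breakend is neither upstream nor downstream). Equidistant
#' candidates are broken toward the smaller start coordinate.
#'
#' @param svs GRanges of SV events.
#' @param genes GRanges with `gene_id` metadata.
#' @return data.frame with one row per SV: upGene, upDist, downGene,
#'   downDist (NA where no flank exists). Distances are bp from the
#'   breakend to the gene's nearest edge.
#' @export
nearestFlankGenes <- function(svs, genes) {
  gChrom <- as.character(GenomicRanges::seqnames(genes))
  gStart <- GenomicRanges::start(genes) - 1
  gEnd <- GenomicRanges::end(genes)
  gid <- S4Vectors::mcols(genes)$gene_id
  out <- data.frame(upGene = rep(NA_character_, length(svs)),
                    upDist = NA_real_, downGene = NA_character_,
                    downDist = NA_real_)
  chrom <- as.character(GenomicRanges::seqnames(svs))
  s <- GenomicRanges::start(svs) - 1
  e <- GenomicRanges::end(svs)
  for (ch in unique(chrom)) {
    gi <- which(gChrom == ch)
    if (!length(gi)) next
    for (i in which(chrom == ch)) {
      up <- gi[gEnd[gi] <= s[i]]
      if (length(up)) {
        d <- s[i] - gEnd[up]
        best <- up[d == min(d)]
        best <- best[which.min(gStart[best])]
        out$upGene[i] <- gid[best]
        out$upDist[i] <- s[i] - gEnd[best]
      }
      dn <- gi[gStart[gi] >= e[i]]
      if (length(dn)) {
        d <- gStart[dn] - e[i]
        best <- dn[d == min(d)]
        best <- best[which.min(gStart[best])]
        out$downGene[i] <- gid[best]
        out$downDist[i] <- gStart[best] - e[i]
      }
    }
  }
  out
}

#' Cohort-relative expression fold change for one gene in one sample
#'
#' fc = expression(gene, sample) / mean expression of the gene over the
#' other samples of the same cohort.
#'
#' @param expression Gene x sample matrix.
#' @param gene Gene id (rowname).
#' @param sample Sample id (colname).
#' @param cohortSamples Character vector of the cohort's sample ids
#'   (defaults to all columns).
#' @return Numeric fold change; NA when the others' mean is zero.
#' @examples
#' m <- matrix(c(6, 1, 2, 3), 1, dimnames = list("g", paste0("s", 1:4)))
#' foldChange(m, "g", "s1")  # 3
#' @export
foldChange <- function(expression, gene, sample,
                       cohortSamples = colnames(expression)) {
  others <- setdiff(cohortSamples, sample)
  if (!length(others)) {
    stop("cohort must contain at least 2 samples", call. = FALSE)
  }
  denom <- mean(expression[gene, others])
  if (is.na(denom) || denom == 0) return(NA_real_)
  unname(expression[gene, sample] / denom)
}

#' Fold-change records for the flanking genes of BA-SVs
#'
#' For every boundary-affecting SV, finds the nearest upstream and
#' downstream genes and computes each gene's cohort-relative fold change in
#' the SV's sample. When `domains` and `classes` are supplied, each record
#' is annotated with the relation of the opposite flank's domain class to
#' the gene's own flank ("to-more-active", "to-less-active", "same-class").
#'
#' @param ba A `tadsv_ba` object from \code{\link{annotateBA}}.
#' @param genes GRanges with `gene_id` metadata.
#' @param expression Gene x sample matrix.
#' @param domains,classes Optional domain GRanges and
#'   `tadsv_domain_classes` for flank-relation annotation.
#' @return data.frame of records: svIndex, sample, cohort, gene, side,
#'   distance, fc, log2fc, flankRelation, filteredReason (empty string;
#'   see \code{\link{applyExpressionFilters}}).
#' @export
expressionFoldChanges <- function(ba, genes, expression, domains = NULL,
                                  classes = NULL) {
  svs <- ba$sv
  isBA <- S4Vectors::mcols(svs)$isBA
  svIdx <- which(isBA)
  if (!length(svIdx)) {
    return(data.frame(svIndex = integer(0), sample = character(0),
                      cohort = character(0), gene = character(0),
                      side = character(0), distance = numeric(0),
                      fc = numeric(0), log2fc = numeric(0),
                      flankRelation = character(0),
                      filteredReason = character(0)))
  }
  flanks <- nearestFlankGenes(svs[svIdx], genes)
  mc <- S4Vectors::mcols(svs)
  sampleOf <- mc$sample_id
  cohortOf <- mc$cohort
  # activity rank of the domain flanking each breakend
  leftRank <- rightRank <- rep(NA_integer_, length(svIdx))
  if (!is.null(domains) && !is.null(classes)) {
    ch <- as.character(GenomicRanges::seqnames(svs[svIdx]))
    rk <- setNames(seq_along(levels(classes$class)) - 1L,
                   levels(classes$class))
    left <- .nearestDomainClass(GenomicRanges::start(svs[svIdx]) - 1, ch,
                                domains, classes$class)
    right <- .nearestDomainClass(GenomicRanges::end(svs[svIdx]), ch,
                                 domains, classes$class)
    leftRank <- unname(rk[left])
    rightRank <- unname(rk[right])
  }
  relationOf <- function(own, other) {
    if (is.na(own) || is.na(other)) return(NA_character_)
    if (other > own) "to-more-active"
    else if (other < own) "to-less-active"
    else "same-class"
  }
  rows <- list()
  for (k in seq_along(svIdx)) {
    i <- svIdx[k]
    # the expression table is the cohort: every column is a cohort sample
    coSamples <- colnames(expression)
    for (side in c("upstream", "downstream")) {
      g <- if (side == "upstream") flanks$upGene[k] else flanks$downGene[k]
      d <- if (side == "upstream") flanks$upDist[k] else flanks$downDist[k]
      if (is.na(g) || !(g %in% rownames(expression))) next
      if (!(sampleOf[i] %in% colnames(expression))) next
      fc <- foldChange(expression, g, sampleOf[i], coSamples)
      rel <- if (side == "upstream") {
        relationOf(leftRank[k], rightRank[k])
      } else {
        relationOf(rightRank[k], leftRank[k])
      }
      rows[[length(rows) + 1L]] <- data.frame(
        svIndex = i, sample = sampleOf[i], cohort = cohortOf[i],
        gene = g, side = side, distance = d, fc = fc,
        log2fc = log2(fc), flankRelation = rel,
        filteredReason = if (is.na(fc)) "zero-denominator" else "",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(svIndex = integer(0), sample = character(0),
                      cohort = character(0), gene = character(0),
                      side = character(0), distance = numeric(0),
                      fc = numeric(0), log2fc = numeric(0),
                      flankRelation = character(0),
                      filteredReason = character(0)))
  }
  do.call(rbind, rows)
}

#' Filter fold-change records
#'
#' Applies the three record filters: (1) cohort-mean expression of the gene
#' below `fpkmMin` (strict; exactly 0.1 is kept); (2) copy number above
#' `cnMax` in that sample for either flanking gene of the SV (strict;
#' exactly 4 is kept); (3) breakend-to-gene distance above `maxDist`
#' (strict; exactly 1 Mb is kept). Filters are independent predicates, so
#' their order cannot change the retained set; the first matching reason is
#' recorded. A missing copy-number entry is treated as diploid (CN = 2)
#' with a warning.
#'
#' @param records data.frame from \code{\link{expressionFoldChanges}}.
#' @param expression Gene x sample matrix.
#' @param cnTable Gene x sample copy-number matrix (may be NULL to skip the
#'   CN filter).
#' @param fpkmMin,cnMax,maxDist Filter thresholds.
#' @return The records with `filteredReason` filled; retained records have
#'   an empty reason.
#' @export
applyExpressionFilters <- function(records, expression, cnTable = NULL,
                                   fpkmMin = 0.1, cnMax = 4,
                                   maxDist = 1e6) {
  if (!nrow(records)) return(records)
  reason <- records$filteredReason
  cohortMean <- vapply(records$gene, function(g) {
    mean(expression[g, ])
  }, numeric(1))
  low <- reason == "" & cohortMean < fpkmMin
  reason[low] <- "low-expression"
  if (!is.null(cnTable)) {
    cnOf <- function(g, s) {
      if (!(g %in% rownames(cnTable)) || !(s %in% colnames(cnTable))) {
        warning("missing copy-number entry for ", g, "/", s,
                "; assuming CN = 2", call. = FALSE)
        return(2)
      }
      cnTable[g, s]
    }
    # CN applies per SV: drop both flanks when either gene is amplified
    for (i in unique(records$svIndex)) {
      sel <- records$svIndex == i
      cns <- mapply(cnOf, records$gene[sel], records$sample[sel])
      if (any(cns > cnMax)) {
        reason[sel & reason == ""] <- "high-copy-number"
      }
    }
  }
  far <- reason == "" & records$distance > maxDist
  reason[far] <- "distal"
  records$filteredReason <- reason
  records
}

#' One-tailed Mann-Whitney comparison of two record groups
#'
#' Tests whether log2 fold changes of group A (records with
#' `flankRelation == groupA`) exceed those of group B. Exact test when both
#' groups have at most 20 records and no ties; tie-corrected normal
#' approximation otherwise.
#'
#' @param records Filtered records (rows with empty `filteredReason` are
#'   used).
#' @param groupA,groupB Values of `flankRelation` defining the groups.
#' @return A list with `p`, `nA`, `nB`, `medianA`, `medianB`, `shift`
#'   (median difference of log2fc).
#' @export
groupTest <- function(records, groupA, groupB) {
  kept <- records[records$filteredReason == "" & !is.na(records$fc), ,
                  drop = FALSE]
  a <- kept$log2fc[kept$flankRelation == groupA]
  b <- kept$log2fc[kept$flankRelation == groupB]
  if (length(a) < 3L) {
    stop("group '", groupA, "' has fewer than 3 records", call. = FALSE)
  }
  if (length(b) < 3L) {
    stop("group '", groupB, "' has fewer than 3 records", call. = FALSE)
  }
  exact <- length(a) <= 20L && length(b) <= 20L &&
    !any(duplicated(c(a, b)))
  wt <- wilcox.test(a, b, alternative = "greater", exact = exact,
                    correct = TRUE)
  list(p = wt$p.value, nA = length(a), nB = length(b),
       medianA = median(a), medianB = median(b),
       shift = median(a) - median(b))
}

#' Fraction of events with a more-than-twofold expression change
#'
#' Strict in both directions: fc > 2 or fc < 0.5; exactly twofold does not
#' count. With `per = "sv"` (default), an SV counts once and qualifies when
#' any of its flank-gene records exceeds twofold; with `per = "record"`,
#' each retained record counts separately.
#'
#' @param records Filtered fold-change records.
#' @param per "sv" or "record".
#' @return Fraction in [0, 1].
#' @export
twofoldFraction <- function(records, per = c("sv", "record")) {
  per <- match.arg(per)
  kept <- records[records$filteredReason == "" & !is.na(records$fc), ,
                  drop = FALSE]
  if (!nrow(kept)) stop("no retained records", call. = FALSE)
  hit <- kept$fc > 2 | kept$fc < 0.5
  if (per == "record") return(mean(hit))
  mean(vapply(split(hit, kept$svIndex), any, logical(1)))
}
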