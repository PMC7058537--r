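# End-to-end orchestration: write a complete synthetic input bundle and run
# the analysis stages over it, producing deterministic TSV/BED outputs and a
# run manifest.

#' Write a complete synthetic input bundle
#'
#' Generates and writes every pipeline input with known ground truth:
#' per-cell-type contact matrices over shared-plus-private planted
#' boundaries, a rearranged tumor matrix with a boundary-deleting event, a
#' cohort SV catalog, a germline deletion set, chromatin-state, LAD and
#' gene tracks, and expression/copy-number tables. Ground truth goes in a
#' `truth/` subdirectory.
#'
#' @param dir Output directory (created).
#' @param chromSizes Named numeric vector (default two 20-Mb chromosomes).
#' @param binSize Bin width in bp.
#' @param cellTypes Cell-type labels for the boundary-calling matrices.
#' @param nBoundaries Shared planted boundaries per chromosome.
#' @param nPrivate Private (cell-type-specific) boundaries per chromosome.
#' @param depth,alpha,tau Contact-map model parameters.
#' @param nSamples Cohort size for the SV catalog.
#' @param seed Root seed; every stage derives its own stream from it.
#' @return Invisibly, a list of written paths plus the truth objects.
#' @export
simulateBundle <- function(dir, chromSizes = c(chr1 = 2e7, chr2 = 2e7),
                           binSize = 25000,
                           cellTypes = c("ctA", "ctB", "ctC", "ctD", "ctE"),
                           nBoundaries = 9L, nPrivate = 2L, depth = 50,
                           alpha = 1, tau = 1, nSamples = 30L, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  shared <- plantedBoundaries(chromSizes, nBoundaries, binSize)
  paths <- list()
  # per-cell-type maps: shared boundaries plus a few private ones
  for (ct in cellTypes) {
    priv <- plantedBoundaries(chromSizes, nPrivate, binSize,
                              jitterBins = 60L,
                              seed = .deriveSeed(seed, paste0("priv", ct)))
    bnd <- sort(c(shared, priv))
    mats <- simulateHiC(chromSizes, bnd, binSize, alpha, tau, depth,
                        seed = .deriveSeed(seed, paste0("hic", ct)))
    for (ch in names(mats)) {
      coo <- file.path(dir, sprintf("matrix_%s_%s.coo", ct, ch))
      writeContactMatrix(mats[[ch]], coo,
                         file.path(dir, sprintf("bins_%s.bed", ch)))
      paths[[sprintf("matrix_%s_%s", ct, ch)]] <- coo
    }
    writeBoundaries(bnd, file.path(dir, "truth",
                                   sprintf("boundaries_%s.bed", ct)))
  }
  writeBoundaries(shared, file.path(dir, "truth", "consensus.bed"))
  # rearranged tumor map on chr1: the tumor cell line has its own, denser
  # TAD landscape (500-kb domains) and one deletion fusing two of them
  tumorB <- plantedBoundaries(chromSizes["chr1"],
                              nPerChrom = as.integer(
                                chromSizes[["chr1"]] / 5e5) - 1L,
                              binSize = binSize)
  target <- tumorB[ceiling(length(tumorB) / 2)]
  center <- round(.grCenters(target) / binSize) * binSize
  fusionSV <- svEvents("chr1", center - 2.5e5, center + 2.5e5, "tumor1",
                       cohort = "cellline", sv_type = "DEL")
  rear <- simulateRearrangedHiC(chromSizes[["chr1"]], "chr1", tumorB,
                                fusionSV, binSize, alpha, tau, depth,
                                seed = .deriveSeed(seed, "rearranged"))
  writeContactMatrix(rear$matrix, file.path(dir, "matrix_tumor_chr1.coo"),
                     file.path(dir, "bins_chr1.bed"))
  writeSVTable(fusionSV, file.path(dir, "tumor_sv.tsv"))
  writeBoundaries(tumorB, file.path(dir, "tumor_boundaries.bed"))
  # cohort SV catalog (mild planted enrichment) and germline deletions
  svs <- simulateSVCatalog(chromSizes, shared, nSamples = nSamples,
                           enrichmentKnob = 0.1,
                           seed = .deriveSeed(seed, "svs"))
  writeSVTable(svs, file.path(dir, "svs.tsv"))
  truthSV <- data.frame(index = seq_along(svs),
                        forcedBA = S4Vectors::mcols(svs)$forcedBA,
                        isBA = S4Vectors::mcols(svs)$isBA)
  write.table(truthSV, file.path(dir, "truth", "sv_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  germ <- simulateSVCatalog(chromSizes, shared, nSamples = 40L,
                            typeMix = c(DEL = 1),
                            lenRange = c(6e4, 3e5), enrichmentKnob = -0.5,
                            cohort = "population", origin = "germline",
                            seed = .deriveSeed(seed, "germline"))
  writeSVTable(germ, file.path(dir, "germline_dels.tsv"))
  # domains from the shared boundaries; planted classes round-robin
  domains <- suppressMessages(domainsFromBoundaries(shared, chromSizes))
  classVec <- factor(domainClassNames()[
    (seq_along(domains) - 1L) %% 5L + 1L],
    levels = domainClassNames())
  states <- simulateStateTrack(domains, classVec, chromSizes,
                               seed = .deriveSeed(seed, "states"))
  df <- .grToBed(states)
  df$state <- S4Vectors::mcols(states)$state
  write.table(df, file.path(dir, "states.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(data.frame(index = seq_along(domains),
                         class = as.character(classVec)),
              file.path(dir, "truth", "domain_classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  lads <- simulateLADTrack(chromSizes, seed = .deriveSeed(seed, "lads"))
  df <- .grToBed(lads)
  df$label <- S4Vectors::mcols(lads)$label
  write.table(df, file.path(dir, "lads.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  genes <- simulateGenes(chromSizes, seed = .deriveSeed(seed, "genes"))
  df <- .grToBed(genes)
  df$name <- S4Vectors::mcols(genes)$gene_id
  df$score <- 0L
  df$strand <- as.character(GenomicRanges::strand(genes))
  write.table(df, file.path(dir, "genes.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  samples <- sprintf("s%03d", seq_len(nSamples))
  tabs <- simulateExpression(genes, samples, domains, classVec,
                             seed = .deriveSeed(seed, "expression"))
  writeGeneSampleTable(tabs$expression, file.path(dir, "expression.tsv"))
  writeGeneSampleTable(tabs$cn, file.path(dir, "cn.tsv"))
  manifest <- list(dir = dir, chromSizes = chromSizes, binSize = binSize,
                   cellTypes = cellTypes, seed = seed,
                   boundaries = shared, domains = domains,
                   classVec = classVec, fusionSV = fusionSV)
  invisible(manifest)
}

.stageOrder <- c("boundaries", "consensus", "sv", "domains",
                 "expression", "fusion")

#' Run the TAD-disruption pipeline over an input bundle
#'
#' Executes the requested stages in dependency order (boundaries ->
#' consensus -> sv -> domains -> expression -> fusion) over the files of a
#' \code{\link{simulateBundle}}-layout directory, writing TSV/BED outputs
#' to `outDir`. Outputs are deterministic: two runs with the same inputs,
#' configuration and seed are byte-identical.
#'
#' @param bundleDir Input bundle directory.
#' @param outDir Output directory (created).
#' @param config A \code{\link{pipelineConfig}}; `nShuffles` governs all
#'   null models.
#' @param stages Character subset of the stage names, any order.
#' @param seed Root seed; per-stage streams are derived from it.
#' @return A run manifest: config snapshot, input digests, seeds, per-stage
#'   outputs.
#' @export
runPipeline <- function(bundleDir, outDir, config = pipelineConfig(),
                        stages = .stageOrder, seed = 1L) {
  bad <- setdiff(stages, .stageOrder)
  if (length(bad)) {
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  stages <- .stageOrder[.stageOrder %in% stages]
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  need <- function(path, stage) {
    if (!file.exists(path)) {
      stop("stage '", stage, "' requires missing input: ", path,
           call. = FALSE)
    }
    path
  }
  binFiles <- list.files(bundleDir, pattern = "^bins_.*\\.bed$",
                         full.names = TRUE)
  chroms <- sub("^bins_(.*)\\.bed$", "\\1", basename(binFiles))
  chromSizes <- setNames(vapply(binFiles, function(f) {
    max(read.table(f, sep = "\t")[[3]])
  }, numeric(1)), chroms)
  matFiles <- list.files(bundleDir,
                         pattern = "^matrix_.*_.*\\.coo$")
  cellTypes <- setdiff(unique(sub("^matrix_([^_]+)_.*$", "\\1", matFiles)),
                       "tumor")
  outputs <- character(0)
  emit <- function(name) {
    p <- file.path(outDir, name)
    outputs <<- c(outputs, p)
    p
  }
  state <- list()

  if ("boundaries" %in% stages) {
    for (ct in cellTypes) {
      calls <- lapply(chroms, function(ch) {
        coo <- need(file.path(bundleDir,
                              sprintf("matrix_%s_%s.coo", ct, ch)),
                    "boundaries")
        mat <- readContactMatrix(coo, file.path(bundleDir,
                                                sprintf("bins_%s.bed", ch)),
                                 ch)
        callBoundariesFromMatrix(mat, config, source = ct)
      })
      bnd <- suppressWarnings(sort(do.call(c, calls)))
      writeBoundaries(bnd, emit(sprintf("boundaries_%s.bed", ct)))
      state$boundaries[[ct]] <- bnd
    }
  }
  if ("consensus" %in% stages) {
    if (is.null(state$boundaries)) {
      state$boundaries <- lapply(setNames(cellTypes, cellTypes),
                                 function(ct) {
        readBoundaries(need(file.path(outDir,
                                      sprintf("boundaries_%s.bed", ct)),
                            "consensus"))
      })
    }
    cons <- consensusBoundaries(state$boundaries, tol = config$consensusTol,
                                binSize = config$binSize)
    writeBoundaries(cons, emit("consensus.bed"))
    state$consensus <- cons
  }
  getConsensus <- function(stage) {
    if (is.null(state$consensus)) {
      state$consensus <<- readBoundaries(
        need(file.path(outDir, "consensus.bed"), stage))
    }
    state$consensus
  }
  if ("sv" %in% stages) {
    cons <- getConsensus("sv")
    svs <- readSVTable(need(file.path(bundleDir, "svs.tsv"), "sv"))
    ba <- annotateBA(svs, cons)
    state$ba <- ba
    mc <- S4Vectors::mcols(ba$sv)
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(ba$sv)),
                     start = GenomicRanges::start(ba$sv) - 1L,
                     end = GenomicRanges::end(ba$sv),
                     sample_id = mc$sample_id, sv_type = mc$sv_type,
                     range = classifySVRange(ba$sv,
                                             config$shortRangeCutoff),
                     isBA = mc$isBA, nBoundaries = mc$nBoundaries)
    write.table(df, emit("ba_annotations.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    enr <- baEnrichment(svs, cons, chromSizes,
                        nShuffles = config$nShuffles,
                        binSize = config$binSize,
                        cutoff = config$shortRangeCutoff,
                        seed = .deriveSeed(seed, "enrich"))
    edf <- do.call(rbind, lapply(enr, function(x) {
      data.frame(sv_type = x$type, n = x$n, baCount = x$baCount,
                 baFraction = x$baFraction, fold = x$fold,
                 z = zScore(x$null), pNormal = pNormal(x$null),
                 pEmpirical = pEmpirical(x$null),
                 nShuffles = x$null@nShuffles)
    }))
    write.table(edf, emit("ba_enrichment.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    rec <- boundaryRecurrence(svs, cons, frac = config$recurrenceFrac)
    rdf <- cbind(.grToBed(cons), fraction = rec$fraction,
                 recurrent = rec$fraction > config$recurrenceFrac)
    write.table(rdf, emit("recurrent_boundaries.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    germPath <- file.path(bundleDir, "germline_dels.tsv")
    if (file.exists(germPath)) {
      germ <- readSVTable(germPath)
      dels <- svs[S4Vectors::mcols(svs)$sv_type == "DEL"]
      gs <- germlineSomaticRates(dels, germ, cons,
                                 lenRange = config$germlineLenRange)
      write.table(data.frame(set = gs$counts$set,
                             nFiltered = gs$counts$nFiltered,
                             nBA = gs$counts$nBA,
                             rate = c(gs$rateSomatic, gs$rateGermline)),
                  emit("germline_somatic.tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  if ("domains" %in% stages) {
    cons <- getConsensus("domains")
    doms <- suppressMessages(domainsFromBoundaries(cons, chromSizes))
    states <- readStateTrack(need(file.path(bundleDir, "states.bed"),
                                  "domains"))
    cov <- stateCoverage(doms, states)
    cls <- classifyDomains(cov, k = config$kmeansK,
                           seed = .deriveSeed(seed, "kmeans"))
    ddf <- cbind(.grToBed(doms), class = as.character(cls$class))
    write.table(ddf, emit("domains.bed"), sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    write.table(cbind(ddf, as.data.frame(round(cov, 6))),
                emit("domain_coverage.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    state$domains <- doms
    state$classes <- cls
    if (!is.null(state$ba)) {
      fp <- flankingPairCounts(state$ba, cons, doms, cls)
      write.table(as.data.frame(fp$pairs), emit("flanking_pairs.tsv"),
                  sep = "\t", quote = FALSE, row.names = TRUE)
    }
    ladPath <- file.path(bundleDir, "lads.bed")
    if (!is.null(state$ba) && file.exists(ladPath)) {
      lads <- readLADTrack(ladPath)
      lt <- suppressMessages(
        ladOverlapTest(state$ba$sv, lads, chromSizes,
                       nShuffles = config$nShuffles,
                       seed = .deriveSeed(seed, "lad")))
      rows <- list()
      for (tp in setdiff(names(lt), "counts")) {
        for (cc in names(lt[[tp]])) {
          sn <- lt[[tp]][[cc]]
          rows[[length(rows) + 1L]] <- data.frame(
            sv_type = tp, category = cc, observed = observedValue(sn),
            null_mean = nullMean(sn), null_sd = nullSd(sn),
            z = zScore(sn), p_normal = pNormal(sn),
            p_empirical = pEmpirical(sn))
        }
      }
      write.table(do.call(rbind, rows), emit("lad_enrichment.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    genesPath <- file.path(bundleDir, "genes.bed")
    exprPath <- file.path(bundleDir, "expression.tsv")
    if (file.exists(genesPath) && file.exists(exprPath)) {
      genes <- readGenesBed(genesPath)
      expr <- readGeneSampleTable(exprPath)
      des <- domainExpressionSummary(doms, cls, genes, expr)
      write.table(des, emit("domain_expression.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  if ("expression" %in% stages) {
    if (is.null(state$ba)) {
      stop("stage 'expression' requires stage 'sv' in the same run",
           call. = FALSE)
    }
    genes <- readGenesBed(need(file.path(bundleDir, "genes.bed"),
                               "expression"))
    expr <- readGeneSampleTable(need(file.path(bundleDir,
                                               "expression.tsv"),
                                     "expression"))
    cnPath <- file.path(bundleDir, "cn.tsv")
    cn <- if (file.exists(cnPath)) readGeneSampleTable(cnPath) else NULL
    rec <- expressionFoldChanges(state$ba, genes, expr,
                                 domains = state$domains,
                                 classes = state$classes)
    rec <- applyExpressionFilters(rec, expr, cn,
                                  fpkmMin = config$fpkmMin,
                                  cnMax = config$cnMax,
                                  maxDist = config$maxGeneDistance)
    rec$fc <- round(rec$fc, 8)
    rec$log2fc <- round(rec$log2fc, 8)
    write.table(rec, emit("fold_changes.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    kept <- rec[rec$filteredReason == "", , drop = FALSE]
    tf <- if (nrow(kept)) twofoldFraction(rec) else NA_real_
    write.table(data.frame(nRecords = nrow(rec), nRetained = nrow(kept),
                           twofoldFraction = tf),
                emit("expression_summary.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if ("fusion" %in% stages) {
    # the tumor sample's own boundary calls give the fusion context; fall
    # back to the cohort consensus when absent
    tumorBPath <- file.path(bundleDir, "tumor_boundaries.bed")
    fusionBnd <- if (file.exists(tumorBPath)) {
      readBoundaries(tumorBPath)
    } else {
      getConsensus("fusion")
    }
    tumorPath <- need(file.path(bundleDir, "matrix_tumor_chr1.coo"),
                      "fusion")
    svPath <- need(file.path(bundleDir, "tumor_sv.tsv"), "fusion")
    mat <- readContactMatrix(tumorPath,
                             file.path(bundleDir, "bins_chr1.bed"),
                             "chr1")
    tsv <- readSVTable(svPath)
    decay <- expectedByDistance(mat)
    rows <- list()
    for (k in seq_along(tsv)) {
      sf <- svScalingFactor(mat, tsv[k], decay,
                            window = config$fusionWindow,
                            otherSVs = tsv[-k],
                            scalingMin = config$scalingMin)
      ratio <- NA_real_
      intraMean <- interMean <- NA_real_
      if (!sf$excluded) {
        lab <- suppressMessages(
          classifyFusionBins(mat, tsv[k], fusionBnd, sf$windowUsed))
        cmp <- fusionDecayCompare(mat, lab, decay)
        ratio <- cmp$ratio
        intraMean <- cmp$intraMean
        interMean <- cmp$interMean
      }
      rows[[length(rows) + 1L]] <- data.frame(
        sv_id = k, scaling_factor = round(sf$scalingFactor, 6),
        excluded = sf$excluded, intra_mean = round(intraMean, 6),
        inter_mean = round(interMean, 6), ratio = round(ratio, 6))
    }
    write.table(do.call(rbind, rows), emit("fusion.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(distance = decay$distance,
                           mean = round(decay$mean, 6), n = decay$n),
                emit("decay.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  inputFiles <- list.files(bundleDir, recursive = TRUE, full.names = TRUE)
  manifest <- list(
    config = unclass(config), seed = seed, stages = stages,
    inputs = data.frame(file = basename(inputFiles),
                        md5 = unname(tools::md5sum(inputFiles))),
    outputs = outputs)
  writeLines(c(sprintf("seed\t%d", seed),
               sprintf("stage\t%s", paste(stages, collapse = ","))),
             file.path(outDir, "run_manifest.txt"))
  invisible(manifest)
}
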