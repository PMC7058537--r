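# Plain-text readers and writers for the pipeline's interchange formats.
# Coordinates on disk are BED-style 0-based half-open; in memory, interval
# data live in GRanges (1-based closed) and are converted on the way in/out.

#' Read a contact matrix from COO text plus a bin table
#'
#' The COO file has three whitespace-separated columns (bin1 index, bin2
#' index, value; 0-based bin indices); the bin table is BED-like with columns
#' chrom, start, end, bin_index. Only entries for `chrom` are used. An
#' optional per-bin normalization vector (one value per line, NA allowed)
#' can be attached by the caller via \code{\link{applyKR}}.
#'
#' @param cooFile Path to the COO triplet file.
#' @param binsFile Path to the bin table.
#' @param chrom Chromosome to load.
#' @return A \linkS4class{ContactMatrix}.
#' @export
readContactMatrix <- function(cooFile, binsFile, chrom) {
  bins <- read.table(binsFile, header = FALSE, sep = "\t",
                     col.names = c("chrom", "start", "end", "bin"),
                     stringsAsFactors = FALSE)
  bins <- bins[bins$chrom == chrom, , drop = FALSE]
  if (!nrow(bins)) stop("no bins for chromosome ", chrom, call. = FALSE)
  bins <- bins[order(bins$start), , drop = FALSE]
  binSize <- bins$end[1] - bins$start[1]
  n <- nrow(bins)
  offset <- min(bins$bin)
  coo <- read.table(cooFile, header = FALSE,
                    col.names = c("i", "j", "value"))
  keep <- coo$i >= offset & coo$i <= max(bins$bin) &
    coo$j >= offset & coo$j <= max(bins$bin)
  coo <- coo[keep, , drop = FALSE]
  m <- matrix(0, n, n)
  ii <- coo$i - offset + 1L
  jj <- coo$j - offset + 1L
  m[cbind(ii, jj)] <- coo$value
  m[cbind(jj, ii)] <- coo$value
  ContactMatrix(chrom, binSize, m)
}

#' Write a contact matrix as COO text plus a bin table
#'
#' Upper-triangle (including diagonal) non-zero, unmasked entries only.
#'
#' @param mat A \linkS4class{ContactMatrix}.
#' @param cooFile,binsFile Output paths.
#' @param binOffset First bin index to use in the bin table.
#' @return Invisibly, the number of COO records written.
#' @export
writeContactMatrix <- function(mat, cooFile, binsFile, binOffset = 0L) {
  n <- nBins(mat)
  bs <- binSize(mat)
  bins <- data.frame(chrom = chromName(mat),
                     start = (seq_len(n) - 1L) * bs,
                     end = seq_len(n) * bs,
                     bin = binOffset + seq_len(n) - 1L)
  write.table(bins, binsFile, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  v <- contactValues(mat)
  idx <- which(upper.tri(v, diag = TRUE) & !is.na(v) & v != 0,
               arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  coo <- data.frame(i = binOffset + idx[, 1L] - 1L,
                    j = binOffset + idx[, 2L] - 1L,
                    value = v[idx])
  write.table(coo, cooFile, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(nrow(coo))
}

#' Read a per-bin normalization vector (KR or ICE biases)
#'
#' One value per line in bin order; \code{NA} or non-numeric lines mark
#' missing (masked) bins.
#' @param path File path.
#' @return Numeric vector with NA for missing bins.
#' @export
readNormVector <- function(path) {
  x <- readLines(path)
  suppressWarnings(as.numeric(x))
}

#' Read TAD boundaries from BED
#'
#' BED6: chrom, start, end, name (source label), score (strength x 1000,
#' rounded), strand. Minimum three columns.
#' @param path File path.
#' @return A GRanges with metadata columns `strength` and `source`.
#' @export
readBoundaries <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  S4Vectors::mcols(gr)$source <-
    if (ncol(df) >= 4) as.character(df[[4]]) else "unknown"
  S4Vectors::mcols(gr)$strength <-
    if (ncol(df) >= 5) as.numeric(df[[5]]) / 1000 else NA_real_
  gr
}

#' Write TAD boundaries as BED6
#'
#' Score column carries \code{round(strength * 1000)}; name carries the
#' source label.
#' @param boundaries GRanges with `strength` and `source` metadata.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeBoundaries <- function(boundaries, path) {
  mc <- S4Vectors::mcols(boundaries)
  strength <- if ("strength" %in% names(mc)) mc$strength else NA_real_
  src <- if ("source" %in% names(mc)) mc$source else "boundary"
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(boundaries)),
    start = GenomicRanges::start(boundaries) - 1L,
    end = GenomicRanges::end(boundaries),
    name = src,
    score = ifelse(is.na(strength), 0L, as.integer(round(strength * 1000))),
    strand = ".")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cohort SV table
#'
#' Tab-separated with header columns chrom, start, end, sample_id, cohort,
#' sv_type, origin (origin optional, default "somatic"). An optional
#' `chrom2` column marks inter-chromosomal records, which are dropped with
#' a message (this pipeline is intra-chromosomal only). Identical
#' (chrom, start, end, sv_type) records within one sample are deduplicated.
#'
#' @param path File path.
#' @return A GRanges with metadata columns sample_id, cohort, sv_type,
#'   origin.
#' @export
readSVTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "sample_id", "cohort", "sv_type")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("SV table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"origin" %in% names(df)) df$origin <- "somatic"
  if ("chrom2" %in% names(df)) {
    inter <- df$chrom2 != df$chrom
    if (any(inter)) {
      message("dropping ", sum(inter), " inter-chromosomal SV record(s)")
      df <- df[!inter, , drop = FALSE]
    }
  }
  if (any(df$start >= df$end)) {
    stop("SV records must satisfy start < end", call. = FALSE)
  }
  key <- paste(df$sample_id, df$chrom, df$start, df$end, df$sv_type)
  dup <- duplicated(key)
  if (any(dup)) {
    message("deduplicated ", sum(dup), " repeated SV record(s)")
    df <- df[!dup, , drop = FALSE]
  }
  svEvents(df$chrom, df$start, df$end, df$sample_id, df$cohort,
           df$sv_type, df$origin)
}

#' Construct an SV event set
#'
#' @param chrom,start,end Breakend coordinates (bp, 0-based half-open).
#' @param sample_id,cohort,sv_type,origin Per-event annotations; `sv_type`
#'   one of DEL, DUP, INV, COMPLEX.
#' @return A GRanges with the annotation metadata columns.
#' @export
svEvents <- function(chrom, start, end, sample_id, cohort = "cohort",
                     sv_type = "DEL", origin = "somatic") {
  if (any(start >= end)) stop("start must be < end", call. = FALSE)
  bad <- setdiff(unique(sv_type), c("DEL", "DUP", "INV", "COMPLEX"))
  if (length(bad)) {
    stop("unknown sv_type: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sample_id = as.character(sample_id), cohort = as.character(cohort),
    sv_type = as.character(sv_type), origin = as.character(origin))
  gr
}

#' Write an SV table
#' @param svs GRanges from \code{\link{svEvents}}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSVTable <- function(svs, path) {
  mc <- S4Vectors::mcols(svs)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(svs)),
    start = GenomicRanges::start(svs) - 1L,
    end = GenomicRanges::end(svs),
    sample_id = mc$sample_id, cohort = mc$cohort,
    sv_type = mc$sv_type, origin = mc$origin)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromatin-state track (BED with state labels)
#'
#' Fourth column is the state, either an integer 1..15 or a label of the
#' form "E<k>".
#' @param path File path.
#' @return GRanges with integer metadata column `state`.
#' @export
readStateTrack <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  state <- df[[4]]
  if (is.character(state)) state <- as.integer(sub("^E", "", state))
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  S4Vectors::mcols(gr)$state <- as.integer(state)
  gr
}

#' Read a LAD track (BED with LAD / interLAD labels)
#' @param path File path.
#' @return GRanges with character metadata column `label`.
#' @export
readLADTrack <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]))
  S4Vectors::mcols(gr)$label <- as.character(df[[4]])
  gr
}

#' Read gene models from BED6
#' @param path File path.
#' @return GRanges with metadata column `gene_id` and strand set.
#' @export
readGenesBed <- function(path) {
  df <- read.table(path, header = FALSE, sep = "\t",
                   stringsAsFactors = FALSE)
  strand <- if (ncol(df) >= 6) df[[6]] else "*"
  gr <- GenomicRanges::GRanges(df[[1]],
                               IRanges::IRanges(df[[2]] + 1L, df[[3]]),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <-
    if (ncol(df) >= 4) as.character(df[[4]]) else paste0("g", seq_len(nrow(df)))
  gr
}

#' Read a gene-by-sample numeric table (expression or copy number)
#'
#' TSV with a header of sample names; first column gene identifiers.
#' @param path File path.
#' @return Numeric matrix, rownames = genes, colnames = samples.
#' @export
readGeneSampleTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                   check.names = FALSE)
  as.matrix(df)
}

#' Write a gene-by-sample numeric table
#' @param m Matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeGeneSampleTable <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
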