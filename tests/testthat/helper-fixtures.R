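# Shared fixture builders. Everything is generated in code; coordinates are
# bp with 25-kb bins unless a test says otherwise.

BS <- 25000

# 3-bin boundaries centered on the bin containing each bp position
mkBoundaries <- function(centers, chrom = "chr1", bs = BS,
                         source = "test") {
  b <- floor(centers / bs)  # 0-based center bin
  gr <- GenomicRanges::GRanges(
    rep(chrom, length(b)),
    IRanges::IRanges((b - 1) * bs + 1, (b + 2) * bs))
  S4Vectors::mcols(gr)$strength <- rep(1, length(gr))
  S4Vectors::mcols(gr)$source <- rep(source, length(gr))
  gr
}

grCenter <- function(gr) {
  (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
}

centerBin0 <- function(gr, bs = BS) floor(grCenter(gr) / bs)

# brute-force BA oracle: full containment, inclusive ends
bruteBA <- function(svStart, svEnd, bStart, bEnd) {
  n <- length(svStart)
  isBA <- logical(n)
  nB <- integer(n)
  for (i in seq_len(n)) {
    cnt <- 0L
    for (j in seq_along(bStart)) {
      if (svStart[i] <= bStart[j] && svEnd[i] >= bEnd[j]) cnt <- cnt + 1L
    }
    nB[i] <- cnt
    isBA[i] <- cnt > 0L
  }
  list(isBA = isBA, nBoundaries = nB)
}

# two-block contact matrix: high within blocks, low between
twoBlockMatrix <- function(n = 60, junction = 30, high = 10, low = 1,
                           chrom = "chr1", bs = BS) {
  blk <- c(rep(1L, junction), rep(2L, n - junction))
  v <- matrix(low, n, n)
  same <- outer(blk, blk, "==")
  v[same] <- high
  ContactMatrix(chrom, bs, v)
}
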