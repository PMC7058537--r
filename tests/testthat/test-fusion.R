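test_that("expectedByDistance recovers flat and power-law decays", {
  cm <- ContactMatrix("chr1", BS, matrix(7, 50, 50))
  dec <- expectedByDistance(cm)
  expect_true(all(abs(dec$mean[dec$n >= 10] - 7) < 1e-12))

  # planted d^(-1) decay: fitted log-log slope -1 +/- 0.05
  n <- 400
  E <- outer(seq_len(n), seq_len(n),
             function(i, j) 200 / pmax(1, abs(i - j)))
  set.seed(81)
  v <- matrix(0, n, n)
  ut <- upper.tri(E, diag = TRUE)
  v[ut] <- rpois(sum(ut), E[ut])
  v <- v + t(v)
  diag(v) <- diag(v) / 2
  dec <- expectedByDistance(ContactMatrix("chr1", BS, v))
  sel <- dec$distance <= 100 & dec$mean > 0
  fit <- lm(log(dec$mean[sel]) ~ log(dec$distance[sel]))
  expect_lt(abs(unname(coef(fit)[2]) + 1), 0.05)

  # fully masked chromosome: empty curve, with a message
  vm <- matrix(NA_real_, 10, 10)
  cm <- new("ContactMatrix", chrom = "chrM", binSize = 25000L,
            values = vm, mask = rep(TRUE, 10))
  expect_message(dec <- expectedByDistance(cm), "fully masked")
  expect_length(dec$perChrom[[1]]$mean, 0L)
})

test_that("sparse distances are pooled with neighbors", {
  # 6-bin matrix: d = 5 has a single pair and must be pooled
  set.seed(82)
  v <- matrix(rpois(36, 20), 6, 6)
  v <- v + t(v)
  dec <- expectedByDistance(ContactMatrix("chr1", BS, v), minPairs = 4)
  # d=3 (3 pairs) is pooled with d=4 (2 pairs) to reach the minimum
  expect_equal(dec$mean[3], dec$mean[4])
  expect_false(any(is.na(dec$mean)))
})

test_that("svScalingFactor is exactly 1 against the matrix's own expected
           model and respects the exclusion threshold", {
  n <- 200
  E <- outer(seq_len(n), seq_len(n),
             function(i, j) 100 / pmax(1, abs(i - j)))
  cm <- ContactMatrix("chr1", BS, E)
  dec <- expectedByDistance(cm)
  sv <- svEvents("chr1", 1e6, 2e6, "s1")
  res <- svScalingFactor(cm, sv, dec)
  expect_equal(res$scalingFactor, 1, tolerance = 1e-12)
  expect_false(res$excluded)

  # scaling below 0.1 flags exclusion
  low <- ContactMatrix("chr1", BS, E * 0.05 + 1e-9)
  res <- svScalingFactor(low, sv, dec)
  expect_lt(res$scalingFactor, 0.1)
  expect_true(res$excluded)
  expect_equal(res$reason, "low-scaling")

  # window truncation: another SV just left of the window cuts it
  other <- svEvents("chr1", c(0.5e6, 2.4e6), c(0.9e6, 2.6e6), "s1")
  res2 <- svScalingFactor(cm, sv, dec, otherSVs = other)
  expect_equal(res2$windowUsed[1], tadsv:::.bpToBin(0.9e6, BS))
  expect_equal(res2$windowUsed[2], tadsv:::.bpToBin(2.4e6 - 1, BS))
})

test_that("a doubled-contact region scales to ~2", {
  cs <- c(chr1 = 2e7, chr2 = 2e7)
  b <- plantedBoundaries(cs, 39)
  dup <- svEvents("chr1", 8e6, 1e7, "t1", sv_type = "DUP")
  ms <- simulateHiC(cs, b, tau = 1, depth = 80, boostRegion = dup,
                    boostFactor = 2, seed = 83)
  dec <- expectedByDistance(ms)
  res <- svScalingFactor(ms$chr1, dup, dec)
  expect_lt(abs(res$scalingFactor - 2), 0.2)
})

test_that("classifyFusionBins partitions the window and matches a hand
           oracle on a 30-bin toy", {
  n <- 30
  cm <- ContactMatrix("chr1", BS, matrix(1, n, n))
  # SV footprint bins 13..18 (0-based bp: [3e5, 4.5e5)); boundaries with
  # center bins 9 and 23 (1-based)
  sv <- svEvents("chr1", 12 * BS, 18 * BS, "s1")
  bnd <- mkBoundaries(c(8.5 * BS, 22.5 * BS))
  lab <- classifyFusionBins(cm, sv, bnd, windowUsed = c(3L, 28L))
  bins <- 3:28
  sBin <- 13L
  eBin <- 18L
  leftEdge <- 10L   # end bin of left boundary (bins 8..10)
  rightEdge <- 22L  # start bin of right boundary (bins 22..24)
  for (a in seq_along(bins)) {
    for (bb in seq_along(bins)) {
      if (bb <= a) next
      i <- bins[a]
      j <- bins[bb]
      want <- if (i < sBin && j > eBin) {
        if (i > leftEdge && j < rightEdge) "intra" else "inter"
      } else "other"
      expect_identical(lab[a, bb], want)
    }
  }
  # partition property: every cross-SV pair is intra or inter
  ut <- lab[upper.tri(lab)]
  crossCount <- sum(outer(bins, bins,
                          function(i, j) i < sBin & j > eBin)[
                      upper.tri(matrix(0, length(bins), length(bins)))])
  expect_equal(sum(ut %in% c("intra", "inter")), crossCount)
})

test_that("fusionDecayCompare separates fused from unrearranged maps", {
  cs <- c(chr1 = 2e7)
  b <- plantedBoundaries(cs, 39)
  tgt <- b[20]
  center <- round(grCenter(tgt) / BS) * BS
  del <- svEvents("chr1", center - 2.5e5, center + 2.5e5, "t1",
                  sv_type = "DEL")
  # fused map: deletion removes the boundary, joining two TADs
  rr <- simulateRearrangedHiC(2e7, "chr1", b, del, depth = 80, seed = 85)
  dec <- expectedByDistance(rr$matrix)
  sf <- svScalingFactor(rr$matrix, del, dec)
  lab <- classifyFusionBins(rr$matrix, del, b, sf$windowUsed)
  cmp <- fusionDecayCompare(rr$matrix, lab, dec)
  expect_gte(cmp$ratio, 1.5)

  # unrearranged map: the same comparison is near 1
  m0 <- simulateHiC(cs, b, tau = 1, depth = 80, seed = 86)$chr1
  dec0 <- expectedByDistance(m0)
  sf0 <- svScalingFactor(m0, del, dec0)
  lab0 <- classifyFusionBins(m0, del, b, sf0$windowUsed)
  cmp0 <- fusionDecayCompare(m0, lab0, dec0)
  expect_lt(abs(cmp0$ratio - 1), 0.15)

  # all pairs one class: the other class is flagged undefined
  n <- 20
  cm <- ContactMatrix("chr1", BS, matrix(2, n, n))
  svAll <- svEvents("chr1", 9 * BS, 11 * BS, "s1")
  labAll <- suppressMessages(
    classifyFusionBins(cm, svAll, GenomicRanges::GRanges(),
                       windowUsed = c(5L, 16L)))
  cmpAll <- fusionDecayCompare(cm, labAll, expectedByDistance(cm))
  expect_true("intra" %in% cmpAll$undefined)
  expect_true(is.na(cmpAll$intraMean))
})

test_that("breakendAggregate is calibrated on null maps and lights up on
           deletions", {
  cs <- c(chr1 = 2e7)
  b <- plantedBoundaries(cs, 39)
  m0 <- simulateHiC(cs, b, tau = 0, depth = 100, seed = 87)$chr1
  set.seed(88)
  st <- round(runif(50, 2e6, 14e6) / BS) * BS
  ln <- round(runif(50, 5e5, 2e6) / BS) * BS
  fakes <- svEvents("chr1", st, st + ln, sprintf("s%02d", 1:50))
  ag <- breakendAggregate(m0, fakes, halfWidth = 2)
  expect_equal(ag$nUsed, 50L)
  expect_lt(abs(ag$centerFold - 1), 0.2)

  # planted deletion: junction pixel enrichment well above 3
  tgt <- b[20]
  center <- round(grCenter(tgt) / BS) * BS
  del <- svEvents("chr1", center - 2.5e5, center + 2.5e5, "t1",
                  sv_type = "DEL")
  rr <- simulateRearrangedHiC(2e7, "chr1", b, del, depth = 80, seed = 89)
  ag2 <- breakendAggregate(rr$matrix, del, halfWidth = 2)
  expect_gt(ag2$centerFold, 3)

  # h = 0 degenerates to the single junction pixel
  ag3 <- breakendAggregate(rr$matrix, del, halfWidth = 0)
  expect_equal(dim(ag3$aggregate), c(1L, 1L))
  expect_equal(ag3$aggregate[1, 1], ag3$centerFold)

  # an SV whose breakend bin is masked is skipped and counted
  vm <- contactValues(m0)
  mask <- rep(FALSE, nBins(m0))
  mask[81] <- TRUE  # bin holding 2e6
  mm <- ContactMatrix("chr1", BS, vm, mask = mask)
  svMasked <- svEvents("chr1", 2e6 + 100, 4e6, "s1")
  agM <- breakendAggregate(mm, svMasked, halfWidth = 1)
  expect_equal(agM$nSkipped, 1L)
})
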