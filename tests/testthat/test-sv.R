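test_that("classifySVRange applies a strict 2-Mb cutoff", {
  sv <- svEvents("chr1", c(0, 0, 0), c(1999999, 2000000, 75000), "s1")
  expect_equal(classifySVRange(sv), c("short", "long", "short"))
  expect_error(svEvents("chr1", 10, 10, "s1"), "start must be < end")
})

test_that("annotateBA requires full containment, inclusive at both ends", {
  b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200001, 275000))
  # sv [100k, 400k) spans boundary [200k, 275k)
  ba <- annotateBA(svEvents("chr1", 1e5, 4e5, "s1"), b)
  expect_true(S4Vectors::mcols(ba$sv)$isBA)
  expect_equal(S4Vectors::mcols(ba$sv)$nBoundaries, 1L)
  expect_length(spannedBoundaries(ba, 1), 1L)

  # sv exactly equal to the boundary interval still counts
  ba <- annotateBA(svEvents("chr1", 2e5, 2.75e5, "s1"), b)
  expect_true(S4Vectors::mcols(ba$sv)$isBA)

  # partial overlap does not
  ba <- annotateBA(svEvents("chr1", 1e5, 2.5e5, "s1"), b)
  expect_false(S4Vectors::mcols(ba$sv)$isBA)
})

test_that("annotateBA agrees exactly with the brute-force containment
           oracle on random configurations", {
  set.seed(31)
  total <- 0L
  for (r in 1:20) {
    nSV <- 25L
    nB <- 20L
    svS <- sort(sample.int(2e7 - 1e6, nSV))
    svE <- svS + sample.int(1e6, nSV)
    bS <- sample.int(2e7 - 75000, nB)
    bE <- bS + sample(c(50000, 75000, 100000), nB, replace = TRUE)
    svs <- svEvents("chr1", svS, svE, "s1")
    b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(bS + 1, bE))
    got <- annotateBA(svs, b)
    want <- bruteBA(svS, svE, bS, bE)
    expect_identical(S4Vectors::mcols(got$sv)$isBA, want$isBA)
    expect_identical(S4Vectors::mcols(got$sv)$nBoundaries, want$nBoundaries)
    total <- total + nSV * nB
  }
  expect_gte(total, 10000L)
})

test_that("the fast shuffle-loop BA counter matches annotateBA", {
  set.seed(33)
  b <- mkBoundaries(sort(sample(seq(1e6, 1.9e7, by = 12500), 12)))
  svS <- sort(sample.int(2e7 - 2e6, 200))
  svE <- svS + sample.int(2e6, 200)
  svs <- svEvents("chr1", svS, svE, "s1")
  slow <- S4Vectors::mcols(annotateBA(svs, b)$sv)$isBA
  fast <- tadsv:::.countBAFast(svS, svE,
                               GenomicRanges::start(b) - 1,
                               GenomicRanges::width(b))
  expect_identical(fast, slow)
})

test_that("BA fraction is monotone in SV length for nested catalogs", {
  set.seed(35)
  b <- mkBoundaries(seq(2e6, 18e6, by = 2e6))
  anchors <- sample.int(1.5e7, 150)
  fracs <- sapply(c(2e5, 5e5, 1e6, 2e6), function(L) {
    svs <- svEvents("chr1", anchors, anchors + L, "s1")
    mean(S4Vectors::mcols(annotateBA(svs, b)$sv)$isBA)
  })
  expect_true(all(diff(fracs) >= 0))
})

test_that("baEnrichment recovers planted duplication enrichment", {
  cs <- c(chr1 = 2e7)
  b <- plantedBoundaries(cs, 9)
  # every DUP forced to span a boundary: large fold, floor empirical p
  svs <- simulateSVCatalog(cs, b, nSamples = 8, meanPerSample = 8,
                           typeMix = c(DUP = 1), lenRange = c(2e5, 1e6),
                           enrichmentKnob = 1, seed = 41)
  enr <- suppressMessages(baEnrichment(svs, b, cs, nShuffles = 400,
                                       seed = 42))
  expect_gt(enr$DUP$fold, 3)
  expect_equal(pEmpirical(enr$DUP$null), 1 / 401)
  expect_equal(enr$DUP$baCount, sum(S4Vectors::mcols(svs)$isBA))

  # a type with no short-range events is omitted with a message
  mixed <- suppressWarnings(c(svs, svEvents("chr1", 1e6, 4e6, "sX",
                                            sv_type = "INV")))
  expect_message(res <- baEnrichment(mixed, b, cs, nShuffles = 10,
                                     seed = 1),
                 "no short-range events")
  expect_false("INV" %in% names(res))
})

test_that("germline/somatic deletion rates use a closed length window", {
  b <- mkBoundaries(c(5e6, 1e7))
  # 50 somatic deletions, 3 spanning a boundary; all in [75k, 250k]
  s <- seq(1e6, 4e6, length.out = 47)
  som <- svEvents("chr1", c(s, 4975000, 9975000, 4955000),
                  c(s + 1e5, 4975000 + 2e5, 9975000 + 2e5, 4955000 + 2e5),
                  "s1")
  germ <- svEvents("chr1", seq(1.2e7, 1.8e7, length.out = 20),
                   seq(1.2e7, 1.8e7, length.out = 20) + 1e5, "g1",
                   origin = "germline")
  res <- germlineSomaticRates(som, germ, b)
  expect_equal(res$rateSomatic, 3 / 50)
  expect_equal(res$rateGermline, 0)
  expect_false(res$flagged)

  # interval is closed: 74,999 excluded, 75,000 included
  filt <- svEvents("chr1", c(0, 0, 0), c(74999, 75000, 250001), "s1")
  res <- germlineSomaticRates(filt, germ, b)
  expect_equal(res$counts$nFiltered[1], 1L)

  # empty filtered set is flagged
  res <- germlineSomaticRates(svEvents("chr1", 0, 5e4, "s1"), germ, b)
  expect_true(res$flagged)
  expect_true(is.na(res$rateSomatic))
})

test_that("boundaryRecurrence is strict and binary", {
  b <- mkBoundaries(c(5e6, 1e7))
  bStart <- GenomicRanges::start(b) - 1
  bEnd <- GenomicRanges::end(b)
  mkCohort <- function(nHit, nSamples, extraPerSample = 0L) {
    svs <- lapply(seq_len(nSamples), function(i) {
      if (i <= nHit) {
        reps <- 1L + extraPerSample
        svEvents("chr1", rep(bStart[1] - 1e4, reps) - 1e3 * seq_len(reps),
                 rep(bEnd[1] + 1e4, reps), sprintf("s%02d", i))
      } else {
        svEvents("chr1", 1e6, 1.2e6, sprintf("s%02d", i))
      }
    })
    suppressWarnings(do.call(c, svs))
  }
  # 1 of 10 samples = 10%, not recurrent under strict >
  res <- boundaryRecurrence(mkCohort(1L, 10L), b, frac = 0.10)
  expect_length(res$recurrent, 0L)
  expect_equal(res$fraction[1], 0.1)
  # 2 of 10 samples is recurrent
  res <- boundaryRecurrence(mkCohort(2L, 10L), b, frac = 0.10)
  expect_length(res$recurrent, 1L)
  # several BA-SVs on one boundary in one sample still score 1
  res <- boundaryRecurrence(mkCohort(1L, 10L, extraPerSample = 2L), b)
  expect_equal(max(res$matrix), 1L)
  expect_equal(res$fraction[1], 0.1)

  expect_error(boundaryRecurrence(GenomicRanges::GRanges(), b),
               "empty cohort")
})

test_that("loopDisruption reports SVs hitting exactly one anchor", {
  a1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6, 1e6 + 1e3))
  a2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2e6, 2e6 + 1e3))
  hitsOne <- svEvents("chr1", 0.95e6, 1.05e6, "s1")       # anchor1 only
  spansBoth <- svEvents("chr1", 0.9e6, 2.1e6, "s1")       # both anchors
  inside <- svEvents("chr1", 1.2e6, 1.8e6, "s1")          # neither
  out <- loopDisruption(hitsOne, a1, a2)
  expect_equal(nrow(out), 1L)
  expect_equal(out$anchor, "anchor1")
  expect_equal(nrow(loopDisruption(spansBoth, a1, a2)), 0L)
  expect_equal(nrow(loopDisruption(inside, a1, a2)), 0L)
})

test_that("boundariesPerSV tabulates spanned-boundary counts", {
  b <- mkBoundaries(c(2e6, 4e6, 6e6))
  svs <- svEvents("chr1",
                  c(1.9e6, 1.9e6, 1e6, 8e6),
                  c(2.2e6, 4.2e6, 1.2e6, 8.2e6),
                  "s1", sv_type = c("DEL", "DEL", "DEL", "DUP"))
  ba <- annotateBA(svs, b)
  tab <- boundariesPerSV(ba, thresholds = 0)
  del <- tab[tab$sv_type == "DEL", ]
  expect_equal(sum(del$fraction), 1)
  expect_equal(del$count[del$k == 1], 1L)
  expect_equal(del$count[del$k == 2], 1L)
  # all BA events spanning exactly one boundary: all mass at k = 1
  one <- annotateBA(svEvents("chr1", c(1.9e6, 3.9e6), c(2.2e6, 4.2e6),
                             "s1"), b)
  tab <- boundariesPerSV(one, thresholds = 0)
  expect_equal(tab$fraction[tab$k == 1], 1)
  # empty input: empty table
  none <- annotateBA(svEvents("chr1", 1e6, 1.1e6, "s1"), b)
  expect_equal(nrow(boundariesPerSV(none)), 0L)
})

test_that("SV tables round-trip and drop inter-chromosomal records", {
  svs <- simulateSVCatalog(c(chr1 = 1e7, chr2 = 1e7),
                           mkBoundaries(c(3e6, 6e6)), nSamples = 4,
                           seed = 10)
  path <- tempfile(fileext = ".tsv")
  writeSVTable(svs, path)
  back <- readSVTable(path)
  expect_equal(length(back), length(svs))
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(svs))
  expect_equal(S4Vectors::mcols(back)$sv_type,
               S4Vectors::mcols(svs)$sv_type)

  # inter-chromosomal rows are dropped with a message
  df <- read.table(path, header = TRUE, sep = "\t")
  df$chrom2 <- df$chrom
  df$chrom2[1] <- "chrX"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(back2 <- readSVTable(path), "inter-chromosomal")
  expect_equal(length(back2), length(svs) - 1L)
})
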