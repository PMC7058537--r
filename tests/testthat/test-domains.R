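test_that("domains are the gaps between adjacent boundaries", {
  b <- mkBoundaries(c(1.0375e6, 2.0375e6))  # intervals [1.0-1.075), [2.0-2.075) Mb
  expect_equal(GenomicRanges::start(b) - 1, c(1.0e6, 2.0e6))
  d <- suppressMessages(domainsFromBoundaries(b))
  expect_length(d, 1L)
  expect_equal(GenomicRanges::start(d) - 1, 1.075e6)
  expect_equal(GenomicRanges::end(d), 2.0e6)

  # touching boundaries leave no domain
  touch <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(1, 75001),
                                                   c(75000, 150000)))
  expect_length(suppressMessages(domainsFromBoundaries(touch)), 0L)

  # three boundaries give two domains; terminal segments are excluded
  d <- suppressMessages(domainsFromBoundaries(mkBoundaries(c(2e6, 5e6,
                                                             8e6))))
  expect_length(d, 2L)

  # a chromosome with fewer than 2 boundaries yields none, with a note
  expect_message(domainsFromBoundaries(mkBoundaries(5e6)), "fewer than 2")
})

test_that("domains plus boundaries tile the interior without overlap", {
  b <- mkBoundaries(sort(sample(seq(1e6, 1.9e7, by = 25000), 8)))
  d <- suppressMessages(domainsFromBoundaries(b))
  all <- sort(c(b, d), ignore.strand = TRUE)
  # consecutive intervals abut exactly between first and last boundary
  expect_true(all(GenomicRanges::start(all)[-1] ==
                    GenomicRanges::end(all)[-length(all)] + 1))
})

test_that("stateCoverage measures bp fractions and rejects malformed
           tracks", {
  d <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e6 + 1, 2e6))
  # fully one state
  tr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 5e6))
  S4Vectors::mcols(tr)$state <- 4L
  cov <- stateCoverage(d, tr)
  expect_equal(cov[1, 4], 1)
  expect_equal(sum(cov), 1)

  # half state 2, half state 9
  tr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(c(1, 1.5e6 + 1),
                                                c(1.5e6, 5e6)))
  S4Vectors::mcols(tr)$state <- c(2L, 9L)
  cov <- stateCoverage(d, tr)
  expect_equal(cov[1, 2], 0.5)
  expect_equal(cov[1, 9], 0.5)

  # toy multi-interval track equals a brute-force bp intersection oracle
  set.seed(51)
  cuts <- sort(c(0, sample.int(3e6, 6), 3e6))
  states <- sample.int(15, 7, replace = TRUE)
  tr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(cuts[-8] + 1, cuts[-1]))
  S4Vectors::mcols(tr)$state <- states
  doms <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(c(2e5, 1.1e6) + 1,
                                                  c(9e5, 2.7e6)))
  cov <- stateCoverage(doms, tr)
  for (k in 1:2) {
    ds <- GenomicRanges::start(doms)[k] - 1
    de <- GenomicRanges::end(doms)[k]
    want <- numeric(15)
    for (j in seq_along(states)) {
      ov <- max(0, min(de, cuts[j + 1]) - max(ds, cuts[j]))
      want[states[j]] <- want[states[j]] + ov
    }
    expect_equal(cov[k, ], want / (de - ds))
  }

  # overlapping intervals of different states are an error
  bad <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1, 5e5), c(1e6, 1.5e6)))
  S4Vectors::mcols(bad)$state <- c(1L, 2L)
  expect_error(stateCoverage(d, bad), "malformed")
})

test_that("classifyDomains recovers planted archetypes and names all five
           centroids correctly", {
  set.seed(53)
  arch <- classArchetypes()
  truth <- rep(domainClassNames(), each = 120)
  cov <- t(sapply(truth, function(cl) {
    g <- rgamma(15, shape = 40 * arch[cl, ] + 1e-6)
    g / sum(g)
  }))
  rownames(cov) <- NULL
  cls <- classifyDomains(cov, seed = 7)
  agreement <- mean(as.character(cls$class) == truth)
  expect_gte(agreement, 0.9)
  # naming: each planted class's majority call carries its own name
  for (cl in domainClassNames()) {
    maj <- names(which.max(table(cls$class[truth == cl])))
    expect_equal(maj, cl)
  }
  expect_equal(levels(cls$class), domainClassNames())
  expect_equal(cls$activityRank[match("active", as.character(cls$class))],
               4L)

  # determinism under a fixed seed
  cls2 <- classifyDomains(cov, seed = 7)
  expect_identical(cls$class, cls2$class)

  # degenerate input: identical rows cannot form 5 clusters
  expect_error(classifyDomains(matrix(1 / 15, 10, 15), seed = 1),
               "distinct")
  expect_error(classifyDomains(cov[1:3, ], seed = 1), "at least k")
})

test_that("assignToCentroids maps rows to their nearest class centroid", {
  set.seed(54)
  arch <- classArchetypes()
  truth <- rep(domainClassNames(), each = 40)
  cov <- t(sapply(truth, function(cl) {
    g <- rgamma(15, shape = 40 * arch[cl, ] + 1e-6)
    g / sum(g)
  }))
  rownames(cov) <- NULL
  cls <- classifyDomains(cov, seed = 3)
  # archetype rows themselves land on the centroid named after them
  got <- assignToCentroids(arch, cls)
  expect_equal(as.character(got), domainClassNames())
})

test_that("flankingPairCounts matches manual assignment on a toy layout", {
  # 6 domains of alternating classes on one chromosome
  d <- GenomicRanges::GRanges("chr1",
                              IRanges::IRanges(seq(0, 5e6, by = 1e6) + 1,
                                               seq(1e6, 6e6, by = 1e6)))
  cls <- structure(list(
    class = factor(c("active", "repressed", "active", "low",
                     "repressed", "active"),
                   levels = domainClassNames()),
    centers = matrix(0, 5, 15, dimnames = list(domainClassNames(), NULL))),
    class = "tadsv_domain_classes")
  # 5 BA-SVs with hand-assigned flank pairs
  svs <- svEvents("chr1",
                  c(0.5e6, 0.5e6, 1.5e6, 3.5e6, 4.5e6),
                  c(1.5e6, 2.5e6, 2.5e6, 4.5e6, 5.5e6), "s1")
  ba <- list(sv = svs, boundaries = GenomicRanges::GRanges(),
             hits = NULL)
  S4Vectors::mcols(ba$sv)$isBA <- rep(TRUE, 5)
  class(ba) <- "tadsv_ba"
  res <- flankingPairCounts(ba, NULL, d, cls)
  # manual: (active,repressed) (active,active) (repressed,active)
  #         (low,repressed) (repressed,active)
  expect_equal(res$nUsed, 5L)
  expect_equal(res$pairs["active", "repressed"], 3L)
  expect_equal(res$pairs["repressed", "active"], 3L)  # symmetric storage
  expect_equal(res$pairs["active", "active"], 1L)
  expect_equal(res$pairs["low", "repressed"], 1L)
  expect_equal(sum(res$pairs[upper.tri(res$pairs, diag = TRUE)]), 5L)
})

test_that("ladOverlapTest categorizes breakends and detects planted
           crossings", {
  cs <- c(chr1 = 2e7)
  # track covering the whole genome with LAD only: everything within-LAD
  allLad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2e7))
  S4Vectors::mcols(allLad)$label <- "LAD"
  svs <- svEvents("chr1", c(1e6, 5e6), c(2e6, 5.5e6), "s1")
  res <- ladOverlapTest(svs, allLad, cs, nShuffles = 50, seed = 1)
  expect_equal(unname(res$counts[, "withinLAD"]), 2)
  expect_equal(unname(res$counts[, "crossing"]), 0)

  # alternating 2-Mb LAD/inter-LAD; SVs planted to straddle label borders
  edges <- seq(0, 2e7, by = 2e6)
  lads <- GenomicRanges::GRanges("chr1",
                                 IRanges::IRanges(edges[-11] + 1,
                                                  edges[-1]))
  S4Vectors::mcols(lads)$label <- rep(c("LAD", "interLAD"), 5)
  cross <- svEvents("chr1", edges[2:9] - 2e5, edges[2:9] + 2e5, "s1")
  res <- ladOverlapTest(cross, lads, cs, nShuffles = 400, seed = 2)
  expect_equal(unname(res$counts[, "crossing"]), 8)
  expect_gt(zScore(res$DEL$crossing), 3)

  # an SV on a chromosome without LAD calls is skipped with a message
  svs2 <- svEvents(c("chr1", "chr9"), c(1e6, 1e6), c(2e6, 2e6), "s1")
  expect_message(
    ladOverlapTest(svs2, lads, c(chr1 = 2e7, chr9 = 2e7), nShuffles = 10,
                   seed = 3),
    "skipping")
})

test_that("domainExpressionSummary recovers the planted activity
           ordering", {
  cs <- c(chr1 = 2e7, chr2 = 2e7)
  b <- plantedBoundaries(cs, 9)
  doms <- suppressMessages(domainsFromBoundaries(b, cs))
  truth <- factor(domainClassNames()[(seq_along(doms) - 1L) %% 5L + 1L],
                  levels = domainClassNames())
  st <- simulateStateTrack(doms, truth, cs, seed = 61)
  cls <- classifyDomains(stateCoverage(doms, st), seed = 62)
  genes <- simulateGenes(cs, 400, seed = 63)
  tabs <- simulateExpression(genes, sprintf("s%02d", 1:20), doms, truth,
                             seed = 64)
  res <- domainExpressionSummary(doms, cls, genes, tabs$expression)
  res <- res[match(domainClassNames(), res$class), ]
  expect_true(all(diff(res$medianLog2) > 0))  # ordering recovered
  expect_true(all(res$pVsActive[1:4] < 0.01))
  expect_true(is.na(res$pVsActive[res$class == "active"]))

  # identical expression everywhere: medians equal
  flat <- tabs$expression
  flat[] <- 1
  res <- domainExpressionSummary(doms, cls, genes, flat)
  expect_equal(unique(res$medianLog2), 0)

  # genes outside all domains are excluded
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1e4, 2e4))
  S4Vectors::mcols(far)$gene_id <- "gX"
  exprX <- matrix(1, 1, 2, dimnames = list("gX", c("a", "b")))
  res <- domainExpressionSummary(doms, cls, far, exprX)
  expect_equal(sum(res$nGenes), 0L)
})
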