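mkGenes <- function(starts, ends, ids = sprintf("g%02d", seq_along(starts)),
                    chrom = "chr1") {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts + 1, ends))
  S4Vectors::mcols(gr)$gene_id <- ids
  gr
}

test_that("nearestFlankGenes picks the closest wholly-outside genes", {
  # 6-gene layout around an SV at [5.0, 6.0) Mb; oracle is a linear scan
  genes <- mkGenes(c(3.0e6, 4.2e6, 4.95e6, 5.4e6, 5.98e6, 6.3e6),
                   c(3.1e6, 4.6e6, 5.05e6, 5.5e6, 6.05e6, 6.4e6))
  sv <- svEvents("chr1", 5e6, 6e6, "s1")
  res <- nearestFlankGenes(sv, genes)
  # g03 straddles the start breakend and g05 the end breakend: excluded
  expect_equal(res$upGene, "g02")
  expect_equal(res$upDist, 5e6 - 4.6e6)
  expect_equal(res$downGene, "g06")
  expect_equal(res$downDist, 6.3e6 - 6e6)

  # equidistant candidates: the smaller start coordinate wins
  tie <- mkGenes(c(1e6, 1.5e6), c(2e6, 2e6), c("gA", "gB"))
  res <- nearestFlankGenes(svEvents("chr1", 2e6, 3e6, "s1"), tie)
  expect_equal(res$upGene, "gA")

  # absent flank is NA, not an error
  res <- nearestFlankGenes(svEvents("chr1", 1e4, 2e4, "s1"), genes)
  expect_true(is.na(res$upGene))
  expect_equal(res$downGene, "g01")
})

test_that("foldChange divides by the mean of the other cohort samples", {
  m <- matrix(c(6, 1, 2, 3), 1, dimnames = list("g", paste0("s", 1:4)))
  expect_equal(foldChange(m, "g", "s1"), 3)  # 6 / mean(1,2,3)
  m2 <- matrix(c(2, 2, 2), 1, dimnames = list("g", paste0("s", 1:3)))
  expect_equal(foldChange(m2, "g", "s1"), 1)
  expect_error(foldChange(m[, 1, drop = FALSE], "g", "s1"), "2 samples")
  # zero denominator flagged as NA
  m3 <- matrix(c(5, 0, 0), 1, dimnames = list("g", paste0("s", 1:3)))
  expect_true(is.na(foldChange(m3, "g", "s1")))
})

test_that("foldChange is invariant to per-gene rescaling", {
  set.seed(71)
  m <- matrix(runif(40, 1, 10), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  for (g in rownames(m)) {
    expect_equal(foldChange(m, g, "s3"), foldChange(m * 13, g, "s3"))
  }
})

test_that("expression filters keep exact-threshold records", {
  genes <- mkGenes(c(1.0e6, 3.0e6), c(1.1e6, 3.1e6), c("gU", "gD"))
  b <- mkBoundaries(2e6)
  sv <- svEvents("chr1", 1.5e6, 2.5e6, "s1")
  ba <- annotateBA(sv, b)
  samples <- paste0("s", 1:6)
  expr <- matrix(1, 2, 6, dimnames = list(c("gU", "gD"), samples))
  rec <- expressionFoldChanges(ba, genes, expr)
  expect_equal(nrow(rec), 2L)

  # cohort mean exactly 0.1 is kept (strict <)
  e2 <- expr
  e2["gU", ] <- 0.1
  out <- applyExpressionFilters(rec, e2, NULL)
  expect_equal(out$filteredReason[out$gene == "gU"], "")
  e2["gU", ] <- 0.0999
  out <- applyExpressionFilters(rec, e2, NULL)
  expect_equal(out$filteredReason[out$gene == "gU"], "low-expression")

  # copy number exactly 4 is kept (strict >); CN > 4 on either flank gene
  # drops both records of the SV
  cn <- matrix(4, 2, 6, dimnames = dimnames(expr))
  out <- applyExpressionFilters(rec, expr, cn)
  expect_true(all(out$filteredReason == ""))
  cn["gD", "s1"] <- 5
  out <- applyExpressionFilters(rec, expr, cn)
  expect_true(all(out$filteredReason == "high-copy-number"))

  # missing CN entry: diploid with a warning
  cnPart <- cn["gU", , drop = FALSE]
  expect_warning(out <- applyExpressionFilters(rec, expr, cnPart),
                 "assuming CN = 2")
  expect_true(all(out$filteredReason == ""))

  # distance exactly 1 Mb is kept (strict >)
  genes2 <- mkGenes(c(0.5e6 - 1e5, 3.5e6), c(0.5e6, 3.6e6), c("gU", "gD"))
  rec2 <- expressionFoldChanges(annotateBA(sv, b), genes2, expr)
  expect_equal(rec2$distance[rec2$gene == "gU"], 1e6)
  out <- applyExpressionFilters(rec2, expr, NULL, maxDist = 1e6)
  expect_equal(out$filteredReason[out$gene == "gU"], "")
  out <- applyExpressionFilters(rec2, expr, NULL, maxDist = 1e6 - 1)
  expect_equal(out$filteredReason[out$gene == "gU"], "distal")
})

test_that("filters are order-independent predicates", {
  set.seed(73)
  genes <- mkGenes(seq(0, 9e6, by = 1e6), seq(0, 9e6, by = 1e6) + 5e4)
  b <- mkBoundaries(c(2.5e6, 6.5e6))
  svs <- svEvents("chr1", c(2.2e6, 6.2e6), c(2.8e6, 6.8e6), c("s1", "s2"))
  samples <- paste0("s", 1:8)
  expr <- matrix(runif(80, 0.01, 5), 10, 8,
                 dimnames = list(S4Vectors::mcols(genes)$gene_id, samples))
  cn <- matrix(sample(2:6, 80, TRUE), 10, 8, dimnames = dimnames(expr))
  rec <- expressionFoldChanges(annotateBA(svs, b), genes, expr)
  a <- applyExpressionFilters(rec, expr, cn)
  # retained set is unchanged if we pre-apply the distance filter alone
  b1 <- applyExpressionFilters(rec, expr, NULL, fpkmMin = 0)
  b2 <- applyExpressionFilters(b1, expr, cn)
  expect_identical(a$filteredReason == "", b2$filteredReason == "")
})

test_that("groupTest is one-tailed and guards group sizes", {
  rec <- data.frame(
    svIndex = 1:12, log2fc = c(3, 2.5, 3.2, 2.8, 0.1, -0.2, 0, 0.2, 0.1,
                               -0.1, 0.05, 0),
    fc = 2^c(3, 2.5, 3.2, 2.8, 0.1, -0.2, 0, 0.2, 0.1, -0.1, 0.05, 0),
    flankRelation = rep(c("to-more-active", "to-less-active"), c(4, 8)),
    filteredReason = "")
  res <- groupTest(rec, "to-more-active", "to-less-active")
  expect_lt(res$p, 0.01)
  expect_gt(res$shift, 2)
  # reversed direction is not significant
  res <- groupTest(rec, "to-less-active", "to-more-active")
  expect_gt(res$p, 0.9)
  # undersized group errors, naming the group
  expect_error(groupTest(rec[c(1, 2, 5:12), ], "to-more-active",
                         "to-less-active"), "to-more-active")
})

test_that("groupTest p is near 0.5 for identical groups", {
  set.seed(75)
  ps <- replicate(100, {
    x <- rnorm(15)
    rec <- data.frame(svIndex = 1:30, log2fc = c(x, sample(x)),
                      fc = 1, filteredReason = "",
                      flankRelation = rep(c("A", "B"), each = 15))
    rec$fc <- 2^rec$log2fc
    groupTest(rec, "A", "B")$p
  })
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})

test_that("twofoldFraction is strict in both directions", {
  rec <- data.frame(svIndex = 1:3, fc = c(4, 1.1, 0.4),
                    log2fc = log2(c(4, 1.1, 0.4)), filteredReason = "")
  expect_equal(twofoldFraction(rec), 2 / 3)
  rec$fc <- c(2, 2, 0.5)
  expect_equal(twofoldFraction(rec), 0)  # exactly twofold does not count
  rec$fc <- c(1, 1, 1)
  expect_equal(twofoldFraction(rec), 0)
  # per-SV: any flank exceeding twofold marks the SV once
  rec <- data.frame(svIndex = c(1, 1, 2, 2), fc = c(4, 1, 1, 1),
                    log2fc = 0, filteredReason = "")
  expect_equal(twofoldFraction(rec, per = "sv"), 0.5)
  expect_equal(twofoldFraction(rec, per = "record"), 0.25)
  expect_error(twofoldFraction(rec[0, ]), "no retained")
})
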