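# Iterative reciprocal-best-hit anchoring.

test_that("rankHits deduplicates per (query, subject) and orders by the documented chain", {
  # two rows for the same subject: the better bit score wins
  hits <- makeHits(c("q1", "q1"), c("s1", "s1"), bits = c(50, 60))
  r <- rankHits(hits)
  expect_identical(nrow(r), 1L)
  expect_equal(r$bit_score, 60)

  # equal bits: E-value breaks the tie
  hits <- makeHits(c("q1", "q1"), c("s2", "s1"), evalue = c(1e-20, 1e-30),
                   bits = 60)
  r <- rankHits(hits)
  expect_identical(r$subject_id, c("s1", "s2"))
  expect_identical(r$rank, c(1L, 2L))

  # E-value ceiling is enforced
  hits <- makeHits("q1", "s1", evalue = 1e-3)
  expect_identical(nrow(rankHits(hits, evalue_max = 1e-5)), 0L)
})

test_that("rankHits assigns a rank bijection per query regardless of row order", {
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    hits <- makeHits(sample(sprintf("q%d", 1:5), n, replace = TRUE),
                     sample(sprintf("s%d", 1:8), n, replace = TRUE),
                     evalue = 10^-runif(n, 6, 40),
                     bits = round(runif(n, 50, 400), 1))
    r1 <- rankHits(hits)
    r2 <- rankHits(hits[sample(nrow(hits)), , drop = FALSE])
    rownames(r2) <- NULL
    expect_identical(r1, r2)
    for (ranks in split(r1$rank, r1$query_id)) {
      expect_identical(sort(ranks), seq_along(ranks))
    }
  }
})

test_that("findRBH keeps only mutual top hits and records the worse scores", {
  fwd <- rankHits(makeHits("a1", "b1", evalue = 1e-40, bits = 300))
  rev <- rankHits(makeHits("b1", "a1", evalue = 1e-35, bits = 280))
  rbh <- findRBH(fwd, rev)
  expect_identical(rbh$a_id, "a1")
  expect_equal(rbh$evalue, 1e-35)      # worse (larger) E-value
  expect_equal(rbh$bit_score, 280)     # worse (smaller) bit score

  # non-reciprocal: a1's top is b1 but b1's top is a2
  fwd <- rankHits(makeHits("a1", "b1", bits = 100))
  rev <- rankHits(makeHits(c("b1", "b1"), c("a2", "a1"), bits = c(90, 80)))
  expect_identical(nrow(findRBH(fwd, rev)), 0L)

  # empty input
  expect_identical(nrow(findRBH(rankHits(emptyish <- makeHits(character(0), character(0))),
                                rankHits(emptyish))), 0L)
})

test_that("a pair masked by a stronger paralog surfaces at the second iteration", {
  # hand-enumerated 5-row table: round 1 fixes (a1,b1); removing both
  # makes a2 and b2 mutual tops at round 2
  fwd <- makeHits(c("a1", "a2", "a2"), c("b1", "b1", "b2"),
                  evalue = c(1e-50, 1e-45, 1e-25), bits = c(100, 90, 50))
  rev <- makeHits(c("b1", "b1", "b2"), c("a1", "a2", "a2"),
                  evalue = c(1e-50, 1e-45, 1e-25), bits = c(100, 90, 50))
  anchors <- anchorPairs(irbhAnchor(fwd, rev))
  expect_identical(anchors$a_id, c("a1", "a2"))
  expect_identical(anchors$b_id, c("b1", "b2"))
  expect_identical(anchors$iteration, c(1L, 2L))

  # classical single-pass RBH finds only the first pair
  single <- findRBH(rankHits(fwd), rankHits(rev))
  expect_identical(single$a_id, "a1")

  # max_iterations = 1 is identical to the single pass
  one <- anchorPairs(irbhAnchor(fwd, rev, max_iterations = 1L))
  expect_identical(one$a_id, "a1")
})

test_that("a perfect mutual-top matching is recovered fully at iteration 1", {
  n <- 12L
  a <- sprintf("a%02d", 1:n)
  b <- sprintf("b%02d", 1:n)
  fwd <- makeHits(a, b, bits = seq(100, by = 5, length.out = n))
  rev <- makeHits(b, a, bits = seq(100, by = 5, length.out = n))
  anchors <- anchorPairs(irbhAnchor(fwd, rev))
  expect_identical(nrow(anchors), n)
  expect_true(all(anchors$iteration == 1L))
  expect_identical(anchors$a_id, a)
  expect_false(anyDuplicated(anchors$b_id) > 0)
})

test_that("concordance classification applies the chrUkn sentinel", {
  genesA <- makeGenes(c("a1", "a2", "a3"), c("chr7", "chr3", "chr3"),
                      c(100L, 100L, 2000L))
  genesB <- makeGenes(c("b1", "b2", "b3"), c("chr7", "chrUkn", "chr5"),
                      c(100L, 100L, 100L))
  fwd <- makeHits(c("a1", "a2", "a3"), c("b1", "b2", "b3"), bits = c(90, 80, 70))
  rev <- makeHits(c("b1", "b2", "b3"), c("a1", "a2", "a3"), bits = c(90, 80, 70))
  anchors <- classifyConcordance(irbhAnchor(fwd, rev), genesA, genesB)
  p <- anchorPairs(anchors)
  expect_identical(p$concordance[p$a_id == "a1"], "same_chromosome")
  expect_identical(p$concordance[p$a_id == "a2"], "involves_chrUkn")
  expect_identical(p$concordance[p$a_id == "a3"], "different_chromosome")
  expect_identical(concordanceSummary(anchors),
                   c(same_chromosome = 1L, different_chromosome = 1L,
                     involves_chrUkn = 1L))
  # anchored id missing from the gene models is a data error naming it
  expect_error(
    classifyConcordance(irbhAnchor(fwd, rev),
                        genesA[mcols(genesA)$gene_id != "a3"], genesB),
    "a3", class = "vinelncDataError")
})

test_that("anchor quality reports bit-score/length ratios and class means", {
  genesA <- makeGenes(c("a1", "a2"), c("chr1", "chr2"), c(100L, 100L))
  genesB <- makeGenes(c("b1", "b2"), c("chr1", "chr1"),
                      c(100L, 5000L), width = c(3000L, 200L))
  fwd <- makeHits(c("a1", "a2"), c("b1", "b2"), bits = c(300, 300))
  rev <- makeHits(c("b1", "b2"), c("a1", "a2"), bits = c(300, 300))
  anchors <- classifyConcordance(irbhAnchor(fwd, rev), genesA, genesB)
  q <- anchorQuality(anchors, genesB)
  expect_equal(q$quality$ratio[q$quality$b_id == "b1"], 300 / 3000)  # 0.1
  means <- q$class_means
  expect_equal(means$mean_ratio[means$concordance == "same_chromosome"], 0.1)
  expect_equal(means$mean_ratio[means$concordance == "different_chromosome"],
               1.5)
  # an empty class is reported as absent, not an error
  onlySame <- classifyConcordance(irbhAnchor(fwd[1, ], rev[1, ]), genesA, genesB)
  m2 <- anchorQuality(onlySame, genesB)$class_means
  expect_true(is.na(m2$mean_ratio[m2$concordance == "different_chromosome"]))
})

test_that("the rescue pass anchors unsupported legacy models with one RBH round", {
  genesA <- makeGenes(c("a1", "a9"), c("chr2", "chr2"), c(100L, 3000L))
  genesB <- makeGenes(c("b1", "b9"), c("chr2", "chr2"), c(100L, 3000L))
  fwd <- makeHits(c("a1", "a9"), c("b1", "b9"), bits = c(200, 150))
  rev <- makeHits(c("b1", "b9"), c("a1", "a9"), bits = c(200, 150))
  res <- rescueUnsupported("b9", fwd, rev, genes_a = genesA, genes_b = genesB)
  expect_identical(res$b_id, "b9")
  expect_identical(res$a_id, "a9")
  expect_true(res$same_chromosome)

  # non-reciprocal top hit yields no rescue
  rev2 <- makeHits("b9", "a1", bits = 150)
  res2 <- rescueUnsupported("b9", fwd["a9" == fwd$query_id, ], rev2,
                            genes_a = genesA, genes_b = genesB)
  expect_identical(nrow(res2), 0L)
})

test_that("the synthetic bundle's planted orthologs are fully recovered, masked pairs at round 2", {
  b <- defaultBundle()
  anchors <- classifyConcordance(irbhAnchor(b$fwd_hits, b$rev_hits),
                                 b$genes_a, b$genes_b)
  p <- anchorPairs(anchors)
  truth <- b$ortholog_truth
  expect_identical(nrow(p), nrow(truth))
  m <- match(truth$a_id, p$a_id)
  expect_false(anyNA(m))
  expect_identical(p$b_id[m], truth$b_id)
  expect_true(all(p$iteration[m][truth$masked] == 2L))
  expect_true(all(p$iteration[m][!truth$masked] == 1L))

  # rescue fixtures: the three unsupported legacy models are rescued
  res <- rescueUnsupported(b$rescue_b_ids, b$rescue_fwd, b$rescue_rev,
                           genes_a = b$genes_a, genes_b = b$genes_b)
  expect_identical(sort(res$b_id), sort(b$rescue_b_ids))
})

test_that("anchor sets refuse duplicated gene ids and write as TSV", {
  bad <- data.frame(a_id = c("a1", "a1"), b_id = c("b1", "b2"),
                    iteration = 1L, evalue = 1e-30, bit_score = 100,
                    concordance = NA_character_)
  expect_error(new("AnchorSet", pairs = bad), "duplicated")
  f <- withr::local_tempfile(fileext = ".tsv")
  anchors <- irbhAnchor(makeHits("a1", "b1"), makeHits("b1", "a1"))
  writeAnchors(anchors, f)
  tab <- read.delim(f)
  expect_identical(tab$a_id, "a1")
  expect_identical(tab$iteration, 1L)
})
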