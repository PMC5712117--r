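# The lncRNA identification pipeline, stage by stage.

test_that("greedy clustering merges identical sequences under the longest representative", {
  s <- paste(rep("ACGTTGCA", 40), collapse = "")
  seqs <- namedDna(list(t1 = s, t2 = s))
  cl <- clusterGreedy(seqs, 0.90)
  expect_identical(length(unique(cl$cluster_id)), 1L)
  expect_identical(cl$member_id[cl$is_representative], "t1")  # id tie-break
})

test_that("greedy clustering separates dissimilar sequences and merges mutated copies", {
  seqs <- namedDna(list(allA = strrep("A", 300), allC = strrep("C", 300)))
  cl <- clusterGreedy(seqs, 0.90)
  expect_identical(length(unique(cl$cluster_id)), 2L)

  set.seed(3)
  base <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  mut <- strsplit(base, "")[[1]]
  flip <- sample(400, 20)  # 5% mismatches
  mut[flip] <- vapply(mut[flip],
                      function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1),
                      character(1))
  seqs <- namedDna(list(orig = base, copy = paste(mut, collapse = "")))
  cl <- clusterGreedy(seqs, 0.90)
  expect_identical(length(unique(cl$cluster_id)), 1L)
})

test_that("expression filter boundary is inclusive at the threshold", {
  expr <- data.frame(transcript_id = c("t1", "t2", "t4"),
                     fpkm = c(1.50, 1.49, 0))
  out <- filterExpression(c("t1", "t2", "t3", "t4"), expr, 1.50)
  expect_identical(out$kept, "t1")                      # FPKM 1.50 kept
  expect_true("t2" %in% out$removed$id)                 # FPKM 1.49 removed
  expect_identical(out$removed$reason[out$removed$id == "t3"],
                   "no_expression_record")
  # fpkm_min 0 removes only record-less transcripts (0 >= 0)
  out0 <- filterExpression(c("t1", "t2", "t3", "t4"), expr, fpkm_min = 0)
  expect_identical(out0$removed$id, "t3")
})

test_that("coding classification bins by the best hit's organism code; only no-hit survives", {
  taxon <- c(VITVI = "plant", HUMAN = "non_plant")
  hits <- rbind(
    makeHits("t1", "SP001_VITVI", evalue = 1e-40, bits = 300),
    makeHits("t1", "SP002_HUMAN", evalue = 1e-30, bits = 200),  # dominated
    makeHits("t2", "SP003_HUMAN", evalue = 1e-25, bits = 150),
    makeHits("t3", "SP004_VITVI", evalue = 1e-10, bits = 60))   # above ceiling
  bins <- classifyCoding(c("t1", "t2", "t3", "t4"), hits, taxon, 1e-20)
  expect_identical(bins$plant, "t1")
  expect_identical(bins$non_plant, "t2")
  expect_setequal(bins$no_hit, c("t3", "t4"))
  # unknown organism code is a data error listing the code
  badMap <- c(VITVI = "plant")
  expect_error(classifyCoding(c("t1", "t2"), hits, badMap, 1e-20),
               "HUMAN", class = "vinelncDataError")
})

test_that("cross-accession consensus drops short alignments and emits the longer transcript", {
  setA <- namedDna(list(q1 = strrep("ACGT", 70),     # 280 nt
                        q2 = strrep("ACGT", 60),     # 240 nt
                        q3 = strrep("ACGT", 75)))    # 300 nt
  setB <- namedDna(list(s1 = strrep("ACGT", 75),     # 300 nt
                        s2 = strrep("TGCA", 55)))    # 220 nt
  hits <- rbind(
    makeHits("q1", "s1", aln = 250, bits = 300),  # subject longer -> s1
    makeHits("q2", "s2", aln = 199, bits = 250),  # below 200 nt -> dropped
    makeHits("q3", "s1", aln = 300, bits = 280))  # q3 == s1 length: tie -> q3
  out <- crossAccessionConsensus(setA, setB, hits, 200L)
  expect_setequal(names(out), c("s1", "q3"))      # s1 emitted once (dedup)
  # unknown id in the hit table is a data error
  expect_error(crossAccessionConsensus(setA, setB,
                                       makeHits("nope", "s1", aln = 250), 200L),
               "nope", class = "vinelncDataError")
})

test_that("Rfam purge removes hits at or below the ceiling and records the family", {
  cmHits <- data.frame(query_id = c("t1", "t2", "t2"),
                       model_accession = c("RF00001", "RF00002", "RF00003"),
                       evalue = c(0.009, 0.011, 0.5), score = c(40, 30, 10))
  out <- rfamFilter(c("t1", "t2", "t3"), cmHits, 0.01)
  expect_identical(out$removed$id, "t1")          # E 0.009 removed
  expect_identical(out$removed$reason, "rfam_RF00001")
  expect_setequal(out$kept, c("t2", "t3"))        # E 0.011 only: kept; no hit: kept
})

test_that("the ORF flag counts start-to-stop codons across all six frames", {
  # 300 nt of repeated TAA stops: longest ORF 0, kept
  stops <- namedDna(list(t1 = strrep("TAA", 100)))
  out <- orfCodingFlag(stops, 100L)
  expect_identical(out$kept, "t1")
  expect_identical(unname(out$orf_codons["t1"]), 0L)

  # ATG + 150 sense codons + TGA -> 151 codons, flagged at default 100
  orf <- paste0("ATG", strrep("GCC", 150), "TGA")
  fwd <- namedDna(list(t2 = orf))
  out <- orfCodingFlag(fwd, 100L)
  expect_identical(out$flagged, "t2")
  expect_identical(unname(out$orf_codons["t2"]), 151L)

  # the same ORF on the reverse strand is still detected (6-frame)
  revSeq <- as.character(reverseComplement(DNAStringSet(orf))[[1]])
  out <- orfCodingFlag(namedDna(list(t3 = revSeq)), 100L)
  expect_identical(out$flagged, "t3")
})

test_that("pipeline configuration rejects non-positive and out-of-range thresholds", {
  expect_error(lncPipelineConfig(fpkm_min = -1), class = "vinelncUsageError")
  expect_error(lncPipelineConfig(cluster_identity = 0.4),
               class = "vinelncUsageError")
  expect_error(clusterGreedy(namedDna(list(a = "ACGT")), identity = 1.2),
               class = "vinelncUsageError")
})

test_that("the audit table conserves transcripts at every stage of a full run", {
  res <- defaultPipelineResult()
  a <- auditTable(res)
  expect_true(all(a$n_in == a$n_kept + a$n_removed))
  # each stage's n_in equals the previous n_kept along its chain
  for (acc in c("a", "b")) {
    chain <- a[a$accession == acc, , drop = FALSE]
    expect_true(all(chain$n_in[-1] == chain$n_kept[-nrow(chain)]))
  }
  both <- a[a$accession == "both", , drop = FALSE]
  expect_identical(both$n_in[1],
                   sum(a$n_kept[a$stage == "coding_classification"]))
  expect_true(all(both$n_in[-1] == both$n_kept[-nrow(both)]))
  # kept counts never increase along the merged chain
  expect_true(all(diff(both$n_kept) <= 0))
})

test_that("pipeline output is invariant to transcript input order", {
  b <- defaultBundle()
  ref <- defaultPipelineResult()
  ev <- b[c("expression_a", "expression_b", "protein_hits_a",
            "protein_hits_b", "taxon_map", "ab_hits", "cm_hits")]
  set.seed(99)
  shufA <- b$transcripts_a[sample(length(b$transcripts_a))]
  shufB <- b$transcripts_b[sample(length(b$transcripts_b))]
  res <- runLncPipeline(shufA, shufB, ev, lncPipelineConfig())
  expect_identical(lncrnaIds(res), lncrnaIds(ref))
  expect_identical(flaggedIds(res), flaggedIds(ref))
})

test_that("empty inputs produce an empty set with an all-zero audit", {
  empty <- DNAStringSet()
  mcols(empty)$description <- character(0)
  ev <- list(expression_a = data.frame(transcript_id = character(0),
                                       fpkm = numeric(0)),
             expression_b = data.frame(transcript_id = character(0),
                                       fpkm = numeric(0)),
             protein_hits_a = makeHits(character(0), character(0)),
             protein_hits_b = makeHits(character(0), character(0)),
             taxon_map = c(VITVI = "plant"),
             ab_hits = makeHits(character(0), character(0)),
             cm_hits = data.frame(query_id = character(0),
                                  model_accession = character(0),
                                  evalue = numeric(0), score = numeric(0)))
  res <- runLncPipeline(empty, empty, ev, lncPipelineConfig())
  expect_identical(length(lncrnaIds(res)), 0L)
  a <- auditTable(res)
  expect_true(all(a$n_in == 0L) && all(a$n_kept == 0L))
})

test_that("externally supplied cluster tables replace the built-in clustering", {
  b <- defaultBundle()
  ev <- b[c("expression_a", "expression_b", "protein_hits_a",
            "protein_hits_b", "taxon_map", "ab_hits", "cm_hits")]
  # precomputed tables that declare every transcript its own representative
  selfCluster <- function(seqs) {
    data.frame(cluster_id = seq_along(seqs) - 1L, member_id = names(seqs),
               is_representative = TRUE, stringsAsFactors = FALSE)
  }
  ev$clusters_a <- selfCluster(b$transcripts_a)
  ev$clusters_b <- selfCluster(b$transcripts_b)
  res <- runLncPipeline(b$transcripts_a, b$transcripts_b, ev,
                        lncPipelineConfig())
  a <- auditTable(res)
  expect_true(all(a$n_removed[a$stage == "cluster"] == 0L))
  # the redundant copies now die at the expression stage or survive to
  # consensus, where they lack a cross-accession partner
  expect_setequal(lncrnaIds(res), lncrnaIds(defaultPipelineResult()))
})
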