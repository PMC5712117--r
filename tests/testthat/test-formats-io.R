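# Readers and writers for the external evidence formats.

test_that("FASTA reading upper-cases, concatenates multi-line records and keeps order", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">t1", "acgt"), f)
  recs <- readFastaRecords(f)
  expect_identical(names(recs), "t1")
  expect_identical(as.character(recs[["t1"]]), "ACGT")

  writeLines(c(">a", "AC", "GT", ">b", "GG"), f)
  recs <- readFastaRecords(f)
  expect_identical(names(recs), c("a", "b"))
  expect_identical(as.character(recs[["a"]]), "ACGT")
})

test_that("FASTA reading converts U to T and rejects duplicate ids and empty sequences", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">r1 some description", "AUGCU"), f)
  recs <- readFastaRecords(f)
  expect_identical(as.character(recs[["r1"]]), "ATGCT")
  expect_identical(mcols(recs)$description, "some description")

  writeLines(c(">t1", "ACGT", ">t1", "GGCC"), f)
  expect_error(readFastaRecords(f), "t1", class = "vinelncFormatError")

  writeLines(c(">empty", "", ">ok", "ACGT"), f)
  expect_error(readFastaRecords(f), "empty", class = "vinelncFormatError")
})

test_that("FASTA write/read round trip reproduces records exactly", {
  f <- withr::local_tempfile(fileext = ".fasta")
  seqs <- namedDna(list(x1 = "ACGTACGTNN", x2 = strrep("ACGT", 40)))
  mcols(seqs)$description <- c("first record", "")
  writeFastaRecords(seqs, f)
  back <- readFastaRecords(f)
  expect_identical(names(back), names(seqs))
  expect_identical(as.character(back), as.character(seqs))
  expect_identical(mcols(back)$description, mcols(seqs)$description)
})

test_that("BLAST tabular reader maps the standard columns and skips comments", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# a comment",
               paste("q1", "s1", "98.5", "240", "0", "0", "1", "240", "1",
                     "240", "1e-50", "200", sep = "\t"),
               paste("q2", "s2", "100.0", "100", "0", "0", "1", "100", "1",
                     "100", "0.0", "180", sep = "\t")), f)
  hits <- readBlastTab(f)
  expect_identical(nrow(hits), 2L)
  expect_identical(hits$query_id, c("q1", "q2"))
  expect_equal(hits$percent_identity[1], 98.5)
  expect_equal(hits$alignment_length[1], 240)
  expect_equal(hits$evalue, c(1e-50, 0))   # E-value 0.0 is accepted
  expect_equal(hits$bit_score, c(200, 180))
})

test_that("BLAST tabular reader reports short rows with their line number", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(c("q1", "s1", "98.5", "240", rep("1", 6), "1e-50", "200"),
                     collapse = "\t"),
               paste("q2", "s2", "90", "100", sep = "\t")), f)
  expect_error(readBlastTab(f), "line 2", class = "vinelncFormatError")
  # extra trailing columns are tolerated
  writeLines(paste(c("q1", "s1", "98.5", "240", rep("1", 6), "1e-50", "200",
                     "extra1", "extra2"), collapse = "\t"), f)
  expect_identical(nrow(readBlastTab(f)), 1L)
})

test_that("hmmscan and cmscan tblout readers pick the documented columns", {
  f <- withr::local_tempfile(fileext = ".tbl")
  writeHmmscan(data.frame(query_id = "gene1", domain_accession = "PF00069.26",
                          evalue = 3.2e-8, score = 55.5), f)
  h <- readHmmscan(f)
  expect_identical(h$query_id, "gene1")
  expect_identical(h$domain_accession, "PF00069")  # version suffix stripped
  expect_equal(h$evalue, 3.2e-8)
  expect_equal(h$score, 55.5)

  writeCmscan(data.frame(query_id = "t9", model_accession = "RF00005",
                         evalue = 0.004, score = 31.2), f)
  cmHits <- readCmscan(f)
  expect_identical(cmHits$query_id, "t9")
  expect_identical(cmHits$model_accession, "RF00005")
  expect_equal(cmHits$evalue, 0.004)
  expect_equal(cmHits$score, 31.2)
})

test_that("expression reader accepts both headered and bare two-column dialects", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tFPKM", "t1\t1.50", "t2\t0.00"), f)
  e <- readExpression(f)
  expect_identical(e$transcript_id, c("t1", "t2"))
  expect_equal(e$fpkm, c(1.5, 0))

  writeLines(c("t1\t2.25", "t2\t7"), f)
  e <- readExpression(f)
  expect_equal(e$fpkm, c(2.25, 7))

  writeLines(c("t1\t-1"), f)
  expect_error(readExpression(f), "negative", class = "vinelncFormatError")
})

test_that("GFF3 gene reader assigns 0-based per-chromosome ranks by start", {
  f <- withr::local_tempfile(fileext = ".gff3")
  genes <- makeGenes(c("g2", "g1", "g3"), c("chr1", "chr1", "chr2"),
                     c(500L, 100L, 900L))
  writeGff3Genes(genes, f)
  back <- readGff3Genes(f)
  tab <- data.frame(gene_id = mcols(back)$gene_id, rank = mcols(back)$rank)
  expect_identical(tab$rank[tab$gene_id == "g1"], 0L)
  expect_identical(tab$rank[tab$gene_id == "g2"], 1L)
  expect_identical(tab$rank[tab$gene_id == "g3"], 0L)
  # rank is a bijection onto 0..n-1 within each chromosome
  byChrom <- split(tab$rank[order(mcols(back)$gene_id)],
                   as.character(seqnames(back))[order(mcols(back)$gene_id)])
  for (r in byChrom) expect_setequal(r, seq_along(r) - 1L)
})

test_that("RNAfold reader parses blocks and validates the dot-bracket", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">t1", "AUGC", "(..) ( -1.20)"), f)
  folds <- readRnafold(f)
  expect_identical(folds$id, "t1")
  expect_equal(folds$mfe, -1.2)
  expect_identical(folds$dot_bracket, "(..)")

  writeLines(c(">t1", "AUGC", "((.) ( -1.20)"), f)
  expect_error(readRnafold(f), "unbalanced", class = "vinelncFormatError")
  writeLines(c(">t1", "AUGC", "(...) ( -1.20)"), f)
  expect_error(readRnafold(f), "length", class = "vinelncFormatError")
})

test_that(".clstr reader recovers members and flags the starred representative", {
  f <- withr::local_tempfile(fileext = ".clstr")
  writeLines(c(">Cluster 0",
               "0\t420nt, >t1... *",
               "1\t400nt, >t2... at +/98.00%",
               ">Cluster 1",
               "0\t300nt, >t3... *"), f)
  cl <- readClstr(f)
  expect_identical(cl$cluster_id, c(0L, 0L, 1L))
  expect_identical(cl$member_id, c("t1", "t2", "t3"))
  expect_identical(cl$is_representative, c(TRUE, FALSE, TRUE))
  expect_setequal(clusterRepresentatives(cl), c("t1", "t3"))

  writeLines(c(">Cluster 0", "0\t420nt, >t1... at +/98.00%"), f)
  expect_error(readClstr(f), "representative", class = "vinelncFormatError")
})

test_that("pfam2go reader accepts both the flat GO-project dialect and 3-column TSV", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("!version: test",
               "Pfam:PF00069 Pkinase > GO:protein kinase activity ; GO:0004672"),
             f)
  m <- readPfam2go(f)
  expect_identical(m$domain_accession, "PF00069")
  expect_identical(m$go_id, "GO:0004672")
  expect_true(is.na(m$go_class))

  writeLines(c("PF00069\tGO:0004672\tmolecular_function",
               "PF00069\tGO:0006468\tbiological_process"), f)
  m <- readPfam2go(f)
  expect_identical(m$go_class, c("molecular_function", "biological_process"))

  writeLines("PF00069\tGO:0004672\tnot_a_root", f)
  expect_error(readPfam2go(f), "ontology", class = "vinelncFormatError")
})

test_that("every file of a written synthetic bundle parses back through its reader", {
  dir <- withr::local_tempdir()
  b <- simBundle(simConfig(seed = 11L), dir)
  a <- readFastaRecords(file.path(dir, "transcripts_a.fasta"))
  expect_identical(as.character(a), as.character(b$transcripts_a))
  expect_equal(readExpression(file.path(dir, "expression_a.tsv"))$fpkm,
               b$expression_a$fpkm)
  abHits <- readBlastTab(file.path(dir, "ab_hits.tsv"))
  expect_identical(abHits$query_id, b$ab_hits$query_id)
  expect_equal(abHits$evalue, b$ab_hits$evalue)
  expect_equal(abHits$bit_score, b$ab_hits$bit_score)
  cmHits <- readCmscan(file.path(dir, "cmscan.tbl"))
  expect_identical(cmHits$query_id, b$cm_hits$query_id)
  expect_equal(cmHits$evalue, b$cm_hits$evalue)
  folds <- readRnafold(file.path(dir, "folds.txt"))
  expect_identical(folds$id, b$folds$id)
  expect_equal(folds$mfe, b$folds$mfe)
  gA <- readGff3Genes(file.path(dir, "annotation_a.gff3"))
  expect_setequal(mcols(gA)$gene_id, mcols(b$genes_a)$gene_id)
  expect_identical(mcols(gA)$rank, mcols(b$genes_a)$rank)
})
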