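#' @title Synthetic fixtures with planted ground truth
#' @description Generates every input the toolkit consumes — transcripts,
#'   expression tables, protein and cross-accession alignment tables,
#'   covariance-model hits, fold results, two gene-model annotations with
#'   planted orthologs, and a self-alignment table with planted tandem
#'   arrays — together with a truth table recording what was planted, so
#'   every pipeline stage and the end-to-end run can be verified without
#'   external data.  Scores are ordinally consistent (better planted
#'   homology gets better scores); no alignment engine is simulated.
#' @name synthetic
NULL

#' Simulation configuration
#'
#' Class parameters emulate the contrasts seen between plant lncRNAs and
#' protein-coding transcripts: lncRNAs are shorter, lower in GC, and have
#' a higher (less negative) length-corrected minimum free energy.  The
#' length-corrected MFE means and standard deviations default to
#' -0.276 +/- 0.026 kcal/mol/nt (coding) versus -0.210 +/- 0.041
#' (noncoding).  Every default bundle also plants one boundary case per
#' pipeline threshold, on each side of the boundary, so threshold
#' inclusivity is pinned by tests.
#'
#' @param seed integer RNG seed; the same seed yields byte-identical
#'   outputs.
#' @param n_coding,n_noncoding,n_housekeeping class sizes
#'   (n_noncoding >= 4 so the four keep-side boundary cases exist).
#' @param n_redundant near-identical copies planted to exercise the
#'   clustering stage.
#' @param coding_gc,noncoding_gc,housekeeping_gc per-class GC targets.
#' @param coding_meanlog,coding_sdlog,noncoding_meanlog,noncoding_sdlog
#'   log-normal length parameters per class.
#' @param coding_mfe_mean,coding_mfe_sd,noncoding_mfe_mean,noncoding_mfe_sd
#'   per-class length-corrected MFE parameters (kcal/mol/nt).
#' @param fpkm_meanlog,fpkm_sdlog expression distribution parameters.
#' @param nonplant_rate fraction of coding transcripts whose best protein
#'   hit is to a non-plant organism.
#' @param n_orthologs planted one-to-one ortholog pairs between the two
#'   gene annotations.
#' @param n_masked_triads ortholog pairs hidden behind a stronger paralog
#'   so they are only recoverable by a second anchoring round.
#' @return a list of class \code{simConfig}.
#' @export
simConfig <- function(seed = 1L, n_coding = 40L, n_noncoding = 30L,
                      n_housekeeping = 6L, n_redundant = 6L,
                      coding_gc = 0.45, noncoding_gc = 0.38,
                      housekeeping_gc = 0.55,
                      coding_meanlog = log(900), coding_sdlog = 0.45,
                      noncoding_meanlog = log(420), noncoding_sdlog = 0.30,
                      coding_mfe_mean = -0.276, coding_mfe_sd = 0.026,
                      noncoding_mfe_mean = -0.210, noncoding_mfe_sd = 0.041,
                      fpkm_meanlog = log(8), fpkm_sdlog = 1,
                      nonplant_rate = 0.2,
                      n_orthologs = 30L, n_masked_triads = 5L) {
  cfg <- as.list(environment())
  counts <- c(n_coding, n_noncoding, n_housekeeping, n_redundant,
              n_orthologs, n_masked_triads)
  if (any(counts < 0)) usageError("all class counts must be >= 0")
  if (n_noncoding > 0 && n_noncoding < 4L) {
    usageError("n_noncoding must be 0 or >= 4 (the keep-side boundary cases)")
  }
  if (2L * n_masked_triads > n_orthologs) {
    usageError("masked triads cannot exceed half the ortholog pairs")
  }
  structure(cfg, class = "simConfig")
}

SIM_CHROMS <- c(paste0("chr", 1:5), "chrUkn")

randomSeq <- function(length, gc) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

mutateSeq <- function(seq, rate) {
  b <- strsplit(seq, "")[[1]]
  hit <- runif(length(b)) < rate
  if (any(hit)) {
    b[hit] <- vapply(b[hit], function(x) {
      sample(setdiff(c("A", "C", "G", "T"), x), 1L)
    }, character(1))
  }
  paste(b, collapse = "")
}

# stomp stop codons into any reading frame until no ORF reaches the flag
# threshold, so planted noncoding transcripts never trip the coding flag
scrubOrfs <- function(seq, max_codons = 100L) {
  for (i in 1:200) {
    info <- longestOrfInfo(seq)
    if (info$codons < max_codons) return(seq)
    s <- if (info$strand == "-") revComp(seq) else seq
    pos <- info$start_nt + 3L * (info$codons %/% 2L)
    substr(s, pos, pos + 2L) <- "TAA"
    seq <- if (info$strand == "-") revComp(s) else s
  }
  dataError("could not scrub open reading frames from a synthetic sequence")
}

# a sequence carrying one ORF of exactly `codons` codons (start included)
plantedOrfSeq <- function(total_length, codons, gc) {
  sense <- c("GCA", "GCC", "GGA", "GGC", "TGC", "GAC", "GAA", "TTC", "CAC",
             "ATC", "AAA", "CTC", "AAC", "CCA", "CAA", "CGC", "TCC", "ACC",
             "GTC", "TAC")
  orf <- paste0("ATG", paste(sample(sense, codons - 1L, replace = TRUE),
                             collapse = ""), "TGA")
  flank <- total_length - nchar(orf)
  left <- max(0L, flank %/% 2L)
  right <- max(0L, flank - left)
  paste0(scrubOrfs(randomSeq(max(left, 3L), gc), codons),
         orf,
         scrubOrfs(randomSeq(max(right, 3L), gc), codons))
}

drawLengths <- function(n, meanlog, sdlog, lo, hi) {
  pmin(pmax(round(rlnorm(n, meanlog, sdlog)), lo), hi)
}

#' Generate transcripts with planted truth
#'
#' Accession-A transcripts for every planted class: protein-coding,
#' noncoding (the first four carrying the keep-side boundary
#' annotations), housekeeping structured RNAs, the removed-side boundary
#' decoys, and near-identical redundant copies.  Noncoding transcripts
#' are scrubbed of accidental long open reading frames so only the
#' planted ORF decoy can trip the coding flag.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{sequences} (named \code{DNAStringSet}) and
#'   \code{truth} (data frame: transcript_id, class, boundary, violation,
#'   planted_fpkm, planted_mfe_per_nt, partner_id, chromosome).
#' @export
genTranscripts <- function(cfg) {
  withr::with_seed(cfg$seed, genTranscriptsImpl(cfg))
}

genTranscriptsImpl <- function(cfg) {
  rows <- list()
  seqs <- character(0)
  addRec <- function(id, seq, class, boundary = NA_character_,
                     violation = NA_character_, fpkm = NA_real_,
                     mfe_per_nt = NA_real_, partner = NA_character_) {
    seqs[[id]] <<- seq
    rows[[length(rows) + 1L]] <<- data.frame(
      transcript_id = id, class = class, boundary = boundary,
      violation = violation, planted_fpkm = fpkm,
      planted_mfe_per_nt = mfe_per_nt, partner_id = partner,
      chromosome = sample(SIM_CHROMS, 1L), stringsAsFactors = FALSE)
  }
  drawFpkm <- function() max(1.6, round(rlnorm(1, cfg$fpkm_meanlog, cfg$fpkm_sdlog), 2))

  codLen <- drawLengths(cfg$n_coding, cfg$coding_meanlog, cfg$coding_sdlog,
                        300L, 4000L)
  for (i in seq_len(cfg$n_coding)) {
    addRec(sprintf("cod_%03d", i), randomSeq(codLen[i], cfg$coding_gc),
           "coding", fpkm = drawFpkm(),
           mfe_per_nt = rnorm(1, cfg$coding_mfe_mean, cfg$coding_mfe_sd))
  }

  lncLen <- drawLengths(cfg$n_noncoding, cfg$noncoding_meanlog,
                        cfg$noncoding_sdlog, 260L, 1500L)
  keepBoundaries <- c("expression_keep", "consensus_keep", "rfam_keep",
                      "protein_keep")
  for (i in seq_len(cfg$n_noncoding)) {
    id <- sprintf("lnc_%03d", i)
    boundary <- if (i <= length(keepBoundaries)) keepBoundaries[i] else NA_character_
    fpkm <- if (identical(boundary, "expression_keep")) 1.50 else drawFpkm()
    addRec(id, scrubOrfs(randomSeq(lncLen[i], cfg$noncoding_gc)),
           "noncoding", boundary = boundary, fpkm = fpkm,
           mfe_per_nt = rnorm(1, cfg$noncoding_mfe_mean, cfg$noncoding_mfe_sd),
           partner = paste0(id, "_vent"))
  }

  for (i in seq_len(cfg$n_housekeeping)) {
    id <- sprintf("hk_%02d", i)
    addRec(id, scrubOrfs(randomSeq(round(runif(1, 300, 600)),
                                   cfg$housekeeping_gc)),
           "housekeeping_ncRNA", fpkm = drawFpkm(),
           partner = paste0(id, "_vent"))
  }

  if (cfg$n_noncoding > 0L) {
    lncLike <- function() scrubOrfs(randomSeq(round(runif(1, 300, 700)),
                                              cfg$noncoding_gc))
    addRec("decoy_fpkm", lncLike(), "decoy", violation = "expression",
           fpkm = 1.49,
           mfe_per_nt = rnorm(1, cfg$noncoding_mfe_mean, cfg$noncoding_mfe_sd))
    addRec("decoy_aln", lncLike(), "decoy", violation = "consensus",
           fpkm = drawFpkm(), partner = "decoy_aln_vent")
    addRec("decoy_rfam", lncLike(), "decoy", violation = "rfam",
           fpkm = drawFpkm(), partner = "decoy_rfam_vent")
    addRec("decoy_prot", lncLike(), "decoy", violation = "coding_classification",
           fpkm = drawFpkm())
    addRec("decoy_orf",
           plantedOrfSeq(600L, 120L, cfg$noncoding_gc), "decoy",
           violation = "orf_flag", fpkm = drawFpkm(),
           partner = "decoy_orf_vent")
  }

  # near-identical copies, slightly shorter so the original stays the
  # cluster representative
  originals <- grep("^(cod|lnc)_", names(seqs), value = TRUE)
  dupSrc <- sample(originals, min(cfg$n_redundant, length(originals)))
  for (src in dupSrc) {
    copy <- mutateSeq(substr(seqs[[src]], 1L, nchar(seqs[[src]]) - 10L), 0.02)
    addRec(paste0("dup_", src), copy, "decoy", violation = "cluster",
           fpkm = drawFpkm())
  }

  out <- if (length(seqs)) DNAStringSet(unlist(seqs)) else
    DNAStringSet(structure(character(0), names = character(0)))
  mcols(out)$description <- rep("", length(out))
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(0), class = character(0),
               boundary = character(0), violation = character(0),
               planted_fpkm = numeric(0), planted_mfe_per_nt = numeric(0),
               partner_id = character(0), chromosome = character(0),
               stringsAsFactors = FALSE)
  list(sequences = out, truth = truth)
}

orderedHitRow <- function(query, subject, pid, aln, evalue, bits) {
  data.frame(query_id = query, subject_id = subject, percent_identity = pid,
             alignment_length = aln, evalue = evalue, bit_score = bits,
             stringsAsFactors = FALSE)
}

bindHits <- function(rows) {
  if (length(rows) == 0L) return(emptyHits())
  do.call(rbind, rows)
}

# planted gene layout: ids laid out along their chromosomes, 2 kb apart
layoutGenes <- function(ids, chroms) {
  offset <- as.integer(stats::ave(seq_along(ids), chroms, FUN = seq_along))
  starts <- 1000L + 2000L * (offset - 1L)
  assignRanks(GRanges(chroms, IRanges(starts, width = 1200L), strand = "+",
                      gene_id = ids))
}

#' Generate all evidence tables for a planted truth
#'
#' @param truthBundle output of \code{\link{genTranscripts}}.
#' @param cfg the \code{\link{simConfig}} used to generate it.
#' @return list with the accession-B partner transcripts, every evidence
#'   table the pipeline and anchoring modules consume, and the planted
#'   truth for orthologs and tandem arrays.
#' @export
genEvidence <- function(truthBundle, cfg) {
  withr::with_seed(cfg$seed + 1L, genEvidenceImpl(truthBundle, cfg))
}

genEvidenceImpl <- function(truthBundle, cfg) {
  truth <- truthBundle$truth
  seqsA <- truthBundle$sequences
  plantCodes <- c("VITVI", "SOYBN", "ARATH")
  nonPlantCodes <- c("HUMAN", "YEAST", "ECOLI")
  taxonMap <- setNames(c(rep("plant", 3), rep("non_plant", 3)),
                       c(plantCodes, nonPlantCodes))

  # ---- accession-B partners: shorter mutated copies of their A mates ----
  partnered <- truth[!is.na(truth$partner_id), , drop = FALSE]
  seqsB <- character(0)
  for (i in seq_len(nrow(partnered))) {
    src <- as.character(seqsA[[partnered$transcript_id[i]]])
    seqsB[[partnered$partner_id[i]]] <-
      mutateSeq(substr(src, 1L, round(nchar(src) * 0.9)), 0.01)
  }
  if (cfg$n_noncoding > 0L) {
    for (i in 1:4) {  # accession-B-only transcripts: die at consensus
      seqsB[[sprintf("bonly_%02d", i)]] <-
        scrubOrfs(randomSeq(round(runif(1, 300, 600)), cfg$noncoding_gc))
    }
  }
  setB <- if (length(seqsB)) DNAStringSet(unlist(seqsB)) else
    DNAStringSet(structure(character(0), names = character(0)))
  mcols(setB)$description <- rep("", length(setB))

  # ---- expression ----
  expressionA <- data.frame(transcript_id = truth$transcript_id,
                            fpkm = truth$planted_fpkm,
                            stringsAsFactors = FALSE)
  expressionB <- data.frame(transcript_id = names(setB),
                            fpkm = round(runif(length(setB), 2, 40), 2),
                            stringsAsFactors = FALSE)

  # ---- protein homology ----
  prot <- list()
  coding <- truth$transcript_id[truth$class == "coding"]
  nonPlant <- runif(length(coding)) < cfg$nonplant_rate
  for (i in seq_along(coding)) {
    code <- if (nonPlant[i]) sample(nonPlantCodes, 1L) else sample(plantCodes, 1L)
    prot[[length(prot) + 1L]] <- orderedHitRow(
      coding[i], sprintf("SP%05d_%s", i, code), round(runif(1, 55, 95), 1),
      round(runif(1, 150, 900)), 10^-runif(1, 30, 80),
      round(runif(1, 250, 900), 1))
    # a dominated second hit with a worse score, always plant-side
    prot[[length(prot) + 1L]] <- orderedHitRow(
      coding[i], sprintf("SP2%04d_%s", i, sample(plantCodes, 1L)),
      round(runif(1, 40, 60), 1), round(runif(1, 100, 400)),
      10^-runif(1, 21, 28), round(runif(1, 80, 200), 1))
  }
  if ("decoy_prot" %in% truth$transcript_id) {
    prot[[length(prot) + 1L]] <- orderedHitRow(
      "decoy_prot", "SPDEC01_VITVI", 70, 300, 1e-20, 180)
  }
  keepers <- truth$transcript_id[!is.na(truth$boundary) &
                                   truth$boundary == "protein_keep"]
  for (id in keepers) {
    prot[[length(prot) + 1L]] <- orderedHitRow(
      id, "SPKEEP1_VITVI", 68, 280, 2e-20, 170)
  }
  # sub-threshold chatter on a few noncoding transcripts
  lncIds <- truth$transcript_id[truth$class == "noncoding"]
  for (id in head(lncIds, 3L)) {
    prot[[length(prot) + 1L]] <- orderedHitRow(
      id, "SPWEAK1_VITVI", 45, 120, 1e-5, 60)
  }
  proteinHitsA <- bindHits(prot)
  proteinHitsB <- emptyHits()

  # ---- cross-accession alignments ----
  ab <- list()
  for (i in seq_len(nrow(partnered))) {
    id <- partnered$transcript_id[i]
    mate <- partnered$partner_id[i]
    lenA <- width(seqsA)[match(id, names(seqsA))]
    lenB <- width(setB)[match(mate, names(setB))]
    aln <- max(200L, round(min(lenA, lenB) * 0.9))
    if (identical(partnered$violation[i], "consensus")) aln <- 199L
    if (identical(partnered$boundary[i], "consensus_keep")) aln <- 200L
    ab[[length(ab) + 1L]] <- orderedHitRow(
      id, mate, round(runif(1, 95, 99), 1), aln, 1e-60,
      round(aln * 1.8, 1))
    # a dominated off-target hit for some queries
    if (i %% 5L == 0L) {
      ab[[length(ab) + 1L]] <- orderedHitRow(
        id, sample(names(setB), 1L), round(runif(1, 80, 90), 1),
        round(aln * 0.6), 1e-20, round(aln * 0.7, 1))
    }
  }
  abHits <- bindHits(ab)

  # ---- covariance-model hits ----
  cm <- list()
  hk <- truth$transcript_id[truth$class == "housekeeping_ncRNA"]
  for (i in seq_along(hk)) {
    cm[[length(cm) + 1L]] <- data.frame(
      query_id = hk[i], model_accession = sprintf("RF%05d", i),
      evalue = 10^-runif(1, 3, 8), score = round(runif(1, 40, 90), 1),
      stringsAsFactors = FALSE)
  }
  if ("decoy_rfam" %in% truth$transcript_id) {
    cm[[length(cm) + 1L]] <- data.frame(
      query_id = "decoy_rfam", model_accession = "RF99901", evalue = 0.01,
      score = 20.0, stringsAsFactors = FALSE)
  }
  rfKeep <- truth$transcript_id[!is.na(truth$boundary) &
                                  truth$boundary == "rfam_keep"]
  for (id in rfKeep) {
    cm[[length(cm) + 1L]] <- data.frame(
      query_id = id, model_accession = "RF99902", evalue = 0.011, score = 18.0,
      stringsAsFactors = FALSE)
  }
  cmHits <- if (length(cm)) do.call(rbind, cm) else
    data.frame(query_id = character(0), model_accession = character(0),
               evalue = numeric(0), score = numeric(0))

  # ---- folds: planted per-class length-corrected MFE ----
  mfePerNt <- truth$planted_mfe_per_nt
  mfePerNt[is.na(mfePerNt)] <- rnorm(sum(is.na(mfePerNt)),
                                     cfg$noncoding_mfe_mean,
                                     cfg$noncoding_mfe_sd)
  lens <- width(seqsA)[match(truth$transcript_id, names(seqsA))]
  folds <- data.frame(id = truth$transcript_id,
                      sequence = as.character(seqsA[truth$transcript_id]),
                      dot_bracket = strrep(".", lens),
                      mfe = round(mfePerNt * lens, 2),
                      stringsAsFactors = FALSE)

  # ---- two gene annotations with planted orthologs ----
  nA <- cfg$n_orthologs + 6L
  idsA <- sprintf("RiesG%03d", seq_len(nA))
  idsB <- sprintf("Vitv%03d", seq_len(nA))
  chromPool <- rep(paste0("chr", 1:5), length.out = nA)
  chromA <- chromPool
  chromB <- chromPool
  if (cfg$n_orthologs >= 5L) {
    chromB[1:2] <- "chrUkn"                     # concordance: involves_chrUkn
    chromB[3:5] <- c("chr4", "chr5", "chr1")    # different placed chromosome
  }
  resA <- sprintf("RiesU%02d", 1:3)   # unsupported legacy-side rescue models
  genesA <- layoutGenes(c(idsA, resA),
                        c(chromA, "chr1", "chr2", "chrUkn"))
  genesB <- layoutGenes(idsB, chromB)

  orth <- data.frame(a_id = idsA[seq_len(cfg$n_orthologs)],
                     b_id = idsB[seq_len(cfg$n_orthologs)],
                     masked = rep(FALSE, cfg$n_orthologs),
                     stringsAsFactors = FALSE)
  fwd <- list(); rev <- list()
  addMutual <- function(a, b, bits) {
    e <- 10^-(bits / 4)
    fwd[[length(fwd) + 1L]] <<- orderedHitRow(a, b, 90, 500, e, bits)
    rev[[length(rev) + 1L]] <<- orderedHitRow(b, a, 90, 500, e, bits)
  }
  maskedIdx <- if (cfg$n_masked_triads > 0L)
    seq_len(2L * cfg$n_masked_triads) else integer(0)
  plainIdx <- setdiff(seq_len(cfg$n_orthologs), maskedIdx)
  for (i in plainIdx) addMutual(orth$a_id[i], orth$b_id[i],
                                round(runif(1, 300, 500)))
  for (tIdx in seq_len(cfg$n_masked_triads)) {
    p <- 2L * tIdx - 1L
    q <- 2L * tIdx
    orth$masked[q] <- TRUE
    # (a_p, b_p) dominate; (a_q, b_q) surface once the first pair is removed
    addMutual(orth$a_id[p], orth$b_id[p], 400)
    fwd[[length(fwd) + 1L]] <- orderedHitRow(orth$a_id[q], orth$b_id[p],
                                             85, 450, 1e-80, 360)
    rev[[length(rev) + 1L]] <- orderedHitRow(orth$b_id[p], orth$a_id[q],
                                             85, 450, 1e-80, 360)
    addMutual(orth$a_id[q], orth$b_id[q], 200)
  }
  # dominated decoy paralog rows that must never change the outcome
  for (i in head(plainIdx, 4L)) {
    fwd[[length(fwd) + 1L]] <- orderedHitRow(
      orth$a_id[i], idsB[nA - 1L], 60, 300, 1e-10, 80)
  }
  fwdHits <- bindHits(fwd)
  revHits <- bindHits(rev)

  # ---- rescue pass fixtures: unanchored legacy models ----
  resB <- idsB[(cfg$n_orthologs + 1L):(cfg$n_orthologs + 3L)]
  rescueFwd <- bindHits(lapply(1:3, function(i)
    orderedHitRow(resA[i], resB[i], 88, 450, 1e-30, 280)))
  rescueRev <- bindHits(lapply(1:3, function(i)
    orderedHitRow(resB[i], resA[i], 88, 450, 1e-30, 280)))

  # ---- self-alignment with planted tandem arrays over annotation B ----
  # (needs >= 5 ortholog genes so every planted chromosome holds enough
  # gene models; degenerate configs get empty tandem fixtures)
  tabB <- geneTable(genesB)
  pickAdjacent <- function(chrom, k) {
    genes <- tabB[tabB$chromosome == chrom, , drop = FALSE]
    genes <- genes[order(genes$rank), , drop = FALSE]
    genes$gene_id[seq_len(k)]
  }
  if (cfg$n_orthologs >= 5L) {
    triple <- pickAdjacent("chr1", 3L)
    pairTandem <- pickAdjacent("chr2", 2L)
    proxPair <- {
      genes <- tabB[tabB$chromosome == "chr3", , drop = FALSE]
      genes <- genes[order(genes$rank), , drop = FALSE]
      genes$gene_id[c(1L, 4L)]
    }
    dispPair <- c(pickAdjacent("chr4", 1L), pickAdjacent("chr5", 1L))
    selfRows <- list()
    addSelf <- function(g1, g2, evalue = 1e-40) {
      selfRows[[length(selfRows) + 1L]] <<- orderedHitRow(g1, g2, 92, 800,
                                                          evalue, 520)
      selfRows[[length(selfRows) + 1L]] <<- orderedHitRow(g2, g1, 92, 800,
                                                          evalue, 520)
    }
    addSelf(triple[1], triple[2])
    addSelf(triple[2], triple[3])
    addSelf(pairTandem[1], pairTandem[2])
    addSelf(proxPair[1], proxPair[2])
    addSelf(dispPair[1], dispPair[2])
    selfRows[[length(selfRows) + 1L]] <- orderedHitRow(triple[1], triple[1],
                                                       100, 1200, 0, 900)
    selfRows[[length(selfRows) + 1L]] <- orderedHitRow(tabB$gene_id[1],
                                                       tabB$gene_id[12],
                                                       55, 150, 1e-19, 70)
    selfHits <- bindHits(selfRows)
    tandemTruth <- list(arrays = list(triple, pairTandem),
                        proximal = proxPair, dispersed = dispPair)
  } else {
    selfHits <- emptyHits()
    tandemTruth <- list(arrays = list(), proximal = character(0),
                        dispersed = character(0))
  }

  list(transcripts_b = setB,
       expression_a = expressionA, expression_b = expressionB,
       protein_hits_a = proteinHitsA, protein_hits_b = proteinHitsB,
       taxon_map = taxonMap, ab_hits = abHits, cm_hits = cmHits,
       folds = folds,
       genes_a = genesA, genes_b = genesB,
       fwd_hits = fwdHits, rev_hits = revHits, self_hits = selfHits,
       rescue_fwd = rescueFwd, rescue_rev = rescueRev,
       rescue_b_ids = resB,
       ortholog_truth = orth, tandem_truth = tandemTruth)
}

#' Generate a complete fixture bundle
#'
#' Runs \code{\link{genTranscripts}} and \code{\link{genEvidence}} and,
#' if \code{outdir} is given, writes every piece in its native text
#' format (FASTA, expression TSV, BLAST tabular, cmscan tblout, RNAfold
#' text, GFF3, truth TSV) so the round trip through the readers can be
#' exercised.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param outdir optional output directory, created if needed.
#' @return list combining the transcripts, truth table and evidence.
#' @export
simBundle <- function(cfg = simConfig(), outdir = NULL) {
  tr <- genTranscripts(cfg)
  ev <- genEvidence(tr, cfg)
  bundle <- c(list(transcripts_a = tr$sequences, truth = tr$truth), ev)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outdir, f)
    writeFastaRecords(bundle$transcripts_a, p("transcripts_a.fasta"))
    writeFastaRecords(bundle$transcripts_b, p("transcripts_b.fasta"))
    writeExpression(bundle$expression_a, p("expression_a.tsv"))
    writeExpression(bundle$expression_b, p("expression_b.tsv"))
    writeBlastTab(bundle$protein_hits_a, p("protein_hits_a.tsv"))
    writeBlastTab(bundle$protein_hits_b, p("protein_hits_b.tsv"))
    writeBlastTab(bundle$ab_hits, p("ab_hits.tsv"))
    writeBlastTab(bundle$fwd_hits, p("fwd_hits.tsv"))
    writeBlastTab(bundle$rev_hits, p("rev_hits.tsv"))
    writeBlastTab(bundle$self_hits, p("self_hits.tsv"))
    writeCmscan(bundle$cm_hits, p("cmscan.tbl"))
    writeRnafold(bundle$folds, p("folds.txt"))
    writeGff3Genes(bundle$genes_a, p("annotation_a.gff3"))
    writeGff3Genes(bundle$genes_b, p("annotation_b.gff3"))
    write.table(bundle$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  bundle
}

#' Write covariance-model hits as a cmscan-style tblout file
#' @param cm_hits data frame with columns query_id, model_accession,
#'   evalue, score.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCmscan <- function(cm_hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#target name  accession  query name  accession  mdl  mdl from  mdl to  seq from  seq to  strand  trunc  pass  gc  bias  score  E-value  inc  description of target",
             con)
  for (i in seq_len(nrow(cm_hits))) {
    writeLines(paste("family", cm_hits$model_accession[i],
                     cm_hits$query_id[i], "-", "cm", 1, 100, 1, 100, "+",
                     "no", 1, 0.5, 0.0, cm_hits$score[i],
                     sprintf("%.15g", cm_hits$evalue[i]), "!", "planted",
                     sep = "  "),
               con)
  }
  invisible(path)
}

#' Write domain hits as an hmmscan-style tblout file
#' @param hits data frame with columns query_id, domain_accession, evalue,
#'   score.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeHmmscan <- function(hits, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#target name  accession  query name  accession  E-value  score  bias", con)
  for (i in seq_len(nrow(hits))) {
    writeLines(paste("domain", hits$domain_accession[i], hits$query_id[i],
                     "-", sprintf("%.15g", hits$evalue[i]), hits$score[i], 0.0,
                     sep = "  "), con)
  }
  invisible(path)
}
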