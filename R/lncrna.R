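#' @title De novo lncRNA identification pipeline
#' @description A chain of individually callable filters that strips a de
#'   novo transcriptome down to putative long non-coding RNAs: redundancy
#'   clustering, expression-level filtering, protein-homology binning,
#'   cross-accession consensus, purging of known structured RNA families,
#'   and an open-reading-frame coding flag.  Every stage records what it
#'   kept and removed, and why, so the run is fully auditable.
#' @name lncrna
NULL

#' Pipeline thresholds
#'
#' Defaults follow the operational definition of a lncRNA (>= 200 nt, no
#' protein-coding capacity) and the thresholds of the filtering chain:
#' clustering at 0.90 identity, expression at FPKM >= 1.50 (inclusive),
#' protein homology significant at E <= 1e-20, cross-accession consensus
#' requiring an alignment of at least 200 nt, structured-RNA purge at
#' Rfam E <= 0.01, and a coding flag at a longest open reading frame of
#' 100 codons.
#'
#' @param cluster_identity clustering identity fraction in (0.5, 1].
#' @param fpkm_min minimum expression level (inclusive).
#' @param protein_evalue_max E-value at or below which a protein hit
#'   marks a transcript as coding.
#' @param min_consensus_alignment minimum cross-accession alignment (nt).
#' @param min_lncrna_length minimum final transcript length (nt).
#' @param rfam_evalue_max covariance-model E-value at or below which a
#'   transcript is purged as a known structured RNA.
#' @param orf_min_codons longest-ORF length (codons, start codon included,
#'   stop excluded) at or above which a transcript is flagged as possibly
#'   coding.
#' @param consensus_query which accession supplies the queries of the
#'   cross-accession alignment table ("a" or "b").
#' @return a list of class \code{lncPipelineConfig}.
#' @export
lncPipelineConfig <- function(cluster_identity = 0.90, fpkm_min = 1.50,
                              protein_evalue_max = 1e-20,
                              min_consensus_alignment = 200L,
                              min_lncrna_length = 200L,
                              rfam_evalue_max = 0.01,
                              orf_min_codons = 100L,
                              consensus_query = c("a", "b")) {
  consensus_query <- match.arg(consensus_query)
  cfg <- list(cluster_identity = cluster_identity, fpkm_min = fpkm_min,
              protein_evalue_max = protein_evalue_max,
              min_consensus_alignment = min_consensus_alignment,
              min_lncrna_length = min_lncrna_length,
              rfam_evalue_max = rfam_evalue_max,
              orf_min_codons = orf_min_codons,
              consensus_query = consensus_query)
  nums <- unlist(cfg[setdiff(names(cfg), "consensus_query")])
  if (any(nums <= 0)) usageError("all pipeline thresholds must be positive")
  if (cluster_identity <= 0.5 || cluster_identity > 1) {
    usageError("cluster_identity must lie in (0.5, 1]")
  }
  structure(cfg, class = "lncPipelineConfig")
}

#' LncRNAResult: outcome of a lncRNA pipeline run
#'
#' @slot sequences \code{DNAStringSet} of the final lncRNA set.
#' @slot lncrna_ids ids of the final set (kept and not coding-flagged).
#' @slot flagged_ids ids flagged as possibly coding by the ORF heuristic
#'   (reported separately, never silently dropped).
#' @slot audit per-stage data frame (stage, accession, n_in, n_kept,
#'   n_removed) with n_in equal to the previous stage's n_kept.
#' @slot log per-transcript event table (id, stage, action, reason).
#' @export
setClass("LncRNAResult", representation(
  sequences = "DNAStringSet", lncrna_ids = "character",
  flagged_ids = "character", audit = "data.frame", log = "data.frame"))

setValidity("LncRNAResult", function(object) {
  if (!setequal(names(object@sequences), object@lncrna_ids)) {
    return("sequences and lncrna_ids disagree")
  }
  a <- object@audit
  if (nrow(a) && any(a$n_in != a$n_kept + a$n_removed)) {
    return("audit violates n_in = n_kept + n_removed")
  }
  if (length(intersect(object@lncrna_ids, object@flagged_ids))) {
    return("a transcript cannot be both final and flagged")
  }
  TRUE
})

setMethod("show", "LncRNAResult", function(object) {
  cat(sprintf("LncRNAResult: %d putative lncRNA(s), %d flagged possibly coding\n",
              length(object@lncrna_ids), length(object@flagged_ids)))
  print(object@audit)
})

#' @describeIn LncRNAResult ids of the final lncRNA set.
#' @param x a \code{LncRNAResult}.
#' @export
lncrnaIds <- function(x) x@lncrna_ids

#' @describeIn LncRNAResult ids flagged as possibly coding.
#' @export
flaggedIds <- function(x) x@flagged_ids

#' @describeIn LncRNAResult the per-stage audit table.
#' @export
auditTable <- function(x) x@audit

#' @describeIn LncRNAResult the per-transcript event log.
#' @export
pipelineLog <- function(x) x@log

#' @describeIn LncRNAResult sequences of the final lncRNA set.
#' @export
lncrnaSequences <- function(x) x@sequences

#' Greedy redundancy clustering of transcripts
#'
#' A CD-HIT-style stand-in used when no external .clstr file is
#' available: sequences are visited longest first (ties by id) and join
#' the first existing cluster whose representative they match at or above
#' the identity threshold, computed as exact matches in an ends-free
#' (overlap) pairwise alignment divided by the length of the shorter
#' sequence (the CD-HIT denominator convention; free end gaps mirror its
#' tolerance of terminal overhangs).  Otherwise they found a new cluster
#' and become its representative.  Exact parity with CD-HIT's
#' word-filtered heuristics is not attempted.
#'
#' @param transcripts a named \code{DNAStringSet}.
#' @param identity identity fraction in (0.5, 1].
#' @return data frame with columns cluster_id, member_id,
#'   is_representative (same shape as \code{\link{readClstr}}).
#' @export
clusterGreedy <- function(transcripts, identity = 0.90) {
  if (identity <= 0.5 || identity > 1) usageError("identity must lie in (0.5, 1]")
  n <- length(transcripts)
  if (n == 0L) {
    return(data.frame(cluster_id = integer(0), member_id = character(0),
                      is_representative = logical(0)))
  }
  ord <- order(-width(transcripts), names(transcripts), method = "radix")
  seqs <- transcripts[ord]
  mcols(seqs) <- NULL
  subMat <- nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                         baseOnly = FALSE)
  repIdx <- integer(0)            # indices (into seqs) of representatives
  assign <- integer(n)            # cluster id per sequence in visit order
  for (i in seq_len(n)) {
    placed <- FALSE
    if (length(repIdx)) {
      aln <- pairwiseAlignment(seqs[repIdx], seqs[[i]], type = "overlap",
                               substitutionMatrix = subMat,
                               gapOpening = 5, gapExtension = 2)
      shorter <- pmin(width(seqs)[repIdx], width(seqs)[i])
      idents <- nmatch(aln) / shorter
      hit <- which(idents >= identity)
      if (length(hit)) {
        assign[i] <- hit[1L]      # first (oldest) qualifying cluster
        placed <- TRUE
      }
    }
    if (!placed) {
      repIdx <- c(repIdx, i)
      assign[i] <- length(repIdx)
    }
  }
  data.frame(cluster_id = assign - 1L,
             member_id = names(seqs),
             is_representative = seq_len(n) %in% repIdx,
             stringsAsFactors = FALSE)[order(assign), , drop = FALSE]
}

#' Representative ids of a cluster table
#' @param clusters data frame from \code{\link{clusterGreedy}} or
#'   \code{\link{readClstr}}.
#' @return character vector of representative member ids.
#' @export
clusterRepresentatives <- function(clusters) {
  sort(clusters$member_id[clusters$is_representative])
}

keptRemoved <- function(ids, keep, reason) {
  ids <- as.character(ids)
  list(kept = sort(ids[keep]),
       removed = data.frame(id = sort(ids[!keep]),
                            reason = reason[!keep][order(ids[!keep])],
                            stringsAsFactors = FALSE))
}

#' Expression-level filter
#'
#' Keeps transcripts whose FPKM is at or above the threshold (the
#' boundary is inclusive).  A transcript with no expression record is
#' removed with reason \code{no_expression_record}.
#'
#' @param ids transcript ids entering the stage.
#' @param expression data frame from \code{\link{readExpression}}.
#' @param fpkm_min inclusive minimum FPKM.
#' @return list with \code{kept} (ids) and \code{removed} (id, reason).
#' @export
filterExpression <- function(ids, expression, fpkm_min = 1.50) {
  fpkm <- expression$fpkm[match(ids, expression$transcript_id)]
  keep <- !is.na(fpkm) & fpkm >= fpkm_min
  reason <- ifelse(is.na(fpkm), "no_expression_record",
                   sprintf("fpkm_%s_below_%s", format(fpkm), format(fpkm_min)))
  keptRemoved(ids, keep, reason)
}

organismCode <- function(subject_id) sub("^.*_", "", subject_id)

#' Bin transcripts by protein homology
#'
#' For each transcript the single best protein hit at or below the
#' E-value ceiling (ranked by bit score, E-value, percent identity,
#' subject id) decides its bin: plant or non-plant according to the
#' organism code of the subject (the token after the last underscore of
#' the subject id, Uniprot style).  Transcripts with no qualifying hit
#' fall into the no-hit bin — the only bin that continues down the
#' pipeline, both homology bins being treated as protein-coding
#' (or contaminant) and removed.
#'
#' @param ids transcript ids entering the stage.
#' @param protein_hits merged blastx/blastp alignment hits.
#' @param taxon_map named character vector mapping organism codes to
#'   \code{"plant"} or \code{"non_plant"}.
#' @param evalue_max qualifying-hit E-value ceiling.
#' @return list with character vectors \code{plant}, \code{non_plant},
#'   \code{no_hit} and a data frame \code{best_hits}.
#' @export
classifyCoding <- function(ids, protein_hits, taxon_map, evalue_max = 1e-20) {
  hits <- protein_hits[protein_hits$query_id %in% ids, , drop = FALSE]
  ranked <- rankHits(hits, evalue_max)
  best <- ranked[ranked$rank == 1L, , drop = FALSE]
  codes <- organismCode(best$subject_id)
  unknown <- setdiff(unique(codes), names(taxon_map))
  if (length(unknown)) {
    dataError(sprintf("organism code(s) missing from taxon map: %s",
                      paste(sort(unknown), collapse = ", ")))
  }
  bin <- unname(taxon_map[codes])
  bad <- setdiff(unique(bin), c("plant", "non_plant"))
  if (length(bad)) {
    dataError(sprintf("taxon map values must be plant/non_plant, got: %s",
                      paste(bad, collapse = ", ")))
  }
  list(plant = sort(best$query_id[bin == "plant"]),
       non_plant = sort(best$query_id[bin == "non_plant"]),
       no_hit = sort(setdiff(ids, best$query_id)),
       best_hits = best)
}

#' Cross-accession consensus
#'
#' Keeps transcripts observed in both accessions: per query the single
#' top hit is taken (same ranking as everywhere else), pairs aligned over
#' fewer than \code{min_alignment} nt are dropped, and for each surviving
#' pair the longer of the two transcripts is emitted (ties go to the
#' query side).  Emitted ids are de-duplicated.
#'
#' @param set_a query-side transcripts (\code{DNAStringSet}).
#' @param set_b subject-side transcripts.
#' @param a_vs_b_hits alignment hits with set_a queries and set_b
#'   subjects.
#' @param min_alignment minimum alignment length (nt, inclusive).
#' @return \code{DNAStringSet} of the emitted consensus transcripts,
#'   sorted by id.
#' @export
crossAccessionConsensus <- function(set_a, set_b, a_vs_b_hits,
                                    min_alignment = 200L) {
  hits <- a_vs_b_hits
  unknownQ <- setdiff(unique(hits$query_id), names(set_a))
  unknownS <- setdiff(unique(hits$subject_id), names(set_b))
  if (length(unknownQ) || length(unknownS)) {
    dataError(sprintf("alignment references unknown transcript id(s): %s",
                      paste(c(unknownQ, unknownS), collapse = ", ")))
  }
  ranked <- rankHits(hits, evalue_max = Inf)
  best <- ranked[ranked$rank == 1L & ranked$alignment_length >= min_alignment, ,
                 drop = FALSE]
  if (nrow(best) == 0L) {
    out <- DNAStringSet()
    mcols(out)$description <- character(0)
    return(out)
  }
  qLen <- width(set_a)[match(best$query_id, names(set_a))]
  sLen <- width(set_b)[match(best$subject_id, names(set_b))]
  fromA <- qLen >= sLen                    # tie goes to the query side
  pick <- ifelse(fromA, best$query_id, best$subject_id)
  keepIds <- sort(unique(pick))
  pool <- c(set_a, set_b[setdiff(names(set_b), names(set_a))])
  out <- pool[keepIds]
  mcols(out)$description <- rep("", length(out))
  out
}

#' Purge known structured RNA families
#'
#' Removes transcripts with at least one covariance-model hit at or below
#' the E-value ceiling; the removal reason records the best-scoring
#' family.
#'
#' @param ids transcript ids entering the stage.
#' @param cm_hits data frame from \code{\link{readCmscan}}.
#' @param evalue_max significance ceiling (inclusive).
#' @return list with \code{kept} and \code{removed} (id, reason).
#' @export
rfamFilter <- function(ids, cm_hits, evalue_max = 0.01) {
  sig <- cm_hits[cm_hits$evalue <= evalue_max & cm_hits$query_id %in% ids, ,
                 drop = FALSE]
  bestFamily <- vapply(split(sig, sig$query_id), function(h) {
    h <- h[order(h$evalue, -h$score, h$model_accession), , drop = FALSE]
    h$model_accession[1L]
  }, character(1))
  keep <- !(ids %in% names(bestFamily))
  reason <- ifelse(keep, "", paste0("rfam_", bestFamily[ids]))
  keptRemoved(ids, keep, reason)
}

revComp <- function(s) as.character(reverseComplement(DNAStringSet(s))[[1]])

# best ATG..stop run on one strand; codons counts the start codon but not
# the stop; start_nt is 1-based on the given strand's sequence
orfScanStrand <- function(s) {
  best <- list(codons = 0L, start_nt = NA_integer_)
  n <- nchar(s)
  for (frame in 0:2) {
    if (n - frame < 6L) next
    ncod <- (n - frame) %/% 3L
    codons <- substring(s, frame + 1L + 3L * (seq_len(ncod) - 1L),
                        frame + 3L * seq_len(ncod))
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    starts <- which(codons == "ATG")
    if (!length(stops) || !length(starts)) next
    prevStop <- 0L
    for (st in stops) {
      cand <- starts[starts > prevStop & starts < st]
      if (length(cand) && st - cand[1L] > best$codons) {
        best <- list(codons = st - cand[1L],
                     start_nt = frame + 1L + 3L * (cand[1L] - 1L))
      }
      prevStop <- st
    }
  }
  best
}

# longest ORF across all 6 frames, with strand and position
longestOrfInfo <- function(seq) {
  fwd <- orfScanStrand(seq)
  rev <- orfScanStrand(revComp(seq))
  if (rev$codons > fwd$codons) c(rev, strand = "-") else c(fwd, strand = "+")
}

# longest ORF (codons, ATG..stop, stop excluded) across all 6 frames
longestOrfCodons <- function(seq) longestOrfInfo(seq)$codons

#' Flag possibly coding transcripts by longest open reading frame
#'
#' A deliberately simple surrogate for a full coding-potential
#' classifier: the longest ATG-to-stop reading frame is computed over all
#' six frames and transcripts reaching \code{orf_min_codons} codons are
#' flagged \code{possibly_coding}.  Flagged transcripts are reported
#' separately, never silently dropped.
#'
#' @param transcripts a named \code{DNAStringSet}.
#' @param orf_min_codons flagging threshold (codons, start codon counted,
#'   stop codon not).
#' @return list with \code{kept} ids, \code{flagged} ids, and
#'   \code{orf_codons} (named integer vector).
#' @export
orfCodingFlag <- function(transcripts, orf_min_codons = 100L) {
  orf <- vapply(as.character(transcripts), longestOrfCodons, integer(1))
  names(orf) <- names(transcripts)
  flagged <- orf >= orf_min_codons
  list(kept = sort(names(transcripts)[!flagged]),
       flagged = sort(names(transcripts)[flagged]),
       orf_codons = orf)
}

auditRow <- function(stage, accession, n_in, n_kept) {
  data.frame(stage = stage, accession = accession, n_in = n_in,
             n_kept = n_kept, n_removed = n_in - n_kept,
             stringsAsFactors = FALSE)
}

logRows <- function(ids, stage, action, reason = "") {
  if (length(ids) == 0L) {
    return(data.frame(id = character(0), stage = character(0),
                      action = character(0), reason = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(id = ids, stage = stage, action = action,
             reason = if (length(reason) == 1L) rep(reason, length(ids)) else reason,
             stringsAsFactors = FALSE)
}

#' Run the full lncRNA identification pipeline
#'
#' Stages, in order: per-accession redundancy clustering (representatives
#' flow on), per-accession expression filter, per-accession protein
#' homology binning (only the no-hit bin continues), cross-accession
#' consensus, minimum-length check, structured-RNA (Rfam) purge, and the
#' ORF coding flag.  The audit table satisfies
#' \code{n_in = n_kept + n_removed} at every stage, with each stage's
#' \code{n_in} equal to the previous \code{n_kept} along its accession
#' chain (the consensus stage merges the two chains).
#'
#' @param raw_a,raw_b the two accessions' transcripts (named
#'   \code{DNAStringSet}).
#' @param evidence list of evidence tables: \code{expression_a},
#'   \code{expression_b}, \code{protein_hits_a}, \code{protein_hits_b},
#'   \code{taxon_map}, \code{ab_hits} (queries from the accession named
#'   by \code{config$consensus_query}), \code{cm_hits}, and optionally
#'   pre-computed \code{clusters_a} / \code{clusters_b} (external .clstr
#'   tables) in place of the built-in greedy clustering.
#' @param config a \code{\link{lncPipelineConfig}}.
#' @return a \code{\link{LncRNAResult}}.
#' @export
runLncPipeline <- function(raw_a, raw_b, evidence, config = lncPipelineConfig()) {
  fixNames <- function(x, label) {
    if (!is.null(names(x))) return(x)
    if (length(x) > 0L) {
      dataError(sprintf("transcripts_%s must carry transcript-id names", label))
    }
    names(x) <- character(0)
    x
  }
  raw_a <- fixNames(raw_a, "a")
  raw_b <- fixNames(raw_b, "b")
  audit <- list()
  log <- list()
  stageGuard <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(vinelncCondition(sprintf("[stage %s] %s", stage, conditionMessage(e)),
                            class(e)[1L]))
    })
  }

  perAccession <- function(label, raw, expression, protein_hits, taxon_map) {
    # clustering
    clusters <- stageGuard("cluster", {
      pre <- evidence[[paste0("clusters_", label)]]
      if (is.null(pre)) clusterGreedy(raw, config$cluster_identity) else pre
    })
    reps <- intersect(clusterRepresentatives(clusters), names(raw))
    collapsed <- setdiff(names(raw), reps)
    audit[[length(audit) + 1L]] <<- auditRow("cluster", label, length(raw),
                                             length(reps))
    log[[length(log) + 1L]] <<- logRows(collapsed, "cluster", "removed",
                                        "redundant_in_cluster")
    # expression
    expr <- stageGuard("expression",
                       filterExpression(reps, expression, config$fpkm_min))
    audit[[length(audit) + 1L]] <<- auditRow("expression", label, length(reps),
                                             length(expr$kept))
    log[[length(log) + 1L]] <<- logRows(expr$removed$id, "expression",
                                        "removed", expr$removed$reason)
    # coding classification
    bins <- stageGuard("coding_classification",
                       classifyCoding(expr$kept, protein_hits, taxon_map,
                                      config$protein_evalue_max))
    audit[[length(audit) + 1L]] <<- auditRow("coding_classification", label,
                                             length(expr$kept),
                                             length(bins$no_hit))
    log[[length(log) + 1L]] <<- logRows(bins$plant, "coding_classification",
                                        "removed", "plant_protein_hit")
    log[[length(log) + 1L]] <<- logRows(bins$non_plant, "coding_classification",
                                        "removed", "non_plant_protein_hit")
    bins$no_hit
  }

  survA <- perAccession("a", raw_a, evidence$expression_a,
                        evidence$protein_hits_a, evidence$taxon_map)
  survB <- perAccession("b", raw_b, evidence$expression_b,
                        evidence$protein_hits_b, evidence$taxon_map)

  # cross-accession consensus over the two accessions' survivors
  qSide <- if (config$consensus_query == "a") survA else survB
  sSide <- if (config$consensus_query == "a") survB else survA
  qSeqs <- raw_a; sSeqs <- raw_b
  if (config$consensus_query == "b") { qSeqs <- raw_b; sSeqs <- raw_a }
  abHits <- evidence$ab_hits
  abHits <- abHits[abHits$query_id %in% qSide & abHits$subject_id %in% sSide, ,
                   drop = FALSE]
  consensus <- stageGuard("consensus",
                          crossAccessionConsensus(qSeqs[intersect(names(qSeqs), qSide)],
                                                  sSeqs[intersect(names(sSeqs), sSide)],
                                                  abHits,
                                                  config$min_consensus_alignment))
  if (is.null(names(consensus)) && length(consensus) == 0L) {
    names(consensus) <- character(0)
  }
  nIn <- length(survA) + length(survB)
  audit[[length(audit) + 1L]] <- auditRow("consensus", "both", nIn,
                                          length(consensus))
  log[[length(log) + 1L]] <- logRows(setdiff(c(survA, survB), names(consensus)),
                                     "consensus", "removed",
                                     "no_cross_accession_support")

  # operational length floor for a lncRNA
  longEnough <- width(consensus) >= config$min_lncrna_length
  log[[length(log) + 1L]] <- logRows(names(consensus)[!longEnough], "length",
                                     "removed", "below_min_lncrna_length")
  audit[[length(audit) + 1L]] <- auditRow("length", "both", length(consensus),
                                          sum(longEnough))
  consensus <- consensus[longEnough]

  # purge known structured RNAs
  rf <- stageGuard("rfam", rfamFilter(names(consensus), evidence$cm_hits,
                                      config$rfam_evalue_max))
  audit[[length(audit) + 1L]] <- auditRow("rfam", "both", length(consensus),
                                          length(rf$kept))
  log[[length(log) + 1L]] <- logRows(rf$removed$id, "rfam", "removed",
                                     rf$removed$reason)
  kept <- consensus[rf$kept]

  # coding-potential surrogate: flag, do not drop
  orf <- stageGuard("orf_flag", orfCodingFlag(kept, config$orf_min_codons))
  audit[[length(audit) + 1L]] <- auditRow("orf_flag", "both", length(kept),
                                          length(orf$kept))
  log[[length(log) + 1L]] <- logRows(orf$flagged, "orf_flag", "flagged",
                                     "possibly_coding")

  final <- kept[orf$kept]
  log[[length(log) + 1L]] <- logRows(names(final), "final", "kept", "lncRNA")
  new("LncRNAResult", sequences = final, lncrna_ids = sort(names(final)),
      flagged_ids = orf$flagged, audit = do.call(rbind, audit),
      log = do.call(rbind, log))
}
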