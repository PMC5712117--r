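#' @title Iterative reciprocal-best-hit anchoring
#' @description Anchors gene models of one annotation to those of another
#'   through an iterative reciprocal-best-hit (iRBH) scheme: classical
#'   reciprocal best hits are fixed, the anchored ids are removed from
#'   every remaining alignment row (as query or subject), and the search
#'   repeats.  Pairs masked by a stronger paralog in round one can then
#'   surface in later rounds.  One-to-one copy number between the two
#'   annotations is the working assumption.
#' @name irbh
NULL

CONCORDANCE_LEVELS <- c("same_chromosome", "different_chromosome",
                        "involves_chrUkn")
CHR_UNKNOWN <- "chrUkn"

#' AnchorSet: reciprocal-best-hit anchors between two annotations
#'
#' Holds one row per anchored pair: the two gene ids, the iteration at
#' which the pair was fixed, the worse (larger) of the two directional
#' E-values, the worse (smaller) of the two directional bit scores, and
#' (after \code{\link{classifyConcordance}}) the chromosome-concordance
#' class.  Each gene id appears in at most one anchor.
#'
#' @slot pairs data frame with columns a_id, b_id, iteration, evalue,
#'   bit_score, concordance.
#' @export
setClass("AnchorSet", representation(pairs = "data.frame"))

setValidity("AnchorSet", function(object) {
  p <- object@pairs
  need <- c("a_id", "b_id", "iteration", "evalue", "bit_score", "concordance")
  if (!all(need %in% names(p))) {
    return(sprintf("pairs must have columns %s", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(p$a_id)) return("duplicated a_id in anchors")
  if (anyDuplicated(p$b_id)) return("duplicated b_id in anchors")
  if (nrow(p) && any(p$iteration < 1L)) return("iteration must be >= 1")
  known <- is.na(p$concordance) | p$concordance %in% CONCORDANCE_LEVELS
  if (!all(known)) return("unknown concordance class")
  TRUE
})

newAnchorSet <- function(pairs) {
  if (!"concordance" %in% names(pairs)) pairs$concordance <- NA_character_
  rownames(pairs) <- NULL
  new("AnchorSet", pairs = pairs)
}

emptyAnchorPairs <- function() {
  data.frame(a_id = character(0), b_id = character(0), iteration = integer(0),
             evalue = numeric(0), bit_score = numeric(0),
             concordance = character(0), stringsAsFactors = FALSE)
}

#' @describeIn AnchorSet the anchor table as a data frame.
#' @param x an \code{AnchorSet}.
#' @export
anchorPairs <- function(x) {
  stopifnot(is(x, "AnchorSet"))
  x@pairs
}

setMethod("show", "AnchorSet", function(object) {
  p <- object@pairs
  cat(sprintf("AnchorSet with %d anchored pair(s)\n", nrow(p)))
  if (nrow(p)) {
    cat(sprintf("  iterations used: %s\n",
                paste(sort(unique(p$iteration)), collapse = ", ")))
    if (!all(is.na(p$concordance))) {
      tab <- table(factor(p$concordance, levels = CONCORDANCE_LEVELS))
      cat(sprintf("  concordance: %s\n",
                  paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
    }
    print(head(p, 5L))
    if (nrow(p) > 5L) cat(sprintf("  ... and %d more\n", nrow(p) - 5L))
  }
})

#' @describeIn AnchorSet number of anchored pairs.
#' @export
setMethod("length", "AnchorSet", function(x) nrow(x@pairs))

hitOrder <- function(hits) {
  order(-hits$bit_score, hits$evalue, -hits$percent_identity,
        hits$subject_id, method = "radix")
}

#' Rank alignment hits per query
#'
#' Drops hits above the E-value ceiling, keeps at most one hit per
#' (query, subject) pair, and orders the survivors of each query by bit
#' score (descending), then E-value (ascending), then percent identity
#' (descending), then subject id (ascending) — a fully deterministic
#' chain, so results never depend on input row order.
#'
#' @param hits alignment hit data frame (see \code{\link{readBlastTab}}).
#' @param evalue_max keep hits with evalue <= this ceiling.
#' @return the retained hits, ordered by query id then rank, with an
#'   integer \code{rank} column (1 = best hit of its query).
#' @export
rankHits <- function(hits, evalue_max = 1e-5) {
  hits <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) {
    out <- emptyHits()
    out$rank <- integer(0)
    return(out)
  }
  hits <- hits[hitOrder(hits), , drop = FALSE]
  # best row per (query, subject) is now first; drop the rest
  key <- paste(hits$query_id, hits$subject_id, sep = "\r")
  hits <- hits[!duplicated(key), , drop = FALSE]
  # radix sort is stable, so within a query the quality order is preserved
  hits <- hits[order(hits$query_id, method = "radix"), , drop = FALSE]
  hits$rank <- as.integer(stats::ave(seq_len(nrow(hits)), hits$query_id,
                                     FUN = seq_along))
  rownames(hits) <- NULL
  hits
}

# top-ranked subject per query as a named character vector
topHitMap <- function(ranked) {
  top <- ranked[ranked$rank == 1L, , drop = FALSE]
  setNames(top$subject_id, top$query_id)
}

topHitRows <- function(ranked) {
  ranked[ranked$rank == 1L, , drop = FALSE]
}

#' Classical reciprocal best hits from two ranked tables
#'
#' A pair (a, b) is returned iff b is a's top-ranked hit and a is b's
#' top-ranked hit.  The pair records the worse of the two directional
#' E-values and the worse of the two directional bit scores.
#'
#' @param fwd ranked hits with annotation-A queries (from
#'   \code{\link{rankHits}}).
#' @param rev ranked hits with annotation-B queries.
#' @return data frame with columns a_id, b_id, evalue, bit_score, sorted
#'   by a_id.
#' @export
findRBH <- function(fwd, rev) {
  ftop <- topHitRows(fwd)
  rtop <- topHitRows(rev)
  rmap <- setNames(rtop$subject_id, rtop$query_id)
  mutual <- !is.na(rmap[ftop$subject_id]) & rmap[ftop$subject_id] == ftop$query_id
  mutual[is.na(mutual)] <- FALSE
  ftop <- ftop[mutual, , drop = FALSE]
  if (nrow(ftop) == 0L) {
    return(data.frame(a_id = character(0), b_id = character(0),
                      evalue = numeric(0), bit_score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ridx <- match(ftop$subject_id, rtop$query_id)
  out <- data.frame(
    a_id = ftop$query_id,
    b_id = ftop$subject_id,
    evalue = pmax(ftop$evalue, rtop$evalue[ridx]),
    bit_score = pmin(ftop$bit_score, rtop$bit_score[ridx]),
    stringsAsFactors = FALSE
  )
  out[order(out$a_id, method = "radix"), , drop = FALSE]
}

#' Iterative reciprocal-best-hit anchoring
#'
#' Repeats \{rank hits, fix reciprocal best hits, remove the anchored ids
#' from every remaining row of both tables (whether query or subject)\}
#' until no new pair is found or \code{max_iterations} rounds have run.
#' Removal happens between rounds, after all of a round's pairs are
#' fixed.  The result is deterministic and independent of input row
#' order.
#'
#' @param fwd_hits alignment hits with annotation-A queries and
#'   annotation-B subjects.
#' @param rev_hits alignment hits with annotation-B queries and
#'   annotation-A subjects.
#' @param evalue_max E-value ceiling applied to both tables.
#' @param max_iterations maximum number of rounds (>= 1).
#' @return an \code{\link{AnchorSet}}; each pair's \code{iteration}
#'   records the round at which it was fixed.
#' @export
irbhAnchor <- function(fwd_hits, rev_hits, evalue_max = 1e-5,
                       max_iterations = 25L) {
  if (max_iterations < 1L) usageError("max_iterations must be >= 1")
  fwd <- rankHits(fwd_hits, evalue_max)
  rev <- rankHits(rev_hits, evalue_max)
  pairs <- emptyAnchorPairs()
  for (iter in seq_len(max_iterations)) {
    found <- findRBH(fwd, rev)
    if (nrow(found) == 0L) break
    found$iteration <- iter
    pairs <- rbind(pairs,
                   found[, c("a_id", "b_id", "iteration", "evalue", "bit_score")])
    aGone <- found$a_id
    bGone <- found$b_id
    fwd <- fwd[!(fwd$query_id %in% aGone) & !(fwd$subject_id %in% bGone), ,
               drop = FALSE]
    rev <- rev[!(rev$query_id %in% bGone) & !(rev$subject_id %in% aGone), ,
               drop = FALSE]
    if (nrow(fwd)) fwd <- rerank(fwd)
    if (nrow(rev)) rev <- rerank(rev)
    if (nrow(fwd) == 0L || nrow(rev) == 0L) break
  }
  newAnchorSet(pairs)
}

# recompute per-query rank after row removal (row order is already correct)
rerank <- function(ranked) {
  ranked$rank <- as.integer(stats::ave(seq_len(nrow(ranked)), ranked$query_id,
                                       FUN = seq_along))
  ranked
}

lookupGenes <- function(ids, genes, side) {
  tab <- geneTable(genes)
  idx <- match(ids, tab$gene_id)
  if (anyNA(idx)) {
    missing <- unique(ids[is.na(idx)])
    dataError(sprintf("anchored %s id(s) missing from gene models: %s",
                      side, paste(missing, collapse = ", ")))
  }
  tab[idx, , drop = FALSE]
}

concordanceClass <- function(chromA, chromB) {
  ifelse(chromA == CHR_UNKNOWN | chromB == CHR_UNKNOWN, "involves_chrUkn",
         ifelse(chromA == chromB, "same_chromosome", "different_chromosome"))
}

#' Classify anchors by chromosome concordance
#'
#' An anchor involving the unplaced-scaffold sentinel \code{chrUkn} on
#' either side is classed \code{involves_chrUkn}; otherwise
#' \code{same_chromosome} iff the chromosome names agree.
#'
#' @param anchors an \code{\link{AnchorSet}}.
#' @param genes_a,genes_b gene models (\code{GRanges} from
#'   \code{\link{readGff3Genes}}) for the two annotations.
#' @return the \code{AnchorSet} with the concordance column filled; the
#'   three class counts are stored in \code{metadata}-style attribute
#'   \code{concordance_summary} retrievable via
#'   \code{\link{concordanceSummary}}.
#' @export
classifyConcordance <- function(anchors, genes_a, genes_b) {
  p <- anchorPairs(anchors)
  if (nrow(p) == 0L) return(anchors)
  ga <- lookupGenes(p$a_id, genes_a, "A")
  gb <- lookupGenes(p$b_id, genes_b, "B")
  p$concordance <- concordanceClass(ga$chromosome, gb$chromosome)
  newAnchorSet(p)
}

#' Concordance class counts of an anchor set
#' @param anchors a classified \code{\link{AnchorSet}}.
#' @return named integer vector over the three concordance classes.
#' @export
concordanceSummary <- function(anchors) {
  p <- anchorPairs(anchors)
  counts <- table(factor(p$concordance, levels = CONCORDANCE_LEVELS))
  setNames(as.integer(counts), CONCORDANCE_LEVELS)
}

#' Anchor quality: bit-score to model-length ratios
#'
#' For each anchor, the ratio of the pair's bit score to the length (nt)
#' of the annotation-B model, a coarse per-base alignment quality.  Class
#' means of the ratio and of the E-value are reported for the two
#' placed-chromosome concordance classes; anchors involving
#' \code{chrUkn}, and empty classes, are reported as absent (\code{NA}).
#'
#' @param anchors a classified \code{\link{AnchorSet}}.
#' @param genes_b annotation-B gene models.
#' @return list with \code{quality} (per-anchor data frame with b_length
#'   and ratio) and \code{class_means} (data frame with concordance,
#'   n, mean_ratio, mean_evalue).
#' @export
anchorQuality <- function(anchors, genes_b) {
  p <- anchorPairs(anchors)
  gb <- lookupGenes(p$b_id, genes_b, "B")
  bLength <- gb$end - gb$start + 1L
  if (any(bLength <= 0L)) dataError("zero-length annotation-B gene model")
  quality <- cbind(p, b_length = bLength, ratio = p$bit_score / bLength)
  classes <- c("same_chromosome", "different_chromosome")
  classMeans <- do.call(rbind, lapply(classes, function(cl) {
    rows <- quality[!is.na(quality$concordance) & quality$concordance == cl, ,
                    drop = FALSE]
    data.frame(concordance = cl, n = nrow(rows),
               mean_ratio = if (nrow(rows)) mean(rows$ratio) else NA_real_,
               mean_evalue = if (nrow(rows)) mean(rows$evalue) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(quality = quality, class_means = classMeans)
}

#' Rescue pass for unsupported legacy gene models
#'
#' Legacy (annotation-B) models that found no iterative anchor are given
#' one non-iterative reciprocal-best-hit pass, restricted to the supplied
#' B ids, and each rescue is labelled with its chromosome concordance.
#'
#' @param unanchored_b_ids annotation-B gene ids left unanchored by
#'   \code{\link{irbhAnchor}}.
#' @param fwd_hits,rev_hits the directional hit tables (A queries / B
#'   queries); callers wanting the pass restricted to a particular
#'   annotation-A model set pre-filter the tables.
#' @param evalue_max E-value ceiling (the anchoring default applies).
#' @param genes_a,genes_b gene models for concordance labelling.
#' @return data frame with columns b_id, a_id, concordance,
#'   same_chromosome (logical).
#' @export
rescueUnsupported <- function(unanchored_b_ids, fwd_hits, rev_hits,
                              evalue_max = 1e-5, genes_a, genes_b) {
  fwd <- fwd_hits[fwd_hits$subject_id %in% unanchored_b_ids, , drop = FALSE]
  rev <- rev_hits[rev_hits$query_id %in% unanchored_b_ids, , drop = FALSE]
  found <- findRBH(rankHits(fwd, evalue_max), rankHits(rev, evalue_max))
  if (nrow(found) == 0L) {
    return(data.frame(b_id = character(0), a_id = character(0),
                      concordance = character(0), same_chromosome = logical(0),
                      stringsAsFactors = FALSE))
  }
  ga <- lookupGenes(found$a_id, genes_a, "A")
  gb <- lookupGenes(found$b_id, genes_b, "B")
  conc <- concordanceClass(ga$chromosome, gb$chromosome)
  out <- data.frame(b_id = found$b_id, a_id = found$a_id, concordance = conc,
                    same_chromosome = conc == "same_chromosome",
                    stringsAsFactors = FALSE)
  out[order(out$b_id, method = "radix"), , drop = FALSE]
}

#' Write an anchor set as TSV
#' @param anchors an \code{\link{AnchorSet}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeAnchors <- function(anchors, path) {
  write.table(anchorPairs(anchors), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
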