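#' @title Gene duplication: tandem pairs and tandemly arrayed genes
#' @description Detects duplicate gene pairs from an all-by-all
#'   self-alignment table, classifies them by gene-order distance
#'   (tandem / proximal / dispersed — a simplified scheme without a
#'   collinearity stage, so no whole-genome-duplication class), and
#'   chains tandem pairs into tandemly arrayed gene (TAG) arrays as
#'   connected components of the tandem-pair graph.
#' @name duplication
NULL

#' Duplicate gene pairs from a self-alignment table
#'
#' Self matches are dropped, directional duplicates (g1->g2 and g2->g1)
#' are merged keeping the better E-value (tie: better bit score), and the
#' E-value ceiling is enforced.  Pairs are stored once with
#' \code{gene_1 < gene_2} lexicographically.
#'
#' @param self_hits alignment hits whose queries and subjects come from
#'   one annotation.
#' @param evalue_max keep pairs with evalue <= this ceiling.
#' @return data frame with columns gene_1, gene_2, evalue, bit_score.
#' @export
findDuplicatePairs <- function(self_hits, evalue_max = 1e-20) {
  hits <- self_hits[self_hits$query_id != self_hits$subject_id &
                      self_hits$evalue <= evalue_max, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(data.frame(gene_1 = character(0), gene_2 = character(0),
                      evalue = numeric(0), bit_score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  g1 <- pmin(hits$query_id, hits$subject_id)
  g2 <- pmax(hits$query_id, hits$subject_id)
  df <- data.frame(gene_1 = g1, gene_2 = g2, evalue = hits$evalue,
                   bit_score = hits$bit_score, stringsAsFactors = FALSE)
  df <- df[order(df$gene_1, df$gene_2, df$evalue, -df$bit_score,
                 method = "radix"), , drop = FALSE]
  df <- df[!duplicated(paste(df$gene_1, df$gene_2, sep = "\r")), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Classify duplicate pairs by gene-order distance
#'
#' A pair is tandem iff both genes sit on the same chromosome at adjacent
#' ranks (|rank difference| = 1); proximal iff on the same chromosome
#' within \code{proximal_window} ranks; otherwise dispersed.  Each gene's
#' class is the highest-precedence kind among its pairs
#' (tandem > proximal > dispersed); genes of the annotation with no pair
#' at all are singletons.  No collinearity stage is run, so the
#' whole-genome/segmental duplication class of full classifiers is out of
#' scope here.
#'
#' @param pairs data frame from \code{\link{findDuplicatePairs}}.
#' @param genes gene models (\code{GRanges} from
#'   \code{\link{readGff3Genes}}).
#' @param proximal_window maximum rank separation still called proximal.
#' @return list with \code{pairs} (kind column added),
#'   \code{gene_classes} (gene_id, class) and \code{singletons}.
#' @export
classifyPairs <- function(pairs, genes, proximal_window = 10L) {
  tab <- geneTable(genes)
  idx1 <- match(pairs$gene_1, tab$gene_id)
  idx2 <- match(pairs$gene_2, tab$gene_id)
  if (anyNA(idx1) || anyNA(idx2)) {
    missing <- unique(c(pairs$gene_1[is.na(idx1)], pairs$gene_2[is.na(idx2)]))
    dataError(sprintf("pair member(s) absent from gene models: %s",
                      paste(missing, collapse = ", ")))
  }
  sameChrom <- tab$chromosome[idx1] == tab$chromosome[idx2]
  dRank <- abs(tab$rank[idx1] - tab$rank[idx2])
  kind <- ifelse(sameChrom & dRank == 1L, "tandem",
                 ifelse(sameChrom & dRank <= proximal_window, "proximal",
                        "dispersed"))
  pairs$kind <- kind
  precedence <- c(tandem = 1L, proximal = 2L, dispersed = 3L)
  dupGenes <- unique(c(pairs$gene_1, pairs$gene_2))
  geneClass <- vapply(dupGenes, function(g) {
    kinds <- pairs$kind[pairs$gene_1 == g | pairs$gene_2 == g]
    names(precedence)[min(precedence[kinds])]
  }, character(1))
  geneClasses <- data.frame(gene_id = dupGenes, class = unname(geneClass),
                            stringsAsFactors = FALSE)
  geneClasses <- geneClasses[order(geneClasses$gene_id), , drop = FALSE]
  rownames(geneClasses) <- NULL
  list(pairs = pairs, gene_classes = geneClasses,
       singletons = sort(setdiff(tab$gene_id, dupGenes)))
}

#' Build tandemly arrayed gene (TAG) arrays
#'
#' Arrays are the connected components of the tandem-pair graph; each
#' pair already links two rank-adjacent genes of one chromosome, so a
#' chain (g1,g2), (g2,g3) yields one 3-gene array — the second gene of a
#' pair acting as the anchor that extends the array.  Members are
#' reported in rank order.
#'
#' @param tandem_pairs pairs of kind tandem (from
#'   \code{\link{classifyPairs}}).
#' @param genes gene models (\code{GRanges}).
#' @return list with \code{arrays} (data frame array_id, chromosome,
#'   gene_id, rank, size) and \code{summary} (n_arrays, n_genes,
#'   n_in_3plus, n_in_2).
#' @export
buildTandemArrays <- function(tandem_pairs, genes) {
  emptySummary <- c(n_arrays = 0L, n_genes = 0L, n_in_3plus = 0L, n_in_2 = 0L)
  emptyArrays <- data.frame(array_id = integer(0), chromosome = character(0),
                            gene_id = character(0), rank = integer(0),
                            size = integer(0), stringsAsFactors = FALSE)
  if (nrow(tandem_pairs) == 0L) {
    return(list(arrays = emptyArrays, summary = emptySummary))
  }
  if ("kind" %in% names(tandem_pairs) && any(tandem_pairs$kind != "tandem")) {
    usageError("buildTandemArrays expects tandem pairs only")
  }
  tab <- geneTable(genes)
  g <- igraph::graph_from_data_frame(tandem_pairs[, c("gene_1", "gene_2")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  membership <- comp$membership
  members <- names(membership)
  idx <- match(members, tab$gene_id)
  if (anyNA(idx)) {
    dataError(sprintf("tandem pair member(s) absent from gene models: %s",
                      paste(members[is.na(idx)], collapse = ", ")))
  }
  arrays <- data.frame(component = unname(membership),
                       chromosome = tab$chromosome[idx],
                       gene_id = members, rank = tab$rank[idx],
                       stringsAsFactors = FALSE)
  arrays <- arrays[order(arrays$chromosome,
                         vapply(split(arrays$rank, arrays$component)[
                           as.character(arrays$component)], min, numeric(1)),
                         arrays$rank), , drop = FALSE]
  arrays$array_id <- match(arrays$component, unique(arrays$component))
  sizes <- table(arrays$array_id)
  arrays$size <- as.integer(sizes[as.character(arrays$array_id)])
  arrays <- arrays[, c("array_id", "chromosome", "gene_id", "rank", "size")]
  rownames(arrays) <- NULL
  sizesPerArray <- as.integer(sizes)
  summary <- c(n_arrays = length(sizesPerArray),
               n_genes = sum(sizesPerArray),
               n_in_3plus = sum(sizesPerArray[sizesPerArray >= 3L]),
               n_in_2 = sum(sizesPerArray[sizesPerArray == 2L]))
  list(arrays = arrays, summary = summary)
}
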