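# Shared fixtures and independent oracle implementations used across the
# test files.  The oracles deliberately avoid the package's own code paths
# so agreement is evidence, not tautology.

suppressPackageStartupMessages({
  library(Biostrings)
  library(GenomicRanges)
})

# ---- fixture cache: the default synthetic bundle is built once ----------

.fixtureCache <- new.env(parent = emptyenv())

defaultBundle <- function() {
  if (is.null(.fixtureCache$bundle)) {
    .fixtureCache$bundle <- simBundle(simConfig())
  }
  .fixtureCache$bundle
}

defaultPipelineResult <- function() {
  if (is.null(.fixtureCache$result)) {
    b <- defaultBundle()
    .fixtureCache$result <- runLncPipeline(
      b$transcripts_a, b$transcripts_b,
      evidence = b[c("expression_a", "expression_b", "protein_hits_a",
                     "protein_hits_b", "taxon_map", "ab_hits", "cm_hits")],
      config = lncPipelineConfig())
  }
  .fixtureCache$result
}

# ---- small constructors --------------------------------------------------

makeHits <- function(query, subject, pid = 90, aln = 300, evalue = 1e-40,
                     bits = 200) {
  n <- length(query)
  data.frame(query_id = query, subject_id = subject,
             percent_identity = rep_len(pid, n),
             alignment_length = rep_len(aln, n),
             evalue = rep_len(evalue, n), bit_score = rep_len(bits, n),
             stringsAsFactors = FALSE)
}

# gene models as GRanges with the package's rank convention (0-based order
# by start within chromosome, ties by gene_id), built independently
makeGenes <- function(gene_id, chromosome, start, width = 1000L) {
  width <- rep_len(width, length(gene_id))
  chromosome <- rep_len(chromosome, length(gene_id))
  ord <- order(chromosome, start, gene_id)
  gr <- GRanges(chromosome[ord], IRanges(start[ord], width = width[ord]),
                strand = "+", gene_id = gene_id[ord])
  chrom <- as.character(seqnames(gr))
  mcols(gr)$rank <- unlist(lapply(split(seq_along(gr), chrom)[unique(chrom)],
                                  function(i) seq_along(i) - 1L),
                           use.names = FALSE)
  gr
}

namedDna <- function(seqs) {
  out <- DNAStringSet(unlist(seqs))
  mcols(out)$description <- rep("", length(out))
  out
}

# ---- independent RBH / iRBH oracle --------------------------------------

# best subject per query under the documented ordering chain, via base R
oracleTopMap <- function(hits) {
  if (nrow(hits) == 0L) return(character(0))
  spl <- split(hits, hits$query_id)
  vapply(spl, function(h) {
    h <- h[order(-h$bit_score, h$evalue, -h$percent_identity, h$subject_id), ,
           drop = FALSE]
    h$subject_id[1L]
  }, character(1))
}

oracleRBH <- function(fwd, rev) {
  ftop <- oracleTopMap(fwd)
  rtop <- oracleTopMap(rev)
  a <- names(ftop)
  keep <- !is.na(rtop[ftop]) & rtop[ftop] == a
  keep[is.na(keep)] <- FALSE
  data.frame(a_id = sort(a[keep]),
             b_id = unname(ftop[sort(a[keep])]),
             stringsAsFactors = FALSE)
}

oracleIrbh <- function(fwd, rev, evalue_max = 1e-5, max_iterations = 25L) {
  fwd <- fwd[fwd$evalue <= evalue_max, , drop = FALSE]
  rev <- rev[rev$evalue <= evalue_max, , drop = FALSE]
  out <- list()
  for (iter in seq_len(max_iterations)) {
    found <- oracleRBH(fwd, rev)
    if (nrow(found) == 0L) break
    found$iteration <- iter
    out[[iter]] <- found
    fwd <- fwd[!(fwd$query_id %in% found$a_id) &
                 !(fwd$subject_id %in% found$b_id), , drop = FALSE]
    rev <- rev[!(rev$query_id %in% found$b_id) &
                 !(rev$subject_id %in% found$a_id), , drop = FALSE]
  }
  if (length(out) == 0L) {
    return(data.frame(a_id = character(0), b_id = character(0),
                      iteration = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# random bipartite hit tables, <= 30 genes per side, distinct bit scores
randomBipartite <- function(seed) {
  set.seed(seed)
  na <- sample(2:30, 1L)
  nb <- sample(2:30, 1L)
  aIds <- sprintf("a%02d", seq_len(na))
  bIds <- sprintf("b%02d", seq_len(nb))
  nEdge <- sample(seq_len(na * nb), 1L)
  edges <- sample(na * nb, nEdge)
  mkTable <- function(q, s) {
    bits <- sample(seq(50, 50 + 4 * length(q) - 1, by = 4))
    makeHits(q, s, pid = round(runif(length(q), 40, 99), 1),
             aln = sample(100:900, length(q), replace = TRUE),
             evalue = 10^-(bits / 3), bits = bits)
  }
  qa <- aIds[((edges - 1L) %% na) + 1L]
  sb <- bIds[((edges - 1L) %/% na) + 1L]
  # the reverse table covers the same edges with independent scores
  list(fwd = mkTable(qa, sb), rev = mkTable(sb, qa))
}

# ---- exhaustive structure enumeration (Nussinov oracle) ------------------

ORACLE_RNA_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

# maximum number of compatible (disjoint, non-crossing) base pairs found by
# backtracking over all candidate pairs -- enumeration, not the DP recursion
enumMaxPairs <- function(sequence, min_loop = 3L) {
  b <- strsplit(chartr("Tt", "Uu", toupper(sequence)), "")[[1]]
  n <- length(b)
  cand <- list()
  for (i in seq_len(n)) {
    j <- i + min_loop + 1L
    while (j <= n) {
      if (paste0(b[i], b[j]) %in% ORACLE_RNA_PAIRS) {
        cand[[length(cand) + 1L]] <- c(i, j)
      }
      j <- j + 1L
    }
  }
  m <- length(cand)
  if (m == 0L) return(0L)
  compat <- function(p, q) {
    if (any(p %in% q)) return(FALSE)
    crossing <- (p[1] < q[1] && q[1] < p[2] && p[2] < q[2]) ||
      (q[1] < p[1] && p[1] < q[2] && q[2] < p[2])
    !crossing
  }
  best <- 0L
  rec <- function(idx, chosen) {
    if (length(chosen) + (m - idx + 1L) <= best) return(invisible(NULL))
    if (idx > m) {
      best <<- max(best, length(chosen))
      return(invisible(NULL))
    }
    ok <- all(vapply(chosen, compat, logical(1), q = cand[[idx]]))
    if (ok) rec(idx + 1L, c(chosen, cand[idx]))
    rec(idx + 1L, chosen)
  }
  rec(1L, list())
  best
}

# parse a dot-bracket string into a list of (i, j) pairs
dotBracketPairs <- function(db) {
  chars <- strsplit(db, "")[[1]]
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    if (chars[i] == ")") {
      pairs[[length(pairs) + 1L]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  pairs
}

# ---- statistics oracles --------------------------------------------------

# brute-force two-sample KS sup-distance over the pooled value set
bruteKsD <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(vapply(grid, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# independent Kolmogorov survival function: both series representations
# are exact for all x > 0, so the reference deliberately uses the OPPOSITE
# branch from the package (which takes theta form below 1, alternating
# form above), making every evaluation a cross-representation check
refKolmogorovSF <- function(x) {
  if (x <= 0) return(1)
  if (x >= 1) {
    k <- 1:50
    cdf <- sqrt(2 * pi) / x * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * x^2)))
    return(min(max(1 - cdf, 0), 1))
  }
  k <- 1:1000
  min(max(2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2)), 0), 1)
}

# ---- connected-components oracle for tandem arrays -----------------------

bruteComponents <- function(pairs) {
  ids <- unique(c(pairs$gene_1, pairs$gene_2))
  comp <- setNames(seq_along(ids), ids)
  repeat {
    changed <- FALSE
    for (r in seq_len(nrow(pairs))) {
      a <- comp[[pairs$gene_1[r]]]
      b <- comp[[pairs$gene_2[r]]]
      if (a != b) {
        comp[comp == max(a, b)] <- min(a, b)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  unname(lapply(split(names(comp), comp), sort))
}

# canonical set-of-sets representation for comparing array memberships
asSetOfSets <- function(lst) {
  sorted <- unname(lapply(lst, sort))
  sorted[order(vapply(sorted, paste, character(1), collapse = "\r"))]
}
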