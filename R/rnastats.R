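#' @title Coding-versus-noncoding comparison statistics
#' @description Metrics and two-sample statistics used to contrast long
#'   non-coding RNAs with protein-coding transcripts: transcript length,
#'   GC content, minimum free energy (MFE) and length-corrected MFE
#'   (kcal/mol/nt); Welch's unequal-variance t with Welch-Satterthwaite
#'   degrees of freedom, Cohen's effect size derived from the t statistic
#'   as d = 2t/sqrt(df), the two-sample Kolmogorov-Smirnov test with its
#'   asymptotic p-value, chromosome-stratified control sampling, and a
#'   Nussinov maximum-base-pairing fold for desk-scale closed-loop tests.
#' @name rnastats
NULL

#' GC content of a sequence
#'
#' (number of G + number of C) / sequence length; ambiguous N bases count
#' in the denominator but never in the numerator.
#'
#' @param sequence a character vector of sequences or a
#'   \code{DNAStringSet}.
#' @return numeric vector of GC fractions in [0, 1].
#' @export
gcContent <- function(sequence) {
  if (is.character(sequence)) {
    sequence <- chartr("Uu", "Tt", sequence)
    sequence <- DNAStringSet(toupper(sequence))
  }
  if (any(width(sequence) == 0L)) dataError("empty sequence has no GC content")
  gc <- letterFrequency(sequence, letters = c("G", "C"))
  unname((gc[, "G"] + gc[, "C"]) / width(sequence))
}

#' Length-corrected minimum free energy
#'
#' @param mfe minimum free energy, kcal/mol.
#' @param length sequence length, nt (> 0).
#' @return MFE per nucleotide, kcal/mol/nt.
#' @export
lengthCorrectedMfe <- function(mfe, length) {
  if (any(length <= 0)) dataError("sequence length must be positive")
  mfe / length
}

#' Welch's unequal-variance t from group summaries
#'
#' t = (mean1 - mean2) / sqrt(sd1^2/n1 + sd2^2/n2), with
#' Welch-Satterthwaite degrees of freedom; the two-sided p-value follows
#' from the t distribution.
#'
#' @param mean1,sd1,n1 first group summary (n1 >= 2).
#' @param mean2,sd2,n2 second group summary (n2 >= 2).
#' @return list with t, df, p (two-sided).
#' @export
welchT <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) dataError("Welch's t needs at least 2 values per group")
  if (sd1 < 0 || sd2 < 0) dataError("standard deviations must be non-negative")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) dataError("degenerate variance: both groups are constant")
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Welch's t from raw samples
#'
#' Computes the group summaries and delegates to \code{\link{welchT}}.
#'
#' @param x,y numeric sample vectors (length >= 2 each).
#' @return list with t, df, p.
#' @export
welchTest <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    dataError("Welch's t needs at least 2 values per group")
  }
  welchT(mean(x), sd(x), length(x), mean(y), sd(y), length(y))
}

#' Cohen's d from a t statistic
#'
#' d = 2|t| / sqrt(df).  The effect size is a magnitude, so the sign of t
#' is discarded and d is invariant to group order.
#'
#' @param t a t statistic.
#' @param df its degrees of freedom (> 0).
#' @return Cohen's d (>= 0).
#' @export
cohensDFromT <- function(t, df) {
  if (df <= 0) dataError("degrees of freedom must be positive")
  2 * abs(t) / sqrt(df)
}

# survival function of the Kolmogorov distribution, two-branch evaluation
kolmogorovSF <- function(x) {
  if (x <= 0) return(1)
  if (x < 1) {
    k <- 1:20
    cdf <- sqrt(2 * pi) / x * sum(exp(-(2 * k - 1)^2 * pi^2 / (8 * x^2)))
    return(min(max(1 - cdf, 0), 1))
  }
  k <- 1:100
  min(max(2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2)), 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum distance between the two empirical distribution
#' functions; the p-value uses the asymptotic Kolmogorov distribution at
#' effective sample size n1*n2/(n1+n2) (excellent at the sample sizes
#' this comparison runs at; no exact small-sample p is attempted).
#'
#' @param values1,values2 numeric sample vectors (non-empty).
#' @return list with D and p.
#' @export
ksTwoSample <- function(values1, values2) {
  n1 <- length(values1)
  n2 <- length(values2)
  if (n1 == 0 || n2 == 0) dataError("KS test needs non-empty samples")
  pooled <- c(values1, values2)
  z <- cumsum(ifelse(order(pooled) <= n1, 1 / n1, -1 / n2))
  ties <- diff(sort(pooled)) == 0
  z <- z[c(!ties, TRUE)]
  D <- max(abs(z))
  nEff <- n1 * n2 / (n1 + n2)
  list(D = D, p = kolmogorovSF(sqrt(nEff) * D))
}

#' Chromosome-stratified random gene sampling
#'
#' Draws, per chromosome, a uniform without-replacement sample of the
#' requested size — used to pick a protein-coding control set whose
#' chromosomal occurrence pattern matches that of the lncRNAs.  The same
#' seed always yields the same sample.
#'
#' @param genes gene models (\code{GRanges}).
#' @param plan named integer vector: chromosome -> number of genes.
#' @param seed integer RNG seed.
#' @return character vector of sampled gene ids.
#' @export
stratifiedSample <- function(genes, plan, seed) {
  tab <- geneTable(genes)
  short <- names(plan)[vapply(names(plan), function(chrom) {
    sum(tab$chromosome == chrom) < plan[[chrom]]
  }, logical(1))]
  if (length(short)) {
    dataError(sprintf("insufficient genes on chromosome(s): %s",
                      paste(short, collapse = ", ")))
  }
  withr::with_seed(seed, {
    unlist(lapply(sort(names(plan)), function(chrom) {
      pool <- sort(tab$gene_id[tab$chromosome == chrom])
      pool[sample.int(length(pool), plan[[chrom]])]
    }), use.names = FALSE)
  })
}

RNA_PAIRS <- c("AU", "UA", "GC", "CG", "GU", "UG")

#' Nussinov maximum base-pairing fold
#'
#' A desk-scale folding stand-in: maximises the number of Watson-Crick
#' plus G-U wobble base pairs under a minimum hairpin loop length and no
#' pseudoknots, with a deterministic traceback (the 5' base of an
#' interval pairs with its smallest admissible partner whenever pairing
#' achieves the optimum).  The pseudo-MFE is -1 kcal/mol per pair — an
#' arbitrary unit useful only for closed-loop testing, not a
#' thermodynamic model.
#'
#' @param sequence one sequence over \{A, C, G, U/T\}.
#' @param min_loop minimum number of unpaired bases in a hairpin loop.
#' @return list with pairs (count), dot_bracket, and pseudo_mfe.
#' @export
nussinovFold <- function(sequence, min_loop = 3L) {
  s <- chartr("Tt", "Uu", toupper(sequence))
  b <- strsplit(s, "")[[1]]
  if (any(!b %in% c("A", "C", "G", "U"))) {
    dataError(sprintf("invalid character '%s' in sequence",
                      b[!b %in% c("A", "C", "G", "U")][1L]))
  }
  n <- length(b)
  canPair <- function(i, j) paste0(b[i], b[j]) %in% RNA_PAIRS
  N <- matrix(0L, nrow = max(n, 1L), ncol = max(n, 1L))
  val <- function(i, j) if (i > j || i < 1 || j > n) 0L else N[i, j]
  if (n >= min_loop + 2L) {
    for (len in (min_loop + 2L):n) {
      for (i in seq_len(n - len + 1L)) {
        j <- i + len - 1L
        best <- val(i + 1L, j)
        ks <- seq.int(i + min_loop + 1L, j)
        for (k in ks) {
          if (canPair(i, k)) {
            cand <- 1L + val(i + 1L, k - 1L) + val(k + 1L, j)
            if (cand > best) best <- cand
          }
        }
        N[i, j] <- best
      }
    }
  }
  db <- rep(".", n)
  stack <- if (n) list(c(1L, n)) else list()
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    while (i < j && val(i, j) > 0L) {
      paired <- FALSE
      if (j - i > min_loop) {
        for (k in seq.int(i + min_loop + 1L, j)) {
          if (canPair(i, k) &&
              1L + val(i + 1L, k - 1L) + val(k + 1L, j) == val(i, j)) {
            db[i] <- "("; db[k] <- ")"
            if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
            j <- k - 1L
            i <- i + 1L
            paired <- TRUE
            break
          }
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  pairs <- if (n) N[1L, n] else 0L
  list(pairs = pairs, dot_bracket = paste(db, collapse = ""),
       pseudo_mfe = -1.0 * pairs)
}

#' Per-transcript metric table
#'
#' Joins sequences with their fold results into the metric table the
#' group comparison consumes: length (nt), GC fraction, MFE (kcal/mol)
#' and length-corrected MFE (kcal/mol/nt).
#'
#' @param seqs a named \code{DNAStringSet}.
#' @param folds data frame with columns id and mfe (e.g. from
#'   \code{\link{readRnafold}}).
#' @return data frame with columns id, length, gc, mfe, mfe_per_nt.
#' @export
transcriptMetrics <- function(seqs, folds) {
  idx <- match(names(seqs), folds$id)
  if (anyNA(idx)) {
    dataError(sprintf("no fold result for transcript(s): %s",
                      paste(names(seqs)[is.na(idx)], collapse = ", ")))
  }
  len <- width(seqs)
  mfe <- folds$mfe[idx]
  data.frame(id = names(seqs), length = len, gc = gcContent(seqs), mfe = mfe,
             mfe_per_nt = lengthCorrectedMfe(mfe, len),
             stringsAsFactors = FALSE)
}

#' Compare lncRNA and coding groups across metrics
#'
#' For each metric (length, GC, MFE, length-corrected MFE) the two groups
#' are compared with Welch's t (two-sided), the Kolmogorov-Smirnov test,
#' and Cohen's d = 2|t|/sqrt(df).
#'
#' @param lnc,coding metric tables from \code{\link{transcriptMetrics}}.
#' @param metrics which metric columns to compare.
#' @return data frame with one row per metric: n1, n2, mean1, sd1, mean2,
#'   sd2, t, df, p_t, d, ks_D, p_ks.
#' @export
compareGroups <- function(lnc, coding,
                          metrics = c("length", "gc", "mfe", "mfe_per_nt")) {
  do.call(rbind, lapply(metrics, function(m) {
    x <- lnc[[m]]
    y <- coding[[m]]
    w <- welchTest(x, y)
    ks <- ksTwoSample(x, y)
    data.frame(metric = m, n1 = length(x), n2 = length(y),
               mean1 = mean(x), sd1 = sd(x), mean2 = mean(y), sd2 = sd(y),
               t = w$t, df = w$df, p_t = w$p,
               d = cohensDFromT(w$t, w$df), ks_D = ks$D, p_ks = ks$p,
               stringsAsFactors = FALSE)
  }))
}
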