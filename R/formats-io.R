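#' @title Readers and writers for external evidence formats
#' @description Every external text format the toolkit consumes is
#'   normalised here into the containers used by the analysis modules:
#'   sequences become \code{DNAStringSet}, gene models become
#'   \code{GRanges} with a per-chromosome rank, and tabular evidence
#'   becomes plain data frames with fixed column names.
#' @name formats-io
NULL

FASTA_ALPHABET <- "ACGTN"

#' Read transcript or gene-model sequences from a FASTA file
#'
#' Sequences are upper-cased and U is converted to T on read, so RNA and
#' DNA input are interchangeable downstream (GC content and folding treat
#' the two alphabets as equivalent).  The first whitespace-delimited token
#' of each header is the record id; the remainder is kept as a
#' \code{description} metadata column.
#'
#' @param path path to a FASTA file.
#' @return A \code{DNAStringSet} named by record id, with a
#'   \code{description} column in \code{mcols}.  An empty file yields an
#'   empty set with a warning.
#' @export
readFastaRecords <- function(path) {
  raw <- readBStringSet(path)
  if (length(raw) == 0L) {
    warning(sprintf("no FASTA records in '%s'", path))
    out <- DNAStringSet()
    mcols(out)$description <- character(0)
    return(out)
  }
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(ids == "")) formatError("FASTA header with empty id")
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    formatError(sprintf("duplicate FASTA ids: %s", paste(dup, collapse = ", ")))
  }
  if (any(width(raw) == 0L)) {
    bad <- ids[width(raw) == 0L]
    formatError(sprintf("FASTA header without sequence: %s",
                        paste(bad, collapse = ", ")))
  }
  seqs <- chartr("u", "t", toupper(as.character(raw)))
  seqs <- chartr("U", "T", seqs)
  if (any(grepl(sprintf("[^%s]", FASTA_ALPHABET), seqs))) {
    bad <- ids[grepl(sprintf("[^%s]", FASTA_ALPHABET), seqs)][1L]
    formatError(sprintf("sequence '%s' contains characters outside {A,C,G,T,U,N}", bad))
  }
  out <- DNAStringSet(seqs)
  names(out) <- ids
  mcols(out)$description <- desc
  out
}

#' Write sequences to FASTA
#'
#' Inverse of \code{\link{readFastaRecords}}: ids and descriptions are
#' restored into the headers so a write/read round trip reproduces the
#' records exactly.
#'
#' @param seqs a named \code{DNAStringSet} (a \code{description} metadata
#'   column, if present, is appended to each header).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeFastaRecords <- function(seqs, path) {
  stopifnot(is(seqs, "DNAStringSet"))
  out <- seqs
  desc <- mcols(seqs)$description
  if (!is.null(desc)) {
    names(out) <- ifelse(nzchar(desc), paste(names(seqs), desc), names(seqs))
  }
  writeXStringSet(out, path, width = 70L)
  invisible(path)
}

blastColumns <- c("query_id", "subject_id", "percent_identity",
                  "alignment_length", "evalue", "bit_score")

#' Read a BLAST tabular (outfmt 6) alignment file
#'
#' Standard 12-column ordering is assumed; columns 1, 2, 3, 4, 11 and 12
#' are kept, additional trailing columns are tolerated and ignored.
#' Comment lines starting with '#' are skipped.
#'
#' @param path path to a tab-separated alignment table.
#' @return data frame with columns query_id, subject_id, percent_identity,
#'   alignment_length, evalue, bit_score.
#' @export
readBlastTab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(emptyHits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    formatError(sprintf("BLAST tabular row with %d < 12 columns at line %d",
                        nf[nf < 12L][1L], lineno[nf < 12L][1L]))
  }
  grab <- function(i) vapply(fields, `[[`, character(1), i)
  hits <- data.frame(
    query_id = grab(1L),
    subject_id = grab(2L),
    percent_identity = parseNumeric(grab(3L), "percent identity", lineno),
    alignment_length = parseNumeric(grab(4L), "alignment length", lineno),
    evalue = parseNumeric(grab(11L), "E-value", lineno),
    bit_score = parseNumeric(grab(12L), "bit score", lineno),
    stringsAsFactors = FALSE
  )
  validateHits(hits, lineno)
  hits
}

emptyHits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             percent_identity = numeric(0), alignment_length = numeric(0),
             evalue = numeric(0), bit_score = numeric(0),
             stringsAsFactors = FALSE)
}

validateHits <- function(hits, lineno = NULL) {
  bad <- hits$percent_identity < 0 | hits$percent_identity > 100 |
    hits$alignment_length < 1 | hits$evalue < 0
  if (any(bad)) {
    where <- if (is.null(lineno)) "" else sprintf(" at line %d", lineno[bad][1L])
    formatError(sprintf("alignment hit violates field ranges%s", where))
  }
  invisible(hits)
}

#' Write alignment hits as a 12-column BLAST tabular file
#'
#' Columns 5-10 (mismatches, gap opens, coordinates) are not modelled by
#' the toolkit and are written as zeros/ones placeholders.
#'
#' @param hits data frame as returned by \code{\link{readBlastTab}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBlastTab <- function(hits, path) {
  n <- nrow(hits)
  tab <- data.frame(
    hits$query_id, hits$subject_id,
    formatC(hits$percent_identity, format = "f", digits = 2),
    as.integer(hits$alignment_length),
    rep(0L, n), rep(0L, n), rep(1L, n), as.integer(hits$alignment_length),
    rep(1L, n), as.integer(hits$alignment_length),
    sprintf("%.15g", hits$evalue),
    formatC(hits$bit_score, format = "f", digits = 1)
  )
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# whitespace-delimited tblout shared by hmmscan and cmscan
readTblout <- function(path, ncolMin) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(list(fields = list(), lineno = integer(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- lengths(fields)
  if (any(nf < ncolMin)) {
    formatError(sprintf("tblout row with %d < %d columns at line %d",
                        nf[nf < ncolMin][1L], ncolMin, lineno[nf < ncolMin][1L]))
  }
  list(fields = fields, lineno = lineno)
}

#' Read hmmscan domain hits (tblout)
#'
#' Hits keep the query id (column 3), the Pfam accession (column 2,
#' version suffix stripped so accessions join against pfam2go), the
#' full-sequence E-value (column 5) and score (column 6).
#'
#' @param path path to an hmmscan \code{--tblout} file.
#' @return data frame with columns query_id, domain_accession, evalue,
#'   score.
#' @export
readHmmscan <- function(path) {
  parsed <- readTblout(path, 6L)
  if (length(parsed$fields) == 0L) {
    return(data.frame(query_id = character(0), domain_accession = character(0),
                      evalue = numeric(0), score = numeric(0)))
  }
  grab <- function(i) vapply(parsed$fields, `[[`, character(1), i)
  out <- data.frame(
    query_id = grab(3L),
    domain_accession = sub("\\.\\d+$", "", grab(2L)),
    evalue = parseNumeric(grab(5L), "E-value", parsed$lineno),
    score = parseNumeric(grab(6L), "score", parsed$lineno),
    stringsAsFactors = FALSE
  )
  if (any(out$evalue < 0)) formatError("negative E-value in hmmscan table")
  out
}

#' Read Infernal cmscan hits (tblout)
#'
#' Keeps the query id (column 3), the Rfam model accession (column 2),
#' the E-value (column 16) and bit score (column 15).
#'
#' @param path path to a cmscan \code{--tblout} file.
#' @return data frame with columns query_id, model_accession, evalue,
#'   score.
#' @export
readCmscan <- function(path) {
  parsed <- readTblout(path, 16L)
  if (length(parsed$fields) == 0L) {
    return(data.frame(query_id = character(0), model_accession = character(0),
                      evalue = numeric(0), score = numeric(0)))
  }
  grab <- function(i) vapply(parsed$fields, `[[`, character(1), i)
  out <- data.frame(
    query_id = grab(3L),
    model_accession = grab(2L),
    evalue = parseNumeric(grab(16L), "E-value", parsed$lineno),
    score = parseNumeric(grab(15L), "score", parsed$lineno),
    stringsAsFactors = FALSE
  )
  if (any(out$evalue < 0)) formatError("negative E-value in cmscan table")
  out
}

#' Read an RSEM-style expression table
#'
#' Two dialects are accepted: a plain two-column (id, FPKM) table with or
#' without a header, and a full RSEM \code{.results} table, in which case
#' the \code{transcript_id} and \code{FPKM} columns are used.
#'
#' @param path path to a tab-separated expression table.
#' @return data frame with columns transcript_id, fpkm.
#' @export
readExpression <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  hasHeader <- length(first) == 1L && grepl("FPKM", first, ignore.case = TRUE)
  df <- read.delim(path, header = hasHeader, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(data.frame(transcript_id = character(0), fpkm = numeric(0)))
  }
  if (hasHeader) {
    idCol <- if ("transcript_id" %in% names(df)) "transcript_id" else names(df)[1L]
    fpkmCol <- names(df)[toupper(names(df)) == "FPKM"][1L]
    if (is.na(fpkmCol)) formatError("expression table header lacks an FPKM column")
    out <- data.frame(transcript_id = as.character(df[[idCol]]),
                      fpkm = parseNumeric(as.character(df[[fpkmCol]]), "FPKM"),
                      stringsAsFactors = FALSE)
  } else {
    if (ncol(df) < 2L) formatError("expression table needs at least 2 columns")
    out <- data.frame(transcript_id = as.character(df[[1L]]),
                      fpkm = parseNumeric(as.character(df[[2L]]), "FPKM"),
                      stringsAsFactors = FALSE)
  }
  if (any(out$fpkm < 0)) formatError("negative FPKM in expression table")
  out
}

#' Write an expression table (id, FPKM)
#' @param expression data frame with columns transcript_id, fpkm.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(expression, path) {
  write.table(expression[, c("transcript_id", "fpkm")], path, sep = "\t",
              quote = FALSE, row.names = FALSE,
              col.names = c("transcript_id", "FPKM"))
  invisible(path)
}

#' Read gene models from a GFF3 annotation
#'
#' Only features of type \code{gene} are kept.  Each gene receives a rank:
#' its 0-based order index along its chromosome by ascending start
#' coordinate, ties broken by gene id.  Coordinates stay in GFF3's
#' 1-based inclusive convention.  The chromosome name \code{chrUkn} is a
#' recognised sentinel for unplaced scaffolds.
#'
#' @param path path to a GFF3 file.
#' @return \code{GRanges} with metadata columns \code{gene_id} and
#'   \code{rank}.
#' @export
readGff3Genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[mcols(gr)$type == "gene"]
  if (length(genes) == 0L) formatError(sprintf("no gene features in '%s'", path))
  ids <- mcols(genes)$ID
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    formatError("GFF3 gene feature without an ID attribute")
  }
  mcols(genes) <- NULL
  mcols(genes)$gene_id <- as.character(ids)
  assignRanks(genes)
}

# rank = 0-based order by start within chromosome, ties by gene_id
assignRanks <- function(genes) {
  ord <- order(as.character(seqnames(genes)), start(genes),
               mcols(genes)$gene_id)
  genes <- genes[ord]
  chrom <- as.character(seqnames(genes))
  mcols(genes)$rank <- unlist(lapply(split(seq_along(genes), chrom)[unique(chrom)],
                                     function(i) seq_along(i) - 1L),
                              use.names = FALSE)
  genes
}

#' Write gene models to GFF3
#' @param genes \code{GRanges} with a \code{gene_id} metadata column.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGff3Genes <- function(genes, path) {
  out <- genes
  mcols(out) <- NULL
  mcols(out)$source <- "vinelnc"
  mcols(out)$type <- "gene"
  mcols(out)$ID <- mcols(genes)$gene_id
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

# gene models as a plain lookup table used by the anchoring/duplication code
geneTable <- function(genes) {
  data.frame(gene_id = mcols(genes)$gene_id,
             chromosome = as.character(seqnames(genes)),
             start = start(genes), end = end(genes),
             strand = as.character(strand(genes)),
             rank = mcols(genes)$rank,
             stringsAsFactors = FALSE)
}

#' Read RNAfold plain-text output
#'
#' Blocks of the form header, sequence, then a dot-bracket structure line
#' ending in the minimum free energy in parentheses, e.g.
#' \code{"((((...)))) ( -4.20)"}.  Dot-bracket length and balance are
#' validated against the sequence.
#'
#' @param path path to an RNAfold output file.
#' @return data frame with columns id, sequence, dot_bracket, mfe
#'   (kcal/mol).
#' @export
readRnafold <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  id <- NULL; seqline <- NULL
  structRe <- "^([.()]+)\\s*\\(\\s*(-?[0-9]+(\\.[0-9]+)?)\\s*\\)\\s*$"
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      id <- sub("\\s.*$", "", sub("^>", "", line))
      seqline <- NULL
    } else if (grepl("^[ACGUTNacgutn]+$", line)) {
      seqline <- toupper(line)
    } else if (grepl(structRe, line)) {
      if (is.null(id)) formatError(sprintf("structure without a header at line %d", i))
      db <- sub(structRe, "\\1", line)
      mfe <- as.numeric(sub(structRe, "\\2", line))
      if (!is.null(seqline) && nchar(db) != nchar(seqline)) {
        formatError(sprintf("dot-bracket length differs from sequence at line %d", i))
      }
      depth <- cumsum((strsplit(db, "")[[1]] == "(") -
                        (strsplit(db, "")[[1]] == ")"))
      if (any(depth < 0) || depth[length(depth)] != 0) {
        formatError(sprintf("unbalanced dot-bracket at line %d", i))
      }
      recs[[length(recs) + 1L]] <- data.frame(
        id = id, sequence = if (is.null(seqline)) NA_character_ else seqline,
        dot_bracket = db, mfe = mfe, stringsAsFactors = FALSE)
      id <- NULL; seqline <- NULL
    } else {
      formatError(sprintf("unrecognised RNAfold line %d: '%s'", i, line))
    }
  }
  if (length(recs) == 0L) {
    return(data.frame(id = character(0), sequence = character(0),
                      dot_bracket = character(0), mfe = numeric(0)))
  }
  do.call(rbind, recs)
}

#' Write fold results as RNAfold-style text
#' @param folds data frame with columns id, sequence, dot_bracket, mfe.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeRnafold <- function(folds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(folds))) {
    writeLines(c(paste0(">", folds$id[i]), folds$sequence[i],
                 sprintf("%s (%6.2f)", folds$dot_bracket[i], folds$mfe[i])),
               con)
  }
  invisible(path)
}

#' Read a CD-HIT .clstr cluster file
#'
#' Sections start with \code{>Cluster n}; member lines carry the sequence
#' id between \code{>} and \code{...}, and the representative is flagged
#' with a trailing \code{*}.
#'
#' @param path path to a .clstr file.
#' @return data frame with columns cluster_id, member_id,
#'   is_representative.  Exactly one representative per cluster and
#'   disjoint member sets are enforced.
#' @export
readClstr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- -1L
  rows <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (grepl("^>Cluster\\s+\\d+", line)) {
      cl <- as.integer(sub("^>Cluster\\s+(\\d+).*$", "\\1", line))
    } else {
      if (cl < 0L) formatError(sprintf("member before any cluster header at line %d", i))
      m <- regmatches(line, regexec(">\\s*(.+?)\\.\\.\\.", line))[[1]]
      if (length(m) < 2L) formatError(sprintf("unparseable .clstr member at line %d", i))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster_id = cl, member_id = m[2],
        is_representative = grepl("\\*\\s*$", line), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows) == 0L) {
    data.frame(cluster_id = integer(0), member_id = character(0),
               is_representative = logical(0))
  } else do.call(rbind, rows)
  if (anyDuplicated(out$member_id)) {
    formatError("member id occurs in more than one cluster")
  }
  reps <- tapply(out$is_representative, out$cluster_id, sum)
  if (length(reps) && any(reps != 1L)) {
    formatError("every cluster must have exactly one representative")
  }
  out
}

#' Write cluster assignments as a CD-HIT-style .clstr file
#' @param clusters data frame with columns cluster_id, member_id,
#'   is_representative (and optionally member lengths in a
#'   \code{length} column).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeClstr <- function(clusters, path) {
  con <- file(path, "w")
  on.exit(close(con))
  len <- if ("length" %in% names(clusters)) clusters$length else rep(0L, nrow(clusters))
  for (cl in unique(clusters$cluster_id)) {
    writeLines(sprintf(">Cluster %d", cl), con)
    rows <- which(clusters$cluster_id == cl)
    for (j in seq_along(rows)) {
      r <- rows[j]
      tail <- if (clusters$is_representative[r]) "*" else "at +/99.00%"
      writeLines(sprintf("%d\t%dnt, >%s... %s", j - 1L, len[r],
                         clusters$member_id[r], tail), con)
    }
  }
  invisible(path)
}

#' Read a pfam2go-style domain-to-GO mapping
#'
#' Two dialects are accepted: the Gene Ontology project's flat file
#' (\code{"Pfam:PF00001 7tm_1 > GO:... ; GO:0004930"}), in which the
#' ontology class is not recorded and is returned as \code{NA}; and a
#' three-column TSV (domain_accession, go_id, go_class) carrying the
#' ontology root class explicitly.
#'
#' @param path path to the mapping file.
#' @return data frame with columns domain_accession, go_id, go_class.
#' @export
readPfam2go <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(trimws(lines))]
  empty <- data.frame(domain_accession = character(0), go_id = character(0),
                      go_class = character(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  if (grepl("^Pfam:", lines[1L])) {
    re <- "^Pfam:(\\S+)\\s+\\S+\\s+>\\s+GO:.*;\\s*(GO:\\d+)\\s*$"
    bad <- !grepl(re, lines)
    if (any(bad)) formatError(sprintf("unparseable pfam2go line: '%s'", lines[bad][1L]))
    out <- data.frame(domain_accession = sub(re, "\\1", lines),
                      go_id = sub(re, "\\2", lines),
                      go_class = NA_character_, stringsAsFactors = FALSE)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L)) {
    formatError("pfam2go TSV dialect needs 3 columns (accession, go_id, go_class)")
  }
  out <- data.frame(domain_accession = vapply(fields, `[[`, "", 1L),
                    go_id = vapply(fields, `[[`, "", 2L),
                    go_class = vapply(fields, `[[`, "", 3L),
                    stringsAsFactors = FALSE)
  valid <- c("molecular_function", "biological_process", "cellular_component")
  if (!all(out$go_class %in% valid)) {
    formatError("go_class must be one of the three ontology roots")
  }
  out
}
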