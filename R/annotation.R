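#' @title Functional-annotation bookkeeping
#' @description E-value filtering of protein-domain hits and joining of
#'   Pfam domain accessions to Gene Ontology terms, with per-ontology
#'   class tallies.
#' @name annotation
NULL

#' Filter domain hits by E-value
#'
#' Keeps hits at or below the E-value ceiling (the boundary is
#' inclusive) and summarises the cohort: total hits, distinct domain
#' accessions, distinct query gene models.
#'
#' @param hits data frame from \code{\link{readHmmscan}}.
#' @param evalue_max significance ceiling (inclusive).
#' @return list with \code{kept} (the retained hits) and \code{summary}
#'   (n_hits, n_unique_domains, n_unique_genes).
#' @export
filterDomainHits <- function(hits, evalue_max = 1e-5) {
  kept <- hits[hits$evalue <= evalue_max, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept,
       summary = c(n_hits = nrow(kept),
                   n_unique_domains = length(unique(kept$domain_accession)),
                   n_unique_genes = length(unique(kept$query_id))))
}

GO_CLASSES <- c("molecular_function", "biological_process",
                "cellular_component")

#' Join filtered domain hits to GO terms
#'
#' One annotation row is produced per (hit, mapped GO term): a domain
#' mapped to two terms and hit in three genes contributes six instances.
#' Domains absent from the mapping contribute nothing.
#'
#' @param kept_hits retained hits from \code{\link{filterDomainHits}}.
#' @param pfam2go mapping from \code{\link{readPfam2go}}.
#' @return list with \code{annotations} (gene_id, domain_accession,
#'   go_id, go_class) and \code{class_counts} (named integer vector over
#'   the three ontology roots plus \code{unclassified} for mappings that
#'   carry no class).
#' @export
joinPfamGo <- function(kept_hits, pfam2go) {
  merged <- merge(
    data.frame(gene_id = kept_hits$query_id,
               domain_accession = kept_hits$domain_accession,
               stringsAsFactors = FALSE),
    pfam2go, by = "domain_accession")
  annotations <- merged[order(merged$gene_id, merged$domain_accession,
                              merged$go_id),
                        c("gene_id", "domain_accession", "go_id", "go_class")]
  rownames(annotations) <- NULL
  counts <- table(factor(annotations$go_class, levels = GO_CLASSES))
  class_counts <- c(setNames(as.integer(counts), GO_CLASSES),
                    unclassified = sum(is.na(annotations$go_class)))
  list(annotations = annotations, class_counts = class_counts)
}
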