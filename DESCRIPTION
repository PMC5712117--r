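Package: vinelnc
Title: Gene-Model Anchoring and De Novo Long Non-Coding RNA Discovery
    for Grapevine Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A format-aware toolkit for reference-free transcriptome
    curation in highly heterozygous plants such as grapevine. Implements
    iterative reciprocal-best-hit (iRBH) anchoring of gene models between
    two annotations with chromosome-concordance classification and a
    rescue pass for unsupported legacy models; a chained, auditable long
    non-coding RNA identification pipeline (redundancy clustering,
    expression filtering, protein-homology binning, cross-accession
    consensus, Rfam purging, and an open-reading-frame coding flag);
    tandem gene array detection from self-alignment tables and gene
    order; and the coding-versus-noncoding thermodynamic comparison
    statistics (length-corrected minimum free energy, Welch's t with
    Welch-Satterthwaite degrees of freedom, two-sample Kolmogorov-Smirnov,
    and Cohen's d derived from t). Readers are provided for FASTA, BLAST
    outfmt-6 tabular, HMMER and Infernal tblout, GFF3 gene models,
    RNAfold text output, CD-HIT cluster files, RSEM-style expression
    tables and pfam2go mappings, and a synthetic fixture generator plants
    ground truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
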