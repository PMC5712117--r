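---
title: "Methods: anchoring, lncRNA identification, and the statistics behind them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anchoring, lncRNA identification, and the statistics behind them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented by `vinelnc`, the
assumptions behind them, every tunable parameter with its default and
rationale, the numerical choices that matter for reproducibility, what
the synthetic generator does and does not emulate, and the limitations
of the approach. Code chunks are illustrative and not evaluated when the
vignette is built.

## 1. Iterative reciprocal-best-hit anchoring

### Model

Anchoring maps gene models between two annotations, A and B, from two
alignment tables (A queried against B and B against A). Within each
query, hits are ranked by bit score (descending), E-value (ascending),
percent identity (descending), and finally subject id — the last key
makes the ranking a total order, so results cannot depend on input row
order. A pair (a, b) is an anchor when each is the other's top-ranked
surviving hit. After each round, anchored ids are struck from *all*
rows of both tables (as query and as subject), and the round repeats.

The iteration is the point: in families of similar paralogs, a single
reciprocal-best-hit pass anchors only the strongest pair, and the
remaining family members point at already-taken partners. Removing
consumed ids lets the second-best pair become mutually best in round 2,
and so on. The procedure is a greedy, score-ordered matching; it does
not claim to find a maximum-weight bipartite matching, but it mirrors
how curators resolve families by strongest-evidence-first.

### Parameters

| parameter | default | rationale |
|---|---|---|
| `evalue_max` | `1e-5` | conventional homology ceiling for nucleotide/protein searches; hits above it are noise for anchoring purposes |
| `max_iterations` | `25` | deep enough for any realistic paralog family; the loop stops early when a round yields nothing |

Each anchor records the *worse* of the two directions' E-values and the
worse bit score — an anchor is only as strong as its weaker direction.

Concordance classification needs both annotations' gene models; an
anchor is `same_chromosome`, `different_chromosome`, or
`involves_chrUkn` when either side sits on the unplaced-scaffold
pseudochromosome (`chrUkn`), which is deliberately kept out of the
other two classes because placement there is an artifact of assembly,
not biology.

A rescue pass (`rescueUnsupported`) re-examines B models left without
an anchor, using the same reciprocity rule on the full tables; it
exists because legacy models absent from a new annotation may still
have a defensible partner even after the main matching consumed their
family.

## 2. The lncRNA evidence chain

### Model and stage order

Each accession is processed independently through the first three
stages, then the two accessions are merged:

1. **Redundancy clustering** — greedy clustering at ≥ 90 % identity,
   where identity is the number of matching positions divided by the
   *shorter* sequence's length (so a fragment nested in a longer
   transcript clusters with it). The longest sequence seeds each
   cluster and only representatives continue. Assumption: near-identical
   transcripts are assembly redundancy, not independent loci.
2. **Expression filter** — representatives with FPKM ≥ 1.50 continue
   (inclusive boundary). Transcripts without an expression record are
   removed with their own reason code: absence of evidence is logged
   distinctly from evidence of low expression.
3. **Protein-homology binning** — the best hit at E ≤ 10⁻²⁰ (same
   ranking chain as anchoring) labels a transcript `plant` or
   `non_plant` by the organism code of the subject id (the token after
   the last underscore, UniProt style). Both bins are removed — plant
   homology means the transcript is an unannotated protein, non-plant
   homology suggests contamination. Only `no_hit` transcripts continue.
4. **Cross-accession consensus** — a transcript needs support in the
   other accession: a top hit aligning ≥ 200 nt. The *longer* transcript
   of the supported pair is emitted (ties go to the query side), and
   duplicates arising when several queries select one subject are
   collapsed. Assumption: a real locus transcribed in both accessions is
   far less likely to be an assembly artifact.
5. **Length floor** — ≥ 200 nt, the standard operational boundary
   between lncRNAs and small RNA classes.
6. **Rfam purge** — covariance-model hits at E ≤ 0.01 remove known
   structured RNAs (rRNA, tRNA, snoRNA…) that pass every upstream test
   but are not lncRNAs.
7. **ORF flag** — an open reading frame of ≥ 100 codons in any of the
   six reading frames marks a transcript *possibly coding*. Flagged
   transcripts are excluded from the final lncRNA set but reported
   separately rather than silently dropped, because a long ORF is
   suggestive, not conclusive.

Every stage writes kept/removed ids with reason strings to a log, and
the audit table satisfies `n_in = n_kept + n_removed` in every row,
with each stage's `n_in` equal to the previous stage's `n_kept` along
its chain. This conservation property is what makes the pipeline's
claims checkable after the fact.

### Parameters

| parameter | default | rationale |
|---|---|---|
| `cluster_identity` | `0.90` | standard CD-HIT-EST-style redundancy threshold; lower values start merging paralogs |
| `fpkm_min` | `1.50` | separates reproducibly expressed transcripts from assembly/mapping noise; inclusive so the boundary value itself passes |
| `protein_evalue_max` | `1e-20` | deliberately strict: only confident protein homology should disqualify a lncRNA candidate |
| `min_consensus_alignment` | `200` | cross-accession support must cover at least a lncRNA-sized region, not a short repeat |
| `min_lncrna_length` | `200` | the conventional lncRNA definition boundary |
| `rfam_evalue_max` | `0.01` | Infernal's own reporting conventions; structured-RNA families are well separated at this level |
| `orf_min_codons` | `100` | ~300 nt of continuous coding frame is unlikely by chance in a transcript of typical lncRNA length |
| `consensus_query` | `"a"` | which accession's transcripts act as queries in the cross-accession table; affects tie-breaking, recorded for reproducibility |

All E-value and FPKM boundaries are **inclusive** (`<=` / `>=`),
matching the usual reading of "at most"/"at least" in filtering
protocols; the test suite pins each boundary on both sides.

## 3. Duplicate genes and tandem arrays

From a self-alignment table, self-hits (a gene against itself) are
dropped, and the two directions of each pair are merged keeping the
better (smaller) E-value. Pairs at E ≤ 10⁻²⁰ are classified by gene
order on the chromosome (0-based rank by start position, ties by gene
id): adjacent ranks on one chromosome → `tandem`; within
`proximal_window = 10` ranks → `proximal`; anything else, including
cross-chromosome pairs → `dispersed`. A gene's own class is the best
class of any pair it participates in (tandem > proximal > dispersed).
Tandem gene arrays are the connected components of the graph whose
edges are the tandem pairs, so an array is a maximal run of mutually
adjacent duplicates. The window of 10 is a conventional definition of
"proximal" in plant duplicate-gene studies: near enough to suggest a
local duplication with later insertions between the copies.

## 4. Statistics

### Welch's t and Cohen's d

Groups of length-corrected minimum free energy (MFE/nt = MFE divided by
transcript length) are compared with Welch's unequal-variance *t*
statistic and Welch–Satterthwaite degrees of freedom. `welchT` works
from group summaries (mean, sd, n) so published summary statistics can
be re-examined without the raw data; `welchTest` computes the same from
raw vectors, and the two agree to floating-point precision. The effect
size is Cohen's d recovered from the statistic, d = 2|t|/√df — the
standard conversion when only *t* and df are available. Degenerate
inputs (n < 2, or both groups with zero variance) raise a data-error
condition instead of returning NaN.

### Two-sample Kolmogorov–Smirnov

The D statistic is the supremum distance between the two empirical
CDFs, computed with R-style tie collapsing over the pooled sorted
sample. The p-value is the asymptotic Kolmogorov survival function
evaluated at √(n₁n₂/(n₁+n₂))·D. Numerically, the survival function has
two exact series representations, and the implementation switches
between them by regime: the theta-function form for small arguments
(where the alternating form needs many terms) and the alternating form
for large arguments (where it converges in a few terms and evaluates
the *survival* probability directly, avoiding the catastrophic `1 −
CDF` cancellation that limits naive implementations to p ≳ 10⁻¹⁵). The
test suite checks the result against an independent evaluation using
the *opposite* branch in each regime, so agreement is a genuine
cross-representation check.

### Folding

`nussinovFold` maximises the number of Watson–Crick plus G·U wobble
pairs with a minimum hairpin loop of 3 unpaired bases, by dynamic
programming with a deterministic traceback (pairing earlier split
points first), and reports a pseudo-MFE of −1 per pair. This is a
*counting* model: it is not a thermodynamic nearest-neighbour energy
model and its pseudo-MFE is not comparable to RNAfold output. It exists
so structure-dependent code paths are exercisable and testable without
an external folding engine; real analyses should import RNAfold text
output via `readRnafold`.

## 5. The synthetic generator

`simBundle(simConfig(...))` fabricates a complete two-accession study:
transcript FASTA for both accessions, expression tables, protein hit
tables with a taxon map, cross-accession hits, Infernal-style tblout,
RNAfold-style fold output, GFF3 gene models, forward/reverse/self
alignment tables, and a ground-truth table tying every planted
transcript to its class and intended fate.

What it **emulates**:

- Class-dependent composition: coding transcripts at GC ≈ 0.45,
  non-coding at ≈ 0.38, housekeeping-like structured RNAs at ≈ 0.55,
  with log-normal length distributions (coding longer than non-coding).
- The study-scale MFE/nt contrast: planted per-nt MFE drawn from
  N(−0.276, 0.026²) for coding and N(−0.210, 0.041²) for non-coding, so
  statistics computed over the bundle reproduce a large effect (d ≈ 2).
- Evidence boundaries: decoys sit exactly on the wrong side of each
  pipeline threshold (FPKM 1.49, alignment 199 nt, Rfam E = 0.01,
  protein E = 10⁻²⁰, a planted ≥ 120-codon ORF) and keep-side twins sit
  exactly on the right side (FPKM 1.50, 200 nt, Rfam E = 0.011, protein
  E = 2·10⁻²⁰), so inclusive/exclusive boundary behaviour is observable
  end to end.
- Paralog masking: ortholog triads whose decoy paralog outscores the
  true partner in one direction, so the true pair only surfaces in
  anchoring round 2.
- Tandem/proximal/dispersed layouts with known array membership.

What it does **not** emulate: real sequence homology (alignment tables
are fabricated to be consistent, not produced by aligning the
sequences), splice isoforms, genome assembly errors, expression
dispersion across replicates, codon usage, or any phylogenetic signal
in the "organism codes". Conclusions about real data cannot be drawn
from the generator; its purpose is to make every code path testable
against known truth, offline and deterministically (`withr::with_seed`
scoping means generation never disturbs the caller's RNG state, and one
seed yields byte-identical files).

Noncoding sequences are scrubbed so no reading frame reaches the ORF
threshold, which makes end-to-end recovery *exact* by construction —
the pipeline finds precisely the planted non-coding set. That is a
test of plumbing correctness, not a performance estimate.

## 6. Numerical choices

- E-values are written with `sprintf("%.15g")` so write/read round
  trips are exact at double precision; formatting with fewer digits was
  observed to break round-trip identity at the 10⁻⁸ relative level.
- All threshold comparisons are inclusive and performed on the raw
  doubles; no epsilon fudging is applied anywhere.
- Welch's statistic is computed in the summary domain (no squaring of
  large sums), and agreement with `t.test` holds to ~10⁻¹⁴ relative.
- The Kolmogorov survival function's branch switch (section 4) is the
  difference between p-values floored at ~10⁻¹⁵ and p-values valid to
  the smallest representable double.
- The deterministic Nussinov traceback guarantees the same structure
  string for the same input across platforms.

## 7. Open questions and decisions taken

- **Which transcript does consensus emit?** When a supported pair
  differs in length, the longer one is kept, on the argument that the
  longer assembly is more complete; ties go to the query accession.
  Emitting the query always, or both, would be defensible alternatives;
  the choice is recorded in the audit trail.
- **Flag or drop long-ORF transcripts?** They are excluded from the
  final set but reported as `flagged`, preserving the information that
  they passed every evidence filter except coding potential.
- **Gene-class precedence for duplicates** (tandem > proximal >
  dispersed) resolves genes participating in pairs of several kinds;
  the alternative of multi-labelling was rejected to keep per-gene
  summaries additive.
- **chrUkn as its own concordance class** rather than folding it into
  `different_chromosome`: unplaced scaffolds say nothing about synteny.

## 8. Limitations

- Anchoring is greedy and score-ordered; pathological score ties across
  families could be matched suboptimally (the deterministic tie-break
  chain makes the outcome reproducible, not optimal).
- The pipeline's protein filter inherits the database's blind spots:
  a real protein with no homolog at E ≤ 10⁻²⁰ in the search set will
  reach the ORF stage.
- The coding/non-coding statistics describe group differences; they do
  not classify individual transcripts, and d computed from t assumes
  approximately equal group sizes.
- The built-in folding is a base-pair-count model only (section 4).
- The synthetic generator's exactness guarantee (section 5) means green
  end-to-end tests demonstrate correct plumbing and boundary handling,
  not sensitivity or specificity on real transcriptomes.
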