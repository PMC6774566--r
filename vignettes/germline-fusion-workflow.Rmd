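---
title: "Curating fusion-transcript candidates from germline RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating fusion-transcript candidates from germline RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(germfuse)
library(dplyr)
```

## The problem

Fusion callers are trained and tuned on tumor, cell-line or simulated data.
Their post-processing filters assume clonal, highly expressed fusion events
and discard everything else — exactly the wrong behavior for germline
rare-disease samples, where a causative fusion may be mosaic, weakly
expressed in a surrogate tissue (usually blood), or supported by only a
handful of read pairs. germfuse replaces those filters with an
evidence-driven curation workflow: keep everything with minimal biological
support, then remove candidates that a normal-control cohort, the study
cohort itself, or the alignment pattern of the candidate sequence explains
better than a genuine fusion, and finally rank what remains by relevance to
the patient's phenotype.

## The workflow, stage by stage

The pipeline stage order is fixed: **depth → normal database → cohort
recurrence → categorization → phenotype ranking**. Every stage partitions
its input — kept plus removed equals input, and each candidate is removed by
at most one stage — so the per-stage attrition table always accounts for
every raw candidate.

### 1. Inclusive read-support rule

A candidate is kept when it has at least `min_split = 1` split read pair
(one member aligning across the junction) **and** at least
`min_spanning = 1` spanning read pair (members flanking the junction
without crossing it). Both evidence classes are required, but at the lowest
possible level — deliberately more inclusive than typical caller defaults
(3 split, 2 spanning), which `depth_filter(x, 3, 2)` reproduces for
comparison. The filter is total, idempotent and monotone in its thresholds.

### 2. Normal-control database

`build_normal_db()` ingests fusion candidates called on unaffected control
samples. An event enters the database only when a single control specimen
reports it with at least `min_reads = 2` supporting reads (split +
spanning): most control-tissue fusion calls carry exactly one supporting
read and are treated as insufficient evidence that the event is a genuine,
recurrent feature of normal tissue. The per-specimen rule is the default
because pooling single-read noise across hundreds of controls would promote
artifacts into the database; `pooled = TRUE` exposes the alternative
reading. Candidates whose canonical breakpoint-pair key
(`fusion_key()` — lexicographic-then-numeric canonical order, so a
reciprocal orientation of the same coordinates shares a key) matches a
database key are removed; `fuzz_bp` widens the match to a symmetric window
on both positions for callers with imprecise breakpoints.

### 3. Cohort recurrence

Patients in a rare-disease cohort are unrelated and expected to carry
distinct disorders, so a breakpoint key observed in two or more patients is
removed from **all** of them — not only later-seen ones, since there is no
privileged patient ordering.

### 4. Alignment-pattern categorization

Three queries are built per candidate (`build_queries()`): the full fusion
contig and the decoupled 5′ and 3′ segments. These are aligned (word size
7, e-value 1, suitable for short queries) to both the genome and the
transcriptome; precomputed 12-column tabular alignment records are the
first-class input so the external aligner is optional. Hits under 90%
identity or 75% query coverage are discarded — the strict reading
(keep-iff-both) is used because keeping 50%-coverage perfect matches would
hollow out the "unbroken alignment" categories below. Top bitscores are
selected per query and database; ties are kept and flagged ambiguous.

The decision tree then assigns exactly one category, in fixed precedence
order (exclusions and single-sequence explanations before fusion calls):

| branch | category | trigger |
|---|---|---|
| A | `EXCLUDED_ABUNDANT` | any involved gene matches the abundant-blood list |
| B | `KNOWN_TRANSCRIPT` | full contig aligns unbroken to one transcript |
| C | `GENOMIC_SEQUENCE` | full contig aligns unbroken to the genome |
| D | `LIKELY_ARTIFACT` | no surviving alignment, or only one segment aligns |
| E | `NOVEL_TRANSCRIPT_SINGLE_GENE` | both segments fall within one gene |
| F | `IMMUNE_DIVERSITY` | two separate immunoglobulin genes |
| G | `INTERCHROMOSOMAL_FUSION` | segment hits on different chromosomes |
| H | `INTRACHROMOSOMAL_FUSION` | two distinct genes/regions, one chromosome |

"Unbroken" means a single maximal alignment block covering at least
`unbroken_coverage` (default 0.75, reusing the coverage gate) of the full
query — the tree gives no numeric definition, so the threshold is exposed.
Branch D subsumes partial alignment: because full-query hits below the 75%
coverage gate never survive filtering, "only a part alignment was possible"
reduces to "fewer than two segments with a surviving hit". Segment hits in
gene-less (intergenic) regions of one chromosome still classify as
intrachromosomal — two distinct regions of a single chromosome are a
reportable rearrangement even without annotated genes. The abundant-gene
test is applied to segment-level gene assignments (not to every gene any
stray hit touches); the shipped lists are editable files of globin symbols
and `TRA*/TRB*/TRG*/TRD*` and `IGH*/IGK*/IGL*` patterns — glob prefixes are
convenient but deliberately broad (e.g. `TRA*` also matches `TRAF` genes),
so studies with such symbols in play should replace the prefix patterns
with explicit locus lists.

Intrachromosomal calls between neighboring genes (no third gene's span
entirely inside the gap between them; strand-agnostic) are flagged
`read_through`; a stricter `read_through_strict` additionally requires the
same strand and transcriptional collinearity. Fusion calls between listed
homologs are flagged `homologous`; a gene is its own homolog by convention,
so duplicate-locus artifacts are flagged rather than silently passed.

### Breakpoint annotation and reading frame

`locate_breakpoint()` asks whether a breakpoint sits on the
**junction-facing** exon edge: the transcriptional 3′ edge of an exon for
the 5′ partner, the 5′ edge for the 3′ partner, in transcription
orientation on either strand. When several transcripts overlap, a
transcript where the position is such an edge is preferred, then the
longest CDS, then the lexicographically smallest identifier — worked
candidate tables report a single transcript per partner without stating a
rule, so a deterministic one is fixed here. `cds_offset` counts coding
nucleotides transcriptionally upstream of the junction (inclusive of the
breakpoint base on the 5′ side, exclusive on the 3′ side); a fusion is
`in_frame` when both offsets are defined, both breakpoints are at exon
boundaries, and the offsets agree modulo 3 — i.e. the downstream partner's
native codon phase is preserved. UTR-only or non-boundary junctions are
`not_applicable` rather than guessed. The test-suite checks every planted
coding fusion against a brute-force oracle that concatenates the CDS
fragments, translates them, and compares the downstream peptide with the
native one.

### 5. Phenotype rank-scores

Fusion-call candidates are ranked by patient relevance. The default scorer
is deliberately simple: annotations are propagated up the phenotype
ontology, the information content of a term is `-log` of the fraction of
scored genes annotated to it, and a gene's similarity to the patient is
the mean (over patient terms) of the best information content of a shared
ancestor with any gene term. The scorer is pluggable (`scorer =` argument)
precisely because production deployments may call an external semantic
similarity tool; what the package owns is the **rank-score contract**:
genes sorted by descending score, ties at the minimum rank of the block,
rank-score = rank / number of scored genes, so 0.01 means top 1% of the
scored disease-gene set. Rank-scores are invariant under any monotone
transform of the raw scores, which is what makes the simple default scorer
an adequate stand-in. Pathway- and interaction-network p-values from
external databases are out of scope; the report keeps a free-text evidence
column instead. The default shortlist cutoff of 0.05 is configurable — the
original analysis used manual review rather than a numeric cutoff, and 0.05
("top 5% of disease genes") is a conservative screen that keeps manual
review tractable without hiding the rest of the report.

## What the synthetic cohort emulates

`simulate_cohort()` is first-class, tested code. It builds a seeded
two-chromosome genome (100 kb + 60 kb, 20 genes — large enough for
neighbor/intergenic geometry, small enough for sub-second tests) whose
inventory covers every branch of the tree: a globin-like gene and a T-cell
receptor family gene (abundant list), two immunoglobulin genes, a
duplicated locus pair with verbatim-identical sequence, adjacent
same-strand genes, and coding genes with 600-nt multi-exon CDS on both
strands. Four patients carry, between them, one candidate of every
category; in-frame (offsets 400/400) and out-of-frame (400/200) coding
fusions are planted at exon edges with known coding offsets. Per patient,
three under-supported candidates exercise the depth rule
((0,4), (5,0), (0,0) — both read classes required); a candidate shared with
control 1 at 3 supporting reads exercises the database rule; a key shared
by patients 1 and 2 exercises cohort recurrence; and the read-through event
is shared with control 2 at a single read, which must *survive* the
database. Control samples otherwise carry mostly single-read private
events (80%), mirroring the support histogram seen in normal-tissue fusion
calls. Alignment records are synthesized directly at the table level with
identities/coverages that respect or violate the 90/75 gates per truth, so
no aligner binary is needed; one integration test exercises the real
aligner wrapper separately.

What the fixture does **not** emulate: sequencing reads (candidates are
planted at the table level the pipeline actually consumes), alignment
ambiguity from genome-wide repeats, imprecise breakpoints, population-scale
control databases, or realistic candidate volumes (a real sample yields
tens of thousands of raw candidates; the fixture plants 7–8). Passing the
planted-truth checks therefore demonstrates that the decision logic,
bookkeeping and annotations are correct — not that the thresholds are
optimal for any particular real dataset.

## Numerical and degenerate-input choices

* Coordinates are 1-based and both-inclusive everywhere; every writer
  records this in its header.
* Strand vocabulary is normalized to `forward`/`reverse` on ingest from
  `+/-/f/r` and paired `ff/fr/rf/rr` tokens.
* Malformed candidate rows are collected and reported, never silently
  dropped; parsing aborts only past 50% malformed rows.
* Score ties in top-hit selection are all retained and flagged; transcript
  choice ties break lexicographically; rank-score ties take the minimum
  rank.
* Medians of per-sample category counts use the lower median (an order
  statistic, so the reported value is always an observed count) with
  type-1 quartiles.
* Empty inputs (header-only files, candidates without sequences, empty
  term sets) flow through as empty results or `not_applicable`/unalignable
  flags rather than errors.

## Problem sizes used by the checks

The shipped test-suite and the acceptance script run the full pipeline on
the default synthetic cohort (4 patients, 3 controls, 30 candidates, 25
alignment records), property-style checks on seeded random candidate sets
(tens of sets of 30–40 candidates), and desk-scale worked examples
(breakpoint separations, rank-score of 100 genes). These sizes were chosen
so the complete suite runs in well under a minute while still exercising
every branch and invariant.

## Known limitations

* The categorization is only as good as the supplied alignments and gene
  models; a missing transcript annotation turns a known transcript into a
  novel-transcript or fusion call.
* Homolog flagging depends entirely on the supplied pair list.
* The default similarity scorer ignores term specificity beyond
  information content and has no notion of pathway neighborhoods.
* Cohort recurrence assumes unrelated patients; related individuals should
  share a `sample_id` or skip that stage.
* Raw-caller column layouts vary; the `tophat_raw` dialect default should
  be validated (and remapped via `column_map`) against the archive at hand.
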