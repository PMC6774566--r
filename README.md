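# germfuse

Curation of gene-fusion transcript candidates from **germline** RNA-seq,
for rare-disease diagnostics. Fusion callers tuned on tumor and cell-line
data discard candidates that matter in germline samples (mosaic events,
weak expression in surrogate tissue such as blood). germfuse keeps every
candidate supported by at least one split **and** one spanning read pair
and removes noise by evidence instead:

1. **depth** — inclusive read-support rule (`split ≥ 1 AND spanning ≥ 1`;
   caller defaults correspond to 3/2);
2. **normal database** — drop events a normal-control specimen reports
   with ≥ 2 supporting reads (single-read control events are insufficient
   evidence);
3. **cohort recurrence** — drop events shared by ≥ 2 unrelated patients;
4. **categorization** — align the fusion contig and its decoupled 5′/3′
   segments to genome and transcriptome (word size 7, e-value 1; keep hits
   with ≥ 90% identity and ≥ 75% query coverage) and assign exactly one of
   eight categories (abundant-gene exclusion, known transcript, genomic
   sequence, likely artifact, single-gene novel transcript, immunoglobulin
   diversity, inter-/intrachromosomal fusion), with read-through and
   homolog flags, exon-boundary and reading-frame annotation
   (in-frame ⇔ coding offsets congruent mod 3) and genomic separation;
5. **phenotype ranking** — rank fusion calls by a **rank-score** =
   rank / number of scored disease genes (0.01 = top 1%), ties at minimum
   rank, pluggable similarity scorer.

A deterministic synthetic-fixture generator (`simulate_cohort()`) builds a
toy genome/annotation, planted candidates of every category with truth
labels, alignment records and a control cohort, so the entire pipeline is
testable offline.

## Worked example

```r
library(germfuse)

sim <- simulate_cohort(sim_config(seed = 42))        # toy cohort, 4 patients
db  <- build_normal_db(sim$controls, min_reads = 2)  # panel of normals
res <- run_pipeline(sim$patients, sim$hits, sim$ref$index, normal_db = db,
                    abundant = sim$abundant,
                    immunoglobulin = sim$immunoglobulin,
                    homologs = sim$homologs,
                    patient_terms = sim$patient_terms,
                    gene_terms = sim$gene_terms, ontology = sim$ontology)

subset(res$attrition, sample_id == "P3")
#> # A tibble: 5 × 5
#>   sample_id stage           n_in n_out n_removed
#> 1 P3        depth              7     4         3
#> 2 P3        normal_db          4     3         1
#> 3 P3        cohort             3     3         0
#> 4 P3        categorization     3     3         0
#> 5 P3        phenotype          3     3         0

res$fusion_calls[res$fusion_calls$sample_id == "P3",
                 c("candidate_id", "category", "frame", "read_through")]
#> # A tibble: 3 × 4
#>   candidate_id category                frame        read_through
#> 1 P3_INTER_OOF INTERCHROMOSOMAL_FUSION out_of_frame FALSE
#> 2 P3_INTRA_IF  INTRACHROMOSOMAL_FUSION in_frame     FALSE
#> 3 P3_INTRA_RT  INTRACHROMOSOMAL_FUSION not_applicable TRUE

res$shortlist[, c("candidate_id", "best_gene", "rank_score")]
#> # A tibble: 2 × 3
#>   candidate_id best_gene rank_score
#> 1 P3_INTRA_IF  CODD            0.05
#> 2 P4_INTRA_HOM PARA2           0.05
```

Patient P3 enters with 7 raw candidates; the read-support rule removes 3,
the normal database removes the event its control shares at 3 supporting
reads, and all 3 survivors are genuine fusion calls — including an
in-frame intrachromosomal fusion whose partner gene (`CODD`) matches the
patient's phenotype terms and is shortlisted at rank-score 0.05, and a
read-through-flagged call between adjacent genes. Single desk
computations work standalone, e.g.
`genomic_separation("chr8", 119592952, "chr8", 118849438)` → `743514`.

A command-line wrapper mirrors the package surface:

```sh
exec/germfuse simulate --seed 17 --out simdir
exec/germfuse normdb build --controls simdir/control_N*.tsv --min-reads 2 --out normdb.tsv
exec/germfuse run --candidates simdir/candidates_P*.tsv --gtf simdir/annotation.gtf \
    --genome-aln simdir/hits_genome.tsv --tx-aln simdir/hits_transcriptome.tsv \
    --normdb normdb.tsv --homologs simdir/homologs.tsv --out rundir
```

## Package layout

* `R/` — candidate I/O and data model, gene-model index (GTF), the three
  evidence filters, alignment gates/summaries, the categorization tree and
  pipeline, phenotype rank-scoring, the synthetic-fixture generator.
* `tests/testthat/` — unit, property-style and end-to-end planted-truth
  tests (oracles: linear scans, brute-force gates, translation of fused
  CDS, stable-sort ranking).
* `vignettes/germline-fusion-workflow.Rmd` — the methods vignette: model,
  assumptions, parameter defaults and design choices.
* `exec/germfuse` — thin CLI over the exported functions.
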