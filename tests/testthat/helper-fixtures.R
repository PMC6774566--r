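# Shared fixtures: one simulated cohort per test run (memoized), a small
# hand-written GTF independent of the simulator, and tibble builders.

.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (is.null(.fixture_env$sim)) {
    .fixture_env$sim <- simulate_cohort(sim_config(42))
  }
  .fixture_env$sim
}

pipeline_fixture <- function() {
  if (is.null(.fixture_env$pipe)) {
    sim <- sim_fixture()
    db <- build_normal_db(sim$controls, min_reads = 2)
    .fixture_env$pipe <- run_pipeline(
      sim$patients, sim$hits, sim$ref$index, normal_db = db,
      abundant = sim$abundant, immunoglobulin = sim$immunoglobulin,
      homologs = sim$homologs, patient_terms = sim$patient_terms,
      gene_terms = sim$gene_terms, ontology = sim$ontology)
  }
  .fixture_env$pipe
}

# two-gene toy GTF: GA (+, 2 exons, full-exon CDS), GB (-, 2 exons), written
# by hand so annotation tests do not depend on the simulator
write_toy_gtf <- function(path = tempfile(fileext = ".gtf")) {
  at <- function(g, t) sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                               paste0("g_", g), g, t)
  lines <- c(
    sprintf("chrT\ttoy\tgene\t100\t550\t.\t+\t.\t%s", at("GA", "tA")),
    sprintf("chrT\ttoy\ttranscript\t100\t550\t.\t+\t.\t%s", at("GA", "tA")),
    sprintf("chrT\ttoy\texon\t100\t250\t.\t+\t.\t%s", at("GA", "tA")),
    sprintf("chrT\ttoy\texon\t400\t550\t.\t+\t.\t%s", at("GA", "tA")),
    sprintf("chrT\ttoy\tCDS\t100\t250\t.\t+\t0\t%s", at("GA", "tA")),
    sprintf("chrT\ttoy\tCDS\t400\t550\t.\t+\t0\t%s", at("GA", "tA")),
    sprintf("chrT\ttoy\tgene\t1000\t1450\t.\t-\t.\t%s", at("GB", "tB")),
    sprintf("chrT\ttoy\ttranscript\t1000\t1450\t.\t-\t.\t%s", at("GB", "tB")),
    sprintf("chrT\ttoy\texon\t1000\t1150\t.\t-\t.\t%s", at("GB", "tB")),
    sprintf("chrT\ttoy\texon\t1300\t1450\t.\t-\t.\t%s", at("GB", "tB")))
  writeLines(lines, path)
  path
}

# quick candidate tibble with defaults for unused fields
make_candidates <- function(n, sample_id = "S1", split = 5L, spanning = 5L,
                            chrom5 = "chr1", chrom3 = "chr1",
                            pos5 = NULL, pos3 = NULL) {
  if (is.null(pos5)) pos5 <- seq_len(n) * 100L
  if (is.null(pos3)) pos3 <- seq_len(n) * 100L + 50L
  as_candidate_set(tibble::tibble(
    candidate_id = sprintf("%s_c%03d", sample_id, seq_len(n)),
    sample_id = sample_id,
    chrom5 = chrom5, pos5 = pos5, strand5 = "forward",
    chrom3 = chrom3, pos3 = pos3, strand3 = "forward",
    split_reads = rep_len(split, n), spanning_reads = rep_len(spanning, n)))
}

# seeded random candidate sets for property-style checks
random_candidates <- function(n, sample_id = "R1") {
  as_candidate_set(tibble::tibble(
    candidate_id = sprintf("%s_r%03d", sample_id, seq_len(n)),
    sample_id = sample_id,
    chrom5 = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos5 = sample(1e5L, n, replace = TRUE),
    strand5 = sample(c("forward", "reverse"), n, replace = TRUE),
    chrom3 = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos3 = sample(1e5L, n, replace = TRUE),
    strand3 = sample(c("forward", "reverse"), n, replace = TRUE),
    split_reads = sample(0:6, n, replace = TRUE),
    spanning_reads = sample(0:6, n, replace = TRUE)))
}

# alignment-summary row builder for direct decision-tree unit tests
make_summary <- function(candidate_id, genes5 = character(0),
                         genes3 = character(0),
                         chrom5_hit = NA_character_,
                         chrom3_hit = NA_character_,
                         any_alignment = TRUE,
                         full_unbroken_tx = FALSE,
                         full_unbroken_genome = FALSE,
                         seg5_aligned = length(genes5) > 0 | !is.na(chrom5_hit),
                         seg3_aligned = length(genes3) > 0 | !is.na(chrom3_hit),
                         ambiguous = FALSE) {
  tibble::tibble(candidate_id = candidate_id,
                 any_alignment = any_alignment,
                 full_unbroken_tx = full_unbroken_tx,
                 full_unbroken_genome = full_unbroken_genome,
                 seg5_aligned = seg5_aligned, seg3_aligned = seg3_aligned,
                 genes5 = list(genes5), genes3 = list(genes3),
                 chrom5_hit = chrom5_hit, chrom3_hit = chrom3_hit,
                 ambiguous = ambiguous)
}

# brute-force translation oracle: build the fused coding sequence from the
# native CDS strings and compare the downstream peptide (past the codon
# straddling the junction) with the native downstream peptide of the 3' gene
translation_frame_oracle <- function(cds5, cds3, offset5, offset3) {
  fused <- paste0(substr(cds5, 1, offset5),
                  substr(cds3, offset3 + 1, nchar(cds3)))
  trim <- function(s) substr(s, 1, 3 * (nchar(s) %/% 3))
  pep <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(trim(s)), no.init.codon = TRUE))
  fused_pep <- pep(fused)
  native_pep <- pep(cds3)
  skip_fused <- ceiling(offset5 / 3) + 1      # first fully-downstream codon
  skip_native <- ceiling(offset3 / 3) + 1
  down_fused <- substr(fused_pep, skip_fused + 1, nchar(fused_pep))
  down_native <- substr(native_pep, skip_native + 1, nchar(native_pep))
  n <- min(nchar(down_fused), nchar(down_native))
  if (n <= 0) return(NA)
  identical(substr(down_fused, 1, n), substr(down_native, 1, n))
}
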