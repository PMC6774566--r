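test_that("decision-tree branches classify directly-constructed summaries", {
  sim <- sim_fixture()
  idx <- sim$ref$index
  ab <- sim$abundant; ig <- sim$immunoglobulin
  cs <- make_candidates(8, sample_id = "U", pos5 = 1000L + 1:8,
                        pos3 = 2000L + 1:8)
  cls <- function(summary_row) {
    categorize_candidates(cs[match(summary_row$candidate_id,
                                   cs$candidate_id), ],
                          summary_row, idx, ab, ig, sim$homologs)$category
  }
  id <- cs$candidate_id
  # abundant-gene involvement trumps even a perfect transcript match
  expect_equal(cls(make_summary(id[1], genes5 = "HBB", genes3 = "GENX",
                                chrom5_hit = "chr1", chrom3_hit = "chr1",
                                full_unbroken_tx = TRUE)),
               "EXCLUDED_ABUNDANT")
  expect_equal(cls(make_summary(id[2], genes5 = "CODA", genes3 = "CODA",
                                chrom5_hit = "chr1", chrom3_hit = "chr1",
                                full_unbroken_tx = TRUE)),
               "KNOWN_TRANSCRIPT")
  expect_equal(cls(make_summary(id[3], chrom5_hit = "chr1",
                                chrom3_hit = "chr1",
                                full_unbroken_genome = TRUE)),
               "GENOMIC_SEQUENCE")
  expect_equal(cls(make_summary(id[4], any_alignment = FALSE,
                                seg5_aligned = FALSE, seg3_aligned = FALSE)),
               "LIKELY_ARTIFACT")
  # only one segment aligns: a part alignment is still an artifact
  expect_equal(cls(make_summary(id[5], genes5 = "CODA", chrom5_hit = "chr1",
                                seg3_aligned = FALSE)),
               "LIKELY_ARTIFACT")
  expect_equal(cls(make_summary(id[6], genes5 = "NOVG", genes3 = "NOVG",
                                chrom5_hit = "chr1", chrom3_hit = "chr1")),
               "NOVEL_TRANSCRIPT_SINGLE_GENE")
  # two separate immunoglobulins precede the interchromosomal call
  expect_equal(cls(make_summary(id[7], genes5 = "IGHV1", genes3 = "IGKV1",
                                chrom5_hit = "chr1", chrom3_hit = "chr2")),
               "IMMUNE_DIVERSITY")
  expect_equal(cls(make_summary(id[8], genes5 = "CODA", genes3 = "CODC",
                                chrom5_hit = "chr1", chrom3_hit = "chr2")),
               "INTERCHROMOSOMAL_FUSION")
})

test_that("gene-less same-chromosome segment hits are an intrachromosomal call", {
  sim <- sim_fixture()
  cs <- make_candidates(1, sample_id = "U", pos5 = 50000L, pos3 = 52000L)
  out <- categorize_candidates(
    cs, make_summary(cs$candidate_id, chrom5_hit = "chr1",
                     chrom3_hit = "chr1"),
    sim$ref$index, sim$abundant, sim$immunoglobulin, sim$homologs)
  expect_equal(out$category, "INTRACHROMOSOMAL_FUSION")
  expect_true(is.na(out$gene5))
})

test_that("a candidate without an alignment summary is a named error", {
  sim <- sim_fixture()
  cs <- make_candidates(1, sample_id = "U")
  expect_error(
    categorize_candidates(cs, make_summary("other_id"), sim$ref$index,
                          sim$abundant, sim$immunoglobulin, sim$homologs),
    cs$candidate_id)
})

test_that("flag constraints hold on the simulated cohort", {
  pipe <- pipeline_fixture()
  cat <- pipe$categorized
  expect_true(all(cat$category[cat$read_through] ==
                    "INTRACHROMOSOMAL_FUSION"))
  expect_true(all(cat$category[cat$homologous] %in% fusion_call_categories()))
  expect_true(all(cat$category %in% fusion_categories()))
  expect_equal(anyDuplicated(cat$candidate_id), 0)   # exactly one category
})

test_that("pipeline reruns are deterministic", {
  sim <- sim_fixture()
  db <- build_normal_db(sim$controls)
  run <- function() run_pipeline(sim$patients, sim$hits, sim$ref$index,
                                 normal_db = db, abundant = sim$abundant,
                                 immunoglobulin = sim$immunoglobulin,
                                 homologs = sim$homologs)
  r1 <- run(); r2 <- run()
  expect_identical(r1$report, r2$report)
  expect_identical(r1$attrition, r2$attrition)
})

test_that("category counts use the lower median and type-1 quartiles", {
  mk <- function(sample, n) tibble::tibble(
    sample_id = sample, category = rep("INTRACHROMOSOMAL_FUSION", n))
  cc <- category_counts(dplyr::bind_rows(mk("a", 3), mk("b", 5), mk("c", 7)))
  got <- cc$summary[cc$summary$category == "INTRACHROMOSOMAL_FUSION", ]
  expect_equal(got$median, 5)
  single <- category_counts(mk("a", 4))
  expect_equal(
    single$summary$median[single$summary$category ==
                            "INTRACHROMOSOMAL_FUSION"], 4)
  # even sample count: lower of the two central order statistics
  even <- category_counts(dplyr::bind_rows(mk("a", 1), mk("b", 2),
                                           mk("c", 3), mk("d", 4)))
  vals <- c(1, 2, 3, 4)
  oracle <- sort(vals)[ceiling(length(vals) / 2)]
  expect_equal(
    even$summary$median[even$summary$category ==
                          "INTRACHROMOSOMAL_FUSION"], oracle)
  # absent categories are zero-filled, not dropped
  expect_true(all(fusion_categories() %in% cc$summary$category))
})
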