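test_that("query construction concatenates, slices and flags degenerate input", {
  cs <- make_candidates(1)
  cs$seq5 <- strrep("A", 60); cs$seq3 <- strrep("C", 40)
  cs$seq_full <- paste0(cs$seq5, cs$seq3)
  q <- build_queries(cs)
  expect_false(q$unalignable)
  expect_named(q$records, paste0(cs$candidate_id, "|", c("full", "seg5", "seg3")))
  expect_equal(nchar(q$records[[1]]), 100)
  # only the full contig plus a known junction: segments sliced from it
  cs2 <- make_candidates(1)
  cs2$seq_full <- paste0(strrep("G", 50), strrep("T", 30))
  q2 <- build_queries(cs2, junction = 50)
  expect_equal(unname(q2$records[paste0(cs2$candidate_id, "|seg5")]),
               strrep("G", 50))
  # no sequence at all
  q3 <- build_queries(make_candidates(1))
  expect_true(q3$unalignable)
})

test_that("identity/coverage gate keeps exactly the compliant hits", {
  qlen <- c("c1|full" = 100L)
  hit <- function(pident, qstart, qend) {
    tibble::tibble(qseqid = "c1|full", sseqid = "chr1", pident = pident,
                   length = qend - qstart + 1L, mismatch = 0L, gapopen = 0L,
                   qstart = qstart, qend = qend, sstart = 1L,
                   send = qend - qstart + 1L, evalue = 1e-5,
                   bitscore = 50, subject_db = "genome")
  }
  hits <- dplyr::bind_rows(hit(95, 1, 80),    # 95% id, 80% cov -> kept
                           hit(89, 1, 99),    # identity below 90 -> removed
                           hit(100, 1, 50))   # coverage below 75 -> removed
  out <- filter_hits(hits, align_config(), qlen)
  expect_equal(out$pident, 95)
  expect_equal(out$coverage, 0.8)
  # pure filter: applying twice equals applying once
  expect_equal(filter_hits(out, align_config(), qlen), out)
  expect_error(filter_hits(dplyr::mutate(hits, qseqid = "who|full"),
                           align_config(), qlen), "unknown query")
})

test_that("the gate agrees with a brute-force oracle on random hits", {
  set.seed(17)
  qlen <- stats::setNames(sample(50:200, 20), paste0("q", 1:20, "|full"))
  hits <- tibble::tibble(
    qseqid = sample(names(qlen), 200, replace = TRUE),
    sseqid = "chr1", pident = round(stats::runif(200, 80, 100), 1),
    mismatch = 0L, gapopen = 0L,
    qstart = sample(1:50, 200, replace = TRUE))
  hits$qend <- pmin(hits$qstart + sample(20:200, 200, replace = TRUE),
                    unname(qlen[hits$qseqid]))
  hits$length <- hits$qend - hits$qstart + 1L
  hits$sstart <- 1L; hits$send <- hits$length
  hits$evalue <- 1e-5; hits$bitscore <- 2 * hits$length
  hits$subject_db <- "genome"
  out <- filter_hits(hits, align_config(), qlen)
  keep_oracle <- vapply(seq_len(nrow(hits)), function(i) {
    cov <- (hits$qend[i] - hits$qstart[i] + 1) / qlen[[hits$qseqid[i]]]
    hits$pident[i] >= 90 && cov >= 0.75
  }, logical(1))
  expect_equal(out$qseqid, hits$qseqid[keep_oracle])
  expect_equal(out$qstart, hits$qstart[keep_oracle])
})

test_that("top-hit selection takes the argmax and flags score ties", {
  base <- tibble::tibble(
    qseqid = "c1|seg5", sseqid = c("t1", "t2", "t3"),
    pident = 100, length = 50L, mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = 50L, sstart = 1L, send = 50L, evalue = 1e-5,
    bitscore = c(100, 80, 60), subject_db = "transcriptome")
  top <- select_top_hits(base)
  expect_equal(nrow(top), 1)
  expect_equal(top$sseqid, "t1")
  expect_false(top$ambiguous)
  tie <- base; tie$bitscore <- c(100, 100, 60)
  top2 <- select_top_hits(tie)
  expect_setequal(top2$sseqid, c("t1", "t2"))
  expect_true(all(top2$ambiguous))
  expect_equal(nrow(select_top_hits(base[0, ])), 0)
})

test_that("alignment summaries resolve unbroken flags, genes and chromosomes", {
  sim <- sim_fixture()
  idx <- sim$ref$index
  cs <- make_candidates(2, sample_id = "S")
  cs$seq5 <- strrep("A", 60); cs$seq3 <- strrep("C", 60)
  cs$seq_full <- paste0(cs$seq5, cs$seq3)
  id1 <- cs$candidate_id[1]; id2 <- cs$candidate_id[2]
  hits <- tibble::tibble(
    qseqid = c(paste0(id1, "|full"), paste0(id2, "|seg5"),
               paste0(id2, "|seg3")),
    sseqid = c("T_CODA", "chr1", "chr2"),
    pident = 100, length = c(120L, 60L, 60L), mismatch = 0L, gapopen = 0L,
    qstart = 1L, qend = c(120L, 60L, 60L),
    sstart = c(1L, 10050L, 15550L), send = c(120L, 10109L, 15609L),
    evalue = 1e-9, bitscore = 200,
    subject_db = c("transcriptome", "genome", "genome"))
  gated <- filter_hits(hits, align_config(), candidate_query_lengths(cs))
  summ <- summarize_alignments(cs, select_top_hits(gated), idx)
  s1 <- summ[summ$candidate_id == id1, ]
  expect_true(s1$full_unbroken_tx)
  expect_false(s1$full_unbroken_genome)
  s2 <- summ[summ$candidate_id == id2, ]
  expect_equal(s2$genes5[[1]], "CODA")
  expect_equal(s2$genes3[[1]], "CODC")
  expect_equal(c(s2$chrom5_hit, s2$chrom3_hit), c("chr1", "chr2"))
  # a candidate with no hits at all
  none <- summarize_alignments(cs[1, ], select_top_hits(gated[0, ]), idx)
  expect_false(none$any_alignment)
})

test_that("the external aligner wrapper reproduces exact and reverse-complement matches", {
  sim <- sim_fixture()
  q5 <- as.character(Biostrings::subseq(sim$ref$genome[["chr1"]],
                                        10101, 10160))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::subseq(sim$ref$genome[["chr1"]], 10201, 10260)))
  qfa <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(c(exact = q5, revc = rc)), qfa)
  out <- run_external_aligner(qfa, sim$ref$genome_fa, align_config())
  hits <- read_alignment_hits(out, "genome")
  ex <- hits[hits$qseqid == "exact", ][1, ]
  expect_equal(ex$pident, 100)
  expect_equal(c(ex$sstart, ex$send), c(10101L, 10160L))
  rv <- hits[hits$qseqid == "revc", ][1, ]
  expect_true(rv$sstart > rv$send)         # reverse orientation signalled
  # empty query file -> empty hit table
  empty_fa <- tempfile(fileext = ".fa")
  writeLines(character(0), empty_fa)
  out2 <- run_external_aligner(empty_fa, sim$ref$genome_fa, align_config())
  expect_equal(nrow(read_alignment_hits(out2, "genome")), 0)
})
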