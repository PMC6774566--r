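test_that("breakpoints at junction-facing exon edges are recognized on both strands", {
  idx <- read_gene_models(write_toy_gtf())
  # forward gene GA, exon 1 = [100,250]: its 3' edge faces a 5'-side junction
  a <- locate_breakpoint("chrT", 250, "five_prime", idx)
  expect_true(a$at_exon_boundary)
  expect_equal(a$exon_index, 1L)
  expect_equal(a$gene, "GA")
  # the same position is not a junction-facing edge for the 3' partner
  b <- locate_breakpoint("chrT", 250, "three_prime", idx)
  expect_false(b$at_exon_boundary)
  # minus-strand gene GB: transcription starts at the rightmost exon, so the
  # 5'-facing junction edge of exon 1 is the genomic start of [1300,1450]
  c1 <- locate_breakpoint("chrT", 1300, "five_prime", idx)
  expect_true(c1$at_exon_boundary)
  expect_equal(c1$exon_index, 1L)
  # mid-intron and intergenic positions
  expect_false(locate_breakpoint("chrT", 300, "five_prime", idx)$at_exon_boundary)
  expect_true(is.na(locate_breakpoint("chrT", 300, "five_prime", idx)$exon_index))
  expect_true(is.na(locate_breakpoint("chrT", 700, "five_prime", idx)$gene))
  expect_warning(z <- locate_breakpoint("chrQ", 1, "five_prime", idx),
                 "absent")
  expect_true(is.na(z$gene))
})

test_that("every junction-facing exon edge is detected (exhaustive edge scan)", {
  sim <- sim_fixture()
  idx <- sim$ref$index
  exons <- idx$exons
  for (i in seq_len(nrow(exons))) {
    e <- exons[i, ]
    edge5 <- if (e$strand == "-") e$start else e$end    # faces 5' junction
    edge3 <- if (e$strand == "-") e$end else e$start    # faces 3' junction
    a5 <- locate_breakpoint(e$chrom, edge5, "five_prime", idx)
    a3 <- locate_breakpoint(e$chrom, edge3, "three_prime", idx)
    expect_true(a5$at_exon_boundary, info = sprintf("row %d 5'", i))
    expect_true(a3$at_exon_boundary, info = sprintf("row %d 3'", i))
    # one base inside the exon is not an edge for either side (exon len 200)
    mid <- e$start + 100L
    expect_false(locate_breakpoint(e$chrom, mid, "five_prime",
                                   idx)$at_exon_boundary)
  }
})

test_that("frame calls follow the coding-offset congruence rule", {
  mk <- function(offset, boundary = TRUE) {
    tibble::tibble(gene = "G", transcript = "T", exon_index = 1L,
                   at_exon_boundary = boundary, cds_offset = offset,
                   strand = "+")
  }
  expect_equal(frame_status(mk(0L), mk(0L)), "in_frame")
  expect_equal(frame_status(mk(100L), mk(1L)), "in_frame")     # 100 = 1 mod 3
  expect_equal(frame_status(mk(100L), mk(0L)), "out_of_frame")
  expect_equal(frame_status(mk(NA_integer_), mk(0L)), "not_applicable")
  expect_equal(frame_status(mk(3L, boundary = FALSE), mk(0L)),
               "not_applicable")
})

test_that("frame calls agree with the translation oracle on planted coding fusions", {
  sim <- sim_fixture()
  idx <- sim$ref$index
  coding <- sim$truth[!is.na(sim$truth$true_frame), ]
  expect_gt(nrow(coding), 0)
  cands <- dplyr::bind_rows(sim$patients)
  for (i in seq_len(nrow(coding))) {
    cand <- cands[cands$candidate_id == coding$candidate_id[i], ]
    ann5 <- locate_breakpoint(cand$chrom5, cand$pos5, "five_prime", idx)
    ann3 <- locate_breakpoint(cand$chrom3, cand$pos3, "three_prime", idx)
    call <- frame_status(ann5, ann3)
    expect_equal(call, coding$true_frame[i])
    oracle <- translation_frame_oracle(
      sim$ref$cds_seqs[[ann5$gene]], sim$ref$cds_seqs[[ann3$gene]],
      ann5$cds_offset, ann3$cds_offset)
    expect_equal(call == "in_frame", oracle,
                 info = coding$candidate_id[i])
  }
})

test_that("genomic separation is symmetric, non-negative and NA across chromosomes", {
  expect_equal(genomic_separation("chr10", 101554225, "chr10", 101515382),
               38843)
  expect_true(is.na(genomic_separation("chr21", 34927578, "chr1", 157670375)))
  set.seed(5)
  for (i in 1:20) {
    p <- sample(1e6L, 2)
    expect_equal(genomic_separation("c", p[1], "c", p[2]),
                 genomic_separation("c", p[2], "c", p[1]))
    expect_gte(genomic_separation("c", p[1], "c", p[2]), 0)
  }
  expect_equal(genomic_separation("c", 7L, "c", 7L), 0)
})

test_that("gene adjacency matches an exhaustive span scan of the toy genome", {
  sim <- sim_fixture()
  idx <- sim$ref$index
  genes <- idx$genes
  # oracle: no third gene's span entirely inside the gap between the two
  oracle <- function(a, b) {
    ga <- genes[genes$symbol == a, ]; gb <- genes[genes$symbol == b, ]
    if (ga$chrom != gb$chrom) return(FALSE)
    lo <- min(ga$end, gb$end) + 1; hi <- max(ga$start, gb$start) - 1
    if (lo > hi) return(TRUE)
    !any(genes$chrom == ga$chrom & !(genes$symbol %in% c(a, b)) &
           genes$start >= lo & genes$end <= hi)
  }
  chr1_syms <- genes$symbol[genes$chrom == "chr1"]
  pairs <- utils::combn(chr1_syms, 2)
  for (j in seq_len(ncol(pairs))) {
    expect_equal(are_neighbors(pairs[1, j], pairs[2, j], idx),
                 oracle(pairs[1, j], pairs[2, j]),
                 info = paste(pairs[, j], collapse = "-"))
  }
  expect_true(are_neighbors("RTA", "RTB", idx))
  expect_false(are_neighbors("PARA1", "PARA2", idx))  # MIDG lies between
  expect_false(are_neighbors("HBB", "IGKV1", idx))    # different chromosomes
  expect_warning(expect_false(are_neighbors("HBB", "NOPE", idx)), "absent")
})

test_that("strict read-through additionally requires collinear same-strand order", {
  sim <- sim_fixture()
  idx <- sim$ref$index
  expect_true(read_through_strict("RTA", "RTB", idx))
  expect_false(read_through_strict("RTB", "RTA", idx))  # wrong direction
})
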