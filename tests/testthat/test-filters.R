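test_that("the inclusive read-support rule requires both read classes", {
  cs <- make_candidates(3)
  cs$split_reads <- c(1L, 5L, 0L)
  cs$spanning_reads <- c(1L, 0L, 0L)
  res <- depth_filter(cs)                 # defaults: 1 split + 1 spanning
  expect_equal(res$kept$candidate_id, cs$candidate_id[1])
  expect_equal(res$removed$candidate_id, cs$candidate_id[2:3])
  empty <- depth_filter(cs[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$removed), 0)
})

test_that("filters partition their input, are idempotent and monotone", {
  set.seed(23)
  for (i in 1:10) {
    cs <- random_candidates(40, sample_id = paste0("R", i))
    res <- depth_filter(cs, 1, 1)
    expect_equal(nrow(res$kept) + nrow(res$removed), nrow(cs))
    expect_length(intersect(res$kept$candidate_id,
                            res$removed$candidate_id), 0)
    again <- depth_filter(res$kept, 1, 1)
    expect_identical(again$kept, res$kept)          # idempotent
    expect_equal(nrow(again$removed), 0)
    # raising thresholds never grows the kept set; the caller-default
    # (3 split, 2 spanning) setting is never more inclusive than (1, 1)
    strict <- depth_filter(cs, 3, 2)
    expect_true(all(strict$kept$candidate_id %in% res$kept$candidate_id))
  }
})

test_that("control events enter the database per specimen at >= 2 supporting reads", {
  mk <- function(id, split, spanning) {
    cs <- make_candidates(1, sample_id = id, pos5 = 500L, pos3 = 900L)
    cs$split_reads <- split; cs$spanning_reads <- spanning
    cs
  }
  key <- fusion_key("chr1", 500L, "chr1", 900L)
  expect_true(key %in% build_normal_db(list(mk("N1", 2L, 1L)))$keys)
  expect_false(key %in% build_normal_db(list(mk("N1", 1L, 0L)))$keys)
  # two controls with one read each: per-specimen rule, not pooled
  two <- list(mk("N1", 1L, 0L), mk("N2", 1L, 0L))
  expect_false(key %in% build_normal_db(two)$keys)
  expect_true(key %in% build_normal_db(two, pooled = TRUE)$keys)
})

test_that("duplicate (key, sample) control rows are summed with a warning", {
  cs <- make_candidates(2, sample_id = "N1", pos5 = c(500L, 500L),
                        pos3 = c(900L, 900L))
  cs$split_reads <- c(1L, 1L); cs$spanning_reads <- c(0L, 0L)
  expect_warning(db <- build_normal_db(list(cs)), "summed")
  expect_true(fusion_key("chr1", 500L, "chr1", 900L) %in% db$keys)
})

test_that("the normal-database filter removes exact and fuzzy key matches", {
  control <- make_candidates(1, sample_id = "N1", pos5 = 500L, pos3 = 900L)
  control$split_reads <- 3L
  db <- build_normal_db(list(control))
  cs <- make_candidates(3, pos5 = c(500L, 503L, 700L),
                        pos3 = c(900L, 900L, 900L))
  exact <- normal_db_filter(cs, db)
  expect_equal(exact$removed$pos5, 500L)
  expect_equal(exact$kept$pos5, c(503L, 700L))
  fuzzy <- normal_db_filter(cs, db, fuzz_bp = 5L)
  expect_equal(fuzzy$removed$pos5, c(500L, 503L))
  # brute-force window oracle over every (candidate, db key) pair
  set.seed(31)
  for (i in 1:5) {
    ctl <- random_candidates(10, "NC")
    ctl$split_reads <- 3L; ctl$spanning_reads <- 1L
    dbi <- build_normal_db(list(ctl))
    cand <- random_candidates(30, paste0("Q", i))
    fz <- 50L
    got <- normal_db_filter(cand, dbi, fuzz_bp = fz)
    ck <- fusion_key(cand$chrom5, cand$pos5, cand$chrom3, cand$pos3)
    parse1 <- function(k) strsplit(k, "[|:]")[[1]]
    oracle_removed <- vapply(ck, function(k) {
      q <- parse1(k)
      any(vapply(dbi$keys, function(d) {
        s <- parse1(d)
        s[1] == q[1] && s[3] == q[3] &&
          abs(as.integer(s[2]) - as.integer(q[2])) <= fz &&
          abs(as.integer(s[4]) - as.integer(q[4])) <= fz
      }, logical(1)))
    }, logical(1))
    expect_equal(got$removed$candidate_id, cand$candidate_id[oracle_removed])
  }
})

test_that("a growing normal database never grows the kept set", {
  cand <- random_candidates(20, "Q")
  ctl_small <- make_candidates(2, sample_id = "N1",
                               pos5 = cand$pos5[1:2], pos3 = cand$pos3[1:2],
                               chrom5 = cand$chrom5[1:2],
                               chrom3 = cand$chrom3[1:2],
                               split = 3L, spanning = 1L)
  ctl_big <- make_candidates(5, sample_id = "N1",
                             pos5 = cand$pos5[1:5], pos3 = cand$pos3[1:5],
                             chrom5 = cand$chrom5[1:5],
                             chrom3 = cand$chrom3[1:5],
                             split = 3L, spanning = 1L)
  kept_small <- normal_db_filter(cand, build_normal_db(list(ctl_small)))$kept
  kept_big <- normal_db_filter(cand, build_normal_db(list(ctl_big)))$kept
  expect_true(all(kept_big$candidate_id %in% kept_small$candidate_id))
})

test_that("cohort recurrence removes a shared key from every carrier", {
  shared <- list(pos5 = 1234L, pos3 = 5678L)
  pa <- make_candidates(2, "A", pos5 = c(shared$pos5, 10L),
                        pos3 = c(shared$pos3, 20L))
  pb <- make_candidates(2, "B", pos5 = c(shared$pos5, 30L),
                        pos3 = c(shared$pos3, 40L))
  pc <- make_candidates(1, "C", pos5 = 50L, pos3 = 60L)
  res <- cohort_recurrence_filter(list(A = pa, B = pb, C = pc))
  expect_equal(res$A$removed$pos5, shared$pos5)   # removed from both carriers
  expect_equal(res$B$removed$pos5, shared$pos5)
  expect_equal(nrow(res$C$removed), 0)
  # key in all three patients: removed from all three
  all3 <- lapply(c("A", "B", "C"), function(s)
    make_candidates(1, s, pos5 = 99L, pos3 = 999L))
  names(all3) <- c("A", "B", "C")
  res3 <- cohort_recurrence_filter(all3)
  expect_true(all(vapply(res3, function(r) nrow(r$kept) == 0, logical(1))))
  # within-patient duplicate does not trigger removal
  dup <- make_candidates(2, "A", pos5 = c(7L, 7L), pos3 = c(8L, 8L))
  resd <- cohort_recurrence_filter(list(A = dup))
  expect_equal(nrow(resd$A$removed), 0)
})

test_that("reciprocal orientations share a key only at identical coordinates", {
  k1 <- fusion_key("chr11", 108129802L, "chr11", 107663526L)
  k2 <- fusion_key("chr11", 107663526L, "chr11", 108129802L)
  expect_identical(k1, k2)                 # same coordinates, swapped sides
  k3 <- fusion_key("chr11", 107673727L, "chr11", 108137898L)
  expect_false(identical(k1, k3))          # the reciprocal event's own pair
})
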