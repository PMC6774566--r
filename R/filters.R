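# The three evidence/frequency filters applied before categorization:
# minimal read support, normal-control database, cohort recurrence.
# Every filter partitions its input (kept + removed = input, disjoint) and
# preserves row order.

#' Canonical matching key for a breakpoint pair
#'
#' Orders the two breakpoints lexicographically by chromosome then
#' numerically by position, so that reciprocal orientations of the same
#' coordinate pair share a key only when the coordinates themselves match.
#'
#' @param chrom5,pos5,chrom3,pos3 breakpoint coordinates (vectorized).
#' @return character vector `"chromA:posA|chromB:posB"`.
#' @export
fusion_key <- function(chrom5, pos5, chrom3, pos3) {
  a <- paste0(chrom5, ":", format(as.integer(pos5), scientific = FALSE,
                                  trim = TRUE))
  b <- paste0(chrom3, ":", format(as.integer(pos3), scientific = FALSE,
                                  trim = TRUE))
  swap <- (chrom3 < chrom5) | (chrom3 == chrom5 & as.integer(pos3) <
                                 as.integer(pos5))
  ifelse(swap, paste0(b, "|", a), paste0(a, "|", b))
}

partition <- function(candidates, keep) {
  list(kept = candidates[keep, , drop = FALSE],
       removed = candidates[!keep, , drop = FALSE])
}

#' Minimal read-support filter
#'
#' Keeps candidates supported by at least `min_split` split read pairs AND
#' at least `min_spanning` spanning read pairs. The defaults (1, 1) are the
#' inclusive rule for germline data; typical caller defaults correspond to
#' (3, 2).
#'
#' @param candidates candidate tibble ([as_candidate_set()]).
#' @param min_split,min_spanning non-negative thresholds.
#' @return list with `kept` and `removed` candidate tibbles partitioning the
#'   input, both in input order.
#' @export
depth_filter <- function(candidates, min_split = 1L, min_spanning = 1L) {
  stopifnot(min_split >= 0, min_spanning >= 0)
  partition(candidates,
            candidates$split_reads >= min_split &
              candidates$spanning_reads >= min_spanning)
}

#' Build a normal-control fusion database
#'
#' A breakpoint-pair key enters the database iff at least one control sample
#' reports it with total supporting reads (split + spanning) of at least
#' `min_reads`. By default the rule is applied per specimen; `pooled = TRUE`
#' instead sums supporting reads over all control samples before applying
#' the threshold. Per-sample counts are retained for inspection.
#'
#' @param control_sets list of control candidate tibbles (or one tibble with
#'   a `sample_id` column).
#' @param min_reads minimum supporting reads for a control event to count as
#'   genuine evidence (default 2: a single supporting read is treated as
#'   insufficient).
#' @param pooled apply `min_reads` to the pooled count across control
#'   samples instead of per specimen.
#' @return object of class `normal_fusion_db`.
#' @export
build_normal_db <- function(control_sets, min_reads = 2L, pooled = FALSE) {
  stopifnot(min_reads >= 1)
  if (is.data.frame(control_sets)) control_sets <- list(control_sets)
  if (length(control_sets) == 0) rlang::abort("control_sets must be non-empty")
  obs <- dplyr::bind_rows(lapply(control_sets, function(cs) {
    tibble::tibble(
      key = fusion_key(cs$chrom5, cs$pos5, cs$chrom3, cs$pos3),
      sample_id = cs$sample_id,
      supporting_reads = cs$split_reads + cs$spanning_reads)
  }))
  obs <- obs[obs$supporting_reads >= 1, , drop = FALSE]
  if (anyDuplicated(obs[, c("key", "sample_id")]) > 0) {
    rlang::warn("duplicate (key, sample) control rows: supporting reads summed")
    obs <- obs |>
      dplyr::group_by(.data$key, .data$sample_id) |>
      dplyr::summarise(supporting_reads = sum(.data$supporting_reads),
                       .groups = "drop")
  }
  passing <- if (pooled) {
    obs |>
      dplyr::group_by(.data$key) |>
      dplyr::summarise(total = sum(.data$supporting_reads)) |>
      dplyr::filter(.data$total >= min_reads) |>
      dplyr::pull("key")
  } else {
    unique(obs$key[obs$supporting_reads >= min_reads])
  }
  structure(
    list(records = obs,
         keys = sort(passing),
         metadata = list(min_reads = as.integer(min_reads), pooled = pooled,
                         n_samples = length(unique(obs$sample_id)))),
    class = "normal_fusion_db")
}

#' @export
print.normal_fusion_db <- function(x, ...) {
  cat(sprintf(
    "<normal_fusion_db: %d key(s) from %d control sample(s); min_reads=%d%s>\n",
    length(x$keys), x$metadata$n_samples, x$metadata$min_reads,
    if (isTRUE(x$metadata$pooled)) ", pooled" else ""))
  invisible(x)
}

#' Serialize / restore a normal-control database
#'
#' Sorted TSV with a `#params` header line; round-trips through
#' [read_normal_db()].
#'
#' @param db a [build_normal_db()] database.
#' @param path file path.
#' @return `path` (writer) or a `normal_fusion_db` (reader).
#' @export
write_normal_db <- function(db, path) {
  stopifnot(inherits(db, "normal_fusion_db"))
  writeLines(sprintf("#params min_reads=%d pooled=%s n_samples=%d",
                     db$metadata$min_reads, db$metadata$pooled,
                     db$metadata$n_samples), path)
  recs <- dplyr::arrange(db$records, .data$key, .data$sample_id)
  readr::write_tsv(recs, path, progress = FALSE, append = TRUE,
                   col_names = TRUE)
  invisible(path)
}

#' @rdname write_normal_db
#' @export
read_normal_db <- function(path) {
  header <- readLines(path, n = 1)
  min_reads <- as.integer(sub(".*min_reads=(\\d+).*", "\\1", header))
  pooled <- grepl("pooled=TRUE", header)
  recs <- readr::read_tsv(path, comment = "#", progress = FALSE,
                          col_types = readr::cols(
                            key = "c", sample_id = "c",
                            supporting_reads = "i"))
  passing <- if (pooled) {
    recs |>
      dplyr::group_by(.data$key) |>
      dplyr::summarise(total = sum(.data$supporting_reads)) |>
      dplyr::filter(.data$total >= min_reads) |>
      dplyr::pull("key")
  } else {
    unique(recs$key[recs$supporting_reads >= min_reads])
  }
  structure(
    list(records = recs, keys = sort(passing),
         metadata = list(min_reads = min_reads, pooled = pooled,
                         n_samples = length(unique(recs$sample_id)))),
    class = "normal_fusion_db")
}

# does candidate i match any db key within +/- fuzz on both positions?
fuzzy_key_match <- function(candidates, db_keys, fuzz_bp) {
  if (length(db_keys) == 0 || nrow(candidates) == 0) {
    return(rep(FALSE, nrow(candidates)))
  }
  parse_key <- function(k) {
    parts <- stringr::str_split_fixed(k, "\\|", 2)
    a <- stringr::str_split_fixed(parts[, 1], ":", 2)
    b <- stringr::str_split_fixed(parts[, 2], ":", 2)
    tibble::tibble(chromA = a[, 1], posA = as.integer(a[, 2]),
                   chromB = b[, 1], posB = as.integer(b[, 2]))
  }
  db <- parse_key(db_keys)
  cand <- parse_key(fusion_key(candidates$chrom5, candidates$pos5,
                               candidates$chrom3, candidates$pos3))
  vapply(seq_len(nrow(cand)), function(i) {
    any(db$chromA == cand$chromA[i] & db$chromB == cand$chromB[i] &
          abs(db$posA - cand$posA[i]) <= fuzz_bp &
          abs(db$posB - cand$posB[i]) <= fuzz_bp)
  }, logical(1))
}

#' Remove candidates present in the normal-control database
#'
#' A candidate is removed iff its canonical breakpoint-pair key matches a
#' database key exactly, or within `fuzz_bp` base pairs on both positions
#' when `fuzz_bp > 0`.
#'
#' @param candidates candidate tibble.
#' @param db a [build_normal_db()] database.
#' @param fuzz_bp breakpoint match window (0 = exact).
#' @return list with `kept` and `removed` partitioning the input in order.
#' @export
normal_db_filter <- function(candidates, db, fuzz_bp = 0L) {
  stopifnot(inherits(db, "normal_fusion_db"), fuzz_bp >= 0)
  key <- fusion_key(candidates$chrom5, candidates$pos5,
                    candidates$chrom3, candidates$pos3)
  hit <- if (fuzz_bp > 0) {
    fuzzy_key_match(candidates, db$keys, fuzz_bp)
  } else {
    key %in% db$keys
  }
  partition(candidates, !hit)
}

#' Remove candidates recurring across cohort patients
#'
#' Patients with rare, distinct disorders are not expected to share a
#' causative fusion: any breakpoint-pair key observed in two or more
#' distinct patients is removed from every patient carrying it. Duplicate
#' observations within one patient do not trigger removal.
#'
#' @param per_patient named list of candidate tibbles, one per patient.
#' @return named list (same names) of `list(kept, removed)` partitions.
#' @export
cohort_recurrence_filter <- function(per_patient) {
  stopifnot(length(per_patient) >= 1, !is.null(names(per_patient)))
  keys_by_patient <- lapply(per_patient, function(cs) {
    unique(fusion_key(cs$chrom5, cs$pos5, cs$chrom3, cs$pos3))
  })
  tally <- table(unlist(keys_by_patient))
  shared <- names(tally)[tally >= 2]
  lapply(per_patient, function(cs) {
    key <- fusion_key(cs$chrom5, cs$pos5, cs$chrom3, cs$pos3)
    partition(cs, !key %in% shared)
  })
}
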