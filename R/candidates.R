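# Candidate data model and readers/writers for external tables.
#
# A candidate set is a plain tibble with one row per putative fusion and a
# fixed column contract (see `candidate_columns()`); helper attributes carry
# provenance and per-row parse errors. Coordinates are 1-based and
# both-inclusive throughout the package.

#' Column contract of a candidate set
#'
#' @return Character vector of the required columns of a candidate tibble:
#'   `candidate_id`, `sample_id`, 5' and 3' breakpoint fields
#'   (`chrom5`, `pos5`, `strand5`, `chrom3`, `pos3`, `strand3`), read support
#'   (`split_reads`, `spanning_reads`) and optional sequences
#'   (`seq_full`, `seq5`, `seq3`).
#' @export
candidate_columns <- function() {
  c("candidate_id", "sample_id",
    "chrom5", "pos5", "strand5", "chrom3", "pos3", "strand3",
    "split_reads", "spanning_reads", "seq_full", "seq5", "seq3")
}

#' Normalize strand tokens to forward/reverse
#'
#' Accepts the vocabularies seen in caller output and report tables:
#' `+`/`-`, `f`/`r`, `forward`/`reverse` (any case).
#'
#' @param x character vector of strand tokens.
#' @return character vector of `"forward"` / `"reverse"` (NA preserved).
#' @export
normalize_strand <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- dplyr::case_match(
    key,
    c("+", "f", "fwd", "forward") ~ "forward",
    c("-", "r", "rev", "reverse") ~ "reverse",
    .default = NA_character_
  )
  bad <- !is.na(key) & key != "" & is.na(out)
  if (any(bad)) {
    rlang::abort(sprintf("unrecognized strand token(s): %s",
                         paste(unique(key[bad]), collapse = ", ")))
  }
  out
}

#' Validate and canonicalize a candidate tibble
#'
#' Fills optional columns with NA, normalizes strands, checks invariants
#' (positive coordinates, non-negative read counts, unique candidate ids,
#' full sequence length equal to the sum of segment lengths when all three
#' are present).
#'
#' @param x data frame with at least the coordinate and read-support columns.
#' @param sample_id optional sample identifier used to fill a missing
#'   `sample_id` column.
#' @return tibble following [candidate_columns()].
#' @export
as_candidate_set <- function(x, sample_id = NULL) {
  x <- tibble::as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    x$sample_id <- if (is.null(sample_id)) "sample" else sample_id
  }
  if (!"candidate_id" %in% names(x)) {
    x$candidate_id <- sprintf("%s_c%05d", x$sample_id, seq_len(nrow(x)))
  }
  for (col in c("seq_full", "seq5", "seq3")) {
    if (!col %in% names(x)) x[[col]] <- NA_character_
  }
  need <- setdiff(candidate_columns(), names(x))
  if (length(need) > 0) {
    rlang::abort(sprintf("candidate set is missing column(s): %s",
                         paste(need, collapse = ", ")))
  }
  x$pos5 <- as.integer(x$pos5)
  x$pos3 <- as.integer(x$pos3)
  x$split_reads <- as.integer(x$split_reads)
  x$spanning_reads <- as.integer(x$spanning_reads)
  x$strand5 <- normalize_strand(x$strand5)
  x$strand3 <- normalize_strand(x$strand3)
  if (any(stats::na.omit(c(x$pos5, x$pos3)) < 1)) {
    rlang::abort("breakpoint positions must be >= 1 (1-based coordinates)")
  }
  if (any(stats::na.omit(c(x$split_reads, x$spanning_reads)) < 0)) {
    rlang::abort("read counts must be non-negative")
  }
  if (anyDuplicated(x$candidate_id) > 0) {
    rlang::abort("candidate_id values must be unique within a candidate set")
  }
  full <- !is.na(x$seq_full) & !is.na(x$seq5) & !is.na(x$seq3)
  if (any(full) &&
      !all(nchar(x$seq_full[full]) == nchar(x$seq5[full]) + nchar(x$seq3[full]))) {
    rlang::abort("seq_full length must equal len(seq5) + len(seq3)")
  }
  x[, candidate_columns()]
}

# Default raw-caller column layout: chromosome pair "chrA-chrB", the two
# breakpoint positions, a two-letter orientation token (ff/fr/rf/rr), then
# split and spanning read counts. Configurable because raw caller archives
# are not guaranteed to share one layout.
tophat_raw_default_map <- function() {
  c(chrom_pair = 1L, pos5 = 2L, pos3 = 3L, orientation = 4L,
    split_reads = 5L, spanning_reads = 6L)
}

#' Read a per-sample fusion-candidate table
#'
#' Two dialects are supported. `generic_tsv` expects a header (or a
#' `column_map`) providing `chrom5, pos5, strand5, chrom3, pos3, strand3,
#' split_reads, spanning_reads` and optionally sequence columns.
#' `tophat_raw` is a headerless raw-caller layout whose column positions are
#' configurable via `column_map` (default: chromosome pair, pos5, pos3,
#' two-letter orientation, split reads, spanning reads).
#'
#' Malformed rows (unparseable coordinates or counts) are collected in the
#' `row_errors` attribute rather than silently dropped; parsing fails only
#' when more than half of the data rows are malformed.
#'
#' @param path file path.
#' @param dialect `"generic_tsv"` or `"tophat_raw"`.
#' @param column_map optional named map (name -> column name or index)
#'   overriding the dialect default.
#' @param sample_id sample identifier; defaults to the file base name.
#' @return candidate tibble (see [candidate_columns()]) with attributes
#'   `row_errors` (tibble of row, message) and `provenance`.
#' @export
read_candidates <- function(path,
                            dialect = c("generic_tsv", "tophat_raw"),
                            column_map = NULL,
                            sample_id = NULL) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) rlang::abort(
                        sprintf("unknown candidate dialect: %s",
                                paste(dialect, collapse = "/"))))
  sample_given <- !is.null(sample_id)
  if (!sample_given) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (dialect == "generic_tsv") {
    raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE, comment = "#")
    if (!is.null(column_map)) {
      map <- column_map
      idx <- vapply(map, function(v) {
        if (is.numeric(v)) as.integer(v) else match(as.character(v), names(raw))
      }, integer(1))
      if (anyNA(idx)) rlang::abort("column_map names a column absent from the file")
      picked <- raw[, idx, drop = FALSE]
      names(picked) <- names(map)
      extra <- setdiff(names(raw), as.character(column_map))
      raw <- dplyr::bind_cols(picked, raw[, extra, drop = FALSE])
    }
    need <- c("chrom5", "pos5", "strand5", "chrom3", "pos3", "strand3",
              "split_reads", "spanning_reads")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0) {
      rlang::abort(sprintf("generic_tsv file lacks column(s): %s",
                           paste(miss, collapse = ", ")))
    }
  } else {
    map <- if (is.null(column_map)) tophat_raw_default_map() else column_map
    cells <- readr::read_tsv(path, col_names = FALSE,
                             col_types = readr::cols(.default = "c"),
                             progress = FALSE, comment = "#")
    if (nrow(cells) == 0) {
      raw <- tibble::tibble(chrom5 = character(), pos5 = character(),
                            strand5 = character(), chrom3 = character(),
                            pos3 = character(), strand3 = character(),
                            split_reads = character(),
                            spanning_reads = character())
    } else {
      get <- function(name) cells[[map[[name]]]]
      pair <- stringr::str_split_fixed(get("chrom_pair"), "-", 2)
      ori <- tolower(get("orientation"))
      raw <- tibble::tibble(
        chrom5 = pair[, 1], pos5 = get("pos5"),
        strand5 = substr(ori, 1, 1),
        chrom3 = pair[, 2], pos3 = get("pos3"),
        strand3 = substr(ori, 2, 2),
        split_reads = get("split_reads"),
        spanning_reads = get("spanning_reads"))
    }
  }
  n_total <- nrow(raw)
  pos5 <- suppressWarnings(as.integer(raw$pos5))
  pos3 <- suppressWarnings(as.integer(raw$pos3))
  split <- suppressWarnings(as.integer(raw$split_reads))
  spanning <- suppressWarnings(as.integer(raw$spanning_reads))
  problems <- dplyr::case_when(
    is.na(pos5) | is.na(pos3) ~ "unparseable breakpoint coordinate",
    is.na(split) | is.na(spanning) ~ "unparseable read count",
    raw$chrom5 == "" | raw$chrom3 == "" ~ "empty chromosome name",
    TRUE ~ NA_character_
  )
  bad <- !is.na(problems)
  if (n_total > 0 && sum(bad) > n_total / 2) {
    rlang::abort(sprintf("%d of %d rows malformed in %s; refusing to parse",
                         sum(bad), n_total, path))
  }
  row_errors <- tibble::tibble(row = which(bad), message = problems[bad])
  keep <- raw[!bad, , drop = FALSE]
  keep$pos5 <- pos5[!bad]
  keep$pos3 <- pos3[!bad]
  keep$split_reads <- split[!bad]
  keep$spanning_reads <- spanning[!bad]
  # a sample_id column in the file wins unless the caller overrides it
  if (!(dialect == "generic_tsv" && !sample_given &&
        "sample_id" %in% names(keep) && !anyNA(keep$sample_id))) {
    keep$sample_id <- sample_id
  }
  # deterministic ids keyed to the original file row, in file order
  keep$candidate_id <- sprintf("%s_c%05d", keep$sample_id,
                               if (nrow(keep) > 0) which(!bad) else integer(0))
  out <- as_candidate_set(keep, sample_id = sample_id)
  attr(out, "row_errors") <- row_errors
  attr(out, "provenance") <- normalizePath(path)
  out
}

#' Write / read the categorized report
#'
#' The report is a UTF-8 TSV with a commented header recording the coordinate
#' convention and run parameters. One row per input candidate carries its
#' filter disposition, category, flags and annotations. Re-reading a written
#' report reproduces the category labels exactly.
#'
#' @param report tibble as produced by [run_pipeline()] (`$report`).
#' @param path output path.
#' @param params optional named list of parameters recorded in the header.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, params = list()) {
  header <- c(
    "# germfuse categorized report",
    "# coordinates: 1-based, both-inclusive",
    sprintf("# param %s=%s", names(params),
            vapply(params, function(p) paste(format(p), collapse = ","),
                   character(1))))
  tryCatch(writeLines(header, path, useBytes = TRUE),
           error = function(e) rlang::abort(
             sprintf("cannot write %s: %s", path, conditionMessage(e))))
  readr::write_tsv(report, path, na = "NA", progress = FALSE,
                   append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_tsv(path, comment = "#", progress = FALSE,
                  col_types = readr::cols())
}
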