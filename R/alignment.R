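# Alignment queries, tabular alignment records (conventional 12-column
# layout) against genome and transcriptome, threshold gates, top-hit
# selection, and reduction to the per-candidate alignment summary consumed
# by the categorization decision tree. Precomputed tabular hits are the
# first-class input; running the external aligner is an optional
# convenience.

#' Alignment configuration
#'
#' Defaults follow short-query alignment of fusion contigs: word size 7 and
#' e-value threshold 1 so short segments still seed alignments, with hits
#' kept only at >= 90% identity and >= 75% query-length coverage.
#' `unbroken_coverage` is the single-block coverage a full-length query must
#' reach for its alignment to count as "unbroken".
#'
#' @param word_size aligner word size (>= 4).
#' @param evalue_max aligner e-value cutoff.
#' @param min_identity minimum fractional identity in (0, 1].
#' @param min_query_coverage minimum fractional query coverage in (0, 1].
#' @param unbroken_coverage single-block coverage defining an unbroken
#'   full-length alignment.
#' @return list of class `align_config`.
#' @export
align_config <- function(word_size = 7L, evalue_max = 1, min_identity = 0.90,
                         min_query_coverage = 0.75,
                         unbroken_coverage = min_query_coverage) {
  stopifnot(word_size >= 4,
            min_identity > 0, min_identity <= 1,
            min_query_coverage > 0, min_query_coverage <= 1,
            unbroken_coverage > 0, unbroken_coverage <= 1)
  structure(list(word_size = as.integer(word_size), evalue_max = evalue_max,
                 min_identity = min_identity,
                 min_query_coverage = min_query_coverage,
                 unbroken_coverage = unbroken_coverage),
            class = "align_config")
}

alignment_hit_columns <- function() {
  c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore")
}

#' Read tabular alignment records
#'
#' Conventional 12-column tabular layout (query, subject, percent identity,
#' alignment length, mismatches, gap opens, query start/end, subject
#' start/end, e-value, bitscore). Subject start greater than subject end
#' signals reverse orientation. Query ids encode the candidate and query
#' kind as `"<candidate_id>|full"`, `"...|seg5"` or `"...|seg3"`.
#'
#' @param path file path (no header).
#' @param subject_db `"genome"` or `"transcriptome"` — which database the
#'   hits are against.
#' @return tibble of hits with a `subject_db` column appended.
#' @export
read_alignment_hits <- function(path, subject_db = c("genome",
                                                     "transcriptome")) {
  subject_db <- match.arg(subject_db)
  hits <- readr::read_tsv(
    path, col_names = alignment_hit_columns(), comment = "#",
    col_types = readr::cols(
      qseqid = "c", sseqid = "c", pident = "d", length = "i", mismatch = "i",
      gapopen = "i", qstart = "i", qend = "i", sstart = "i", send = "i",
      evalue = "d", bitscore = "d"),
    progress = FALSE)
  hits$subject_db <- subject_db
  hits
}

#' Decompose a query id into candidate id and query kind
#'
#' @param qseqid character vector of query ids.
#' @return tibble with `candidate_id` and `query_kind`
#'   (`full`/`seg5`/`seg3`).
#' @export
parse_query_id <- function(qseqid) {
  tibble::tibble(candidate_id = sub("\\|[^|]*$", "", qseqid),
                 query_kind = sub("^.*\\|", "", qseqid))
}

#' Build the three alignment queries of a candidate
#'
#' Emits the full-length fusion contig plus the decoupled 5' and 3' segments
#' as named sequences. When only the full sequence is present and the
#' junction offset within it is known, the segments are sliced from it.
#' A candidate with no sequence at all is returned with
#' `unalignable = TRUE` and no records.
#'
#' @param candidate one-row candidate tibble.
#' @param junction optional 1-based offset of the last 5'-segment base
#'   within `seq_full`, used to slice segments when they are absent.
#' @return list with `records` (named character vector of sequences, ids
#'   `"<candidate_id>|full"` etc.) and `unalignable` flag.
#' @export
build_queries <- function(candidate, junction = NULL) {
  stopifnot(nrow(candidate) == 1)
  id <- candidate$candidate_id
  seq_full <- candidate$seq_full
  seq5 <- candidate$seq5
  seq3 <- candidate$seq3
  if (is.na(seq_full) && !is.na(seq5) && !is.na(seq3)) {
    seq_full <- paste0(seq5, seq3)
  }
  if (!is.na(seq_full) && is.na(seq5) && is.na(seq3) && !is.null(junction)) {
    stopifnot(junction >= 1, junction < nchar(seq_full))
    seq5 <- substr(seq_full, 1L, junction)
    seq3 <- substr(seq_full, junction + 1L, nchar(seq_full))
  }
  recs <- c(full = seq_full, seg5 = seq5, seg3 = seq3)
  recs <- recs[!is.na(recs)]
  if (length(recs) == 0) {
    return(list(records = character(0), unalignable = TRUE))
  }
  names(recs) <- paste0(id, "|", names(recs))
  list(records = recs, unalignable = FALSE)
}

#' Query lengths of a candidate set
#'
#' @param candidates candidate tibble.
#' @return named integer vector keyed by query id (`"<id>|full"`,
#'   `"<id>|seg5"`, `"<id>|seg3"`); absent sequences are omitted, with the
#'   full length inferred from the segments when needed.
#' @export
candidate_query_lengths <- function(candidates) {
  out <- integer(0)
  for (i in seq_len(nrow(candidates))) {
    cand <- candidates[i, ]
    full_len <- if (!is.na(cand$seq_full)) nchar(cand$seq_full)
      else if (!is.na(cand$seq5) && !is.na(cand$seq3))
        nchar(cand$seq5) + nchar(cand$seq3)
      else NA_integer_
    lens <- c(full = full_len,
              seg5 = if (is.na(cand$seq5)) NA_integer_ else nchar(cand$seq5),
              seg3 = if (is.na(cand$seq3)) NA_integer_ else nchar(cand$seq3))
    lens <- lens[!is.na(lens)]
    if (length(lens) > 0) {
      names(lens) <- paste0(cand$candidate_id, "|", names(lens))
      out <- c(out, lens)
    }
  }
  out
}

#' Identity/coverage gate on alignment hits
#'
#' Retains a hit iff its percent identity is at least `100 * min_identity`
#' and its query coverage `(qend - qstart + 1) / query_length` is at least
#' `min_query_coverage`. Order is preserved; the gate is a pure filter
#' (applying it twice equals applying it once).
#'
#' @param hits hit tibble ([read_alignment_hits()]).
#' @param cfg an [align_config()].
#' @param query_lengths named integer vector keyed by query id
#'   ([candidate_query_lengths()]).
#' @return filtered hit tibble with a `coverage` column appended.
#' @export
filter_hits <- function(hits, cfg = align_config(), query_lengths) {
  stopifnot(inherits(cfg, "align_config"))
  if (nrow(hits) == 0) {
    hits$coverage <- numeric(0)
    return(hits)
  }
  unknown <- setdiff(unique(hits$qseqid), names(query_lengths))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("hit(s) reference unknown query id(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  hits$coverage <- (hits$qend - hits$qstart + 1) /
    unname(query_lengths[hits$qseqid])
  hits[hits$pident >= 100 * cfg$min_identity &
         hits$coverage >= cfg$min_query_coverage, , drop = FALSE]
}

#' Select top-scoring hits per query and database
#'
#' Keeps the maximal-bitscore hit for each (query id, subject database)
#' pair; score ties are all retained and marked `ambiguous`.
#'
#' @param hits threshold-filtered hit tibble (with `subject_db`).
#' @return tibble of top hits with an `ambiguous` column.
#' @export
select_top_hits <- function(hits) {
  if (nrow(hits) == 0) {
    hits$ambiguous <- logical(0)
    return(hits)
  }
  hits |>
    dplyr::group_by(.data$qseqid, .data$subject_db) |>
    dplyr::filter(.data$bitscore == max(.data$bitscore)) |>
    dplyr::mutate(ambiguous = dplyr::n() > 1) |>
    dplyr::ungroup()
}

# gene symbols overlapped by a genome hit's subject interval (any overlap;
# multi-gene overlaps retain all symbols)
genome_hit_genes <- function(hits, index) {
  lapply(seq_len(nrow(hits)), function(i) {
    g <- genes_overlapping(index, hits$sseqid[i],
                           min(hits$sstart[i], hits$send[i]),
                           max(hits$sstart[i], hits$send[i]))
    unique(g$symbol)
  })
}

# gene symbol(s) of a transcriptome hit via transcript -> gene
tx_hit_genes <- function(hits, index) {
  map <- stats::setNames(index$transcripts$symbol,
                         index$transcripts$transcript_id)
  lapply(hits$sseqid, function(s) {
    sym <- unname(map[s])
    sym[!is.na(sym)]
  })
}

#' Reduce top hits to a per-candidate alignment summary
#'
#' For each candidate: whether the full-length query produced an unbroken
#' (single-block, >= `unbroken_coverage`) alignment to a transcript or to
#' the genome; whether each decoupled segment has a surviving top hit; the
#' gene symbols resolved for each segment (genome hits by gene-span overlap,
#' transcriptome hits via transcript-to-gene); the chromosome backing each
#' segment's best placement; and alignment-ambiguity.
#'
#' @param candidates candidate tibble.
#' @param top_hits output of [select_top_hits()] (already gate-filtered).
#' @param index a [read_gene_models()] index.
#' @param cfg an [align_config()].
#' @return tibble with one row per candidate: `candidate_id`,
#'   `any_alignment`, `full_unbroken_tx`, `full_unbroken_genome`,
#'   `seg5_aligned`, `seg3_aligned`, `genes5`, `genes3` (list columns),
#'   `chrom5_hit`, `chrom3_hit`, `ambiguous`.
#' @export
summarize_alignments <- function(candidates, top_hits, index,
                                 cfg = align_config()) {
  stopifnot(inherits(cfg, "align_config"))
  qlen <- candidate_query_lengths(candidates)
  if (nrow(top_hits) > 0) {
    parsed <- parse_query_id(top_hits$qseqid)
    top_hits$candidate_id <- parsed$candidate_id
    top_hits$query_kind <- parsed$query_kind
    if (!"ambiguous" %in% names(top_hits)) top_hits$ambiguous <- FALSE
  } else {
    top_hits$candidate_id <- character(0)
    top_hits$query_kind <- character(0)
    if (!"ambiguous" %in% names(top_hits)) top_hits$ambiguous <- logical(0)
    if (!"coverage" %in% names(top_hits)) top_hits$coverage <- numeric(0)
    if (!"coverage" %in% names(top_hits)) {
      top_hits$coverage <- (top_hits$qend - top_hits$qstart + 1) /
        unname(qlen[top_hits$qseqid])
    }
  }
  seg_info <- function(hits) {
    if (nrow(hits) == 0) {
      return(list(aligned = FALSE, genes = character(0),
                  chrom = NA_character_, ambiguous = FALSE))
    }
    genome <- hits[hits$subject_db == "genome", , drop = FALSE]
    tx <- hits[hits$subject_db == "transcriptome", , drop = FALSE]
    genes <- unique(c(unlist(genome_hit_genes(genome, index)),
                      unlist(tx_hit_genes(tx, index))))
    chrom <- if (nrow(genome) > 0) {
      genome$sseqid[1]
    } else if (length(genes) > 0) {
      g <- index$genes[index$genes$symbol %in% genes, ]
      if (nrow(g) > 0) g$chrom[1] else NA_character_
    } else NA_character_
    list(aligned = TRUE, genes = genes, chrom = chrom,
         ambiguous = any(hits$ambiguous))
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    id <- candidates$candidate_id[i]
    hits <- if (nrow(top_hits) > 0) {
      top_hits[top_hits$candidate_id == id, , drop = FALSE]
    } else top_hits
    full <- hits[hits$query_kind == "full", , drop = FALSE]
    unbroken <- function(db) {
      h <- full[full$subject_db == db, , drop = FALSE]
      nrow(h) > 0 && any(h$coverage >= cfg$unbroken_coverage)
    }
    s5 <- seg_info(hits[hits$query_kind == "seg5", , drop = FALSE])
    s3 <- seg_info(hits[hits$query_kind == "seg3", , drop = FALSE])
    tibble::tibble(
      candidate_id = id,
      any_alignment = nrow(hits) > 0,
      full_unbroken_tx = unbroken("transcriptome"),
      full_unbroken_genome = unbroken("genome"),
      seg5_aligned = s5$aligned, seg3_aligned = s3$aligned,
      genes5 = list(s5$genes), genes3 = list(s3$genes),
      chrom5_hit = s5$chrom, chrom3_hit = s3$chrom,
      ambiguous = isTRUE(s5$ambiguous) || isTRUE(s3$ambiguous) ||
        (nrow(full) > 0 && any(full$ambiguous)))
  })
  dplyr::bind_rows(rows)
}

#' Run the external nucleotide aligner (optional convenience)
#'
#' Wraps `makeblastdb` + `blastn` with the configured word size and e-value,
#' writing 12-column tabular records that [read_alignment_hits()] parses.
#' Identical configuration and inputs give identical output. When the
#' aligner is not on the PATH, a clear error instructs the user to supply
#' precomputed tabular hits instead.
#'
#' @param query_fa FASTA of queries.
#' @param subject_fa FASTA of the subject database.
#' @param cfg an [align_config()].
#' @param out output path for the tabular hits.
#' @return `out`, invisibly.
#' @export
run_external_aligner <- function(query_fa, subject_fa, cfg = align_config(),
                                 out = tempfile(fileext = ".tsv")) {
  blastn <- Sys.which("blastn")
  makedb <- Sys.which("makeblastdb")
  if (blastn == "" || makedb == "") {
    rlang::abort(paste(
      "blastn/makeblastdb not found on PATH;",
      "supply precomputed 12-column tabular hits via read_alignment_hits()"))
  }
  dbdir <- tempfile("blastdb")
  dir.create(dbdir)
  db <- file.path(dbdir, "subject")
  status <- system2(makedb, c("-in", shQuote(subject_fa), "-dbtype", "nucl",
                              "-out", shQuote(db)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) rlang::abort("makeblastdb failed")
  status <- system2(blastn, c("-query", shQuote(query_fa), "-db", shQuote(db),
                              "-word_size", cfg$word_size,
                              "-evalue", format(cfg$evalue_max),
                              "-outfmt", "6", "-out", shQuote(out)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) rlang::abort("blastn failed")
  invisible(out)
}
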