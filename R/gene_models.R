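# Interval-queryable gene models built from a GTF. Genes carry symbol,
# strand and span; transcripts carry exons ordered in transcription
# direction and CDS intervals, powering exon-boundary, reading-frame,
# neighbor and separation annotation.

#' Build a gene-model index from a GTF file
#'
#' Requires exon features with `gene_id` and `transcript_id` attributes
#' (Ensembl-style). Gene spans come from `gene` features when present,
#' otherwise from the union of a gene's exons. CDS features, when present,
#' provide the coding intervals used for reading-frame calls.
#'
#' @param path GTF file path.
#' @return object of class `gene_model_index` with elements
#'   `genes`, `transcripts`, `exons`, `cds` (tibbles) and GRanges indexes
#'   for interval queries.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ex <- gr[type == "exon"]
  if (length(ex) == 0) rlang::abort(sprintf("no exon features in %s", path))
  exm <- S4Vectors::mcols(ex)
  if (is.null(exm$gene_id) || anyNA(exm$gene_id)) {
    bad <- if (is.null(exm$gene_id)) seq_along(ex) else which(is.na(exm$gene_id))
    rlang::abort(sprintf(
      "exon feature(s) missing gene_id (e.g. exon record %d of %s)",
      bad[1], path))
  }
  if (is.null(exm$transcript_id) || anyNA(exm$transcript_id)) {
    rlang::abort(sprintf("exon feature(s) missing transcript_id in %s", path))
  }
  symbol_of <- function(m) {
    if (!is.null(m$gene_name) && !all(is.na(m$gene_name))) {
      ifelse(is.na(m$gene_name), m$gene_id, m$gene_name)
    } else m$gene_id
  }
  exons <- tibble::tibble(
    transcript_id = as.character(exm$transcript_id),
    gene_id = as.character(exm$gene_id),
    chrom = as.character(GenomicRanges::seqnames(ex)),
    strand = as.character(GenomicRanges::strand(ex)),
    start = GenomicRanges::start(ex),
    end = GenomicRanges::end(ex))
  # exon rank in transcription direction (5' -> 3')
  exons <- exons |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(exon_rank = ifelse(.data$strand == "-",
                                     dplyr::n() - dplyr::row_number() + 1L,
                                     dplyr::row_number())) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$transcript_id, .data$exon_rank)

  cds_gr <- gr[type == "CDS"]
  cds <- if (length(cds_gr) > 0) {
    cm <- S4Vectors::mcols(cds_gr)
    tibble::tibble(
      transcript_id = as.character(cm$transcript_id),
      chrom = as.character(GenomicRanges::seqnames(cds_gr)),
      start = GenomicRanges::start(cds_gr),
      end = GenomicRanges::end(cds_gr))
  } else {
    tibble::tibble(transcript_id = character(), chrom = character(),
                   start = integer(), end = integer())
  }

  cds_len <- cds |>
    dplyr::group_by(.data$transcript_id) |>
    dplyr::summarise(cds_len = sum(.data$end - .data$start + 1L))
  transcripts <- exons |>
    dplyr::group_by(.data$transcript_id, .data$gene_id, .data$chrom,
                    .data$strand) |>
    dplyr::summarise(tx_start = min(.data$start), tx_end = max(.data$end),
                     n_exons = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(cds_len, by = "transcript_id") |>
    dplyr::mutate(cds_len = ifelse(is.na(.data$cds_len), 0L, .data$cds_len))

  gene_rows <- gr[type == "gene"]
  genes <- if (length(gene_rows) > 0) {
    gm <- S4Vectors::mcols(gene_rows)
    tibble::tibble(
      gene_id = as.character(gm$gene_id),
      symbol = as.character(symbol_of(gm)),
      chrom = as.character(GenomicRanges::seqnames(gene_rows)),
      strand = as.character(GenomicRanges::strand(gene_rows)),
      start = GenomicRanges::start(gene_rows),
      end = GenomicRanges::end(gene_rows))
  } else {
    sym_map <- tibble::tibble(gene_id = as.character(exm$gene_id),
                              symbol = as.character(symbol_of(exm))) |>
      dplyr::distinct(.data$gene_id, .keep_all = TRUE)
    exons |>
      dplyr::group_by(.data$gene_id, .data$chrom, .data$strand) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop") |>
      dplyr::left_join(sym_map, by = "gene_id") |>
      dplyr::select("gene_id", "symbol", "chrom", "strand", "start", "end")
  }
  symbol_map <- stats::setNames(genes$symbol, genes$gene_id)
  transcripts$symbol <- unname(symbol_map[transcripts$gene_id])

  genes_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand, gene_id = genes$gene_id, symbol = genes$symbol)
  tx_gr <- GenomicRanges::GRanges(
    transcripts$chrom, IRanges::IRanges(transcripts$tx_start,
                                        transcripts$tx_end),
    transcript_id = transcripts$transcript_id)
  exons_gr <- GenomicRanges::GRanges(
    exons$chrom, IRanges::IRanges(exons$start, exons$end),
    transcript_id = exons$transcript_id, exon_rank = exons$exon_rank)

  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds, genes_gr = genes_gr, tx_gr = tx_gr,
                 exons_gr = exons_gr),
            class = "gene_model_index")
}

#' @export
print.gene_model_index <- function(x, ...) {
  cat(sprintf(
    "<gene_model_index: %d gene(s), %d transcript(s), %d exon(s), %d CDS segment(s)>\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

query_gr <- function(chrom, start, end = start) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
}

#' Genes overlapping a point or interval
#'
#' @param index a [read_gene_models()] index.
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval (point query when `end`
#'   omitted).
#' @return tibble of matching rows of `index$genes` (0 rows when none).
#' @export
genes_overlapping <- function(index, chrom, start, end = start) {
  stopifnot(inherits(index, "gene_model_index"))
  if (!chrom %in% as.character(GenomicRanges::seqnames(index$genes_gr)) &&
      !chrom %in% index$genes$chrom) {
    return(index$genes[0, ])
  }
  hits <- GenomicRanges::findOverlaps(query_gr(chrom, start, end),
                                      index$genes_gr, ignore.strand = TRUE)
  index$genes[S4Vectors::subjectHits(hits), ]
}

#' Transcripts (and containing exons) at a genomic position
#'
#' @inheritParams genes_overlapping
#' @param pos 1-based position.
#' @return tibble with one row per overlapping transcript: `transcript_id`,
#'   `gene_id`, `symbol`, `strand`, `cds_len`, and `exon_rank` of the exon
#'   containing the position (NA when intronic).
#' @export
transcripts_at <- function(index, chrom, pos) {
  stopifnot(inherits(index, "gene_model_index"))
  hits <- GenomicRanges::findOverlaps(query_gr(chrom, pos), index$tx_gr,
                                      ignore.strand = TRUE)
  tx <- index$transcripts[S4Vectors::subjectHits(hits), ]
  if (nrow(tx) == 0) return(dplyr::mutate(tx, exon_rank = integer(0)))
  ex_hits <- GenomicRanges::findOverlaps(query_gr(chrom, pos),
                                         index$exons_gr, ignore.strand = TRUE)
  ex <- index$exons[S4Vectors::subjectHits(ex_hits), ]
  rank_map <- stats::setNames(ex$exon_rank, ex$transcript_id)
  tx$exon_rank <- unname(rank_map[tx$transcript_id])
  tx
}
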