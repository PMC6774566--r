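# Breakpoint-level biology: gene/exon localization, exon-boundary tests,
# reading-frame status, genomic separation, neighbor and homolog relations.

# Junction-facing exon edge for a breakpoint, in transcription orientation:
# the 5' partner contributes sequence up to and including the breakpoint, so
# its junction edge is the transcriptional 3' edge of an exon; the 3' partner
# resumes at the breakpoint, so its edge is a transcriptional 5' exon edge.
junction_edge_matches <- function(pos, side, strand, exon_start, exon_end) {
  if (side == "five_prime") {
    if (strand == "-") pos == exon_start else pos == exon_end
  } else {
    if (strand == "-") pos == exon_end else pos == exon_start
  }
}

# Coding nucleotides transcriptionally upstream of the junction within one
# transcript. The 5' side includes the breakpoint base itself; the 3' side
# counts strictly before it. NA when the transcript has no CDS.
cds_offset_at <- function(index, transcript_id, pos, side, strand) {
  cds <- index$cds[index$cds$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(cds) == 0) return(NA_integer_)
  if (strand == "-") {
    lo <- if (side == "five_prime") pos else pos + 1L
    hi <- Inf
  } else {
    lo <- -Inf
    hi <- if (side == "five_prime") pos else pos - 1L
  }
  ov <- pmax(0, pmin(cds$end, hi) - pmax(cds$start, lo) + 1)
  as.integer(sum(ov))
}

#' Annotate one breakpoint against the gene models
#'
#' Locates the breakpoint in a gene/transcript, tests whether it falls on the
#' junction-facing exon edge (the transcriptional 3' edge of an exon for the
#' 5' partner, the 5' edge for the 3' partner), and computes the count of
#' coding nucleotides transcriptionally upstream of the junction
#' (`cds_offset`, NA for non-coding transcripts).
#'
#' When several transcripts overlap the position, a transcript where the
#' position is a junction-facing exon edge is preferred; among those, the
#' longest CDS, then the lexicographically smallest id.
#'
#' @param chrom,pos breakpoint coordinate (1-based).
#' @param side `"five_prime"` or `"three_prime"` — which partner of the
#'   fusion this breakpoint belongs to.
#' @param index a [read_gene_models()] index.
#' @return one-row tibble: `gene`, `transcript`, `exon_index`,
#'   `at_exon_boundary`, `cds_offset`, `strand`.
#' @export
locate_breakpoint <- function(chrom, pos, side = c("five_prime", "three_prime"),
                              index) {
  side <- match.arg(side)
  stopifnot(inherits(index, "gene_model_index"))
  empty <- tibble::tibble(gene = NA_character_, transcript = NA_character_,
                          exon_index = NA_integer_, at_exon_boundary = FALSE,
                          cds_offset = NA_integer_, strand = NA_character_)
  if (!chrom %in% index$genes$chrom) {
    rlang::warn(sprintf("chromosome %s absent from gene models", chrom))
    return(empty)
  }
  tx <- transcripts_at(index, chrom, pos)
  if (nrow(tx) == 0) {
    g <- genes_overlapping(index, chrom, pos)
    if (nrow(g) > 0) {           # inside a gene span but outside transcripts
      empty$gene <- g$symbol[1]
      empty$strand <- g$strand[1]
    }
    return(empty)
  }
  per_tx <- lapply(seq_len(nrow(tx)), function(i) {
    t <- tx[i, ]
    exons <- index$exons[index$exons$transcript_id == t$transcript_id, ]
    containing <- exons[exons$start <= pos & pos <= exons$end, ]
    boundary <- nrow(containing) > 0 &&
      junction_edge_matches(pos, side, t$strand,
                            containing$start[1], containing$end[1])
    tibble::tibble(
      gene = t$symbol, transcript = t$transcript_id,
      exon_index = if (nrow(containing) > 0) containing$exon_rank[1]
                   else NA_integer_,
      at_exon_boundary = boundary,
      cds_offset = cds_offset_at(index, t$transcript_id, pos, side, t$strand),
      strand = t$strand, cds_len = t$cds_len)
  })
  cand <- dplyr::bind_rows(per_tx) |>
    dplyr::arrange(dplyr::desc(.data$at_exon_boundary),
                   dplyr::desc(.data$cds_len), .data$transcript)
  dplyr::select(cand[1, ], -"cds_len")
}

#' Reading-frame status of a fusion junction
#'
#' A fusion is in frame when both breakpoints sit at junction-facing exon
#' boundaries of coding transcripts and the count of coding nucleotides
#' upstream of the junction is congruent modulo 3 between the two partners,
#' i.e. the downstream gene's native codon phase is preserved. Non-coding or
#' non-boundary junctions are `not_applicable`.
#'
#' @param ann5,ann3 annotations from [locate_breakpoint()] for the 5' and 3'
#'   breakpoints.
#' @return `"in_frame"`, `"out_of_frame"` or `"not_applicable"`.
#' @export
frame_status <- function(ann5, ann3) {
  if (!isTRUE(ann5$at_exon_boundary) || !isTRUE(ann3$at_exon_boundary) ||
      is.na(ann5$cds_offset) || is.na(ann3$cds_offset)) {
    return("not_applicable")
  }
  if ((ann5$cds_offset - ann3$cds_offset) %% 3L == 0L) "in_frame"
  else "out_of_frame"
}

#' Genomic separation of a breakpoint pair
#'
#' @param chrom5,pos5,chrom3,pos3 breakpoint coordinates (vectorized).
#' @return absolute base-pair distance when both breakpoints share a
#'   chromosome, NA otherwise (interchromosomal).
#' @export
genomic_separation <- function(chrom5, pos5, chrom3, pos3) {
  ifelse(chrom5 == chrom3, abs(as.numeric(pos5) - as.numeric(pos3)), NA_real_)
}

#' Are two genes genomic neighbors?
#'
#' TRUE when the genes share a chromosome and no third gene's span lies
#' entirely within the interval between them (strand-agnostic). Used to flag
#' intrachromosomal fusions between adjacent genes as potential read-through
#' transcription.
#'
#' @param geneA,geneB gene symbols.
#' @param index a [read_gene_models()] index.
#' @return logical scalar. Genes absent from the index give FALSE with a
#'   warning.
#' @export
are_neighbors <- function(geneA, geneB, index) {
  stopifnot(inherits(index, "gene_model_index"))
  g <- index$genes
  a <- g[g$symbol == geneA, ]
  b <- g[g$symbol == geneB, ]
  if (nrow(a) == 0 || nrow(b) == 0) {
    rlang::warn(sprintf("gene(s) absent from index: %s",
                        paste(c(geneA, geneB)[c(nrow(a) == 0, nrow(b) == 0)],
                              collapse = ", ")))
    return(FALSE)
  }
  a <- a[1, ]; b <- b[1, ]
  if (a$chrom != b$chrom || a$symbol == b$symbol) return(FALSE)
  left <- if (a$start <= b$start) a else b
  right <- if (a$start <= b$start) b else a
  gap_start <- left$end + 1L
  gap_end <- right$start - 1L
  if (gap_start > gap_end) return(TRUE)  # abutting or overlapping spans
  between <- g$chrom == a$chrom &
    !(g$symbol %in% c(a$symbol, b$symbol)) &
    g$start >= gap_start & g$end <= gap_end
  !any(between)
}

#' Strict read-through test
#'
#' A stricter relation than [are_neighbors()]: additionally requires both
#' genes on the same strand with the 5' partner transcriptionally upstream of
#' the 3' partner, i.e. the configuration compatible with co-transcription of
#' adjacent genes.
#'
#' @param gene5,gene3 5' and 3' partner gene symbols.
#' @param index a [read_gene_models()] index.
#' @return logical scalar.
#' @export
read_through_strict <- function(gene5, gene3, index) {
  if (!are_neighbors(gene5, gene3, index)) return(FALSE)
  g <- index$genes
  a <- g[g$symbol == gene5, ][1, ]
  b <- g[g$symbol == gene3, ][1, ]
  if (a$strand != b$strand) return(FALSE)
  if (a$strand == "-") a$start > b$start else a$start < b$start
}
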