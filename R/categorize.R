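# The alignment-pattern decision tree: exactly one category per candidate,
# plus read-through and homolog flags, and the fixed-order pipeline
# (depth -> normal_db -> cohort -> categorize -> phenotype).

#' Fusion candidate categories
#'
#' The eight categories of the alignment-pattern decision tree, in
#' precedence order: exclusion of blood-abundant genes; whole-contig
#' explanations (known transcript, genomic sequence); artifacts (no or only
#' partial alignment); single-gene novel transcripts; immunoglobulin
#' diversity; and finally inter- and intrachromosomal fusion calls.
#'
#' @return character vector of category labels.
#' @export
fusion_categories <- function() {
  c("EXCLUDED_ABUNDANT", "KNOWN_TRANSCRIPT", "GENOMIC_SEQUENCE",
    "LIKELY_ARTIFACT", "NOVEL_TRANSCRIPT_SINGLE_GENE", "IMMUNE_DIVERSITY",
    "INTERCHROMOSOMAL_FUSION", "INTRACHROMOSOMAL_FUSION")
}

#' Categories treated as potential fusions downstream
#' @return character vector (subset of [fusion_categories()]).
#' @export
fusion_call_categories <- function() {
  c("INTERCHROMOSOMAL_FUSION", "INTRACHROMOSOMAL_FUSION")
}

# Decision tree over one candidate's alignment summary. Branch precedence is
# fixed (exclusion and single-sequence explanations before fusion calls):
#   A abundant gene involved        -> EXCLUDED_ABUNDANT
#   B full query unbroken vs tx     -> KNOWN_TRANSCRIPT
#   C full query unbroken vs genome -> GENOMIC_SEQUENCE
#   D no / only partial alignment   -> LIKELY_ARTIFACT
#   E both segments in one gene     -> NOVEL_TRANSCRIPT_SINGLE_GENE
#   F two separate immunoglobulins  -> IMMUNE_DIVERSITY
#   G segment hits on two chroms    -> INTERCHROMOSOMAL_FUSION
#   H two genes/regions, one chrom  -> INTRACHROMOSOMAL_FUSION
classify_one <- function(summary_row, abundant, immunoglobulin) {
  genes5 <- summary_row$genes5[[1]]
  genes3 <- summary_row$genes3[[1]]
  involved <- unique(c(genes5, genes3))
  if (length(involved) > 0 && any(matches_symbol_set(abundant, involved))) {
    return("EXCLUDED_ABUNDANT")
  }
  if (isTRUE(summary_row$full_unbroken_tx)) return("KNOWN_TRANSCRIPT")
  if (isTRUE(summary_row$full_unbroken_genome)) return("GENOMIC_SEQUENCE")
  if (!isTRUE(summary_row$any_alignment) ||
      !isTRUE(summary_row$seg5_aligned) || !isTRUE(summary_row$seg3_aligned)) {
    return("LIKELY_ARTIFACT")
  }
  if (length(intersect(genes5, genes3)) > 0) {
    return("NOVEL_TRANSCRIPT_SINGLE_GENE")
  }
  ig5 <- genes5[matches_symbol_set(immunoglobulin, genes5)]
  ig3 <- genes3[matches_symbol_set(immunoglobulin, genes3)]
  if (length(ig5) > 0 && length(ig3) > 0 &&
      length(setdiff(ig5, ig3)) + length(setdiff(ig3, ig5)) > 0) {
    return("IMMUNE_DIVERSITY")
  }
  chrom5 <- summary_row$chrom5_hit
  chrom3 <- summary_row$chrom3_hit
  if (!is.na(chrom5) && !is.na(chrom3) && chrom5 != chrom3) {
    return("INTERCHROMOSOMAL_FUSION")
  }
  "INTRACHROMOSOMAL_FUSION"
}

#' Categorize candidates from their alignment summaries
#'
#' Applies the decision tree (see [fusion_categories()]) to each candidate,
#' annotates breakpoints against the gene models (gene, transcript, exon
#' index, exon-boundary status), calls reading-frame status and genomic
#' separation, and sets the read-through (intrachromosomal neighbors) and
#' homolog flags on fusion calls.
#'
#' @param candidates candidate tibble.
#' @param summaries [summarize_alignments()] output covering every
#'   candidate; an error names any candidate without a summary.
#' @param index a [read_gene_models()] index.
#' @param abundant,immunoglobulin [gene_symbol_set()] lists.
#' @param homologs a [homolog_set()].
#' @return tibble with one row per candidate: identity and support columns,
#'   `category`, flags (`read_through`, `read_through_strict`, `homologous`,
#'   `ambiguous_alignment`), partner genes, per-breakpoint annotation
#'   columns, `exon_boundary`, `frame`, `separation_bp`.
#' @export
categorize_candidates <- function(candidates, summaries, index,
                                  abundant = default_abundant_list(),
                                  immunoglobulin = default_immunoglobulin_list(),
                                  homologs = homolog_set(
                                    data.frame(a = character(),
                                               b = character()))) {
  missing_sum <- setdiff(candidates$candidate_id, summaries$candidate_id)
  if (length(missing_sum) > 0) {
    rlang::abort(sprintf(
      "no alignment summary for candidate(s): %s (align or declare unalignable)",
      paste(missing_sum, collapse = ", ")))
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    cand <- candidates[i, ]
    s <- summaries[summaries$candidate_id == cand$candidate_id, ][1, ]
    category <- classify_one(s, abundant, immunoglobulin)
    ann5 <- locate_breakpoint(cand$chrom5, cand$pos5, "five_prime", index)
    ann3 <- locate_breakpoint(cand$chrom3, cand$pos3, "three_prime", index)
    genes5 <- s$genes5[[1]]
    genes3 <- s$genes3[[1]]
    gene5 <- if (length(genes5) > 0) genes5[1] else NA_character_
    gene3 <- if (length(genes3) > 0) genes3[1] else NA_character_
    is_fusion <- category %in% fusion_call_categories()
    read_through <- category == "INTRACHROMOSOMAL_FUSION" &&
      !is.na(gene5) && !is.na(gene3) && are_neighbors(gene5, gene3, index)
    rt_strict <- read_through && read_through_strict(gene5, gene3, index)
    homologous <- is_fusion && !is.na(gene5) && !is.na(gene3) &&
      are_homologs(gene5, gene3, homologs)
    frame <- frame_status(ann5, ann3)
    tibble::tibble(
      candidate_id = cand$candidate_id, sample_id = cand$sample_id,
      category = category,
      read_through = read_through, read_through_strict = rt_strict,
      homologous = homologous,
      ambiguous_alignment = isTRUE(s$ambiguous),
      gene5 = gene5, gene3 = gene3,
      chrom5 = cand$chrom5, pos5 = cand$pos5, strand5 = cand$strand5,
      chrom3 = cand$chrom3, pos3 = cand$pos3, strand3 = cand$strand3,
      split_reads = cand$split_reads, spanning_reads = cand$spanning_reads,
      transcript5 = ann5$transcript, transcript3 = ann3$transcript,
      exon5 = ann5$exon_index, exon3 = ann3$exon_index,
      at_boundary5 = ann5$at_exon_boundary,
      at_boundary3 = ann3$at_exon_boundary,
      exon_boundary = paste0(
        ifelse(ann5$at_exon_boundary, "Exon", "Intron"), "-",
        ifelse(ann3$at_exon_boundary, "Exon", "Intron")),
      frame = frame,
      separation_bp = genomic_separation(cand$chrom5, cand$pos5,
                                         cand$chrom3, cand$pos3))
  })
  dplyr::bind_rows(rows)
}

# 0-row categorized tibble with the full column contract
categorized_template <- function() {
  tibble::tibble(
    candidate_id = character(0), sample_id = character(0),
    category = character(0), read_through = logical(0),
    read_through_strict = logical(0), homologous = logical(0),
    ambiguous_alignment = logical(0),
    gene5 = character(0), gene3 = character(0),
    chrom5 = character(0), pos5 = integer(0), strand5 = character(0),
    chrom3 = character(0), pos3 = integer(0), strand3 = character(0),
    split_reads = integer(0), spanning_reads = integer(0),
    transcript5 = character(0), transcript3 = character(0),
    exon5 = integer(0), exon3 = integer(0),
    at_boundary5 = logical(0), at_boundary3 = logical(0),
    exon_boundary = character(0), frame = character(0),
    separation_bp = numeric(0))
}

lower_median <- function(x) {
  x <- sort(x)
  if (length(x) == 0) return(NA_real_)
  x[ceiling(length(x) / 2)]
}

#' Per-category candidate counts across samples
#'
#' Counts candidates per sample and category (zero-filled over the supplied
#' samples) and summarises with the lower median (order statistic: for an
#' even number of samples the lower of the two central values) and type-1
#' quartiles.
#'
#' @param categorized categorized tibble ([categorize_candidates()] output,
#'   possibly concatenated over samples).
#' @param samples optional character vector fixing the sample universe
#'   (defaults to samples present in `categorized`).
#' @return list with `per_sample` (sample x category counts) and `summary`
#'   (category, median, q1, q3).
#' @export
category_counts <- function(categorized, samples = NULL) {
  if (is.null(samples)) samples <- unique(categorized$sample_id)
  per_sample <- categorized |>
    dplyr::filter(.data$sample_id %in% samples) |>
    dplyr::group_by(.data$sample_id, .data$category) |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    tidyr::complete(sample_id = samples,
                    category = fusion_categories(),
                    fill = list(n = 0L))
  summary <- per_sample |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      median = lower_median(.data$n),
      q1 = stats::quantile(.data$n, 0.25, type = 1, names = FALSE),
      q3 = stats::quantile(.data$n, 0.75, type = 1, names = FALSE))
  list(per_sample = per_sample, summary = summary)
}

#' Run the full curation pipeline
#'
#' Fixed stage order: read-support filter, normal-control database filter,
#' cohort-recurrence filter, alignment-pattern categorization, and (when
#' phenotype inputs are supplied) rank-score prioritization of fusion-call
#' candidates. Every input candidate appears in the report with the stage
#' that removed it (or its category and scores when retained); a per-stage
#' attrition table records counts entering and leaving each stage for every
#' sample.
#'
#' @param per_patient named list of candidate tibbles, one per patient.
#' @param hits combined gate-unfiltered alignment hit tibble (with
#'   `subject_db`) covering all candidates, or NULL when no candidate
#'   reaches categorization.
#' @param index a [read_gene_models()] index.
#' @param normal_db a [build_normal_db()] database (optional).
#' @param abundant,immunoglobulin,homologs symbol lists and homolog pairs.
#' @param cfg an [align_config()].
#' @param min_split,min_spanning read-support thresholds.
#' @param fuzz_bp normal-database breakpoint match window.
#' @param patient_terms optional named list: patient -> phenotype term ids.
#' @param gene_terms optional gene-to-term association tibble
#'   (`gene`, `term`).
#' @param ontology optional ontology ([read_obo()]).
#' @param rank_cutoff shortlist rank-score cutoff.
#' @return list: `report` (all candidates with dispositions), `categorized`,
#'   `attrition`, `category_summary`, `shortlist`, `params`.
#' @export
run_pipeline <- function(per_patient, hits, index,
                         normal_db = NULL,
                         abundant = default_abundant_list(),
                         immunoglobulin = default_immunoglobulin_list(),
                         homologs = homolog_set(data.frame(a = character(),
                                                           b = character())),
                         cfg = align_config(),
                         min_split = 1L, min_spanning = 1L, fuzz_bp = 0L,
                         patient_terms = NULL, gene_terms = NULL,
                         ontology = NULL, rank_cutoff = 0.05) {
  stopifnot(is.list(per_patient), !is.null(names(per_patient)))
  per_patient <- lapply(per_patient, as_candidate_set)
  samples <- names(per_patient)
  disposition <- dplyr::bind_rows(per_patient)[, c("candidate_id",
                                                   "sample_id")]
  disposition$removed_stage <- NA_character_
  mark_removed <- function(disposition, removed, stage) {
    tag <- paste(disposition$sample_id, disposition$candidate_id)
    hit <- tag %in% paste(removed$sample_id, removed$candidate_id)
    disposition$removed_stage[hit & is.na(disposition$removed_stage)] <- stage
    disposition
  }
  attrition <- list()
  note_stage <- function(stage, before, after) {
    tibble::tibble(
      sample_id = samples, stage = stage,
      n_in = unname(vapply(before, nrow, integer(1))),
      n_out = unname(vapply(after, nrow, integer(1)))) |>
      dplyr::mutate(n_removed = .data$n_in - .data$n_out)
  }

  # stage 1: read support
  d <- lapply(per_patient, depth_filter,
              min_split = min_split, min_spanning = min_spanning)
  kept <- lapply(d, `[[`, "kept")
  for (p in samples) disposition <- mark_removed(disposition,
                                                 d[[p]]$removed, "depth")
  attrition$depth <- note_stage("depth", per_patient, kept)

  # stage 2: normal-control database
  before <- kept
  if (!is.null(normal_db)) {
    nd <- lapply(kept, normal_db_filter, db = normal_db, fuzz_bp = fuzz_bp)
    kept <- lapply(nd, `[[`, "kept")
    for (p in samples) disposition <- mark_removed(disposition,
                                                   nd[[p]]$removed,
                                                   "normal_db")
  }
  attrition$normal_db <- note_stage("normal_db", before, kept)

  # stage 3: cohort recurrence
  before <- kept
  cr <- cohort_recurrence_filter(kept)
  kept <- lapply(cr, `[[`, "kept")
  for (p in samples) disposition <- mark_removed(disposition,
                                                 cr[[p]]$removed, "cohort")
  attrition$cohort <- note_stage("cohort", before, kept)

  # stage 4: alignment-pattern categorization
  survivors <- dplyr::bind_rows(kept)
  categorized <- NULL
  if (nrow(survivors) > 0) {
    if (is.null(hits)) {
      rlang::abort("stage categorize: alignment hits required but not supplied")
    }
    qlen <- candidate_query_lengths(survivors)
    surviving_hits <- hits[parse_query_id(hits$qseqid)$candidate_id %in%
                             survivors$candidate_id, , drop = FALSE]
    gated <- filter_hits(surviving_hits, cfg, qlen)
    top <- select_top_hits(gated)
    summaries <- summarize_alignments(survivors, top, index, cfg)
    categorized <- categorize_candidates(survivors, summaries, index,
                                         abundant, immunoglobulin, homologs)
  } else {
    categorized <- categorized_template()
  }
  fusion_calls <- categorized[categorized$category %in%
                                fusion_call_categories(), , drop = FALSE]
  non_fusion <- categorized[!categorized$category %in%
                              fusion_call_categories(), , drop = FALSE]
  disposition <- mark_removed(disposition, non_fusion, "categorization")
  after_cat <- lapply(samples, function(p) {
    fusion_calls[fusion_calls$sample_id == p, , drop = FALSE]
  })
  names(after_cat) <- samples
  attrition$categorization <- note_stage("categorization", kept, after_cat)

  # stage 5: phenotype rank-scoring (annotates; removes nothing)
  shortlist <- NULL
  if (!is.null(patient_terms) && !is.null(gene_terms) &&
      !is.null(ontology) && nrow(fusion_calls) > 0) {
    prio <- dplyr::bind_rows(lapply(samples, function(p) {
      calls <- fusion_calls[fusion_calls$sample_id == p, , drop = FALSE]
      if (nrow(calls) == 0) return(calls)
      if (is.null(patient_terms[[p]])) {
        calls$rank_score <- NA_real_
        calls$best_gene <- NA_character_
        calls$unscored <- TRUE
        calls$shortlisted <- FALSE
        return(calls)
      }
      prioritize_candidates(calls, patient_terms[[p]], gene_terms, ontology,
                            cutoff = rank_cutoff)$candidates
    }))
    fusion_calls <- prio
    shortlist <- prio[which(!is.na(prio$rank_score) & prio$shortlisted), ,
                      drop = FALSE]
    shortlist <- shortlist[order(shortlist$rank_score), , drop = FALSE]
  }
  attrition$phenotype <- note_stage("phenotype", after_cat, after_cat)

  report <- disposition |>
    dplyr::left_join(
      dplyr::select(categorized, -"sample_id"), by = "candidate_id") |>
    dplyr::mutate(kept = is.na(.data$removed_stage))
  params <- list(min_split = min_split, min_spanning = min_spanning,
                 normdb_min_reads = if (is.null(normal_db)) NA_integer_
                   else normal_db$metadata$min_reads,
                 fuzz_bp = fuzz_bp,
                 min_identity = cfg$min_identity,
                 min_query_coverage = cfg$min_query_coverage,
                 unbroken_coverage = cfg$unbroken_coverage,
                 rank_cutoff = rank_cutoff)
  list(report = report,
       categorized = categorized,
       fusion_calls = fusion_calls,
       attrition = dplyr::bind_rows(attrition),
       category_summary = if (nrow(categorized) > 0)
         category_counts(categorized, samples = samples) else NULL,
       shortlist = shortlist,
       params = params)
}
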