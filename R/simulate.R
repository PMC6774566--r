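# Deterministic generator of toy references, annotations, planted
# candidates of every category, alignment records, control cohorts and
# phenotype fixtures, so the entire pipeline is testable without any
# external download. Alignment records are synthesized directly at the
# table level (the pipeline's actual input), not by running an aligner.

#' Simulation configuration
#'
#' The defaults define the fixture cohort the test-suite and acceptance
#' checks run on: 4 patients and 3 controls over a two-chromosome toy
#' genome with ~20 genes; per patient, three under-supported candidates
#' (removed by the read-support rule), one candidate shared with a control
#' at 3 supporting reads (removed by the normal database), one candidate
#' shared between two patients (removed by cohort recurrence), and planted
#' candidates covering every decision-tree category including in-frame and
#' out-of-frame coding fusions with known coding offsets. Control events
#' are mostly single-read, mirroring the support profile of fusion calls in
#' normal tissue.
#'
#' @param seed mandatory integer seed (< 2^31 - 8).
#' @param n_controls number of control samples (>= 2).
#' @param control_private_events random private events per control.
#' @param control_single_read_frac fraction of private control events
#'   carrying a single supporting read.
#' @param max_support upper bound of the split/spanning support draw for
#'   retained candidates.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, n_controls = 3L, control_private_events = 6L,
                       control_single_read_frac = 0.8, max_support = 30L) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed == floor(seed),
            abs(seed) < 2^31 - 8,
            n_controls >= 2, control_private_events >= 0,
            control_single_read_frac >= 0, control_single_read_frac <= 1,
            max_support >= 1)
  structure(list(seed = as.integer(seed), n_controls = as.integer(n_controls),
                 control_private_events = as.integer(control_private_events),
                 control_single_read_frac = control_single_read_frac,
                 max_support = as.integer(max_support)),
            class = "sim_config")
}

sim_chrom_lengths <- function() c(chr1 = 100000L, chr2 = 60000L)

# Fixed gene inventory: positions are deterministic; sequence content is
# seeded. Exon i of a gene occupies [start + (i-1)*500, start + (i-1)*500
# + 199]. Coding genes have a CDS covering every exon (600 nt, 200 codons).
sim_gene_layout <- function() {
  tibble::tribble(
    ~symbol,   ~chrom, ~strand, ~start,  ~n_exons, ~coding,
    "HBB",     "chr1", "+",      1000L,  2L, FALSE,
    "IGHV1",   "chr1", "+",      5000L,  2L, FALSE,
    "CODA",    "chr1", "+",     10000L,  3L, TRUE,
    "RTA",     "chr1", "+",     20000L,  3L, FALSE,
    "RTB",     "chr1", "+",     22000L,  3L, FALSE,
    "SPACER1", "chr1", "+",     30000L,  2L, FALSE,
    "PARA1",   "chr1", "+",     40000L,  2L, FALSE,
    "MIDG",    "chr1", "+",     43000L,  2L, FALSE,
    "PARA2",   "chr1", "+",     46000L,  2L, FALSE,
    "CODB",    "chr1", "-",     60000L,  3L, TRUE,
    "GENW",    "chr1", "+",     65000L,  2L, FALSE,
    "NOVG",    "chr1", "+",     70000L,  4L, FALSE,
    "CODD",    "chr1", "+",     75000L,  3L, TRUE,
    "GENX",    "chr1", "+",     80000L,  2L, FALSE,
    "SPACER2", "chr1", "+",     84000L,  2L, FALSE,
    "GENY",    "chr1", "+",     88000L,  2L, FALSE,
    "IGKV1",   "chr2", "+",      5000L,  2L, FALSE,
    "CODC",    "chr2", "+",     15000L,  3L, TRUE,
    "GENZ",    "chr2", "-",     30000L,  2L, FALSE,
    "TRBV1",   "chr2", "+",     45000L,  2L, FALSE)
}

sim_exon_len <- function() 200L
sim_exon_step <- function() 500L

# genomic exon intervals (ascending) of a layout gene
sim_exons_of <- function(layout, symbol) {
  g <- layout[layout$symbol == symbol, ]
  stopifnot(nrow(g) == 1)
  i <- seq_len(g$n_exons)
  start <- g$start + (i - 1L) * sim_exon_step()
  tibble::tibble(symbol = symbol, chrom = g$chrom, strand = g$strand,
                 exon_genomic = i, start = start,
                 end = start + sim_exon_len() - 1L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_cds <- function(n_codons) {
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Build the toy reference bundle
#'
#' Generates a seeded two-chromosome genome, writes `genome.fa`,
#' `annotation.gtf` and `transcriptome.fa` (exon concatenation of every
#' transcript, reverse-complemented for minus-strand genes) into `dir`, and
#' parses the annotation back through [read_gene_models()]. The gene
#' inventory includes a globin-like abundant gene, two immunoglobulin
#' genes, a homolog pair with identical sequence, two adjacent same-strand
#' genes (read-through substrate) and coding genes with multi-exon CDS on
#' both strands. Identical seeds give byte-identical files.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list: `dir`, file paths, `layout`, `genome` (DNAStringSet),
#'   `tx_seqs` (DNAStringSet), `cds_seqs` (named character, coding genes),
#'   `index` (gene_model_index).
#' @export
make_toy_reference <- function(cfg, dir = tempfile("germfuse_ref_")) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  lens <- sim_chrom_lengths()
  layout <- sim_gene_layout()
  genome <- lapply(lens, function(n) strsplit(random_dna(n), "")[[1]])

  cds_seqs <- character(0)
  for (i in seq_len(nrow(layout))) {
    g <- layout[i, ]
    if (!g$coding) next
    cds <- random_cds(g$n_exons * sim_exon_len() / 3L)
    cds_seqs[[g$symbol]] <- cds
    laid <- if (g$strand == "-") revcomp_chr(cds) else cds
    exons <- sim_exons_of(layout, g$symbol)
    offset <- 0L
    for (j in seq_len(nrow(exons))) {
      piece <- substr(laid, offset + 1L, offset + sim_exon_len())
      genome[[g$chrom]][exons$start[j]:exons$end[j]] <- strsplit(piece, "")[[1]]
      offset <- offset + sim_exon_len()
    }
  }
  # homolog pair: PARA2's locus is a verbatim copy of PARA1's
  p1 <- layout[layout$symbol == "PARA1", ]
  p2 <- layout[layout$symbol == "PARA2", ]
  span_len <- (p1$n_exons - 1L) * sim_exon_step() + sim_exon_len()
  genome[["chr1"]][p2$start:(p2$start + span_len - 1L)] <-
    genome[["chr1"]][p1$start:(p1$start + span_len - 1L)]

  genome_ss <- Biostrings::DNAStringSet(vapply(genome, paste,
                                               character(1), collapse = ""))
  names(genome_ss) <- names(lens)

  gtf_lines <- character(0)
  tx_seqs <- character(0)
  for (i in seq_len(nrow(layout))) {
    g <- layout[i, ]
    exons <- sim_exons_of(layout, g$symbol)
    gene_id <- paste0("G_", g$symbol)
    tx_id <- paste0("T_", g$symbol)
    attr_base <- sprintf('gene_id "%s"; gene_name "%s"; transcript_id "%s";',
                         gene_id, g$symbol, tx_id)
    span <- c(min(exons$start), max(exons$end))
    line <- function(feature, s, e, frame = ".", extra = "") {
      sprintf("%s\tgermfuse_sim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              g$chrom, feature, s, e, g$strand, frame,
              paste(attr_base, extra))
    }
    gtf_lines <- c(gtf_lines, line("gene", span[1], span[2]),
                   line("transcript", span[1], span[2]))
    order_tx <- if (g$strand == "-") rev(seq_len(nrow(exons))) else
      seq_len(nrow(exons))
    for (rank in seq_along(order_tx)) {
      j <- order_tx[rank]
      gtf_lines <- c(gtf_lines,
                     line("exon", exons$start[j], exons$end[j],
                          extra = sprintf('exon_number "%d";', rank)))
      if (g$coding) {
        phase <- (3L - ((rank - 1L) * sim_exon_len()) %% 3L) %% 3L
        gtf_lines <- c(gtf_lines,
                       line("CDS", exons$start[j], exons$end[j],
                            frame = as.character(phase),
                            extra = sprintf('exon_number "%d";', rank)))
      }
    }
    spliced <- paste(vapply(seq_len(nrow(exons)), function(j) {
      paste(genome[[g$chrom]][exons$start[j]:exons$end[j]], collapse = "")
    }, character(1)), collapse = "")
    tx_seqs[[tx_id]] <- if (g$strand == "-") revcomp_chr(spliced) else spliced
  }

  genome_fa <- file.path(dir, "genome.fa")
  gtf_path <- file.path(dir, "annotation.gtf")
  tx_fa <- file.path(dir, "transcriptome.fa")
  Biostrings::writeXStringSet(genome_ss, genome_fa)
  writeLines(gtf_lines, gtf_path)
  tx_ss <- Biostrings::DNAStringSet(tx_seqs)
  Biostrings::writeXStringSet(tx_ss, tx_fa)

  list(dir = dir, genome_fa = genome_fa, gtf = gtf_path,
       transcriptome_fa = tx_fa, layout = layout, genome = genome_ss,
       tx_seqs = tx_ss, cds_seqs = cds_seqs,
       index = read_gene_models(gtf_path))
}

# 1-based inclusive genome slice as a character string
ref_slice <- function(ref, chrom, start, end, revcomp = FALSE) {
  s <- as.character(Biostrings::subseq(ref$genome[[chrom]], start, end))
  if (revcomp) revcomp_chr(s) else s
}

sim_hit <- function(qid, db, sseqid, sstart, send, qstart, qend,
                    pident = 100) {
  len <- qend - qstart + 1L
  tibble::tibble(qseqid = qid, sseqid = sseqid, pident = pident,
                 length = len, mismatch = 0L, gapopen = 0L,
                 qstart = qstart, qend = qend, sstart = sstart, send = send,
                 evalue = 1e-20, bitscore = 2 * len, subject_db = db)
}

# one planted candidate + its synthesized alignment records + truth row
plant_one <- function(ref, pid, name, spec, support) {
  id <- paste0(pid, "_", name)
  seg_hit <- function(kind, h) {
    if (is.null(h)) return(NULL)
    sim_hit(paste0(id, "|", kind), h$db, h$sseqid, h$sstart, h$send,
            h$qstart, h$qend, pident = if (is.null(h$pident)) 100 else
              h$pident)
  }
  cand <- tibble::tibble(
    candidate_id = id, sample_id = pid,
    chrom5 = spec$chrom5, pos5 = spec$pos5, strand5 = spec$strand5,
    chrom3 = spec$chrom3, pos3 = spec$pos3, strand3 = spec$strand3,
    split_reads = support[1], spanning_reads = support[2],
    seq_full = if (!is.na(spec$seq5) && !is.na(spec$seq3))
      paste0(spec$seq5, spec$seq3) else spec$seq_full,
    seq5 = spec$seq5, seq3 = spec$seq3)
  hits <- dplyr::bind_rows(
    seg_hit("full", spec$hit_full),
    seg_hit("seg5", spec$hit5),
    seg_hit("seg3", spec$hit3))
  truth <- tibble::tibble(
    candidate_id = id, sample_id = pid,
    true_category = spec$category,
    true_read_through = isTRUE(spec$read_through),
    true_read_through_strict = isTRUE(spec$read_through_strict),
    true_homologous = isTRUE(spec$homologous),
    true_frame = if (is.null(spec$frame)) NA_character_ else spec$frame,
    expected_disposition = spec$disposition)
  list(candidate = cand, hits = hits, truth = truth)
}

# planted-candidate blueprints; coordinates derive from the fixed layout
sim_blueprints <- function(ref) {
  layout <- ref$layout
  ex <- function(sym, i) sim_exons_of(layout, sym)[i, ]
  g <- function(sym) layout[layout$symbol == sym, ]
  slice <- function(sym_exon, from, len, revcomp = FALSE) {
    ref_slice(ref, sym_exon$chrom, from, from + len - 1L, revcomp = revcomp)
  }
  ghit <- function(chrom, sstart, send, qstart, qend, pident = 100) {
    list(db = "genome", sseqid = chrom, sstart = sstart, send = send,
         qstart = qstart, qend = qend, pident = pident)
  }
  thit <- function(tx, sstart, send, qstart, qend) {
    list(db = "transcriptome", sseqid = tx, sstart = sstart, send = send,
         qstart = qstart, qend = qend, pident = 100)
  }
  bp <- function(sym5, pos5, sym3, pos3) {
    list(chrom5 = g(sym5)$chrom, pos5 = pos5,
         strand5 = ifelse(g(sym5)$strand == "-", "reverse", "forward"),
         chrom3 = g(sym3)$chrom, pos3 = pos3,
         strand3 = ifelse(g(sym3)$strand == "-", "reverse", "forward"))
  }

  blue <- list()

  # A: abundant gene (globin) involvement trumps everything else
  e <- ex("HBB", 1); x <- ex("GENX", 1)
  blue$ABUND <- c(bp("HBB", e$start + 159L, "GENX", x$start + 100L), list(
    seq5 = slice(e, e$start + 100L, 60L),
    seq3 = slice(x, x$start + 100L, 50L), seq_full = NA_character_,
    hit5 = ghit(e$chrom, e$start + 100L, e$start + 159L, 1L, 60L),
    hit3 = ghit(x$chrom, x$start + 100L, x$start + 149L, 1L, 50L),
    hit_full = NULL,
    category = "EXCLUDED_ABUNDANT", disposition = "categorization"))

  # B: full contig matches one transcript without interruption
  e1 <- ex("CODA", 1); e2 <- ex("CODA", 2)
  blue$KNOWN <- c(bp("CODA", e1$end, "CODA", e2$start), list(
    seq5 = slice(e1, e1$end - 59L, 60L),
    seq3 = slice(e2, e2$start, 60L), seq_full = NA_character_,
    hit5 = ghit(e1$chrom, e1$end - 59L, e1$end, 1L, 60L),
    hit3 = ghit(e2$chrom, e2$start, e2$start + 59L, 1L, 60L),
    hit_full = thit("T_CODA", 141L, 260L, 1L, 120L),
    category = "KNOWN_TRANSCRIPT", disposition = "categorization"))

  # C: full contig is one contiguous (intergenic) genomic block
  blue$GENOMIC <- c(list(chrom5 = "chr1", pos5 = 50559L, strand5 = "forward",
                         chrom3 = "chr1", pos3 = 50560L,
                         strand3 = "forward"),
                    list(
    seq5 = ref_slice(ref, "chr1", 50500L, 50559L),
    seq3 = ref_slice(ref, "chr1", 50560L, 50619L), seq_full = NA_character_,
    hit5 = ghit("chr1", 50500L, 50559L, 1L, 60L),
    hit3 = ghit("chr1", 50560L, 50619L, 1L, 60L),
    hit_full = ghit("chr1", 50500L, 50619L, 1L, 120L),
    category = "GENOMIC_SEQUENCE", disposition = "categorization"))

  # D: no surviving alignment (the one decoy hit fails the identity gate)
  blue$ARTIF <- c(list(chrom5 = "chr1", pos5 = 3000L, strand5 = "forward",
                       chrom3 = "chr2", pos3 = 1000L, strand3 = "forward"),
                  list(
    seq5 = random_dna(60L), seq3 = random_dna(50L), seq_full = NA_character_,
    hit5 = NULL, hit3 = NULL,
    hit_full = ghit("chr1", 200L, 309L, 1L, 110L, pident = 85),
    category = "LIKELY_ARTIFACT", disposition = "categorization"))

  # E: both segments inside one gene, no full transcript match (exon skip)
  n1 <- ex("NOVG", 1); n3 <- ex("NOVG", 3)
  blue$NOVEL <- c(bp("NOVG", n1$end, "NOVG", n3$start), list(
    seq5 = slice(n1, n1$end - 59L, 60L),
    seq3 = slice(n3, n3$start, 50L), seq_full = NA_character_,
    hit5 = ghit(n1$chrom, n1$end - 59L, n1$end, 1L, 60L),
    hit3 = ghit(n3$chrom, n3$start, n3$start + 49L, 1L, 50L),
    hit_full = NULL,
    category = "NOVEL_TRANSCRIPT_SINGLE_GENE",
    disposition = "categorization"))

  # F: two separate immunoglobulin loci (precedes the interchromosomal call)
  ih <- ex("IGHV1", 1); ik <- ex("IGKV1", 1)
  blue$IMMUNE <- c(bp("IGHV1", ih$start + 159L, "IGKV1", ik$start + 100L),
                   list(
    seq5 = slice(ih, ih$start + 100L, 60L),
    seq3 = slice(ik, ik$start + 100L, 50L), seq_full = NA_character_,
    hit5 = ghit(ih$chrom, ih$start + 100L, ih$start + 159L, 1L, 60L),
    hit3 = ghit(ik$chrom, ik$start + 100L, ik$start + 149L, 1L, 50L),
    hit_full = NULL,
    category = "IMMUNE_DIVERSITY", disposition = "categorization"))

  # G: interchromosomal coding fusion at exon edges; coding offsets 400 vs
  # 200 break the downstream codon phase (out of frame)
  a2 <- ex("CODA", 2); c2 <- ex("CODC", 2)
  blue$INTER_OOF <- c(bp("CODA", a2$end, "CODC", c2$start), list(
    seq5 = slice(a2, a2$end - 59L, 60L),
    seq3 = slice(c2, c2$start, 50L), seq_full = NA_character_,
    hit5 = ghit(a2$chrom, a2$end - 59L, a2$end, 1L, 60L),
    hit3 = ghit(c2$chrom, c2$start, c2$start + 49L, 1L, 50L),
    hit_full = NULL,
    category = "INTERCHROMOSOMAL_FUSION", frame = "out_of_frame",
    disposition = "retained"))

  # H (in frame): minus-strand CODB exon 2 junction edge to CODD exon 3;
  # both partners contribute 400 coding nt upstream of the junction
  b2 <- ex("CODB", 2); d3 <- ex("CODD", 3)
  blue$INTRA_IF <- c(bp("CODB", b2$start, "CODD", d3$start), list(
    seq5 = slice(b2, b2$start, 60L, revcomp = TRUE),
    seq3 = slice(d3, d3$start, 50L), seq_full = NA_character_,
    hit5 = ghit(b2$chrom, b2$start + 59L, b2$start, 1L, 60L),
    hit3 = ghit(d3$chrom, d3$start, d3$start + 49L, 1L, 50L),
    hit_full = NULL,
    category = "INTRACHROMOSOMAL_FUSION", frame = "in_frame",
    disposition = "retained"))

  # H + read-through: adjacent same-strand genes
  r2 <- ex("RTA", 2); rb1 <- ex("RTB", 1)
  blue$INTRA_RT <- c(bp("RTA", r2$end, "RTB", rb1$start), list(
    seq5 = slice(r2, r2$end - 59L, 60L),
    seq3 = slice(rb1, rb1$start, 50L), seq_full = NA_character_,
    hit5 = ghit(r2$chrom, r2$end - 59L, r2$end, 1L, 60L),
    hit3 = ghit(rb1$chrom, rb1$start, rb1$start + 49L, 1L, 50L),
    hit_full = NULL,
    category = "INTRACHROMOSOMAL_FUSION", read_through = TRUE,
    read_through_strict = TRUE, disposition = "retained"))

  # H + homolog flag: the duplicated loci (another gene lies between them)
  p1 <- ex("PARA1", 1); p2 <- ex("PARA2", 1)
  blue$INTRA_HOM <- c(bp("PARA1", p1$start + 159L, "PARA2", p2$start + 100L),
                      list(
    seq5 = slice(p1, p1$start + 100L, 60L),
    seq3 = slice(p2, p2$start + 100L, 50L), seq_full = NA_character_,
    hit5 = ghit(p1$chrom, p1$start + 100L, p1$start + 159L, 1L, 60L),
    hit3 = ghit(p2$chrom, p2$start + 100L, p2$start + 149L, 1L, 50L),
    hit_full = NULL,
    category = "INTRACHROMOSOMAL_FUSION", homologous = TRUE,
    disposition = "retained"))

  # H plain: two distinct same-chromosome genes, non-adjacent, non-homolog
  x1 <- ex("GENX", 1); y1 <- ex("GENY", 1)
  blue$INTRA_PLAIN <- c(bp("GENX", x1$end, "GENY", y1$start), list(
    seq5 = slice(x1, x1$end - 59L, 60L),
    seq3 = slice(y1, y1$start, 50L), seq_full = NA_character_,
    hit5 = ghit(x1$chrom, x1$end - 59L, x1$end, 1L, 60L),
    hit3 = ghit(y1$chrom, y1$start, y1$start + 49L, 1L, 50L),
    hit_full = NULL,
    category = "INTRACHROMOSOMAL_FUSION", disposition = "retained"))

  # A (T-cell receptor family): abundant exclusion on the pattern lists
  t1 <- ex("TRBV1", 1); z1 <- ex("GENZ", 1)
  blue$ABUND_TR <- c(bp("TRBV1", t1$start + 159L, "GENZ", z1$start + 100L),
                     list(
    seq5 = slice(t1, t1$start + 100L, 60L),
    seq3 = slice(z1, z1$start + 100L, 50L), seq_full = NA_character_,
    hit5 = ghit(t1$chrom, t1$start + 100L, t1$start + 159L, 1L, 60L),
    hit3 = ghit(z1$chrom, z1$start + 100L, z1$start + 149L, 1L, 50L),
    hit_full = NULL,
    category = "EXCLUDED_ABUNDANT", disposition = "categorization"))

  blue
}

# coordinates used by the non-category plants (shared keys)
sim_shared_coords <- function() {
  list(
    norm = list(chrom5 = "chr1", pos5 = 80150L, strand5 = "forward",
                chrom3 = "chr2", pos3 = 30150L, strand3 = "reverse"),
    cohort = list(chrom5 = "chr1", pos5 = 43100L, strand5 = "forward",
                  chrom3 = "chr1", pos3 = 80050L, strand3 = "forward"),
    depth = list(
      list(chrom5 = "chr1", pos5 = 65100L, strand5 = "forward",
           chrom3 = "chr1", pos3 = 30100L, strand3 = "forward"),
      list(chrom5 = "chr1", pos5 = 65150L, strand5 = "forward",
           chrom3 = "chr2", pos3 = 5250L, strand3 = "forward"),
      list(chrom5 = "chr2", pos5 = 15100L, strand5 = "forward",
           chrom3 = "chr2", pos3 = 45250L, strand3 = "forward")))
}

#' Plant the patient cohort: candidates, alignment records, truth labels
#'
#' Four patients receive, between them, at least one candidate of every
#' decision-tree category (with flags and coding-frame truths), plus
#' per-patient under-supported candidates, one candidate shared with the
#' control cohort at database-level support, and one candidate shared
#' between two patients. Alignment records are synthesized directly with
#' identities/coverages that respect or violate the 90%/75% gates according
#' to the planted truth.
#'
#' @param cfg a [sim_config()].
#' @param ref a [make_toy_reference()] bundle.
#' @return list: `patients` (named list of candidate tibbles), `hits`
#'   (combined 12-column records with `subject_db`), `truth` (one row per
#'   candidate), `homolog_pairs` (tibble).
#' @export
plant_candidates <- function(cfg, ref) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  blue <- sim_blueprints(ref)
  shared <- sim_shared_coords()
  pids <- paste0("P", 1:4)
  assign_map <- list(
    P1 = c("ABUND", "KNOWN", "GENOMIC"),
    P2 = c("ARTIF", "NOVEL", "IMMUNE"),
    P3 = c("INTER_OOF", "INTRA_IF", "INTRA_RT"),
    P4 = c("INTRA_HOM", "INTRA_PLAIN", "ABUND_TR"))
  support_draw <- function() {
    c(sample(seq_len(cfg$max_support), 1), sample(seq_len(cfg$max_support), 1))
  }
  depth_supports <- list(c(0L, 4L), c(5L, 0L), c(0L, 0L))

  patients <- list(); hits <- list(); truth <- list()
  for (pid in pids) {
    rows <- list(); t_rows <- list()
    for (k in seq_along(shared$depth)) {
      p <- plant_one(ref, pid, paste0("DF", k),
                     c(shared$depth[[k]],
                       list(seq5 = NA_character_, seq3 = NA_character_,
                            seq_full = NA_character_, hit5 = NULL,
                            hit3 = NULL, hit_full = NULL,
                            category = NA_character_,
                            disposition = "depth")),
                     depth_supports[[k]])
      rows <- c(rows, list(p$candidate)); t_rows <- c(t_rows, list(p$truth))
    }
    p <- plant_one(ref, pid, "NORM",
                   c(shared$norm,
                     list(seq5 = NA_character_, seq3 = NA_character_,
                          seq_full = NA_character_, hit5 = NULL,
                          hit3 = NULL, hit_full = NULL,
                          category = NA_character_,
                          disposition = "normal_db")),
                   c(2L, 2L))
    rows <- c(rows, list(p$candidate)); t_rows <- c(t_rows, list(p$truth))
    if (pid %in% c("P1", "P2")) {
      p <- plant_one(ref, pid, "COH",
                     c(shared$cohort,
                       list(seq5 = NA_character_, seq3 = NA_character_,
                            seq_full = NA_character_, hit5 = NULL,
                            hit3 = NULL, hit_full = NULL,
                            category = NA_character_,
                            disposition = "cohort")),
                     c(3L, 3L))
      rows <- c(rows, list(p$candidate)); t_rows <- c(t_rows, list(p$truth))
    }
    for (name in assign_map[[pid]]) {
      p <- plant_one(ref, pid, name, blue[[name]], support_draw())
      rows <- c(rows, list(p$candidate))
      t_rows <- c(t_rows, list(p$truth))
      hits <- c(hits, list(p$hits))
    }
    patients[[pid]] <- as_candidate_set(dplyr::bind_rows(rows))
    truth <- c(truth, t_rows)
  }
  list(patients = patients,
       hits = dplyr::bind_rows(hits),
       truth = dplyr::bind_rows(truth),
       homolog_pairs = tibble::tibble(geneA = "PARA1", geneB = "PARA2"))
}

#' Generate the control cohort
#'
#' Control 1 carries the patient-shared event at 3 supporting reads (so the
#' normal database removes the patient copies); control 2 carries the
#' read-through event's key at a single supporting read (insufficient
#' evidence, so the patient copy survives); each control additionally
#' carries seeded private events, mostly single-read.
#'
#' @param cfg a [sim_config()].
#' @param ref a [make_toy_reference()] bundle.
#' @return named list of control candidate tibbles.
#' @export
make_control_cohort <- function(cfg, ref) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  shared <- sim_shared_coords()
  rt <- sim_blueprints(ref)$INTRA_RT
  lens <- sim_chrom_lengths()
  controls <- list()
  for (i in seq_len(cfg$n_controls)) {
    cid <- paste0("N", i)
    rows <- list()
    if (i == 1) {
      rows <- c(rows, list(tibble::tibble(
        sample_id = cid, chrom5 = shared$norm$chrom5,
        pos5 = shared$norm$pos5, strand5 = shared$norm$strand5,
        chrom3 = shared$norm$chrom3, pos3 = shared$norm$pos3,
        strand3 = shared$norm$strand3, split_reads = 2L,
        spanning_reads = 1L)))
    }
    if (i == 2) {
      rows <- c(rows, list(tibble::tibble(
        sample_id = cid, chrom5 = rt$chrom5, pos5 = rt$pos5,
        strand5 = rt$strand5, chrom3 = rt$chrom3, pos3 = rt$pos3,
        strand3 = rt$strand3, split_reads = 1L, spanning_reads = 0L)))
    }
    for (k in seq_len(cfg$control_private_events)) {
      chroms <- sample(names(lens), 2, replace = TRUE)
      single <- stats::runif(1) < cfg$control_single_read_frac
      rows <- c(rows, list(tibble::tibble(
        sample_id = cid, chrom5 = chroms[1],
        pos5 = sample(lens[[chroms[1]]], 1),
        strand5 = sample(c("forward", "reverse"), 1),
        chrom3 = chroms[2], pos3 = sample(lens[[chroms[2]]], 1),
        strand3 = sample(c("forward", "reverse"), 1),
        split_reads = 1L, spanning_reads = if (single) 0L else 1L)))
    }
    controls[[cid]] <- as_candidate_set(dplyr::bind_rows(rows),
                                        sample_id = cid)
  }
  controls
}

sim_ontology <- function() {
  phenotype_ontology(
    tibble::tibble(id = c("HP:0000001", "HP:0000118", "HP:0001250",
                          "HP:0001251", "HP:0002011", "HP:0003155",
                          "HP:0000924", "HP:0004322", "HP:0002719"),
                   name = c("All", "Phenotypic abnormality", "Seizure",
                            "Ataxia", "CNS abnormality",
                            "Skeletal abnormality", "Exostoses",
                            "Short stature", "Immune abnormality")),
    list("HP:0000118" = "HP:0000001", "HP:0001250" = "HP:0000118",
         "HP:0001251" = "HP:0000118", "HP:0002011" = "HP:0000118",
         "HP:0003155" = "HP:0000118", "HP:0000924" = "HP:0003155",
         "HP:0004322" = "HP:0003155", "HP:0002719" = "HP:0000118"))
}

sim_gene_terms <- function(cfg) {
  set.seed(cfg$seed + 3L)
  fixed <- tibble::tribble(
    ~gene, ~term,
    "CODD", "HP:0000924",
    "CODD", "HP:0004322",
    "CODB", "HP:0001250",
    "CODA", "HP:0001251",
    "CODC", "HP:0002719",
    "RTA",  "HP:0002011",
    "RTB",  "HP:0002011")
  others <- setdiff(sim_gene_layout()$symbol, fixed$gene)
  leaves <- c("HP:0001250", "HP:0001251", "HP:0002011", "HP:0000924",
              "HP:0004322", "HP:0002719")
  dplyr::bind_rows(fixed, tibble::tibble(
    gene = others, term = sample(leaves, length(others), replace = TRUE)))
}

sim_patient_terms <- function() {
  list(P1 = c("HP:0001251"), P2 = c("HP:0002719"),
       P3 = c("HP:0000924", "HP:0004322"), P4 = c("HP:0002011"))
}

#' Generate the complete synthetic cohort
#'
#' One call builds the reference bundle, patient cohort, control cohort,
#' normal database inputs, phenotype fixtures and truth labels. Fully
#' deterministic under the seed.
#'
#' @param cfg a [sim_config()].
#' @param dir reference output directory (temp dir by default).
#' @return list: `config`, `ref`, `patients`, `controls`, `hits`, `truth`,
#'   `homologs` ([homolog_set()]), `abundant`, `immunoglobulin`,
#'   `patient_terms`, `gene_terms`, `ontology`.
#' @export
simulate_cohort <- function(cfg, dir = tempfile("germfuse_sim_")) {
  ref <- make_toy_reference(cfg, dir = file.path(dir, "ref"))
  planted <- plant_candidates(cfg, ref)
  controls <- make_control_cohort(cfg, ref)
  list(config = cfg, ref = ref,
       patients = planted$patients, controls = controls,
       hits = planted$hits, truth = planted$truth,
       homologs = homolog_set(planted$homolog_pairs),
       abundant = default_abundant_list(),
       immunoglobulin = default_immunoglobulin_list(),
       patient_terms = sim_patient_terms(),
       gene_terms = sim_gene_terms(cfg),
       ontology = sim_ontology())
}

#' Write a simulated cohort as a file bundle
#'
#' Emits every input the pipeline consumes (candidate TSVs, alignment
#' record TSVs, reference FASTA/GTF, homolog pairs, gene lists, phenotype
#' tables) plus `truth.tsv`, so a complete run can be reproduced from files
#' alone.
#'
#' @param sim a [simulate_cohort()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in c("genome_fa", "gtf", "transcriptome_fa")) {
    file.copy(sim$ref[[f]], dir, overwrite = TRUE)
  }
  for (pid in names(sim$patients)) {
    readr::write_tsv(sim$patients[[pid]],
                     file.path(dir, paste0("candidates_", pid, ".tsv")),
                     na = "NA", progress = FALSE)
  }
  for (cid in names(sim$controls)) {
    readr::write_tsv(sim$controls[[cid]],
                     file.path(dir, paste0("control_", cid, ".tsv")),
                     na = "NA", progress = FALSE)
  }
  twelve <- alignment_hit_columns()
  readr::write_tsv(sim$hits[sim$hits$subject_db == "genome", twelve],
                   file.path(dir, "hits_genome.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(sim$hits[sim$hits$subject_db == "transcriptome", twelve],
                   file.path(dir, "hits_transcriptome.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(tibble::tibble(geneA = "PARA1", geneB = "PARA2"),
                   file.path(dir, "homologs.tsv"), col_names = FALSE,
                   progress = FALSE)
  readr::write_tsv(sim$gene_terms, file.path(dir, "gene_terms.tsv"),
                   progress = FALSE)
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), na = "NA",
                   progress = FALSE)
  invisible(dir)
}
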