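# Phenotype-driven prioritization of fusion-call candidates. The similarity
# scorer is pluggable; the default measures, for each patient term, the
# information content of the most informative common ancestor shared with
# any of a gene's terms, averaged over patient terms. Genes are then ranked
# and reported as a rank-score: rank divided by the number of scored genes,
# so 0.01 means the gene scores in the top 1% of the scored disease-gene
# set.

#' Read a minimal OBO-format ontology
#'
#' Parses `[Term]` stanzas for `id:`, `name:` and `is_a:` lines, which is
#' all the default scorer needs (the term hierarchy).
#'
#' @param path OBO file path.
#' @return object of class `phenotype_ontology`: `terms` tibble (`id`,
#'   `name`) and `parents` (named list of parent term ids).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  ids <- character(0); names_ <- character(0); parents <- list()
  cur <- NULL
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) {
      ids <<- c(ids, cur$id)
      names_ <<- c(names_, if (is.null(cur$name)) NA_character_ else cur$name)
      parents[[cur$id]] <<- cur$parents
    }
  }
  for (line in lines) {
    line <- trimws(line)
    if (line == "[Term]") {
      flush(); cur <- list(parents = character(0))
    } else if (grepl("^\\[", line)) {
      flush(); cur <- NULL
    } else if (!is.null(cur)) {
      if (startsWith(line, "id:")) {
        cur$id <- trimws(sub("^id:", "", line))
      } else if (startsWith(line, "name:")) {
        cur$name <- trimws(sub("^name:", "", line))
      } else if (startsWith(line, "is_a:")) {
        target <- trimws(sub("^is_a:", "", line))
        target <- trimws(sub("!.*$", "", target))
        cur$parents <- c(cur$parents, target)
      }
    }
  }
  flush()
  phenotype_ontology(tibble::tibble(id = ids, name = names_), parents)
}

#' Construct an ontology from terms and parent links
#'
#' @param terms tibble with `id` (and optionally `name`).
#' @param parents named list mapping a term id to its parent id(s).
#' @return object of class `phenotype_ontology`.
#' @export
phenotype_ontology <- function(terms, parents) {
  terms <- tibble::as_tibble(terms)
  if (!"name" %in% names(terms)) terms$name <- NA_character_
  structure(list(terms = terms, parents = parents),
            class = "phenotype_ontology")
}

#' @export
print.phenotype_ontology <- function(x, ...) {
  cat(sprintf("<phenotype_ontology: %d term(s)>\n", nrow(x$terms)))
  invisible(x)
}

#' Ancestors of a term (including itself)
#'
#' @param ontology a [phenotype_ontology()].
#' @param term term id.
#' @return character vector of ancestor term ids (self included); empty for
#'   unknown terms.
#' @export
term_ancestors <- function(ontology, term) {
  stopifnot(inherits(ontology, "phenotype_ontology"))
  if (!term %in% ontology$terms$id) return(character(0))
  seen <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    seen <- union(seen, frontier)
    frontier <- setdiff(
      unique(unlist(ontology$parents[frontier], use.names = FALSE)), seen)
    frontier <- frontier[frontier %in% ontology$terms$id]
  }
  seen
}

#' Information content of ontology terms from a gene-term table
#'
#' Annotations are propagated to ancestors: a gene annotated to a term is
#' implicitly annotated to all its ancestors. The information content of a
#' term is `-log(fraction of genes annotated to it)`; the root of the
#' hierarchy, carrying every annotated gene, has information content 0.
#'
#' @param gene_terms tibble with `gene` and `term` columns.
#' @param ontology a [phenotype_ontology()].
#' @return named numeric vector of information contents (terms with no
#'   annotated gene are absent).
#' @export
information_content <- function(gene_terms, ontology) {
  genes <- unique(gene_terms$gene)
  n_genes <- length(genes)
  if (n_genes == 0) return(stats::setNames(numeric(0), character(0)))
  per_gene <- lapply(split(gene_terms$term, gene_terms$gene), function(terms) {
    unique(unlist(lapply(unique(terms), term_ancestors,
                         ontology = ontology)))
  })
  counts <- table(unlist(per_gene, use.names = FALSE))
  ic <- -log(as.numeric(counts) / n_genes)
  stats::setNames(ic, names(counts))
}

#' Phenotype similarity between a patient and one gene (default scorer)
#'
#' Mean, over the patient's terms, of the maximum information content of the
#' most informative common ancestor shared with any of the gene's terms.
#' Disjoint term sets whose only common ancestor is the root score 0.
#' Unknown term ids are skipped with a warning; empty term sets score 0.
#'
#' @param patient_terms character vector of the patient's phenotype term ids.
#' @param gene_term_ids character vector of the gene's term ids.
#' @param ontology a [phenotype_ontology()].
#' @param ic precomputed [information_content()] vector.
#' @return non-negative numeric score.
#' @export
similarity_score <- function(patient_terms, gene_term_ids, ontology, ic) {
  known <- function(terms, who) {
    unknown <- setdiff(terms, ontology$terms$id)
    if (length(unknown) > 0) {
      rlang::warn(sprintf("unknown %s term(s) skipped: %s", who,
                          paste(unknown, collapse = ", ")))
    }
    setdiff(terms, unknown)
  }
  patient_terms <- known(unique(patient_terms), "patient")
  gene_term_ids <- known(unique(gene_term_ids), "gene")
  if (length(patient_terms) == 0 || length(gene_term_ids) == 0) return(0)
  gene_anc <- lapply(gene_term_ids, term_ancestors, ontology = ontology)
  per_term <- vapply(patient_terms, function(p) {
    p_anc <- term_ancestors(ontology, p)
    best <- 0
    for (g_anc in gene_anc) {
      common <- intersect(p_anc, g_anc)
      common_ic <- ic[common]
      common_ic <- common_ic[!is.na(common_ic)]
      if (length(common_ic) > 0) best <- max(best, max(common_ic))
    }
    best
  }, numeric(1))
  mean(per_term)
}

#' Rank-scores from raw similarity scores
#'
#' Genes are ranked by descending raw score; ties receive the minimum rank
#' of the tied block (so ties never worsen a gene's rank-score); the
#' rank-score is rank divided by the number of scored genes. The top gene of
#' 100 scores 0.01; the worst of any set scores 1 (absent ties).
#'
#' @param scores named numeric vector (gene -> raw score) or tibble with
#'   `gene` and `raw_score`.
#' @return tibble: `gene`, `raw_score`, `rank`, `rank_score`, ordered by
#'   ascending rank then gene.
#' @export
rank_scores <- function(scores) {
  if (is.data.frame(scores)) {
    genes <- scores$gene; raw <- scores$raw_score
  } else {
    genes <- names(scores); raw <- unname(scores)
  }
  stopifnot(length(genes) >= 1)
  rank <- rank(-raw, ties.method = "min")
  out <- tibble::tibble(gene = genes, raw_score = raw,
                        rank = as.integer(rank),
                        rank_score = rank / length(genes))
  dplyr::arrange(out, .data$rank, .data$gene)
}

#' Phenotype-prioritize categorized fusion candidates
#'
#' Scores every gene of the association table against the patient's terms,
#' converts to rank-scores, and annotates each fusion-call candidate with
#' the better (smaller) rank-score of its two partner genes. Candidates at
#' or under the cutoff are flagged `shortlisted`; all candidates stay in the
#' output with their scores (manual review remains a human step). Candidates
#' with neither gene in the association table are flagged `unscored`.
#'
#' @param categorized categorized candidate tibble (fusion-call rows are
#'   scored; other rows pass through unscored).
#' @param patient_terms patient phenotype term ids.
#' @param gene_terms gene-to-term association tibble (`gene`, `term`).
#' @param ontology a [phenotype_ontology()].
#' @param cutoff rank-score shortlist cutoff (default 0.05).
#' @param categories categories eligible for scoring.
#' @param scorer similarity function with the signature of
#'   [similarity_score()] (pluggable).
#' @return list: `candidates` (input plus `rank_score`, `best_gene`,
#'   `unscored`, `shortlisted`), `gene_ranks` (full rank table),
#'   `shortlist` (ascending rank-score).
#' @export
prioritize_candidates <- function(categorized, patient_terms, gene_terms,
                                  ontology, cutoff = 0.05,
                                  categories = fusion_call_categories(),
                                  scorer = similarity_score) {
  gene_terms <- tibble::as_tibble(gene_terms)
  ic <- information_content(gene_terms, ontology)
  by_gene <- split(gene_terms$term, gene_terms$gene)
  raw <- vapply(by_gene, function(terms) {
    scorer(patient_terms, unique(terms), ontology, ic)
  }, numeric(1))
  ranks <- rank_scores(raw)
  rs <- stats::setNames(ranks$rank_score, ranks$gene)
  eligible <- categorized$category %in% categories
  pick <- function(g5, g3) {
    vals <- rs[c(g5, g3)]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(c(NA_real_, NA_character_))
    best <- which.min(vals)
    c(vals[best], names(vals)[best])
  }
  n <- nrow(categorized)
  rank_score <- rep(NA_real_, n)
  best_gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (!eligible[i]) next
    p <- pick(categorized$gene5[i], categorized$gene3[i])
    rank_score[i] <- as.numeric(p[1])
    best_gene[i] <- p[2]
  }
  out <- categorized
  out$rank_score <- rank_score
  out$best_gene <- best_gene
  out$unscored <- eligible & is.na(rank_score)
  out$shortlisted <- !is.na(rank_score) & rank_score <= cutoff
  shortlist <- out[out$shortlisted, , drop = FALSE]
  shortlist <- shortlist[order(shortlist$rank_score), , drop = FALSE]
  list(candidates = out, gene_ranks = ranks, shortlist = shortlist)
}
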