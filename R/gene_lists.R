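# Symbol lists (abundant blood genes, immunoglobulins) and homologous-gene
# pairs. Symbol matching is case-insensitive and supports glob patterns so a
# short editable list like "TRB*" covers a whole locus family.

#' Gene symbol set with glob-pattern matching
#'
#' @param symbols character vector of symbols and/or glob patterns
#'   (e.g. `"HBB"`, `"TRB*"`).
#' @param name label for the list (`"abundant_blood"`, `"immunoglobulin"`,
#'   or any custom string).
#' @return object of class `gene_symbol_set`.
#' @export
gene_symbol_set <- function(symbols, name = "custom") {
  symbols <- unique(trimws(as.character(symbols)))
  symbols <- symbols[symbols != ""]
  if (length(symbols) > 0 && any(is.na(symbols))) {
    rlang::abort("gene list patterns must be non-empty strings")
  }
  structure(
    list(name = name, symbols = symbols,
         regex = vapply(symbols, function(s) utils::glob2rx(toupper(s)),
                        character(1))),
    class = "gene_symbol_set")
}

#' @export
print.gene_symbol_set <- function(x, ...) {
  cat(sprintf("<gene_symbol_set '%s': %d pattern(s)>\n",
              x$name, length(x$symbols)))
  invisible(x)
}

#' Test symbols against a gene list
#'
#' @param set a [gene_symbol_set()].
#' @param symbols character vector of gene symbols.
#' @return logical vector: does each symbol match any pattern in the set?
#'   NA symbols match nothing.
#' @export
matches_symbol_set <- function(set, symbols) {
  stopifnot(inherits(set, "gene_symbol_set"))
  if (length(set$regex) == 0) return(rep(FALSE, length(symbols)))
  up <- toupper(symbols)
  out <- rep(FALSE, length(symbols))
  for (rx in set$regex) {
    out <- out | !is.na(up) & grepl(rx, up)
  }
  out
}

#' Read a plain-text gene list
#'
#' One symbol or glob pattern per line; `#` comments and blank lines ignored.
#'
#' @param path file path.
#' @param name list label.
#' @return a [gene_symbol_set()].
#' @export
read_gene_list <- function(path, name = "custom") {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  gene_symbol_set(lines[lines != ""], name = name)
}

#' Default abundant-blood and immunoglobulin gene lists
#'
#' Editable copies ship in `inst/extdata/`: globin loci plus T-cell receptor
#' locus prefixes for the abundant-blood list; immunoglobulin heavy/kappa/
#' lambda locus prefixes for the immunoglobulin list.
#'
#' @return a [gene_symbol_set()].
#' @export
default_abundant_list <- function() {
  read_gene_list(system.file("extdata", "abundant_blood.txt",
                             package = "germfuse"),
                 name = "abundant_blood")
}

#' @rdname default_abundant_list
#' @export
default_immunoglobulin_list <- function() {
  read_gene_list(system.file("extdata", "immunoglobulin.txt",
                             package = "germfuse"),
                 name = "immunoglobulin")
}

#' Homologous-gene pair set
#'
#' Membership is symmetric: inserting (A, B) makes both (A, B) and (B, A)
#' queryable. A gene is considered homologous to itself by convention, so
#' duplicate-locus artifacts are flagged rather than silently passed.
#'
#' @param pairs two-column data frame (or matrix) of gene symbols.
#' @return object of class `homolog_set`.
#' @export
homolog_set <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2) rlang::abort("homolog pairs need two columns")
  a <- toupper(trimws(pairs[[1]]))
  b <- toupper(trimws(pairs[[2]]))
  keys <- unique(vapply(seq_along(a), function(i) {
    paste(sort(c(a[i], b[i])), collapse = "\t")
  }, character(1)))
  structure(list(keys = keys), class = "homolog_set")
}

#' @export
print.homolog_set <- function(x, ...) {
  cat(sprintf("<homolog_set: %d unordered pair(s)>\n", length(x$keys)))
  invisible(x)
}

#' Read a homologous-gene pair list (two-column TSV)
#'
#' Duplicated Genes Database style: two gene symbols per line, tab or
#' whitespace separated; `#` comments ignored.
#'
#' @param path file path.
#' @return a [homolog_set()].
#' @export
read_homolog_pairs <- function(path) {
  if (!file.exists(path)) rlang::abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[lines != ""]
  if (length(lines) == 0) return(homolog_set(data.frame(a = character(),
                                                        b = character())))
  parts <- stringr::str_split_fixed(lines, "[\t ]+", 2)
  homolog_set(data.frame(a = parts[, 1], b = parts[, 2]))
}

#' Are two genes listed as homologs?
#'
#' Symmetric lookup; identical symbols return TRUE (self-homology).
#'
#' @param geneA,geneB gene symbols (vectorized).
#' @param homologs a [homolog_set()].
#' @return logical vector.
#' @export
are_homologs <- function(geneA, geneB, homologs) {
  stopifnot(inherits(homologs, "homolog_set"))
  a <- toupper(trimws(as.character(geneA)))
  b <- toupper(trimws(as.character(geneB)))
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  vapply(seq_len(n), function(i) {
    if (is.na(a[i]) || is.na(b[i])) return(FALSE)
    if (a[i] == b[i]) return(TRUE)
    paste(sort(c(a[i], b[i])), collapse = "\t") %in% homologs$keys
  }, logical(1))
}
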