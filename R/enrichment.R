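# GO biological-process over-representation analysis.
#
# One-tailed exact test: for a query list of n proteins drawn from a
# universe of N, a term annotating K universe proteins and overlapping the
# query in k, p = P(X >= k) under the hypergeometric null. Multiple
# testing is corrected by Benjamini-Hochberg (default) or Bonferroni.
# Significant terms are grouped into semantic classes and functional
# blocks via a curated term dictionary; no hierarchical (parent-term)
# filtering is applied.

#' Read a two-column gene-to-term annotation table
#'
#' @param path TSV with columns `gene` and `term` (one row per
#'   annotation); an optional `aspect` column is filtered to `"BP"` when
#'   present.
#' @return Named list: `term -> character vector of genes`.
#' @export
read_annotations <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "term") %in% names(d))) {
    stop("annotation table must have columns gene, term")
  }
  if ("aspect" %in% names(d)) d <- d[d$aspect == "BP", , drop = FALSE]
  lapply(split(d$gene, d$term), unique)
}

#' One-tailed hypergeometric enrichment test
#'
#' Tests every annotation term for over-representation in a query protein
#' list against a background universe. Query members outside the universe
#' are dropped with a warning. The p-value is the upper-tail
#' hypergeometric probability `P(X >= k)`; `k = 0` gives `p = 1`.
#'
#' @param query Character vector of query proteins/genes.
#' @param annotations Named list `term -> genes` (see
#'   [read_annotations()]); annotated sets are intersected with the
#'   universe.
#' @param universe Character vector: the background gene universe
#'   (default: union of all annotated genes).
#' @param alpha Significance threshold on the adjusted p (default 0.05).
#' @param correction `"BH"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`.
#' @return Data frame with one row per term: `term`, `k`, `K`, `n`, `N`,
#'   `p`, `p_adj`, `significant`, ordered by `p`.
#' @export
enrich <- function(query, annotations, universe = NULL, alpha = 0.05,
                   correction = c("BH", "bonferroni")) {
  correction <- match.arg(correction)
  if (is.null(universe)) universe <- unique(unlist(annotations))
  universe <- unique(universe)
  dropped <- setdiff(query, universe)
  if (length(dropped)) {
    warning(length(dropped), " query member(s) outside the universe dropped")
  }
  query <- unique(intersect(query, universe))
  if (!length(query)) {
    warning("empty query after universe intersection")
    return(data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p = numeric(0),
                      p_adj = numeric(0), significant = logical(0)))
  }
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(annotations), function(term) {
    genes <- intersect(annotations[[term]], universe)
    K <- length(genes)
    k <- length(intersect(genes, query))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = if (correction == "BH") "BH" else "bonferroni")
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a curated term-to-semantic-class dictionary
#'
#' @param path TSV with columns `term`, `semantic_class`,
#'   `functional_block`.
#' @return Data frame of class `semantic_dictionary`.
#' @export
read_semantic_dictionary <- function(path = system.file(
  "extdata", "semantic_dictionary.tsv", package = "wppina")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("term", "semantic_class", "functional_block")
  if (!all(need %in% names(d))) {
    stop("semantic dictionary must have columns: ", paste(need, collapse = ", "))
  }
  class(d) <- c("semantic_dictionary", class(d))
  d
}

#' Group significant terms into semantic classes and functional blocks
#'
#' Every significant term is assigned its semantic class and functional
#' block from the curated dictionary; terms absent from the dictionary go
#' to the `"unassigned"` block. Blocks are ranked by their best (minimum)
#' raw p-value.
#'
#' @param results [enrich()] output.
#' @param dictionary A [read_semantic_dictionary()] table.
#' @param significant_only Group only significant terms (default `TRUE`).
#' @return List with `terms` (results plus `semantic_class`,
#'   `functional_block`) and `blocks` (block, best_p, n_terms,
#'   semantic_classes), blocks ordered by `best_p`.
#' @export
group_terms <- function(results, dictionary, significant_only = TRUE) {
  if (significant_only) results <- results[results$significant, , drop = FALSE]
  idx <- match(results$term, dictionary$term)
  results$semantic_class <- ifelse(is.na(idx), "unassigned",
                                   dictionary$semantic_class[idx])
  results$functional_block <- ifelse(is.na(idx), "unassigned",
                                     dictionary$functional_block[idx])
  if (!nrow(results)) {
    return(list(terms = results,
                blocks = data.frame(block = character(0), best_p = numeric(0),
                                    n_terms = integer(0),
                                    semantic_classes = character(0))))
  }
  blocks <- do.call(rbind, lapply(split(results, results$functional_block),
                                  function(df) {
    data.frame(
      block = df$functional_block[[1]],
      best_p = min(df$p),
      n_terms = nrow(df),
      semantic_classes = paste(sort(unique(df$semantic_class)), collapse = "|"),
      stringsAsFactors = FALSE
    )
  }))
  blocks <- blocks[order(blocks$best_p, blocks$block), , drop = FALSE]
  rownames(blocks) <- NULL
  list(terms = results, blocks = blocks)
}
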