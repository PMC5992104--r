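# Tissue co-expression plausibility scoring of interaction pairs.
#
# A (seed, interactor) pair is called co-expressed in a tissue when both
# genes reach the RPKM threshold (default 3, inclusive) in that tissue.
# This is deliberately a crude joint-thresholding analysis: temporal
# expression and subcellular localization are not modeled.

#' Read a gene x tissue RPKM expression matrix
#'
#' @param path TSV with genes in rows (first column `gene`) and one column
#'   per tissue.
#' @return Numeric matrix with gene rownames and tissue colnames.
#' @export
read_expression_matrix <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[[1]] != "gene") stop("first column must be 'gene'")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene
  if (any(m < 0)) stop("RPKM values must be non-negative")
  m
}

#' Tissues in which both members of a pair are expressed
#'
#' @param gene_a,gene_b Gene symbols of the pair (order irrelevant).
#' @param matrix Expression matrix from [read_expression_matrix()].
#' @param threshold RPKM threshold (default 3, inclusive `>=`).
#' @return Character vector of tissues where both genes reach the
#'   threshold; a gene missing from the matrix yields an empty set with
#'   attribute `not_found` listing the missing gene(s).
#' @export
coexpressed_tissues <- function(gene_a, gene_b, matrix, threshold = 3) {
  missing <- setdiff(c(gene_a, gene_b), rownames(matrix))
  if (length(missing)) {
    out <- character(0)
    attr(out, "not_found") <- missing
    return(out)
  }
  both <- matrix[gene_a, ] >= threshold & matrix[gene_b, ] >= threshold
  colnames(matrix)[both]
}

#' Co-expression report for a set of interaction pairs
#'
#' @param pairs Data frame with columns `seed` and `partner` (gene
#'   symbols).
#' @param matrix Expression matrix.
#' @param threshold RPKM threshold (default 3).
#' @return List with `pairs` (the input plus `n_tissues`, `tissues`
#'   `|`-joined, `not_found` flag) and the tissue list used.
#' @export
coexpression_report <- function(pairs, matrix, threshold = 3) {
  sets <- lapply(seq_len(nrow(pairs)), function(i) {
    coexpressed_tissues(pairs$seed[[i]], pairs$partner[[i]], matrix, threshold)
  })
  pairs$n_tissues <- vapply(sets, length, integer(1))
  pairs$tissues <- vapply(sets, paste, character(1), collapse = "|")
  pairs$not_found <- vapply(sets, function(s) !is.null(attr(s, "not_found")),
                            logical(1))
  list(pairs = pairs, tissues = colnames(matrix), threshold = threshold,
       tissue_sets = sets)
}

#' Summarize a co-expression report
#'
#' Per-tissue percentages are over the pairs whose genes were found in
#' the matrix and are rounded to the nearest integer; a tissue in which
#' no seed reaches the threshold yields 0. Also reports the mean number
#' of co-expressed tissues per pair and how many pairs are co-expressed
#' in at least `k` tissues for every `k`.
#'
#' @param report Output of [coexpression_report()].
#' @return List with `per_tissue_pct` (named integer vector),
#'   `mean_tissues`, `pairs_with_at_least` (named vector over k),
#'   `n_pairs_scored`, `n_not_found`.
#' @export
summarize_coexpression <- function(report) {
  pairs <- report$pairs
  sets <- report$tissue_sets
  found <- !pairs$not_found
  n_scored <- sum(found)
  per_tissue <- vapply(report$tissues, function(t) {
    sum(vapply(sets[found], function(s) t %in% s, logical(1)))
  }, integer(1))
  n_tissues <- length(report$tissues)
  at_least <- vapply(seq_len(n_tissues), function(k) {
    sum(pairs$n_tissues[found] >= k)
  }, integer(1))
  names(at_least) <- seq_len(n_tissues)
  list(
    per_tissue_pct = if (n_scored) .pct(per_tissue, n_scored, digits = 0) else per_tissue * 0,
    mean_tissues = if (n_scored) mean(pairs$n_tissues[found]) else NA_real_,
    pairs_with_at_least = at_least,
    n_pairs_scored = n_scored,
    n_not_found = sum(!found)
  )
}
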