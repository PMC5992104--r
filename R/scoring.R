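# Replication-aware confidence scoring of literature-derived interactions.
#
# Each seed-partner pair receives three additive components:
#   MS (method score):      1 if one grouped detection method, 2 if several
#   PS (publication score): 1 if one publication, 2 if several
#   CS (CRAPome score):     0, -0.5 or -1 contaminant penalty, applied only
#                           when the pair has APMS evidence
# total = MS + PS + CS in [1, 4]; pairs must exceed the threshold (default
# 2) to enter the network, which enforces independent replication by method
# and/or publication.

#' Aggregate evidence per seed-partner pair
#'
#' Collapses deduplicated, filtered interaction records into one evidence
#' set per unordered (seed, partner) pair: the set of unique grouped
#' detection methods, the set of unique publications, and whether every
#' supporting record is affinity-purification mass spectrometry
#' (`apms_only`).
#'
#' @param records Normalized, method-grouped interaction records
#'   (columns `seed`, `partner`, `method_group`, `is_apms`, `publication`).
#' @return A `data.frame` with one row per pair: `seed`, `partner`,
#'   `methods` and `publications` (list columns), `n_methods`,
#'   `n_publications`, `apms_any`, `apms_only`.
#' @export
aggregate_evidence <- function(records) {
  if (!nrow(records)) {
    return(data.frame(
      seed = character(0), partner = character(0),
      n_methods = integer(0), n_publications = integer(0),
      apms_any = logical(0), apms_only = logical(0)
    ))
  }
  key <- .pair_key(records$seed, records$partner)
  idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(idx, function(i) {
    methods <- sort(unique(records$method_group[i]))
    pubs <- sort(unique(records$publication[i]))
    data.frame(
      seed = records$seed[i][[1]],
      partner = records$partner[i][[1]],
      n_methods = length(methods),
      n_publications = length(pubs),
      apms_any = any(records$is_apms[i]),
      apms_only = all(records$is_apms[i]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$methods <- lapply(idx, function(i) sort(unique(records$method_group[i])))
  out$publications <- lapply(idx, function(i) sort(unique(records$publication[i])))
  rownames(out) <- NULL
  out
}

#' Method score component
#'
#' One grouped detection method scores 1; multiple methods score 2
#' (saturating — five methods still score 2).
#'
#' @param n_methods Integer vector of unique grouped-method counts.
#' @return Integer vector of 1s and 2s.
#' @export
method_score <- function(n_methods) {
  stopifnot(all(n_methods >= 1L))
  ifelse(n_methods >= 2L, 2L, 1L)
}

#' Publication score component
#'
#' One publication scores 1; multiple publications score 2.
#'
#' @param n_publications Integer vector of unique publication counts.
#' @return Integer vector of 1s and 2s.
#' @export
publication_score <- function(n_publications) {
  stopifnot(all(n_publications >= 1L))
  ifelse(n_publications >= 2L, 2L, 1L)
}

#' Read a contaminant-frequency (CRAPome-style) table
#'
#' @param path TSV with columns `protein`, `n_hit`, `n_total` (datasets in
#'   the contaminant repository in which the protein appears, and total
#'   datasets). The hit fraction is `n_hit / n_total`.
#' @return A `data.frame` of class `crapome_table` with `protein` and
#'   `hit_fraction` columns; `attr(, "n_datasets")` records the repository
#'   size.
#' @export
read_crapome <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "n_hit", "n_total")
  if (!all(need %in% names(d))) {
    stop("contaminant table must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(
    protein = as.character(d$protein),
    hit_fraction = d$n_hit / d$n_total,
    stringsAsFactors = FALSE
  )
  if (any(out$hit_fraction < 0 | out$hit_fraction > 1)) {
    stop("hit fractions must lie in [0, 1]")
  }
  attr(out, "n_datasets") <- max(d$n_total)
  class(out) <- c("crapome_table", class(out))
  out
}

#' CRAPome contaminant score component
#'
#' Evaluated on the partner (prey) protein, and only for pairs with APMS
#' evidence; pairs never seen by APMS always score 0. With `f` the fraction
#' of contaminant-repository control datasets containing the partner:
#' \itemize{
#'   \item `f > 0.5` and APMS is the only evidence: -1
#'   \item `f > 0.5` with additional non-APMS evidence, or `f` in
#'     \[0.3, 0.5\] with APMS-only evidence: -0.5
#'   \item otherwise (including any partner absent from the table,
#'     `f = 0`): 0
#' }
#'
#' @param partner Character vector of partner accessions.
#' @param apms_any Logical; does the pair have any APMS evidence?
#' @param apms_only Logical; is APMS the only evidence?
#' @param crapome A [read_crapome()] table (or `NULL` for no penalty).
#' @return Numeric vector of 0, -0.5 or -1.
#' @export
crapome_score <- function(partner, apms_any, apms_only, crapome = NULL) {
  f <- rep(0, length(partner))
  if (!is.null(crapome)) {
    idx <- match(partner, crapome$protein)
    f[!is.na(idx)] <- crapome$hit_fraction[idx[!is.na(idx)]]
  }
  score <- numeric(length(partner))
  high <- apms_any & f > 0.5
  score[high & apms_only] <- -1
  score[high & !apms_only] <- -0.5
  mid_apms_only <- apms_any & apms_only & f >= 0.3 & f <= 0.5
  score[mid_apms_only] <- -0.5
  score
}

#' Score aggregated evidence sets
#'
#' Computes MS, PS, CS and their total for every evidence set.
#'
#' @param evidence Output of [aggregate_evidence()].
#' @param crapome A [read_crapome()] table or `NULL`.
#' @return `evidence` with `ms`, `ps`, `cs` and `total` columns appended.
#' @export
score_evidence <- function(evidence, crapome = NULL) {
  if (!nrow(evidence)) {
    evidence$ms <- integer(0); evidence$ps <- integer(0)
    evidence$cs <- numeric(0); evidence$total <- numeric(0)
    return(evidence)
  }
  evidence$ms <- method_score(evidence$n_methods)
  evidence$ps <- publication_score(evidence$n_publications)
  evidence$cs <- crapome_score(evidence$partner, evidence$apms_any,
                               evidence$apms_only, crapome)
  evidence$total <- evidence$ms + evidence$ps + evidence$cs
  evidence
}

#' Partition scored pairs at the confidence threshold
#'
#' Pairs with `total > threshold` are retained; the rest are discarded but
#' kept with their evidence so that sub-threshold pairs can later be
#' rescued by experimental replication. The default threshold 2 means a
#' single-method, single-publication, penalty-free pair (total exactly 2)
#' does not survive: every retained interaction is independently
#' replicated by method and/or publication.
#'
#' @param scored Output of [score_evidence()].
#' @param threshold Numeric score threshold (default 2); retention is
#'   strict (`total > threshold`).
#' @return List with `retained` and `discarded` data frames partitioning
#'   the input.
#' @export
total_and_threshold <- function(scored, threshold = 2) {
  keep <- scored$total > threshold
  list(retained = scored[keep, , drop = FALSE],
       discarded = scored[!keep, , drop = FALSE])
}

# Percentage with conventional half-up rounding (38/57 -> 66.7).
.pct <- function(num, den, digits = 1) {
  p <- 100 * num / den
  p[!is.finite(p)] <- 0
  scale <- 10^digits
  floor(p * scale + 0.5) / scale
}

#' Per-seed retention of interactors across confidence thresholding
#'
#' Counts, for each seed, the distinct partner proteins reported before
#' thresholding and retained after it, with the retention percentage to
#' one decimal (half-up).
#'
#' @param scored All scored pairs (pre-threshold).
#' @param retained The retained pairs from [total_and_threshold()].
#' @param seeds Character vector of seed accessions (order preserved in
#'   the output).
#' @return A `data.frame` with `seed`, `n_reported`, `n_retained`,
#'   `retention_pct`.
#' @export
retention_summary <- function(scored, retained, seeds) {
  n_for <- function(df, s) {
    partners <- c(df$partner[df$seed == s], df$seed[df$partner == s])
    length(unique(partners))
  }
  n_reported <- vapply(seeds, n_for, integer(1), df = scored)
  n_retained <- vapply(seeds, n_for, integer(1), df = retained)
  data.frame(
    seed = seeds,
    n_reported = unname(n_reported),
    n_retained = unname(n_retained),
    retention_pct = .pct(unname(n_retained), unname(n_reported)),
    stringsAsFactors = FALSE
  )
}

#' Build the literature-derived network
#'
#' Assembles an igraph of seed nodes and retained partners, edges weighted
#' by the total confidence score and tagged with provenance
#' `"literature"`. Seeds with no retained partner remain as isolated
#' nodes. Seed-seed edges (homo- and heterodimer evidence) are kept and
#' can be listed with [dimer_edges()].
#'
#' @param retained Retained scored pairs.
#' @param seeds Character vector of seed accessions.
#' @return An `igraph` object; vertex attribute `role` is `"seed"` or
#'   `"interactor"`, edge attributes `ms`, `ps`, `cs`, `total`,
#'   `provenance`.
#' @export
build_literature_network <- function(retained, seeds) {
  edges <- data.frame(
    from = retained$seed, to = retained$partner,
    ms = retained$ms, ps = retained$ps, cs = retained$cs,
    total = retained$total, provenance = "literature",
    stringsAsFactors = FALSE
  )
  vertices <- data.frame(
    name = union(seeds, union(retained$seed, retained$partner)),
    stringsAsFactors = FALSE
  )
  vertices$role <- ifelse(vertices$name %in% seeds, "seed", "interactor")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  g
}

#' List seed-seed (dimer) edges of a network
#'
#' Self-loops are homodimer evidence; seed-to-seed edges are heterodimers.
#'
#' @param g An igraph network whose vertices carry a `role` attribute.
#' @return Data frame with `seed_a`, `seed_b`, `homodimer`.
#' @export
dimer_edges <- function(g) {
  el <- igraph::as_edgelist(g)
  role <- igraph::V(g)$role
  names(role) <- igraph::V(g)$name
  sel <- role[el[, 1]] == "seed" & role[el[, 2]] == "seed"
  data.frame(
    seed_a = el[sel, 1], seed_b = el[sel, 2],
    homodimer = el[sel, 1] == el[sel, 2],
    stringsAsFactors = FALSE
  )
}
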