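# Integration of the literature-derived and experimental networks into a
# common-core network.
#
# Common (non-seed) nodes fall into three categories:
#   i   same seed supported in both networks
#   ii  present in both networks but for disjoint seed sets
#   iii literature evidence below the confidence threshold, rescued when
#       the microarray replicates the same seed-partner pair (the array
#       contributes one extra non-APMS method and one extra publication,
#       which lifts the re-scored total over the threshold)
# A node may satisfy several categories for different seeds; summary
# counts report it once under its strongest category (i > iii > ii).

.seed_sets <- function(g) {
  role <- igraph::V(g)$role
  names(role) <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  seeds <- names(role)[role == "seed"]
  nodes <- names(role)[role != "seed"]
  sets <- lapply(nodes, function(n) {
    touching <- unique(c(el[el[, 1] == n, 2], el[el[, 2] == n, 1]))
    sort(intersect(touching, seeds))
  })
  names(sets) <- nodes
  sets
}

#' Overlap the literature and experimental networks (categories i and ii)
#'
#' Non-seed nodes present in both networks are classified by comparing the
#' seed sets that reach them in each network: overlapping seed sets give
#' category `"i"`, disjoint (but both non-empty) sets give category
#' `"ii"`. Seed nodes themselves are excluded.
#'
#' @param lit Literature igraph from [build_literature_network()].
#' @param exp Experimental igraph from [build_experimental_network()].
#' @return Data frame with `protein`, `category`, `seeds_literature`,
#'   `seeds_experimental` (both `|`-joined strings).
#' @export
overlap_networks <- function(lit, exp) {
  lit_sets <- .seed_sets(lit)
  exp_sets <- .seed_sets(exp)
  common <- intersect(names(lit_sets), names(exp_sets))
  common <- common[vapply(common, function(n) {
    length(lit_sets[[n]]) > 0L && length(exp_sets[[n]]) > 0L
  }, logical(1))]
  if (!length(common)) {
    return(data.frame(protein = character(0), category = character(0),
                      seeds_literature = character(0),
                      seeds_experimental = character(0),
                      stringsAsFactors = FALSE))
  }
  category <- vapply(common, function(n) {
    if (length(intersect(lit_sets[[n]], exp_sets[[n]]))) "i" else "ii"
  }, character(1))
  data.frame(
    protein = common,
    category = unname(category),
    seeds_literature = vapply(lit_sets[common], paste, character(1), collapse = "|"),
    seeds_experimental = vapply(exp_sets[common], paste, character(1), collapse = "|"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Rescue sub-threshold literature pairs replicated by the microarray
#'
#' For every discarded literature pair whose partner is an array positive
#' of the same seed, the microarray contributes one additional grouped
#' method (`"protein array"`, non-APMS) and one additional publication
#' (`"this_study"`). The pair is re-scored; pairs whose new total exceeds
#' the threshold become category-iii common-core members. Re-scoring
#' never lowers a total.
#'
#' @param discarded Discarded pairs from [total_and_threshold()] (scored
#'   evidence rows).
#' @param positives Named per-seed positive-hit list from
#'   [call_positives()].
#' @param crapome A [read_crapome()] table or `NULL`.
#' @param threshold Confidence threshold (default 2, strict `>`).
#' @return Data frame of rescued pairs with original and re-scored
#'   components (`ms2`, `ps2`, `cs2`, `total2`) and `category = "iii"`.
#' @export
rescue_subthreshold <- function(discarded, positives, crapome = NULL,
                                threshold = 2) {
  if (!nrow(discarded)) {
    out <- discarded
    out$total2 <- numeric(0)
    out$category <- character(0)
    return(out)
  }
  replicated <- vapply(seq_len(nrow(discarded)), function(i) {
    s <- discarded$seed[[i]]
    p <- discarded$partner[[i]]
    s %in% names(positives) && p %in% positives[[s]]$protein
  }, logical(1))
  cand <- discarded[replicated, , drop = FALSE]
  if (!nrow(cand)) {
    cand$ms2 <- integer(0); cand$ps2 <- integer(0)
    cand$cs2 <- numeric(0); cand$total2 <- numeric(0)
    cand$category <- character(0)
    return(cand)
  }
  # one extra method and one extra publication; array evidence is
  # non-APMS, so apms_only becomes FALSE
  cand$ms2 <- method_score(cand$n_methods + 1L)
  cand$ps2 <- publication_score(cand$n_publications + 1L)
  cand$cs2 <- crapome_score(cand$partner, cand$apms_any, FALSE, crapome)
  cand$total2 <- cand$ms2 + cand$ps2 + cand$cs2
  rescued <- cand[cand$total2 > threshold, , drop = FALSE]
  rescued$category <- rep("iii", nrow(rescued))
  rownames(rescued) <- NULL
  rescued
}

#' Assemble the common-core network
#'
#' Combines category i/ii nodes from [overlap_networks()] and category-iii
#' rescued pairs into one node table (each node reported once, strongest
#' category first: i > iii > ii) and an igraph of seeds plus common
#' nodes. Node `tier` is the number of distinct seeds supporting the node
#' across both networks, mirroring the two-/three-/four-seed node classes
#' of the network figures. Seed-seed dimer edges are excluded from the
#' common-core interactor set.
#'
#' @param common Output of [overlap_networks()].
#' @param rescued Output of [rescue_subthreshold()].
#' @param seeds Character vector of seed accessions.
#' @return List with `nodes` (protein/category/seeds/tier data frame) and
#'   `graph` (igraph, edge attribute `provenance`).
#' @export
build_common_core <- function(common, rescued, seeds) {
  rescued_nodes <- if (nrow(rescued)) {
    stats::aggregate(seed ~ partner, data = rescued,
                     FUN = function(s) paste(sort(unique(s)), collapse = "|"))
  } else {
    data.frame(partner = character(0), seed = character(0))
  }
  tab <- rbind(
    data.frame(protein = common$protein, category = common$category,
               seeds_literature = common$seeds_literature,
               seeds_experimental = common$seeds_experimental,
               stringsAsFactors = FALSE),
    data.frame(protein = rescued_nodes$partner,
               category = rep("iii", nrow(rescued_nodes)),
               seeds_literature = rescued_nodes$seed,
               seeds_experimental = rescued_nodes$seed,
               stringsAsFactors = FALSE)
  )
  tab <- tab[!(tab$protein %in% seeds), , drop = FALSE]
  if (nrow(tab)) {
    strength <- c(i = 1L, iii = 2L, ii = 3L)
    tab <- tab[order(tab$protein, strength[tab$category]), , drop = FALSE]
    dup <- duplicated(tab$protein)
    # merge seed sets across categories before dropping duplicates
    seeds_of <- function(col) {
      vapply(split(tab[[col]], tab$protein), function(x) {
        paste(sort(unique(unlist(strsplit(x, "|", fixed = TRUE)))), collapse = "|")
      }, character(1))
    }
    lit_all <- seeds_of("seeds_literature")
    exp_all <- seeds_of("seeds_experimental")
    tab <- tab[!dup, , drop = FALSE]
    tab$seeds_literature <- unname(lit_all[tab$protein])
    tab$seeds_experimental <- unname(exp_all[tab$protein])
  }
  all_seeds_of <- function(i) {
    u <- union(strsplit(tab$seeds_literature[[i]], "|", fixed = TRUE)[[1]],
               strsplit(tab$seeds_experimental[[i]], "|", fixed = TRUE)[[1]])
    sort(u[nzchar(u)])
  }
  tab$tier <- vapply(seq_len(nrow(tab)), function(i) length(all_seeds_of(i)),
                     integer(1))
  edges <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    data.frame(from = all_seeds_of(i), to = tab$protein[[i]],
               provenance = "common_core", stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        provenance = character(0))
  }
  vertices <- data.frame(name = c(seeds, tab$protein), stringsAsFactors = FALSE)
  vertices$role <- ifelse(vertices$name %in% seeds, "seed", "interactor")
  vertices$tier <- c(rep(NA_integer_, length(seeds)), tab$tier)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
  rownames(tab) <- NULL
  list(nodes = tab, graph = g)
}
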