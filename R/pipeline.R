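# End-to-end orchestration: ingest -> qc -> score -> array -> integrate ->
# coexpress -> enrich, driven by a YAML configuration, with a Markdown run
# report and machine-readable stage outputs. Every stage is a pure
# function of the stage inputs and the configuration.

.STAGES <- c("ingest", "score", "array", "integrate", "coexpress", "enrich")

#' Read and validate a pipeline run configuration
#'
#' @param path YAML file. Required keys: `seeds` (name -> accession map),
#'   `inputs` (paths for `mitab` (db name -> file), `dictionary`,
#'   `crapome`, `array`, `array_background`, `expression`, `annotations`,
#'   `semantic_dictionary`). Optional with defaults: `control_bait`
#'   (`"GFP"`), `thresholds` (`score` 2, `z` 3, `rpkm` 3, `alpha` 0.05),
#'   `correction` (`"BH"`), `method_groups` (bundled default map),
#'   `output_dir` (`"results"`). Relative input paths resolve against the
#'   config file's directory.
#' @return A validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  defaults <- list(
    control_bait = "GFP",
    thresholds = list(score = 2, z = 3, rpkm = 3, alpha = 0.05),
    correction = "BH",
    output_dir = "results"
  )
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$seeds) || !length(cfg$seeds)) stop("config needs a 'seeds' map")
  need_inputs <- c("mitab", "dictionary", "crapome", "array",
                   "array_background", "expression", "annotations",
                   "semantic_dictionary")
  missing <- setdiff(need_inputs, names(cfg$inputs))
  if (length(missing)) {
    stop("config 'inputs' missing: ", paste(missing, collapse = ", "))
  }
  resolve <- function(p) {
    ifelse(startsWith(p, "/"), p, file.path(base, p))
  }
  cfg$inputs$mitab <- lapply(cfg$inputs$mitab, resolve)
  for (k in setdiff(need_inputs, "mitab")) {
    cfg$inputs[[k]] <- resolve(cfg$inputs[[k]])
  }
  if (!is.null(cfg$method_groups)) cfg$method_groups <- resolve(cfg$method_groups)
  if (!startsWith(cfg$output_dir, "/")) {
    cfg$output_dir <- file.path(base, cfg$output_dir)
  }
  for (f in c(unlist(cfg$inputs$mitab),
              unlist(cfg$inputs[setdiff(need_inputs, "mitab")]))) {
    if (!file.exists(f)) stop("input file not found: ", f)
  }
  class(cfg) <- c("run_config", class(cfg))
  cfg
}

#' Export a network as SIF plus an edge-attribute table
#'
#' @param g An igraph network.
#' @param prefix Output path prefix; writes `<prefix>.sif`,
#'   `<prefix>_edges.tsv` and `<prefix>.graphml`.
#' @export
export_network <- function(g, prefix) {
  el <- igraph::as_edgelist(g)
  prov <- igraph::edge_attr(g, "provenance")
  if (is.null(prov)) prov <- rep("interacts", nrow(el))
  sif <- data.frame(a = el[, 1], type = prov, b = el[, 2])
  utils::write.table(sif, paste0(prefix, ".sif"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  edges <- as.data.frame(igraph::as_data_frame(g, what = "edges"))
  utils::write.table(edges, paste0(prefix, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  igraph::write_graph(g, paste0(prefix, ".graphml"), format = "graphml")
  invisible(prefix)
}

#' Run the pipeline
#'
#' Executes the requested stages (plus any earlier stages they depend on)
#' and writes networks, stage tables and a Markdown report under the
#' configured output directory.
#'
#' @param config A [read_run_config()] list, or a path to a config YAML.
#' @param stages Character vector of stages to run (default all of
#'   `ingest`, `score`, `array`, `integrate`, `coexpress`, `enrich`).
#' @return Invisibly, a list of stage results (`qc`, `evidence`,
#'   `retention`, `lit_network`, `positives`, `exp_summary`,
#'   `exp_network`, `common`, `rescued`, `core`, `coexpression`,
#'   `enrichment`, ...).
#' @export
run_pipeline <- function(config, stages = .STAGES) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, .STAGES, several.ok = TRUE)
  # stages are sequential; run the prefix closure of what was asked
  last <- max(match(stages, .STAGES))
  run <- .STAGES[seq_len(last)]
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = config)
  seeds <- unlist(config$seeds)
  report <- c("# Pipeline run report", "")

  # ---- ingest + qc + dedupe -------------------------------------------
  dict <- read_protein_dictionary(config$inputs$dictionary)
  map <- if (is.null(config$method_groups)) read_method_groups()
         else read_method_groups(config$method_groups)
  raw <- lapply(names(config$inputs$mitab), function(db) {
    read_mitab(config$inputs$mitab[[db]], db)
  })
  n_raw <- sum(vapply(raw, nrow, integer(1)))
  norm <- normalize_ids(do.call(rbind, raw), dict, seeds)
  qc <- apply_qc_filters(norm$records, dict, map)
  deduped <- merge_and_dedupe(qc$records)
  res$rejections <- rbind(
    norm$rejected[c("id_a", "id_b", "source_db", "publication", "reason")],
    data.frame(id_a = qc$rejected$seed, id_b = qc$rejected$partner,
               source_db = qc$rejected$source_db,
               publication = qc$rejected$publication,
               reason = qc$rejected$reason, stringsAsFactors = FALSE)
  )
  utils::write.table(res$rejections, file.path(out_dir, "rejections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  res$deduped <- deduped
  report <- c(report, "## Ingest",
              sprintf("- raw MITAB records: %d", n_raw),
              sprintf("- rejected at normalization/QC: %d", nrow(res$rejections)),
              sprintf("- records after deduplication: %d", nrow(deduped)), "")
  if (last < 2L) return(.finish_report(report, out_dir, res))

  # ---- score -----------------------------------------------------------
  crapome <- read_crapome(config$inputs$crapome)
  evidence <- aggregate_evidence(deduped)
  scored <- score_evidence(evidence, crapome)
  parts <- total_and_threshold(scored, config$thresholds$score)
  res$scored <- scored
  res$retained <- parts$retained
  res$discarded <- parts$discarded
  res$retention <- retention_summary(scored, parts$retained, seeds)
  res$retention$seed_name <- names(seeds)[match(res$retention$seed, seeds)]
  res$lit_network <- build_literature_network(parts$retained, seeds)
  utils::write.table(
    scored[c("seed", "partner", "n_methods", "n_publications", "apms_only",
             "ms", "ps", "cs", "total")],
    file.path(out_dir, "confidence_scores.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$retention, file.path(out_dir, "retention.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_network(res$lit_network, file.path(out_dir, "literature_network"))
  report <- c(report, "## Literature network",
    sprintf("- scored pairs: %d; retained at total > %g: %d",
            nrow(scored), config$thresholds$score, nrow(parts$retained)),
    sprintf("- %s: %d reported, %d retained (%.1f%%)",
            res$retention$seed_name, res$retention$n_reported,
            res$retention$n_retained, res$retention$retention_pct),
    sprintf("- seed-seed dimer edges: %d", nrow(dimer_edges(res$lit_network))),
    "")
  if (last < 3L) return(.finish_report(report, out_dir, res))

  # ---- array -----------------------------------------------------------
  array_tab <- read_array_table(config$inputs$array)
  background <- utils::read.delim(config$inputs$array_background,
                                  stringsAsFactors = FALSE)
  res$positives <- call_positives(array_tab, seeds,
                                  control = config$control_bait,
                                  background = background,
                                  z_threshold = config$thresholds$z)
  res$exp_summary <- experimental_summary(res$positives)
  res$exp_network <- build_experimental_network(res$positives)
  pos_tab <- do.call(rbind, lapply(names(res$positives), function(s) {
    df <- res$positives[[s]]
    if (nrow(df)) data.frame(seed = s, protein = df$protein, z = df$z) else NULL
  }))
  utils::write.table(pos_tab, file.path(out_dir, "array_positives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_network(res$exp_network, file.path(out_dir, "experimental_network"))
  s <- res$exp_summary
  report <- c(report, "## Experimental network",
    sprintf("- positives per bait: %s",
            paste(sprintf("%s=%d", names(seeds), s$per_seed), collapse = ", ")),
    sprintf("- %d interactions across %d nodes", s$n_interactions, s$n_nodes),
    sprintf("- nodes shared by >=2 baits: %.1f%%; >=3: %.1f%%; all %d: %.1f%%",
            s$pct_shared_2plus, s$pct_shared_3plus, length(seeds),
            s$tier_pct[[length(s$tier_pct)]]),
    "")
  if (last < 4L) return(.finish_report(report, out_dir, res))

  # ---- integrate -------------------------------------------------------
  res$common <- overlap_networks(res$lit_network, res$exp_network)
  res$rescued <- rescue_subthreshold(res$discarded, res$positives, crapome,
                                     config$thresholds$score)
  res$core <- build_common_core(res$common, res$rescued, seeds)
  lit_all_nodes <- setdiff(unique(c(res$scored$seed, res$scored$partner)), seeds)
  exp_nodes <- setdiff(igraph::V(res$exp_network)$name, seeds)
  res$n_nonthresholded_overlap <- length(intersect(lit_all_nodes, exp_nodes))
  utils::write.table(res$core$nodes, file.path(out_dir, "common_core.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  export_network(res$core$graph, file.path(out_dir, "common_core_network"))
  cats <- table(factor(res$core$nodes$category, levels = c("i", "ii", "iii")))
  report <- c(report, "## Common core",
    sprintf("- thresholded-literature / array common interactors: %d",
            nrow(res$common)),
    sprintf("- non-thresholded overlap: %d", res$n_nonthresholded_overlap),
    sprintf("- rescued sub-threshold pairs: %d", nrow(res$rescued)),
    sprintf("- common-core interactors: %d (category i: %d, ii: %d, iii: %d)",
            nrow(res$core$nodes), cats[["i"]], cats[["ii"]], cats[["iii"]]),
    "")
  if (last < 5L) return(.finish_report(report, out_dir, res))

  # ---- coexpress -------------------------------------------------------
  expr <- read_expression_matrix(config$inputs$expression)
  core_pairs <- .core_pairs_as_symbols(res$core, dict, seeds)
  rep_cx <- coexpression_report(core_pairs, expr, config$thresholds$rpkm)
  res$coexpression <- rep_cx
  res$coexpression_summary <- summarize_coexpression(rep_cx)
  utils::write.table(rep_cx$pairs, file.path(out_dir, "coexpression_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cs <- res$coexpression_summary
  pct <- cs$per_tissue_pct
  report <- c(report, "## Co-expression",
    sprintf("- pairs scored: %d (not found in matrix: %d)",
            cs$n_pairs_scored, cs$n_not_found),
    sprintf("- mean co-expressed tissues per pair: %.1f", cs$mean_tissues),
    sprintf("- top tissues: %s",
            paste(sprintf("%s=%d%%", names(sort(pct, decreasing = TRUE))[1:3],
                          sort(pct, decreasing = TRUE)[1:3]), collapse = ", ")),
    "")
  if (last < 6L) return(.finish_report(report, out_dir, res))

  # ---- enrich ----------------------------------------------------------
  annotations <- read_annotations(config$inputs$annotations)
  sem <- read_semantic_dictionary(config$inputs$semantic_dictionary)
  universe <- unique(unlist(annotations))
  query <- unique(core_pairs$partner)
  res$enrichment <- enrich(query, annotations, universe,
                           alpha = config$thresholds$alpha,
                           correction = config$correction)
  res$blocks <- group_terms(res$enrichment, sem)
  utils::write.table(res$blocks$terms, file.path(out_dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$blocks$blocks, file.path(out_dir, "functional_blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  top <- utils::head(res$blocks$blocks, 3L)
  report <- c(report, "## Functional enrichment",
    sprintf("- significant BP terms: %d", sum(res$enrichment$significant)),
    if (nrow(top)) sprintf("- top block: %s (best p = %.2e)",
                           top$block[[1]], top$best_p[[1]]) else
      "- no significant terms",
    "")
  .finish_report(report, out_dir, res)
}

.finish_report <- function(report, out_dir, res) {
  writeLines(report, file.path(out_dir, "report.md"))
  res$report <- report
  invisible(res)
}

# Common-core (seed, node) pairs translated to gene symbols for the
# expression matrix; one pair per (supporting seed, node).
.core_pairs_as_symbols <- function(core, dict, seeds) {
  nodes <- core$nodes
  sym <- function(acc) {
    s <- dict$gene_symbol[match(acc, dict$accession)]
    ifelse(is.na(s), acc, s)
  }
  rows <- lapply(seq_len(nrow(nodes)), function(i) {
    supp <- union(
      strsplit(nodes$seeds_literature[[i]], "|", fixed = TRUE)[[1]],
      strsplit(nodes$seeds_experimental[[i]], "|", fixed = TRUE)[[1]]
    )
    supp <- supp[nzchar(supp)]
    data.frame(seed = sym(supp), partner = sym(nodes$protein[[i]]),
               seed_acc = supp, partner_acc = nodes$protein[[i]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(seed = character(0), partner = character(0),
                      seed_acc = character(0), partner_acc = character(0))
  }
  out
}
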