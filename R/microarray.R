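# Protein-microarray hit calling.
#
# Binding strength is expressed as a Z-score: the number of background
# standard deviations a spot's fluorescence lies above the array
# background. Each array protein is spotted in duplicate and the per-spot
# Z values are averaged. Hits are called at Z > 3 (strict), and hits of a
# seed bait that also bind the GFP negative-control bait are subtracted as
# non-specific binders.

#' Read spot-level protein-microarray fluorescence tables
#'
#' @param path TSV with columns `bait`, `protein`, `spot_index`,
#'   `intensity` and an optional `spot_class` column (`probe` or
#'   `background`); background spots, when present, feed the fallback
#'   background estimator of [compute_z()].
#' @return A `data.frame` of class `array_table`.
#' @export
read_array_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("bait", "protein", "spot_index", "intensity")
  if (!all(need %in% names(d))) {
    stop("array table must have columns: ", paste(need, collapse = ", "))
  }
  if (!"spot_class" %in% names(d)) d$spot_class <- "probe"
  d$intensity <- as.numeric(d$intensity)
  class(d) <- c("array_table", class(d))
  d
}

# Robust fallback background model: median location, MAD scale of the
# designated background/buffer spots of one bait's array.
.estimate_background <- function(tab) {
  bg <- tab$intensity[tab$spot_class == "background"]
  if (length(bg) < 2L) {
    stop("no background spots to estimate background from; supply bg_mean/bg_sd")
  }
  list(mean = stats::median(bg), sd = stats::mad(bg))
}

#' Compute duplicate-averaged Z-scores for one bait
#'
#' Per spot, `z = (intensity - bg_mean) / bg_sd`; per array protein, the
#' spot Z values are averaged (Z of spots, not of intensities). A protein
#' is a hit when its averaged Z strictly exceeds `z_threshold`; Z exactly
#' at the threshold is not a hit.
#'
#' @param table An [read_array_table()] data frame restricted to one bait
#'   (or with a single bait value).
#' @param bg_mean,bg_sd Background fluorescence mean and standard
#'   deviation for this array. When `NULL`, both are estimated robustly
#'   (median/MAD) from rows with `spot_class == "background"`.
#' @param z_threshold Hit-calling threshold (default 3, strict `>`).
#' @return Data frame with `bait`, `protein`, `z`, `n_spots`, `is_hit`.
#' @export
compute_z <- function(table, bg_mean = NULL, bg_sd = NULL, z_threshold = 3) {
  bait <- unique(table$bait)
  if (length(bait) != 1L) {
    stop("compute_z expects spots of a single bait; got: ",
         paste(bait, collapse = ", "))
  }
  if (is.null(bg_mean) || is.null(bg_sd)) {
    bg <- .estimate_background(table)
    if (is.null(bg_mean)) bg_mean <- bg$mean
    if (is.null(bg_sd)) bg_sd <- bg$sd
  }
  if (!is.finite(bg_sd) || bg_sd <= 0) {
    stop("background standard deviation must be positive")
  }
  probes <- table[table$spot_class == "probe", , drop = FALSE]
  z_spot <- (probes$intensity - bg_mean) / bg_sd
  agg <- tapply(z_spot, probes$protein, mean)
  n <- tapply(z_spot, probes$protein, length)
  out <- data.frame(
    bait = bait,
    protein = names(agg),
    z = as.numeric(agg),
    n_spots = as.integer(n),
    stringsAsFactors = FALSE
  )
  out$is_hit <- out$z > z_threshold
  rownames(out) <- NULL
  out
}

#' Subtract negative-control (GFP) hits from seed-bait hits
#'
#' Proteins that bind the negative-control bait are non-specific binders:
#' any seed hit that is also a control hit is removed. The subtraction is
#' on hit sets, not on Z differences.
#'
#' @param seed_calls [compute_z()] output for one seed bait.
#' @param control_calls [compute_z()] output for the negative-control
#'   (GFP) bait.
#' @return List with `positives` (retained hit rows) and `removed`
#'   (seed hits excluded as control binders).
#' @export
subtract_control <- function(seed_calls, control_calls) {
  control_hits <- control_calls$protein[control_calls$is_hit]
  hits <- seed_calls[seed_calls$is_hit, , drop = FALSE]
  keep <- !(hits$protein %in% control_hits)
  list(positives = hits[keep, , drop = FALSE],
       removed = hits[!keep, , drop = FALSE])
}

#' Call positives for every seed bait of an array experiment
#'
#' Runs [compute_z()] per bait and [subtract_control()] against the
#' control bait.
#'
#' @param table Full [read_array_table()] data frame (all baits).
#' @param seeds Character vector of seed bait names.
#' @param control Name of the negative-control bait (default `"GFP"`).
#' @param background Optional data frame `bait`/`bg_mean`/`bg_sd`; when
#'   absent, backgrounds are estimated per array from background spots.
#' @param z_threshold Hit-calling threshold (default 3).
#' @return Named list (per seed) of positive-hit data frames.
#' @export
call_positives <- function(table, seeds, control = "GFP",
                           background = NULL, z_threshold = 3) {
  bg_for <- function(b) {
    if (is.null(background)) return(list(mean = NULL, sd = NULL))
    row <- background[background$bait == b, , drop = FALSE]
    if (!nrow(row)) return(list(mean = NULL, sd = NULL))
    list(mean = row$bg_mean[[1]], sd = row$bg_sd[[1]])
  }
  calls_for <- function(b) {
    bg <- bg_for(b)
    compute_z(table[table$bait == b, , drop = FALSE],
              bg_mean = bg$mean, bg_sd = bg$sd, z_threshold = z_threshold)
  }
  control_calls <- calls_for(control)
  out <- lapply(seeds, function(s) subtract_control(calls_for(s), control_calls)$positives)
  names(out) <- seeds
  out
}

#' Build the experimental (microarray) network
#'
#' One edge per (seed, positive hit); the interaction count is the sum of
#' per-seed positives and the node count is the size of the union of
#' positive proteins. Every interactor node carries a `tier`: the number
#' of seed baits that hit it.
#'
#' @param positives Named list of per-seed positive-hit data frames from
#'   [call_positives()].
#' @return An `igraph` with vertex attributes `role` and `tier` and edge
#'   attributes `z` and `provenance = "experimental"`; summary counts via
#'   [experimental_summary()].
#' @export
build_experimental_network <- function(positives) {
  seeds <- names(positives)
  edges <- do.call(rbind, lapply(seeds, function(s) {
    p <- positives[[s]]
    if (!nrow(p)) return(NULL)
    data.frame(from = s, to = p$protein, z = p$z,
               provenance = "experimental", stringsAsFactors = FALSE)
  }))
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0),
                        z = numeric(0), provenance = character(0))
  }
  interactors <- sort(unique(edges$to))
  tier <- vapply(interactors, function(p) {
    sum(vapply(positives, function(df) p %in% df$protein, logical(1)))
  }, integer(1))
  vertices <- data.frame(
    name = c(seeds, setdiff(interactors, seeds)),
    stringsAsFactors = FALSE
  )
  vertices$role <- ifelse(vertices$name %in% seeds, "seed", "interactor")
  vertices$tier <- ifelse(vertices$role == "seed", NA_integer_,
                          tier[match(vertices$name, interactors)])
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = vertices)
}

#' Summarize an experimental network
#'
#' @param positives Named list of per-seed positive-hit data frames.
#' @return List with `per_seed` counts, `n_interactions` (sum of per-seed
#'   positives), `n_nodes` (union of interactors), `tiers` (nodes shared
#'   by exactly k seeds, k = 1..number of seeds) and `tier_pct`
#'   (percentage of the network in each tier, one decimal, half-up), plus
#'   `pct_shared_2plus` and `pct_shared_3plus`.
#' @export
experimental_summary <- function(positives) {
  seeds <- names(positives)
  per_seed <- vapply(positives, nrow, integer(1))
  proteins <- sort(unique(unlist(lapply(positives, `[[`, "protein"))))
  tier <- vapply(proteins, function(p) {
    sum(vapply(positives, function(df) p %in% df$protein, logical(1)))
  }, integer(1))
  k <- seq_along(seeds)
  tiers <- vapply(k, function(i) sum(tier == i), integer(1))
  names(tiers) <- paste0("tier", k)
  n_nodes <- length(proteins)
  list(
    per_seed = per_seed,
    n_interactions = sum(per_seed),
    n_nodes = n_nodes,
    tiers = tiers,
    tier_pct = .pct(tiers, n_nodes),
    pct_shared_2plus = .pct(sum(tier >= 2L), n_nodes),
    pct_shared_3plus = .pct(sum(tier >= 3L), n_nodes)
  )
}
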