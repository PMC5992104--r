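# Synthetic fixture generator.
#
# Emulates every input the pipeline consumes -- multi-database MITAB files,
# a reviewed-protein dictionary, a contaminant-frequency table, spot-level
# protein-microarray fluorescence, a gene x tissue RPKM matrix and GO BP
# annotations with a semantic dictionary -- with planted ground truth
# written alongside as an answer key. The answer key is computed from the
# generator's own construction plan (fixed per-pattern score constants,
# planted binder lists, planted tissue counts), never by calling the
# pipeline, so it is an independent end-to-end oracle.
#
# The default spec IS the headline shape of the study the pipeline models:
# per-seed literature interactors 57/38 (DAPK1-like), 85/14, 481/113 and
# 7/4 reported/retained; array positives 87, 51, 78, 87 across a 226-node
# union with 5 nodes common to all four baits; 13 tissues of which
# skeletal muscle has no seed expression; one planted enriched GO term.

# Evidence patterns with their hand-derived score constants. Patterns A-D
# are replicated (retained at threshold 2), E-H are single-evidence
# (discarded). f is the planted contaminant hit fraction of the partner
# (NA = not in the contaminant table).
.PATTERNS <- list(
  A = list(methods = c("MI:0018", "MI:0019"), n_pubs = 1L, f = NA,  ms = 2, ps = 1, cs = 0),
  B = list(methods = "MI:0018",               n_pubs = 2L, f = NA,  ms = 1, ps = 2, cs = 0),
  C = list(methods = c("MI:0018", "MI:0096"), n_pubs = 2L, f = NA,  ms = 2, ps = 2, cs = 0),
  D = list(methods = c("MI:0004", "MI:0018"), n_pubs = 2L, f = 0.8, ms = 2, ps = 2, cs = -0.5),
  E = list(methods = "MI:0018",               n_pubs = 1L, f = NA,  ms = 1, ps = 1, cs = 0),
  F = list(methods = "MI:0004",               n_pubs = 1L, f = 0.8, ms = 1, ps = 1, cs = -1),
  G = list(methods = "MI:0004",               n_pubs = 1L, f = 0.4, ms = 1, ps = 1, cs = -0.5),
  H = list(methods = "MI:0004",               n_pubs = 1L, f = 0.1, ms = 1, ps = 1, cs = 0)
)

.MI_LABEL <- c("MI:0018" = "two hybrid", "MI:0019" = "coimmunoprecipitation",
               "MI:0096" = "pull down", "MI:0004" = "affinity chromatography technology")

.DEFAULT_TISSUES <- c(
  "reproductive_apparatus", "brain", "intestine", "heart", "lung", "liver",
  "kidney", "adipose", "blood", "skin", "pancreas", "spleen",
  "skeletal_muscle"
)

.DEFAULT_DBS <- c("IntAct", "BioGRID", "InnateDB", "InnateDB-All",
                  "InnateDB-IMEx", "MINT")

#' Describe a synthetic fixture
#'
#' Returns the parameter set consumed by [generate_fixture()]. The
#' defaults reproduce the headline shape of the study the pipeline
#' models; see the package vignette for what each default emulates.
#'
#' @param seed Random seed; outputs are byte-identical given the same
#'   spec and seed.
#' @param seeds Seed-protein gene symbols (default the four ROCO-family
#'   kinases/GTPases the pipeline was built around).
#' @param n_reported,n_retained Per-seed literature interactor counts
#'   before and after confidence thresholding.
#' @param overlap `"headline"` plants dimer edges, shared literature
#'   interactors and the literature/array overlap structure (48
#'   non-thresholded / 14 thresholded common proteins, 20 rescuable);
#'   `"none"` plants none of it (pure retention fixture).
#' @param tiers `"headline"` plants the multi-bait array overlap (226
#'   nodes, tiers 173/34/14/5); `"disjoint"` gives every bait its own
#'   binders.
#' @param n_databases Number of source databases (max 6 named ones).
#' @param db_overlap_rate Probability that a record is annotated in a
#'   second database (exercises deduplication).
#' @param array List overriding array defaults: `n_proteins` (400,
#'   standing in for a full 9480-protein array), `bg_mean` (500),
#'   `bg_sd` (50), `z_target` (5), `n_sticky` (10 non-specific binders
#'   present in seed and control arrays), `n_control_only` (5),
#'   `per_seed` (planted specific binders per bait).
#' @param n_tissues Number of expression tissues (13; the last tissue has
#'   no seed expression).
#' @param n_terms Number of GO BP terms besides the planted enriched one
#'   and the universe-wide root term.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         seeds = c("DAPK1", "LRRK1", "LRRK2", "MASL1"),
                         n_reported = c(57L, 85L, 481L, 7L),
                         n_retained = c(38L, 14L, 113L, 4L),
                         overlap = c("headline", "none"),
                         tiers = c("headline", "disjoint"),
                         n_databases = 6L,
                         db_overlap_rate = 0.3,
                         array = list(),
                         n_tissues = 13L,
                         n_terms = 40L) {
  overlap <- match.arg(overlap)
  tiers <- match.arg(tiers)
  array_defaults <- list(n_proteins = 400L, bg_mean = 500, bg_sd = 50,
                         z_target = 5, n_sticky = 10L, n_control_only = 5L,
                         per_seed = c(87L, 51L, 78L, 87L))
  if (length(seeds) != 4L && !length(array$per_seed)) {
    array_defaults$per_seed <- rep(20L, length(seeds))
  }
  array <- utils::modifyList(array_defaults, array)
  ns <- length(seeds)
  stopifnot(ns >= 1L, length(n_reported) == ns, length(n_retained) == ns)
  if (any(n_retained > n_reported) || any(n_retained < 0L)) {
    stop("inconsistent fixture spec: need 0 <= n_retained <= n_reported")
  }
  if ((overlap == "headline" || tiers == "headline") && ns != 4L) {
    stop("the headline overlap/tier design requires exactly four seeds")
  }
  if (length(array$per_seed) != ns) {
    stop("array$per_seed must have one entry per seed")
  }
  if (n_databases < 1L || n_databases > length(.DEFAULT_DBS)) {
    stop("n_databases must be between 1 and ", length(.DEFAULT_DBS))
  }
  if (n_tissues < 2L) stop("need at least two tissues")
  structure(list(
    seed = as.integer(seed), seeds = seeds,
    n_reported = as.integer(n_reported), n_retained = as.integer(n_retained),
    overlap = overlap, tiers = tiers,
    n_databases = as.integer(n_databases), db_overlap_rate = db_overlap_rate,
    array = array, n_tissues = as.integer(n_tissues),
    n_terms = as.integer(n_terms)
  ), class = "fixture_spec")
}

# Headline literature/array overlap constants (four seeds). Columns are
# seed indices; values were chosen so that thresholded overlap = 14
# (10 category-i + 4 category-ii), rescuable sub-threshold overlap = 20
# and total non-thresholded overlap = 48.
.HL <- list(
  homodimers = 1:3,
  heterodimers = list(c(1L, 3L), c(2L, 3L)),
  shared = list(list(a = 1L, b = 3L, n = 3L), list(a = 2L, b = 3L, n = 2L)),
  cat_i = c(3L, 2L, 3L, 2L),
  cat_ii = list(c(lit = 1L, arr = 4L), c(lit = 3L, arr = 2L),
                c(lit = 3L, arr = 4L), c(lit = 2L, arr = 1L)),
  cat_iii = c(5L, 5L, 8L, 2L),
  nonrescued = list(c(lit = 3L, arr = 1L, n = 5L), c(lit = 3L, arr = 2L, n = 4L),
                    c(lit = 3L, arr = 4L, n = 3L), c(lit = 1L, arr = 2L, n = 1L),
                    c(lit = 1L, arr = 4L, n = 1L)),
  tier4 = 5L,
  tier3_excluding = c(3L, 4L, 4L, 3L),        # count of 3-seed nodes NOT touching seed i
  tier2_pairs = rbind(c(1L, 2L, 6L), c(1L, 3L, 6L), c(1L, 4L, 5L),
                      c(2L, 3L, 5L), c(2L, 4L, 6L), c(3L, 4L, 6L))
)

#' Generate every pipeline input with planted ground truth
#'
#' Writes the six input classes (MITAB files per database, protein
#' dictionary, contaminant table, spot-level array table with background,
#' expression matrix, GO annotations with semantic dictionary), a ready
#' pipeline configuration `run.yaml`, and the answer key
#' (`answer_key.yaml` plus per-pair/per-positive/per-tissue TSVs).
#' Deterministic: the same spec produces byte-identical output.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the answer key as a list (also written to
#'   `answer_key.yaml`).
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  ns <- length(spec$seeds)

  # ---- protein registry ------------------------------------------------
  reg <- new.env(parent = emptyenv())
  reg$n <- 0L
  reg$rows <- list()
  new_proteins <- function(k, role, taxid = 9606L, reviewed = TRUE) {
    if (k == 0L) return(character(0))
    idx <- reg$n + seq_len(k)
    reg$n <- reg$n + k
    acc <- sprintf("Q%05d", idx)
    reg$rows[[length(reg$rows) + 1L]] <- data.frame(
      accession = acc, canonical = acc,
      gene_symbol = sprintf("GENE%04d", idx),
      taxid = taxid, reviewed = reviewed, role = role,
      stringsAsFactors = FALSE
    )
    acc
  }
  seed_acc <- sprintf("P%05d", seq_len(ns))
  reg$rows[[1L]] <- data.frame(
    accession = seed_acc, canonical = seed_acc, gene_symbol = spec$seeds,
    taxid = 9606L, reviewed = TRUE, role = "seed", stringsAsFactors = FALSE
  )

  # ---- literature plan -------------------------------------------------
  # pairs: one row per (seed, partner) with its evidence pattern and role
  pair_rows <- list()
  add_pair <- function(seed_idx, partner, pattern, class) {
    pair_rows[[length(pair_rows) + 1L]] <<- data.frame(
      seed = seed_acc[[seed_idx]], partner = partner, pattern = pattern,
      class = class, stringsAsFactors = FALSE
    )
  }
  used_retained <- integer(ns)
  used_discarded <- integer(ns)
  arr_extra <- vector("list", ns)          # lit-overlap proteins bound by each bait
  for (i in seq_len(ns)) arr_extra[[i]] <- character(0)
  cat_i_prot <- character(0)
  cat_ii_prot <- character(0)
  cat_iii_prot <- character(0)
  nonres_prot <- character(0)

  retained_cycle <- c("A", "B", "C", "D")
  discarded_cycle <- c("E", "E", "F", "G", "H")

  if (spec$overlap == "headline") {
    for (i in .HL$homodimers) {
      add_pair(i, seed_acc[[i]], "C", "dimer")
      used_retained[[i]] <- used_retained[[i]] + 1L
    }
    for (hd in .HL$heterodimers) {
      add_pair(hd[[1]], seed_acc[[hd[[2]]]], "C", "dimer")
      used_retained[[hd[[1]]]] <- used_retained[[hd[[1]]]] + 1L
      used_retained[[hd[[2]]]] <- used_retained[[hd[[2]]]] + 1L
    }
    for (sh in .HL$shared) {
      prots <- new_proteins(sh$n, "lit_shared")
      for (p in prots) {
        add_pair(sh$a, p, "C", "shared")
        add_pair(sh$b, p, "A", "shared")
      }
      used_retained[[sh$a]] <- used_retained[[sh$a]] + sh$n
      used_retained[[sh$b]] <- used_retained[[sh$b]] + sh$n
    }
    for (i in seq_len(ns)) {
      prots <- new_proteins(.HL$cat_i[[i]], "lit_cat_i")
      for (p in prots) add_pair(i, p, "A", "cat_i")
      arr_extra[[i]] <- c(arr_extra[[i]], prots)
      cat_i_prot <- c(cat_i_prot, prots)
      used_retained[[i]] <- used_retained[[i]] + length(prots)
    }
    for (cc in .HL$cat_ii) {
      p <- new_proteins(1L, "lit_cat_ii")
      add_pair(cc[["lit"]], p, "B", "cat_ii")
      arr_extra[[cc[["arr"]]]] <- c(arr_extra[[cc[["arr"]]]], p)
      cat_ii_prot <- c(cat_ii_prot, p)
      used_retained[[cc[["lit"]]]] <- used_retained[[cc[["lit"]]]] + 1L
    }
    for (i in seq_len(ns)) {
      prots <- new_proteins(.HL$cat_iii[[i]], "lit_cat_iii")
      for (j in seq_along(prots)) {
        add_pair(i, prots[[j]], discarded_cycle[(j - 1L) %% 5L + 1L], "cat_iii")
      }
      arr_extra[[i]] <- c(arr_extra[[i]], prots)
      cat_iii_prot <- c(cat_iii_prot, prots)
      used_discarded[[i]] <- used_discarded[[i]] + length(prots)
    }
    for (nr in .HL$nonrescued) {
      prots <- new_proteins(nr[["n"]], "lit_nonrescued")
      for (p in prots) add_pair(nr[["lit"]], p, "E", "nonrescued")
      arr_extra[[nr[["arr"]]]] <- c(arr_extra[[nr[["arr"]]]], prots)
      nonres_prot <- c(nonres_prot, prots)
      used_discarded[[nr[["lit"]]]] <- used_discarded[[nr[["lit"]]]] + nr[["n"]]
    }
  }
  n_discard <- spec$n_reported - spec$n_retained
  for (i in seq_len(ns)) {
    k_left <- spec$n_retained[[i]] - used_retained[[i]]
    d_left <- n_discard[[i]] - used_discarded[[i]]
    if (k_left < 0L || d_left < 0L) {
      stop("inconsistent fixture spec: seed ", spec$seeds[[i]],
           " cannot hold the planted overlap structure")
    }
    prots <- new_proteins(k_left, "lit_ordinary")
    for (j in seq_along(prots)) {
      add_pair(i, prots[[j]], retained_cycle[(j - 1L) %% 4L + 1L], "ordinary")
    }
    prots <- new_proteins(d_left, "lit_ordinary")
    for (j in seq_along(prots)) {
      add_pair(i, prots[[j]], discarded_cycle[(j - 1L) %% 5L + 1L], "ordinary")
    }
  }
  pairs <- do.call(rbind, pair_rows)
  pat <- .PATTERNS[pairs$pattern]
  pairs$ms <- vapply(pat, `[[`, numeric(1), "ms")
  pairs$ps <- vapply(pat, `[[`, numeric(1), "ps")
  pairs$cs <- vapply(pat, `[[`, numeric(1), "cs")
  pairs$total <- pairs$ms + pairs$ps + pairs$cs
  pairs$retained <- pairs$total > 2

  # contaminant table entries implied by the patterns
  f_planted <- vapply(pat, `[[`, numeric(1), "f")
  crap <- unique(data.frame(protein = pairs$partner, f = f_planted,
                            stringsAsFactors = FALSE)[!is.na(f_planted), ])
  if (anyDuplicated(crap$protein)) {
    stop("internal plan error: conflicting contaminant fractions")
  }

  # ---- MITAB records ---------------------------------------------------
  dbs <- .DEFAULT_DBS[seq_len(spec$n_databases)]
  pub_counter <- 0L
  new_pub <- function() {
    pub_counter <<- pub_counter + 1L
    sprintf("%07d", pub_counter)
  }
  rec_rows <- list()
  add_record <- function(seed, partner, mi, pub, taxid_b = 9606L,
                         type_b = "protein", id_b = NULL) {
    rec_rows[[length(rec_rows) + 1L]] <<- data.frame(
      id_a = paste0("uniprotkb:", seed),
      id_b = if (is.null(id_b)) paste0("uniprotkb:", partner) else id_b,
      method = mi, pub = pub, taxid_b = taxid_b, type_b = type_b,
      stringsAsFactors = FALSE
    )
  }
  for (r in seq_len(nrow(pairs))) {
    p <- .PATTERNS[[pairs$pattern[[r]]]]
    pubs <- vapply(seq_len(p$n_pubs), function(i) new_pub(), character(1))
    if (length(p$methods) == 2L && p$n_pubs == 1L) {
      add_record(pairs$seed[[r]], pairs$partner[[r]], p$methods[[1]], pubs[[1]])
      add_record(pairs$seed[[r]], pairs$partner[[r]], p$methods[[2]], pubs[[1]])
    } else if (length(p$methods) == 1L && p$n_pubs == 2L) {
      add_record(pairs$seed[[r]], pairs$partner[[r]], p$methods[[1]], pubs[[1]])
      add_record(pairs$seed[[r]], pairs$partner[[r]], p$methods[[1]], pubs[[2]])
    } else if (length(p$methods) == 2L && p$n_pubs == 2L) {
      add_record(pairs$seed[[r]], pairs$partner[[r]], p$methods[[1]], pubs[[1]])
      add_record(pairs$seed[[r]], pairs$partner[[r]], p$methods[[2]], pubs[[2]])
    } else {
      add_record(pairs$seed[[r]], pairs$partner[[r]], p$methods[[1]], pubs[[1]])
    }
  }
  # filter fodder: chemicals, unreviewed, non-human, unmapped -- all
  # removed before scoring, so planted counts are untouched
  unrev <- new_proteins(2L * ns, "junk_unreviewed", reviewed = FALSE)
  mouse <- new_proteins(2L * ns, "junk_mouse", taxid = 10090L)
  for (i in seq_len(ns)) {
    add_record(seed_acc[[i]], NA, "MI:0018", new_pub(),
               id_b = sprintf("chebi:CHEBI:%05d", i), type_b = "small molecule")
    add_record(seed_acc[[i]], NA, "MI:0018", new_pub(),
               id_b = sprintf("chebi:CHEBI:%05d", i + 100L), type_b = "small molecule")
    add_record(seed_acc[[i]], unrev[[2L * i - 1L]], "MI:0018", new_pub())
    add_record(seed_acc[[i]], unrev[[2L * i]], "MI:0019", new_pub())
    add_record(seed_acc[[i]], mouse[[2L * i - 1L]], "MI:0018", new_pub(),
               taxid_b = 10090L)
    add_record(seed_acc[[i]], mouse[[2L * i]], "MI:0096", new_pub(),
               taxid_b = 10090L)
    add_record(seed_acc[[i]], NA, "MI:0018", new_pub(),
               id_b = sprintf("uniprotkb:X9%04d", i))   # not in dictionary
  }
  records <- do.call(rbind, rec_rows)
  records$db <- dbs[(seq_len(nrow(records)) - 1L) %% length(dbs) + 1L]
  # duplicate some records into a second database (same publication and
  # method: exact equivalents that deduplication must remove)
  dup <- stats::runif(nrow(records)) < spec$db_overlap_rate
  if (length(dbs) > 1L && any(dup)) {
    extra <- records[dup, , drop = FALSE]
    extra$db <- dbs[match(extra$db, dbs) %% length(dbs) + 1L]
    records <- rbind(records, extra)
  }
  # alias and isoform spellings of the first planted pair duplicate an
  # existing record, so normalization + dedupe must absorb them
  first_partner <- pairs$partner[[1L]]
  alias_acc <- "Q90001"
  first_rec <- records[records$id_b == paste0("uniprotkb:", first_partner), ][1L, ]
  alias_rows <- rbind(first_rec, first_rec)
  alias_rows$id_b <- c(paste0("uniprotkb:", alias_acc),
                       paste0("uniprotkb:", first_partner, "-2"))
  alias_rows$db <- rep(dbs[[length(dbs)]], 2L)
  records <- rbind(records, alias_rows)

  # ---- array plan ------------------------------------------------------
  arr <- spec$array
  binders <- vector("list", ns)
  names(binders) <- spec$seeds
  if (spec$tiers == "headline") {
    tier2_deg <- integer(ns); tier3_deg <- 14L - .HL$tier3_excluding
    for (k in seq_len(nrow(.HL$tier2_pairs))) {
      tier2_deg[.HL$tier2_pairs[k, 1:2]] <- tier2_deg[.HL$tier2_pairs[k, 1:2]] +
        .HL$tier2_pairs[k, 3L]
    }
    tier1_n <- arr$per_seed - tier2_deg - tier3_deg - .HL$tier4
    overlap_used <- vapply(arr_extra, length, integer(1))
    if (any(tier1_n < overlap_used)) {
      stop("inconsistent fixture spec: array per_seed too small for the planted overlap")
    }
    for (i in seq_len(ns)) {
      binders[[i]] <- c(arr_extra[[i]],
                        new_proteins(tier1_n[[i]] - overlap_used[[i]], "array_tier1"))
    }
    for (k in seq_len(nrow(.HL$tier2_pairs))) {
      prots <- new_proteins(.HL$tier2_pairs[k, 3L], "array_tier2")
      for (i in .HL$tier2_pairs[k, 1:2]) binders[[i]] <- c(binders[[i]], prots)
    }
    for (i in seq_len(ns)) {
      prots <- new_proteins(.HL$tier3_excluding[[i]], "array_tier3")
      for (j in setdiff(seq_len(ns), i)) binders[[j]] <- c(binders[[j]], prots)
    }
    prots <- new_proteins(.HL$tier4, "array_tier4")
    for (i in seq_len(ns)) binders[[i]] <- c(binders[[i]], prots)
  } else {
    overlap_used <- vapply(arr_extra, length, integer(1))
    if (any(arr$per_seed < overlap_used)) {
      stop("inconsistent fixture spec: array per_seed too small for the planted overlap")
    }
    for (i in seq_len(ns)) {
      binders[[i]] <- c(arr_extra[[i]],
                        new_proteins(arr$per_seed[[i]] - overlap_used[[i]], "array_tier1"))
    }
  }
  sticky <- new_proteins(arr$n_sticky, "array_sticky")
  control_only <- new_proteins(arr$n_control_only, "array_control_only")
  union_binders <- unique(unlist(binders))
  on_array <- unique(c(union_binders, sticky, control_only))
  n_inert <- arr$n_proteins - length(on_array)
  if (n_inert < 0L) {
    stop("inconsistent fixture spec: more planted array proteins (",
         length(on_array), ") than array positions (", arr$n_proteins, ")")
  }
  on_array <- c(on_array, new_proteins(n_inert, "array_inert"))

  # ---- spot intensities ------------------------------------------------
  baits <- c(spec$seeds, "GFP")
  bait_acc <- c(seed_acc, "GFP")
  spot_rows <- vector("list", length(baits))
  for (b in seq_along(baits)) {
    z <- matrix(stats::runif(2L * length(on_array), -2, 2), ncol = 2L)
    hit <- if (baits[[b]] == "GFP") rep(FALSE, length(on_array))
           else on_array %in% binders[[b]]
    z[hit, ] <- arr$z_target + stats::runif(2L * sum(hit), -0.3, 0.3)
    is_sticky <- on_array %in% sticky
    z[is_sticky, ] <- arr$z_target + 1 + stats::runif(2L * sum(is_sticky), -0.3, 0.3)
    if (baits[[b]] == "GFP") {
      is_ctl <- on_array %in% control_only
      z[is_ctl, ] <- arr$z_target + stats::runif(2L * sum(is_ctl), -0.3, 0.3)
    }
    probe <- data.frame(
      bait = bait_acc[[b]],
      protein = rep(on_array, 2L),
      spot_index = rep(1:2, each = length(on_array)),
      intensity = round(arr$bg_mean + c(z) * arr$bg_sd, 2),
      spot_class = "probe",
      stringsAsFactors = FALSE
    )
    bg <- data.frame(
      bait = bait_acc[[b]],
      protein = sprintf("BUFFER%02d", 1:50),
      spot_index = 1L,
      intensity = round(stats::rlnorm(50, log(arr$bg_mean), arr$bg_sd / arr$bg_mean), 2),
      spot_class = "background",
      stringsAsFactors = FALSE
    )
    spot_rows[[b]] <- rbind(probe, bg)
  }
  array_tab <- do.call(rbind, spot_rows)

  # ---- protein dictionary (plus alias + isoform parent entries) --------
  filler <- new_proteins(100L, "expr_filler")     # extra expressed genes
  decoys <- new_proteins(5L, "crapome_decoy")     # contaminants never seen
  dict <- do.call(rbind, reg$rows)
  dict <- rbind(dict, data.frame(
    accession = alias_acc, canonical = first_partner,
    gene_symbol = dict$gene_symbol[dict$accession == first_partner],
    taxid = 9606L, reviewed = TRUE, role = "alias", stringsAsFactors = FALSE
  ))

  # ---- common core / co-expression plan --------------------------------
  sym_of <- function(acc) dict$gene_symbol[match(acc, dict$accession)]
  core_prot <- c(cat_i_prot, cat_ii_prot, cat_iii_prot)
  core_pairs <- pairs[pairs$class %in% c("cat_i", "cat_iii"),
                      c("seed", "partner", "class")]
  if (length(cat_ii_prot)) {
    cc_lit <- pairs[pairs$class == "cat_ii", c("seed", "partner", "class")]
    cc_arr <- data.frame(
      seed = seed_acc[vapply(.HL$cat_ii, `[[`, integer(1), "arr")],
      partner = cat_ii_prot, class = "cat_ii", stringsAsFactors = FALSE)
    core_pairs <- rbind(core_pairs, cc_lit, cc_arr)
  }
  core_pairs <- unique(core_pairs[, c("seed", "partner")])

  tissues <- if (spec$n_tissues == 13L) .DEFAULT_TISSUES else
    c(sprintf("tissue%02d", seq_len(spec$n_tissues - 1L)), "skeletal_muscle")
  silent_tissue <- tissues[[length(tissues)]]
  pref <- tissues[-length(tissues)]          # inclusion preference order
  excluded_gene <- if (length(cat_iii_prot)) cat_iii_prot[[length(cat_iii_prot)]] else NA
  n_tissue_planted <- stats::setNames(integer(0), character(0))
  core_unique <- unique(core_pairs$partner)
  for (p in core_unique) {
    n_tissue_planted[[p]] <- if (p %in% cat_i_prot) length(pref) else
      sample(5:min(11, length(pref)), 1L)
  }

  # expression matrix: seeds expressed everywhere except the silent
  # tissue; each core partner expressed in its first n_tissue_planted
  # preference tissues
  expr_genes <- c(seed_acc, setdiff(core_unique, excluded_gene), filler)
  expr <- matrix(round(stats::runif(length(expr_genes) * length(tissues), 0, 2.5), 2),
                 nrow = length(expr_genes),
                 dimnames = list(sym_of(expr_genes), tissues))
  expr[seq_len(ns), pref] <- round(stats::runif(ns * length(pref), 4, 20), 2)
  for (p in setdiff(core_unique, excluded_gene)) {
    k <- n_tissue_planted[[p]]
    expr[sym_of(p), pref[seq_len(k)]] <- round(stats::runif(k, 4, 20), 2)
  }
  expr[sym_of(filler), ] <- round(stats::runif(length(filler) * length(tissues), 0, 10), 2)

  # answer-key co-expression: generator-side arithmetic only
  core_pairs$n_tissues <- ifelse(
    core_pairs$partner == excluded_gene, 0L,
    unname(n_tissue_planted[core_pairs$partner]))
  core_pairs$not_found <- core_pairs$partner == excluded_gene
  core_pairs$tissues <- ifelse(core_pairs$not_found, "",
    vapply(core_pairs$n_tissues, function(k) {
      paste(sort(pref[seq_len(k)]), collapse = "|")
    }, character(1)))
  found <- !core_pairs$not_found
  per_tissue_pct <- vapply(seq_along(pref), function(j) {
    .pct(sum(core_pairs$n_tissues[found] >= j), sum(found), digits = 0)
  }, numeric(1))
  names(per_tissue_pct) <- pref
  per_tissue_pct[[silent_tissue]] <- 0

  # ---- GO annotations --------------------------------------------------
  universe <- dict$gene_symbol[dict$reviewed & dict$taxid == 9606L &
                                 dict$role != "alias"]
  planted_term <- "GO:SYN0001"
  core_sym <- sym_of(unique(core_prot))
  planted_genes <- c(core_sym[seq_len(min(10L, length(core_sym)))],
                     sample(setdiff(universe, core_sym), 5L))
  ann_rows <- list(
    data.frame(gene = universe, term = "GO:SYN0000", stringsAsFactors = FALSE),
    data.frame(gene = planted_genes, term = planted_term, stringsAsFactors = FALSE)
  )
  blocks <- c("cell death", "development", "transport", "protein metabolism",
              "intracellular organization", "signal transduction")
  sem_rows <- list(
    data.frame(term = "GO:SYN0000", semantic_class = "cellular process",
               functional_block = "general", stringsAsFactors = FALSE),
    data.frame(term = planted_term, semantic_class = "stress",
               functional_block = "response to stimulus", stringsAsFactors = FALSE)
  )
  for (t in seq_len(spec$n_terms)) {
    term <- sprintf("GO:SYN%04d", t + 1L)
    genes <- sample(universe, sample(20:40, 1L))
    ann_rows[[length(ann_rows) + 1L]] <- data.frame(
      gene = genes, term = term, stringsAsFactors = FALSE)
    sem_rows[[length(sem_rows) + 1L]] <- data.frame(
      term = term, semantic_class = sprintf("class%02d", (t - 1L) %% 8L + 1L),
      functional_block = blocks[(t - 1L) %% length(blocks) + 1L],
      stringsAsFactors = FALSE)
  }
  annotations <- do.call(rbind, ann_rows)
  annotations$aspect <- "BP"
  semantic <- do.call(rbind, sem_rows)

  # ---- write files -----------------------------------------------------
  wt <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    file
  }
  wt(dict[, c("accession", "canonical", "gene_symbol", "taxid", "reviewed")],
     "dictionary.tsv")
  crap_out <- data.frame(protein = crap$protein,
                         n_hit = round(crap$f * 411), n_total = 411L)
  crap_out <- rbind(crap_out, data.frame(protein = decoys,
                                         n_hit = sample(300:411, 5L),
                                         n_total = 411L))
  wt(crap_out, "crapome.tsv")
  mitab_files <- character(0)
  for (db in dbs) {
    sub <- records[records$db == db, , drop = FALSE]
    fn <- paste0("mitab_", gsub("[^A-Za-z0-9]", "_", db), ".tsv")
    .write_mitab(sub, file.path(out_dir, fn))
    mitab_files[[db]] <- fn
  }
  wt(array_tab, "array.tsv")
  wt(data.frame(bait = bait_acc, bg_mean = arr$bg_mean, bg_sd = arr$bg_sd),
     "array_background.tsv")
  wt(data.frame(gene = rownames(expr), expr, check.names = FALSE),
     "expression.tsv")
  wt(annotations, "annotations.tsv")
  wt(semantic, "semantic_dictionary.tsv")

  # ---- answer key ------------------------------------------------------
  n_retained_chk <- vapply(seq_len(ns), function(i) {
    sum((pairs$seed == seed_acc[[i]] | pairs$partner == seed_acc[[i]]) & pairs$retained)
  }, integer(1))
  exp_summary <- if (spec$tiers == "headline") {
    tier_counts <- c(tier1 = sum(tier1_n), tier2 = sum(.HL$tier2_pairs[, 3L]),
                     tier3 = 14L, tier4 = .HL$tier4)
    list(per_seed = as.list(stats::setNames(arr$per_seed, spec$seeds)),
         n_interactions = sum(arr$per_seed),
         n_nodes = length(union_binders),
         tiers = as.list(tier_counts),
         tier4_pct = .pct(.HL$tier4, length(union_binders)),
         pct_shared_2plus = .pct(sum(tier_counts[2:4]), length(union_binders)),
         pct_shared_3plus = .pct(sum(tier_counts[3:4]), length(union_binders)))
  } else {
    list(per_seed = as.list(stats::setNames(arr$per_seed, spec$seeds)),
         n_interactions = sum(arr$per_seed),
         n_nodes = length(union_binders))
  }
  key <- list(
    seeds = as.list(stats::setNames(seed_acc, spec$seeds)),
    literature = list(
      n_reported = as.list(stats::setNames(spec$n_reported, spec$seeds)),
      n_retained = as.list(stats::setNames(spec$n_retained, spec$seeds)),
      retention_pct = as.list(stats::setNames(
        .pct(spec$n_retained, spec$n_reported), spec$seeds))
    ),
    experimental = exp_summary,
    integration = list(
      n_common_thresholded = length(cat_i_prot) + length(cat_ii_prot),
      cat_i = as.list(cat_i_prot),
      cat_ii = as.list(cat_ii_prot),
      cat_iii = as.list(cat_iii_prot),
      n_common_core = length(core_prot),
      n_nonthresholded_overlap = length(core_prot) + length(nonres_prot)
    ),
    coexpression = list(
      not_found = if (is.na(excluded_gene)) list() else sym_of(excluded_gene),
      silent_tissue = silent_tissue,
      per_tissue_pct = as.list(per_tissue_pct)
    ),
    enrichment = list(
      planted_term = planted_term,
      k = min(10L, length(core_sym)),
      K = length(planted_genes),
      functional_block = "response to stimulus"
    )
  )
  stopifnot(all(n_retained_chk == spec$n_retained))
  yaml::write_yaml(key, file.path(out_dir, "answer_key.yaml"))
  pairs$gene_symbol <- sym_of(pairs$partner)
  wt(pairs, "answer_key_pairs.tsv")
  pos_key <- do.call(rbind, lapply(seq_len(ns), function(i) {
    data.frame(seed = seed_acc[[i]], protein = binders[[i]],
               stringsAsFactors = FALSE)
  }))
  wt(pos_key, "answer_key_positives.tsv")
  wt(core_pairs, "answer_key_coexpression.tsv")

  # ---- ready-to-run pipeline config ------------------------------------
  config <- list(
    seeds = as.list(stats::setNames(seed_acc, spec$seeds)),
    control_bait = "GFP",
    inputs = list(
      mitab = as.list(mitab_files),
      dictionary = "dictionary.tsv",
      crapome = "crapome.tsv",
      array = "array.tsv",
      array_background = "array_background.tsv",
      expression = "expression.tsv",
      annotations = "annotations.tsv",
      semantic_dictionary = "semantic_dictionary.tsv"
    ),
    thresholds = list(score = 2, z = 3, rpkm = 3, alpha = 0.05),
    correction = "BH",
    output_dir = "results"
  )
  yaml::write_yaml(config, file.path(out_dir, "run.yaml"))
  invisible(key)
}

# Write records as a MITAB 2.5 file with the two extended interactor-type
# columns (22 columns total; unused columns are "-").
.write_mitab <- function(records, path) {
  fmt_method <- function(mi) sprintf('psi-mi:"%s"(%s)',
                                     mi, unname(.MI_LABEL[mi]))
  fmt_tax <- function(t) sprintf("taxid:%d(%s)", t,
                                 ifelse(t == 9606L, "human", "other"))
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    cols <- rep("-", 22L)
    cols[1] <- r$id_a
    cols[2] <- r$id_b
    cols[7] <- fmt_method(r$method)
    cols[9] <- paste0("pubmed:", r$pub)
    cols[10] <- fmt_tax(9606L)
    cols[11] <- fmt_tax(r$taxid_b)
    cols[12] <- 'psi-mi:"MI:0915"(physical association)'
    cols[21] <- 'psi-mi:"MI:0326"(protein)'
    cols[22] <- sprintf('psi-mi:"MI:0000"(%s)', r$type_b)
    paste(cols, collapse = "\t")
  }, character(1))
  header <- paste0("#", paste(c("ID(s) interactor A", "ID(s) interactor B",
    paste("col", 3:22)), collapse = "\t"))
  writeLines(c(header, lines), path)
}
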