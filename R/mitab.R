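# PSI-MI TAB 2.5 ingestion and identifier normalization.
#
# Only a subset of the 15 core MITAB columns is consumed: interactor ids
# (1-2), detection method (7), publication (9), taxids (10-11) and, when the
# file carries the extended columns, interactor types (21-22). Multi-value
# fields are "|"-delimited; "-" denotes null.

.MITAB_MIN_COLS <- 15L

#' Read a PSI-MI TAB 2.5 file
#'
#' Parses a tab-separated MITAB 2.5 file into one interaction record per data
#' row. Identifier namespaces (e.g. `uniprotkb:`) are preserved verbatim in
#' `id_a`/`id_b`; the detection-method column is reduced to its `MI:nnnn`
#' term; the publication column to its first PubMed identifier (or the first
#' identifier present). Rows with fewer than 15 columns are skipped with a
#' warning, not an error.
#'
#' @param path Path to a MITAB 2.5 file. A leading header line (starting
#'   with `#`) is ignored.
#' @param source_db Name of the database of origin, recorded on every record.
#' @return A `data.frame` with columns `source_db`, `id_a`, `id_b`,
#'   `taxid_a`, `taxid_b` (integer, `NA` when unknown), `method_term`,
#'   `publication`, `type_a`, `type_b` (molecule-type labels, `NA` when the
#'   file has no type columns) and `n_skipped` rows attribute via
#'   `attr(, "skipped")`.
#' @export
read_mitab <- function(path, source_db) {
  if (!file.exists(path)) {
    stop("MITAB file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) && startsWith(lines[[1]], "#")) {
    lines <- lines[-1]
  }
  if (!length(lines)) {
    return(.empty_mitab(source_db))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= .MITAB_MIN_COLS
  if (any(!ok)) {
    warning(sum(!ok), " malformed MITAB row(s) skipped in ", basename(path))
  }
  fields <- fields[ok]
  if (!length(fields)) {
    out <- .empty_mitab(source_db)
    attr(out, "skipped") <- sum(!ok)
    return(out)
  }
  col <- function(i) vapply(fields, function(f) {
    if (length(f) >= i) f[[i]] else "-"
  }, character(1))
  out <- data.frame(
    source_db   = source_db,
    id_a        = .mitab_pick_id(col(1L)),
    id_b        = .mitab_pick_id(col(2L)),
    taxid_a     = .mitab_taxid(col(10L)),
    taxid_b     = .mitab_taxid(col(11L)),
    method_term = .mitab_mi_term(col(7L)),
    publication = .mitab_publication(col(9L)),
    type_a      = .mitab_type(col(21L)),
    type_b      = .mitab_type(col(22L)),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- sum(!ok)
  out
}

.empty_mitab <- function(source_db) {
  data.frame(
    source_db = character(0), id_a = character(0), id_b = character(0),
    taxid_a = integer(0), taxid_b = integer(0), method_term = character(0),
    publication = character(0), type_a = character(0), type_b = character(0),
    stringsAsFactors = FALSE
  )
}

# Identifier priority inside a "|"-delimited cross-reference list: the
# UniProt namespace first, else the first parseable "ns:value" entry.
.mitab_pick_id <- function(x) {
  vapply(strsplit(x, "|", fixed = TRUE), function(parts) {
    parts <- parts[nzchar(parts) & parts != "-"]
    if (!length(parts)) return(NA_character_)
    uni <- grep("^uniprotkb:", parts, value = TRUE)
    if (length(uni)) uni[[1]] else parts[[1]]
  }, character(1))
}

.mitab_taxid <- function(x) {
  vapply(strsplit(x, "|", fixed = TRUE), function(parts) {
    m <- regmatches(parts, regexpr("taxid:-?[0-9]+", parts))
    m <- unlist(m)
    if (!length(m)) return(NA_integer_)
    tax <- suppressWarnings(as.integer(sub("taxid:", "", m[[1]], fixed = TRUE)))
    if (is.na(tax) || tax <= 0L) NA_integer_ else tax
  }, integer(1))
}

.mitab_mi_term <- function(x) {
  m <- regmatches(x, regexpr("MI:[0-9]{4}", x))
  out <- rep(NA_character_, length(x))
  has <- regexpr("MI:[0-9]{4}", x) > 0L
  out[has] <- m
  out
}

.mitab_publication <- function(x) {
  vapply(strsplit(x, "|", fixed = TRUE), function(parts) {
    parts <- parts[nzchar(parts) & parts != "-"]
    if (!length(parts)) return(NA_character_)
    pm <- grep("^pubmed:", parts, value = TRUE)
    if (length(pm)) sub("^pubmed:", "", pm[[1]]) else parts[[1]]
  }, character(1))
}

# Interactor type, e.g. psi-mi:"MI:0326"(protein) -> "protein".
.mitab_type <- function(x) {
  lab <- sub("^.*\\(([^)]*)\\)\\s*$", "\\1", x)
  lab[x == "-" | !nzchar(x) | lab == x] <- NA_character_
  lab
}

#' Read a reviewed-protein dictionary table
#'
#' The dictionary maps every known accession (canonical, secondary or
#' isoform parent) to its canonical accession, gene symbol, species taxid
#' and reviewed status. Canonical accessions must map to themselves.
#'
#' @param path TSV with header columns `accession`, `canonical`,
#'   `gene_symbol`, `taxid`, `reviewed` (logical or 0/1).
#' @return A `data.frame` of class `protein_dictionary`.
#' @export
read_protein_dictionary <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("accession", "canonical", "gene_symbol", "taxid", "reviewed")
  if (!all(need %in% names(d))) {
    stop("dictionary must have columns: ", paste(need, collapse = ", "))
  }
  d$taxid <- as.integer(d$taxid)
  d$reviewed <- as.logical(d$reviewed) | d$reviewed %in% c("1", "yes")
  if (anyDuplicated(d$accession)) {
    stop("dictionary accessions must be unique")
  }
  canon <- unique(d$canonical)
  self <- d$canonical[match(canon, d$accession)]
  if (any(is.na(self)) || any(self != canon)) {
    stop("every canonical accession must appear as a self-mapping entry")
  }
  class(d) <- c("protein_dictionary", class(d))
  d
}

# Strip a namespace prefix and an isoform suffix ("-N") from a raw
# interactor identifier; transcript-specific information is collapsed to
# the parent accession before dictionary lookup.
.strip_accession <- function(id) {
  acc <- sub("^[A-Za-z0-9_.]+:", "", id)
  sub("-[0-9]+$", "", acc)
}

#' Normalize interaction records against a protein dictionary
#'
#' Maps both interactors of each record to canonical accessions and orients
#' the pair as (seed, partner). Records whose partner cannot be mapped are
#' routed to a rejection log with reason `"unmapped"`; records in which no
#' declared seed participates are rejected with reason `"no_seed"`. Raw
#' identifiers that resolve to more than one canonical accession would be
#' rejected as `"ambiguous"`, but a valid dictionary (unique accession rows)
#' precludes this by construction.
#'
#' Mapping is idempotent: normalizing an already-normalized set is a no-op.
#'
#' @param records Data frame from [read_mitab()] (any subset of its rows).
#' @param dict A [read_protein_dictionary()] table.
#' @param seeds Character vector of canonical seed accessions.
#' @return A list with `records` (normalized interactions: `seed`, `partner`,
#'   `method_term`, `publication`, `source_db`, `taxid_seed`,
#'   `taxid_partner`, `type_partner`, `partner_reviewed`) and `rejected`
#'   (record key + `reason`).
#' @export
normalize_ids <- function(records, dict, seeds) {
  stopifnot(inherits(dict, "protein_dictionary"))
  if (!nrow(records)) {
    return(list(records = .empty_normalized(), rejected = .empty_rejection()))
  }
  acc_a <- .strip_accession(records$id_a)
  acc_b <- .strip_accession(records$id_b)
  can_a <- dict$canonical[match(acc_a, dict$accession)]
  can_b <- dict$canonical[match(acc_b, dict$accession)]

  a_is_seed <- !is.na(can_a) & can_a %in% seeds
  b_is_seed <- !is.na(can_b) & can_b %in% seeds

  # Orient so the seed member comes first; for seed-seed edges keep the
  # lexicographically smaller accession as "seed" (the pair is unordered).
  seed_first <- a_is_seed & (!b_is_seed | .na_false(can_a <= can_b))
  seed    <- ifelse(seed_first, can_a, can_b)
  partner <- ifelse(seed_first, can_b, can_a)
  partner_raw_mapped <- ifelse(seed_first, !is.na(can_b), !is.na(can_a))
  taxid_seed    <- ifelse(seed_first, records$taxid_a, records$taxid_b)
  taxid_partner <- ifelse(seed_first, records$taxid_b, records$taxid_a)
  type_partner  <- ifelse(seed_first, records$type_b, records$type_a)

  # unmapped partners carrying an explicit non-protein molecule type are
  # logged as non_protein (chemicals, miRNA, ... are never in a protein
  # dictionary, so the type label is the informative reason)
  reason <- rep(NA_character_, nrow(records))
  reason[!partner_raw_mapped] <- ifelse(
    tolower(ifelse(is.na(type_partner), "", type_partner))[!partner_raw_mapped] %in%
      .NONPROTEIN_TYPES, "non_protein", "unmapped")
  reason[!(a_is_seed | b_is_seed)] <- "no_seed"

  keep <- is.na(reason)
  out <- data.frame(
    seed = seed[keep],
    partner = partner[keep],
    method_term = records$method_term[keep],
    publication = records$publication[keep],
    source_db = records$source_db[keep],
    taxid_seed = taxid_seed[keep],
    taxid_partner = taxid_partner[keep],
    type_partner = type_partner[keep],
    stringsAsFactors = FALSE
  )
  out$partner_reviewed <- dict$reviewed[match(out$partner, dict$accession)]
  rejected <- data.frame(
    id_a = records$id_a[!keep],
    id_b = records$id_b[!keep],
    source_db = records$source_db[!keep],
    publication = records$publication[!keep],
    reason = reason[!keep],
    stringsAsFactors = FALSE
  )
  list(records = out, rejected = rejected)
}

.na_false <- function(x) {
  x[is.na(x)] <- FALSE
  x
}

.empty_normalized <- function() {
  data.frame(
    seed = character(0), partner = character(0), method_term = character(0),
    publication = character(0), source_db = character(0),
    taxid_seed = integer(0), taxid_partner = integer(0),
    type_partner = character(0), partner_reviewed = logical(0),
    stringsAsFactors = FALSE
  )
}

.empty_rejection <- function() {
  data.frame(
    id_a = character(0), id_b = character(0), source_db = character(0),
    publication = character(0), reason = character(0),
    stringsAsFactors = FALSE
  )
}

# Canonical unordered-pair key: members sorted lexicographically, so that
# A-B and B-A collapse; self-interactions (homodimers) are A-A.
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Merge per-database record sets and remove repeated equivalent entries
#'
#' An entry is "repeated equivalent" when the same unordered protein pair is
#' supported by the same publication and the same (grouped, if
#' [reassign_methods()] has run) detection method in more than one source
#' database. Exactly one record per such key survives; its `source_db` field
#' lists every contributing database, sorted and `|`-joined, so the output is
#' independent of input ordering. Applying the operation twice is a no-op.
#'
#' @param ... One or more normalized-interaction data frames (typically one
#'   per source database), or a single list of them.
#' @return A single deduplicated normalized-interaction data frame.
#' @export
merge_and_dedupe <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1L && is.list(inputs[[1]]) && !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  rec <- do.call(rbind, inputs)
  if (is.null(rec) || !nrow(rec)) return(.empty_normalized())
  method <- if ("method_group" %in% names(rec)) rec$method_group else rec$method_term
  key <- paste(.pair_key(rec$seed, rec$partner), rec$publication, method, sep = "~")
  # deterministic survivor regardless of input ordering
  ord <- order(key, rec$seed, rec$partner, rec$source_db)
  rec <- rec[ord, , drop = FALSE]
  key <- key[ord]
  split_db <- split(rec$source_db, key)
  merged_db <- vapply(split_db, function(dbs) {
    paste(sort(unique(dbs)), collapse = "|")
  }, character(1))
  first <- !duplicated(key)
  out <- rec[first, , drop = FALSE]
  out$source_db <- unname(merged_db[key[first]])
  out <- out[order(key[first]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write normalized interaction records to a MITAB-like TSV
#'
#' Round-trips with [read_normalized()]: writing and re-reading reproduces
#' the same normalized set.
#'
#' @param records Normalized-interaction data frame.
#' @param path Output file path.
#' @export
write_normalized <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "-")
  invisible(path)
}

#' @rdname write_normalized
#' @return `read_normalized()` returns the normalized-interaction data frame.
#' @export
read_normalized <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "-")
  chr <- c("seed", "partner", "method_term", "publication", "source_db",
           "type_partner", "method_group")
  for (col in intersect(chr, names(d))) d[[col]] <- as.character(d[[col]])
  for (col in intersect(c("taxid_seed", "taxid_partner"), names(d))) {
    d[[col]] <- as.integer(d[[col]])
  }
  for (col in intersect(c("partner_reviewed", "is_apms"), names(d))) {
    d[[col]] <- as.logical(d[[col]])
  }
  d
}
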