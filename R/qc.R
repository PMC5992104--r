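# Quality filters applied to normalized interaction records before
# confidence scoring: non-protein interactors, unreviewed annotations and
# non-human interactors (including seed orthologs) are removed, and
# detection-method terms are reassigned to coarse method groups.
#
# Each filter is a pure predicate on a record, so the retained set is
# independent of the order in which the filters are chained, and
# |retained| + |rejected| = |input| for every filter.

.HUMAN_TAXID <- 9606L

.NONPROTEIN_TYPES <- c("small molecule", "ribonucleic acid",
                       "deoxyribonucleic acid", "nucleic acid", "gene",
                       "complex", "chemical", "mirna", "rna", "drug")

.filter_split <- function(records, keep, reason) {
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason
  else rejected$reason <- character(0)
  list(records = records[keep, , drop = FALSE], rejected = rejected)
}

#' Remove non-protein interactors
#'
#' Drops records whose partner is typed as a chemical, small molecule,
#' nucleic acid or any other non-protein molecule class. Records with no
#' type label but an identifier that resolved through the protein
#' dictionary (UniProt namespace) are treated as proteins, since MITAB 2.5
#' files frequently omit the interactor-type columns.
#'
#' @param records Normalized-interaction data frame (column `type_partner`).
#' @return List with `records` (retained) and `rejected` (reason
#'   `"non_protein"`).
#' @export
filter_non_protein <- function(records) {
  type <- tolower(ifelse(is.na(records$type_partner), "protein",
                         records$type_partner))
  keep <- !(type %in% .NONPROTEIN_TYPES)
  .filter_split(records, keep, "non_protein")
}

#' Remove partners without a reviewed annotation
#'
#' Unreviewed (TrEMBL-style automatic) entries are discarded. Isoform and
#' transcript suffixes have already been collapsed to the canonical parent
#' during normalization, so the reviewed flag is checked on the canonical
#' accession.
#'
#' @param records Normalized-interaction data frame.
#' @param dict A [read_protein_dictionary()] table.
#' @return List with `records` and `rejected` (reason `"unreviewed"`).
#' @export
filter_unreviewed <- function(records, dict) {
  reviewed <- dict$reviewed[match(records$partner, dict$accession)]
  keep <- .na_false(reviewed)
  .filter_split(records, keep, "unreviewed")
}

#' Remove non-human interactors
#'
#' Both members of the pair must carry the human taxid (9606). Seed
#' orthologs from other species are rejected like any other non-human
#' interactor. Records with an unknown partner taxid are rejected
#' conservatively.
#'
#' @param records Normalized-interaction data frame.
#' @return List with `records` and `rejected` (reason `"non_human"`).
#' @export
filter_non_human <- function(records) {
  keep <- .na_false(records$taxid_partner == .HUMAN_TAXID) &
    (is.na(records$taxid_seed) | records$taxid_seed == .HUMAN_TAXID)
  .filter_split(records, keep, "non_human")
}

#' Read a detection-method group map
#'
#' The map mirrors the role of a molecular-interaction ontology rollup:
#' similar PSI-MI detection-method terms are grouped so that, e.g., all
#' two-hybrid variants count as a single method in the method score. The
#' package ships a default map covering the common MI branches
#' (`system.file("extdata", "method_groups.tsv", package = "wppina")`).
#'
#' @param path TSV with columns `mi_term`, `group`, `is_apms`.
#' @return A `data.frame` of class `method_group_map`.
#' @export
read_method_groups <- function(path = system.file("extdata", "method_groups.tsv",
                                                  package = "wppina")) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "character", "character"))
  need <- c("mi_term", "group", "is_apms")
  if (!all(need %in% names(m))) {
    stop("method group map must have columns: ", paste(need, collapse = ", "))
  }
  m$is_apms <- as.logical(m$is_apms) | m$is_apms %in% c("1", "yes")
  if (anyDuplicated(m$mi_term)) stop("each MI term must map to exactly one group")
  if (!any(m$is_apms)) stop("at least one method group must be flagged APMS")
  class(m) <- c("method_group_map", class(m))
  m
}

#' Reassign detection methods to method groups
#'
#' Attaches a `method_group` and `is_apms` flag to every record. Terms
#' absent from the map fall back to the raw term itself as a singleton
#' non-APMS group (one warning summarizes them); records with an unknown
#' method term get the group `"unknown"`.
#'
#' @param records Normalized-interaction data frame (column `method_term`).
#' @param map A [read_method_groups()] table.
#' @return The records with `method_group` and `is_apms` columns added.
#' @export
reassign_methods <- function(records, map = read_method_groups()) {
  stopifnot(inherits(map, "method_group_map"))
  idx <- match(records$method_term, map$mi_term)
  group <- map$group[idx]
  is_apms <- map$is_apms[idx]
  unmapped <- is.na(idx) & !is.na(records$method_term)
  if (any(unmapped)) {
    warning(length(unique(records$method_term[unmapped])),
            " detection-method term(s) not in the group map; kept as singleton groups")
    group[unmapped] <- records$method_term[unmapped]
    is_apms[unmapped] <- FALSE
  }
  unknown <- is.na(records$method_term)
  group[unknown] <- "unknown"
  is_apms[unknown] <- FALSE
  records$method_group <- group
  records$is_apms <- is_apms
  records
}

#' Apply the full quality-filter chain
#'
#' Convenience wrapper running [filter_non_protein()],
#' [filter_unreviewed()], [filter_non_human()] and [reassign_methods()] in
#' sequence and pooling the rejection logs.
#'
#' @inheritParams filter_unreviewed
#' @inheritParams reassign_methods
#' @return List with `records` (filtered, method-grouped) and `rejected`.
#' @export
apply_qc_filters <- function(records, dict, map = read_method_groups()) {
  s1 <- filter_non_protein(records)
  s2 <- filter_unreviewed(s1$records, dict)
  s3 <- filter_non_human(s2$records)
  rejected <- rbind(
    s1$rejected[names(s3$rejected)],
    s2$rejected[names(s3$rejected)],
    s3$rejected
  )
  list(records = reassign_methods(s3$records, map), rejected = rejected)
}
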