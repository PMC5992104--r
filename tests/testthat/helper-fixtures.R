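# Shared fixtures, all built in code.

# Tiny protein dictionary: canonical P0000x entries, one secondary alias,
# one unreviewed entry, one mouse ortholog.
make_dict <- function() {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(
    "accession\tcanonical\tgene_symbol\ttaxid\treviewed",
    "P00001\tP00001\tSEEDA\t9606\tTRUE",
    "P00002\tP00002\tSEEDB\t9606\tTRUE",
    "Q00001\tQ00001\tGENE1\t9606\tTRUE",
    "Q00002\tQ00002\tGENE2\t9606\tTRUE",
    "Q00003\tQ00003\tGENE3\t9606\tTRUE",
    "Q00009\tQ00001\tGENE1\t9606\tTRUE",   # secondary alias of Q00001
    "T00001\tT00001\tTREMBL1\t9606\tFALSE", # unreviewed
    "M00001\tM00001\tMseeda\t10090\tTRUE"   # mouse ortholog
  ), path)
  read_protein_dictionary(path)
}

# Normalized-interaction rows in one call.
nrec <- function(seed, partner, method = "MI:0018", pub = "1", db = "dbA",
                 taxid_partner = 9606L, type = NA_character_,
                 reviewed = TRUE) {
  data.frame(seed = seed, partner = partner, method_term = method,
             publication = pub, source_db = db, taxid_seed = 9606L,
             taxid_partner = taxid_partner, type_partner = type,
             partner_reviewed = reviewed, stringsAsFactors = FALSE)
}

# Evidence-set row as produced by aggregate_evidence(), for direct scoring.
ev_row <- function(seed = "P00001", partner = "Q00001", n_methods = 1L,
                   n_publications = 1L, apms_any = FALSE, apms_only = FALSE) {
  data.frame(seed = seed, partner = partner, n_methods = n_methods,
             n_publications = n_publications, apms_any = apms_any,
             apms_only = apms_only, stringsAsFactors = FALSE)
}

crapome_with <- function(...) {
  # crapome_with(Q00001 = 0.8, ...) -> crapome_table
  f <- c(...)
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c("protein\tn_hit\tn_total",
               sprintf("%s\t%d\t1000", names(f), round(f * 1000))), path)
  read_crapome(path)
}

# The headline fixture (the generator's default stated world) and the full
# pipeline run on it are expensive enough to share across test files.
.headline_cache <- new.env(parent = emptyenv())
headline_fixture <- function() {
  if (is.null(.headline_cache$key)) {
    dir <- file.path(tempdir(), "wppina-headline-fixture")
    generate_fixture(fixture_spec(seed = 42), dir)
    .headline_cache$dir <- dir
    .headline_cache$key <- yaml::read_yaml(file.path(dir, "answer_key.yaml"))
  }
  list(dir = .headline_cache$dir, key = .headline_cache$key)
}
headline_run <- function() {
  if (is.null(.headline_cache$res)) {
    fx <- headline_fixture()
    .headline_cache$res <- suppressWarnings(
      run_pipeline(read_run_config(file.path(fx$dir, "run.yaml")))
    )
  }
  .headline_cache$res
}
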