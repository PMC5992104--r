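# MITAB ingestion, identifier normalization, merging and deduplication.

mitab_row <- function(id_a, id_b, method = 'psi-mi:"MI:0018"(two hybrid)',
                      pub = "pubmed:1000001", tax_a = "taxid:9606(human)",
                      tax_b = "taxid:9606(human)", extra = character(0)) {
  paste(c(id_a, id_b, "-", "-", "-", "-", method, "-", pub, tax_a, tax_b,
          "-", "-", "-", "-", extra), collapse = "\t")
}

write_mitab_fixture <- function(rows, env = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = env)
  writeLines(c("#ID(s) interactor A\tID(s) interactor B", rows), path)
  path
}

test_that("read_mitab parses the consumed MITAB 2.5 columns", {
  path <- write_mitab_fixture(c(
    mitab_row("uniprotkb:Q38SD2", "uniprotkb:Q00001"),
    mitab_row("uniprotkb:P00001|intact:EBI-1", "ddbj/embl/genbank:AAA1|uniprotkb:Q00002"),
    mitab_row("uniprotkb:P00001", "uniprotkb:Q00003",
              method = 'psi-mi:"MI:0004"(affinity chromatography technology)',
              pub = "doi:10.1/x|pubmed:2000002", tax_b = "taxid:10090(mouse)")
  ))
  rec <- read_mitab(path, "dbA")
  expect_equal(nrow(rec), 3L)
  # namespace retained verbatim
  expect_equal(rec$id_a[[1]], "uniprotkb:Q38SD2")
  # UniProt namespace preferred inside multi-value fields
  expect_equal(rec$id_a[[2]], "uniprotkb:P00001")
  expect_equal(rec$id_b[[2]], "uniprotkb:Q00002")
  expect_equal(rec$method_term, c("MI:0018", "MI:0018", "MI:0004"))
  expect_equal(rec$publication[[3]], "2000002")
  expect_equal(rec$taxid_b, c(9606L, 9606L, 10090L))
  expect_equal(rec$source_db, rep("dbA", 3))
})

test_that("read_mitab handles empty, malformed and missing files", {
  empty <- write_mitab_fixture(character(0))
  expect_equal(nrow(read_mitab(empty, "dbA")), 0L)

  bad <- write_mitab_fixture(c(mitab_row("uniprotkb:A", "uniprotkb:B"),
                               "uniprotkb:A\tuniprotkb:B\tonly-three-cols"))
  expect_warning(rec <- read_mitab(bad, "dbA"), "malformed")
  expect_equal(nrow(rec), 1L)

  expect_error(read_mitab(file.path(tempdir(), "nope.tsv"), "dbA"), "not found")
})

test_that("read_mitab picks up extended interactor-type columns when present", {
  path <- write_mitab_fixture(mitab_row(
    "uniprotkb:P00001", "chebi:CHEBI:1234",
    extra = c("-", "-", "-", "-", "-",
              'psi-mi:"MI:0326"(protein)', 'psi-mi:"MI:0328"(small molecule)')))
  rec <- read_mitab(path, "dbA")
  expect_equal(rec$type_a, "protein")
  expect_equal(rec$type_b, "small molecule")
})

test_that("normalize_ids maps aliases and isoforms to canonical accessions", {
  dict <- make_dict()
  raw <- data.frame(
    source_db = "dbA",
    id_a = rep("uniprotkb:P00001", 4),
    id_b = c("uniprotkb:Q00009",      # secondary alias of Q00001
             "uniprotkb:Q00001-2",    # isoform of Q00001
             "uniprotkb:Q00002",      # already canonical
             "uniprotkb:ZZZZZ"),      # absent from dictionary
    taxid_a = 9606L, taxid_b = 9606L, method_term = "MI:0018",
    publication = c("1", "2", "3", "4"),
    type_a = NA_character_, type_b = NA_character_,
    stringsAsFactors = FALSE
  )
  out <- normalize_ids(raw, dict, seeds = "P00001")
  expect_equal(out$records$partner, c("Q00001", "Q00001", "Q00002"))
  expect_equal(out$rejected$reason, "unmapped")
  # unmapped partner with a non-protein type gets the informative reason
  raw$id_b[[4]] <- "chebi:CHEBI:1"
  raw$type_b[[4]] <- "small molecule"
  out2 <- normalize_ids(raw, dict, seeds = "P00001")
  expect_equal(out2$rejected$reason, "non_protein")
})

test_that("normalization is idempotent and orients seed-seed pairs stably", {
  dict <- make_dict()
  raw <- data.frame(
    source_db = "dbA",
    id_a = c("uniprotkb:P00002", "uniprotkb:Q00001"),
    id_b = c("uniprotkb:P00001", "uniprotkb:P00001"),
    taxid_a = 9606L, taxid_b = 9606L, method_term = "MI:0018",
    publication = "1", type_a = NA_character_, type_b = NA_character_,
    stringsAsFactors = FALSE
  )
  out <- normalize_ids(raw, dict, seeds = c("P00001", "P00002"))
  # seed-seed edge oriented lexicographically; seed detected on either side
  expect_equal(out$records$seed, c("P00001", "P00001"))
  expect_equal(out$records$partner, c("P00002", "Q00001"))
  # re-normalizing the normalized output changes nothing
  renorm <- data.frame(
    source_db = out$records$source_db,
    id_a = paste0("uniprotkb:", out$records$seed),
    id_b = paste0("uniprotkb:", out$records$partner),
    taxid_a = out$records$taxid_seed, taxid_b = out$records$taxid_partner,
    method_term = out$records$method_term,
    publication = out$records$publication,
    type_a = NA_character_, type_b = out$records$type_partner,
    stringsAsFactors = FALSE
  )
  out2 <- normalize_ids(renorm, dict, seeds = c("P00001", "P00002"))
  expect_equal(out2$records$seed, out$records$seed)
  expect_equal(out2$records$partner, out$records$partner)
  expect_equal(nrow(out2$rejected), 0L)
})

test_that("merge_and_dedupe removes repeated equivalent entries only", {
  a <- nrec("P00001", "Q00001", pub = "1", db = "dbA")
  b <- nrec("P00001", "Q00001", pub = "1", db = "dbB")   # same pub: duplicate
  c <- nrec("P00001", "Q00001", pub = "2", db = "dbB")   # new pub: evidence
  d <- nrec("Q00001", "P00001", pub = "1", db = "dbC")   # reversed pair order
  merged <- merge_and_dedupe(a, b, c, d)
  expect_equal(nrow(merged), 2L)
  surv <- merged[merged$publication == "1", ]
  expect_equal(surv$source_db, "dbA|dbB|dbC")
  # idempotent and order-independent
  expect_equal(merge_and_dedupe(merged), merged)
  expect_equal(merge_and_dedupe(d, c, b, a), merged)
})

test_that("dedupe keys include the grouped method so distinct evidence survives", {
  a <- reassign_methods(nrec("P00001", "Q00001", method = "MI:0018", pub = "1"))
  b <- reassign_methods(nrec("P00001", "Q00001", method = "MI:0004", pub = "1"))
  expect_equal(nrow(merge_and_dedupe(a, b)), 2L)
  # but two MI terms of the same group from the same publication collapse
  y1 <- reassign_methods(nrec("P00001", "Q00001", method = "MI:0018", pub = "1"))
  y2 <- reassign_methods(nrec("P00001", "Q00001", method = "MI:0397", pub = "1"))
  expect_equal(nrow(merge_and_dedupe(y1, y2)), 1L)
})

test_that("normalized records round-trip through TSV", {
  recs <- reassign_methods(rbind(
    nrec("P00001", "Q00001", pub = "1"),
    nrec("P00001", "Q00002", method = "MI:0004", pub = "2")
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_normalized(recs, path)
  back <- read_normalized(path)
  expect_equal(back[order(back$partner), names(recs)],
               recs[order(recs$partner), ], ignore_attr = TRUE)
})
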