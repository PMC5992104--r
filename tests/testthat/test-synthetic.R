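# Fixture generator: determinism, planted retention, spec validation and
# answer-key consistency with the pipeline.

test_that("generation is deterministic given the same spec", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sp <- fixture_spec(seed = 7, n_reported = rep(10L, 4), n_retained = rep(4L, 4),
                     overlap = "none", tiers = "disjoint",
                     array = list(per_seed = rep(8L, 4), n_proteins = 60L))
  k1 <- generate_fixture(sp, d1)
  k2 <- generate_fixture(sp, d2)
  expect_identical(k1, k2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # a different seed moves the stochastic parts (spot intensities)
  d3 <- withr::local_tempdir()
  generate_fixture(fixture_spec(seed = 8, n_reported = rep(10L, 4),
                                n_retained = rep(4L, 4),
                                overlap = "none", tiers = "disjoint",
                                array = list(per_seed = rep(8L, 4),
                                             n_proteins = 60L)), d3)
  expect_false(identical(readLines(file.path(d1, "array.tsv")),
                         readLines(file.path(d3, "array.tsv"))))
})

test_that("a 40%-replication fixture yields exactly 40% retention end to end", {
  dir <- withr::local_tempdir()
  sp <- fixture_spec(seed = 3, n_reported = rep(10L, 4), n_retained = rep(4L, 4),
                     overlap = "none", tiers = "disjoint",
                     array = list(per_seed = rep(8L, 4), n_proteins = 60L))
  generate_fixture(sp, dir)
  res <- suppressWarnings(run_pipeline(read_run_config(file.path(dir, "run.yaml")),
                                       stages = "score"))
  expect_equal(res$retention$n_reported, rep(10L, 4))
  expect_equal(res$retention$n_retained, rep(4L, 4))
  expect_equal(res$retention$retention_pct, rep(40, 4))
})

test_that("inconsistent specs fail loudly", {
  expect_error(fixture_spec(n_reported = c(5L, 5L, 5L, 5L),
                            n_retained = c(6L, 0L, 0L, 0L)), "inconsistent")
  # headline overlap cannot fit into tiny interactomes
  expect_error(
    generate_fixture(fixture_spec(n_reported = rep(5L, 4),
                                  n_retained = rep(2L, 4)),
                     withr::local_tempdir()),
    "inconsistent")
  # more planted array proteins than array positions
  expect_error(
    generate_fixture(fixture_spec(array = list(n_proteins = 50L)),
                     withr::local_tempdir()),
    "inconsistent|array")
})

test_that("the answer key matches the pipeline on every stage", {
  fx <- headline_fixture()
  res <- headline_run()
  key <- fx$key

  # literature retention
  expect_equal(res$retention$n_reported, unname(unlist(key$literature$n_reported)))
  expect_equal(res$retention$n_retained, unname(unlist(key$literature$n_retained)))
  expect_equal(res$retention$retention_pct,
               unname(unlist(key$literature$retention_pct)))
  # per-pair scores
  pairs_key <- read.delim(file.path(fx$dir, "answer_key_pairs.tsv"),
                          stringsAsFactors = FALSE)
  got <- res$scored
  m <- match(paste(pmin(pairs_key$seed, pairs_key$partner),
                   pmax(pairs_key$seed, pairs_key$partner)),
             paste(pmin(got$seed, got$partner), pmax(got$seed, got$partner)))
  expect_false(anyNA(m))
  expect_equal(got$ms[m], pairs_key$ms)
  expect_equal(got$ps[m], pairs_key$ps)
  expect_equal(got$cs[m], pairs_key$cs)
  expect_equal(got$total[m], pairs_key$total)
  expect_equal(got$total[m] > 2, pairs_key$retained)

  # array positives after control subtraction = planted binders exactly
  pos_key <- read.delim(file.path(fx$dir, "answer_key_positives.tsv"),
                        stringsAsFactors = FALSE)
  for (s in names(res$positives)) {
    expect_setequal(res$positives[[s]]$protein,
                    pos_key$protein[pos_key$seed == s])
  }
  es <- res$exp_summary
  expect_equal(es$n_interactions, key$experimental$n_interactions)
  expect_equal(es$n_nodes, key$experimental$n_nodes)
  expect_equal(as.list(es$tiers), key$experimental$tiers)

  # integration categories
  expect_equal(nrow(res$common), key$integration$n_common_thresholded)
  expect_setequal(res$core$nodes$protein[res$core$nodes$category == "i"],
                  unlist(key$integration$cat_i))
  expect_setequal(res$core$nodes$protein[res$core$nodes$category == "ii"],
                  unlist(key$integration$cat_ii))
  expect_setequal(res$rescued$partner, unlist(key$integration$cat_iii))
  expect_equal(nrow(res$core$nodes), key$integration$n_common_core)
  expect_equal(res$n_nonthresholded_overlap,
               key$integration$n_nonthresholded_overlap)

  # co-expression tissue sets
  cx_key <- read.delim(file.path(fx$dir, "answer_key_coexpression.tsv"),
                       stringsAsFactors = FALSE, na.strings = NULL)
  got_cx <- res$coexpression$pairs
  mk <- match(paste(cx_key$seed, cx_key$partner),
              paste(got_cx$seed_acc, got_cx$partner_acc))
  expect_false(anyNA(mk))
  expect_equal(got_cx$n_tissues[mk], cx_key$n_tissues)
  sort_set <- function(x) {
    vapply(strsplit(x, "|", fixed = TRUE),
           function(s) paste(sort(s), collapse = "|"), character(1))
  }
  expect_equal(sort_set(got_cx$tissues[mk]), sort_set(ifelse(is.na(cx_key$tissues), "", cx_key$tissues)))
  expect_equal(got_cx$not_found[mk], cx_key$not_found)
  expect_equal(as.list(res$coexpression_summary$per_tissue_pct),
               key$coexpression$per_tissue_pct)

  # planted GO term is the top enrichment hit and lands in its block
  expect_equal(res$enrichment$term[[1]], key$enrichment$planted_term)
  expect_true(res$enrichment$significant[[1]])
  expect_equal(res$blocks$blocks$block[[1]], key$enrichment$functional_block)
})
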