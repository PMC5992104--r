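# Confidence scoring: MS/PS/CS components, totals, threshold and the
# literature network.

# Independent restatement of the scoring rules, written as a literal
# bracket-by-bracket transcription for oracle comparison.
oracle_score <- function(n_methods, n_pubs, f, apms_any, apms_only) {
  ms <- if (n_methods >= 2) 2 else 1
  ps <- if (n_pubs >= 2) 2 else 1
  cs <- 0
  if (apms_any) {
    if (f > 0.5 && apms_only) {
      cs <- -1
    } else if ((f > 0.5 && !apms_only) || (f >= 0.3 && f <= 0.5 && apms_only)) {
      cs <- -0.5
    }
  }
  c(ms = ms, ps = ps, cs = cs, total = ms + ps + cs)
}

test_that("aggregate_evidence collapses records into per-pair evidence sets", {
  recs <- reassign_methods(rbind(
    nrec("P00001", "Q00001", method = "MI:0019", pub = "1"),
    nrec("P00001", "Q00001", method = "MI:0019", pub = "2"),
    nrec("P00001", "Q00001", method = "MI:0018", pub = "3"),
    nrec("P00001", "Q00002", method = "MI:0004", pub = "4")
  ))
  ev <- aggregate_evidence(recs)
  ev <- ev[order(ev$partner), ]
  expect_equal(ev$n_methods, c(2L, 1L))
  expect_equal(ev$n_publications, c(3L, 1L))
  expect_equal(ev$methods[[1]], c("coimmunoprecipitation", "two hybrid"))
  expect_equal(ev$apms_only, c(FALSE, TRUE))
  expect_equal(ev$apms_any, c(FALSE, TRUE))
})

test_that("method and publication scores saturate at 2", {
  expect_equal(method_score(c(1L, 2L, 5L)), c(1L, 2L, 2L))
  expect_equal(publication_score(c(1L, 2L, 10L)), c(1L, 2L, 2L))
})

test_that("CRAPome score follows the contaminant brackets", {
  crap <- crapome_with(HI = 0.8, MID = 0.4, LO = 0.1, EDGE5 = 0.5, EDGE3 = 0.3)
  cs <- function(p, any, only) crapome_score(p, any, only, crap)
  expect_equal(cs("HI", TRUE, TRUE), -1)       # >50%, APMS-only
  expect_equal(cs("HI", TRUE, FALSE), -0.5)    # >50%, plus non-APMS evidence
  expect_equal(cs("MID", TRUE, TRUE), -0.5)    # 30-50%, APMS-only
  expect_equal(cs("MID", TRUE, FALSE), 0)      # 30-50% with non-APMS evidence
  expect_equal(cs("LO", TRUE, TRUE), 0)        # <30%
  expect_equal(cs("HI", FALSE, FALSE), 0)      # no APMS evidence: never penalized
  # boundaries: 0.5 belongs to the 30-50% bracket, 0.3 is inside it
  expect_equal(cs("EDGE5", TRUE, TRUE), -0.5)
  expect_equal(cs("EDGE3", TRUE, TRUE), -0.5)
  # absent from the table: hit fraction 0
  expect_equal(cs("UNSEEN", TRUE, TRUE), 0)
})

test_that("all 12 (MS, PS, CS) combinations match the rule enumeration", {
  crap <- crapome_with(HI = 0.8, MID = 0.4)
  # realize each CS level through an actual evidence configuration
  cs_setup <- list(
    `0`    = list(partner = "CLEAN", apms_any = TRUE,  apms_only = TRUE,  f = 0),
    `-0.5` = list(partner = "MID",   apms_any = TRUE,  apms_only = TRUE,  f = 0.4),
    `-1`   = list(partner = "HI",    apms_any = TRUE,  apms_only = TRUE,  f = 0.8)
  )
  for (nm in c(1L, 2L)) for (np in c(1L, 2L)) for (cs_nm in names(cs_setup)) {
    s <- cs_setup[[cs_nm]]
    ev <- ev_row(partner = s$partner, n_methods = nm, n_publications = np,
                 apms_any = s$apms_any, apms_only = s$apms_only)
    got <- score_evidence(ev, crap)
    want <- oracle_score(nm, np, s$f, s$apms_any, s$apms_only)
    expect_equal(got$ms, unname(want["ms"]), info = paste(nm, np, cs_nm))
    expect_equal(got$ps, unname(want["ps"]), info = paste(nm, np, cs_nm))
    expect_equal(got$cs, unname(want["cs"]), info = paste(nm, np, cs_nm))
    expect_equal(got$total, unname(want["total"]), info = paste(nm, np, cs_nm))
    expect_true(got$total >= 1 && got$total <= 4)
  }
})

test_that("totals are monotone in added methods and publications", {
  crap <- crapome_with(HI = 0.8)
  for (partner in c("HI", "CLEAN")) {
    base <- score_evidence(ev_row(partner = partner, n_methods = 1L,
                                  n_publications = 1L, apms_any = TRUE,
                                  apms_only = TRUE), crap)
    more_m <- score_evidence(ev_row(partner = partner, n_methods = 2L,
                                    n_publications = 1L, apms_any = TRUE,
                                    apms_only = FALSE), crap)
    more_p <- score_evidence(ev_row(partner = partner, n_methods = 1L,
                                    n_publications = 2L, apms_any = TRUE,
                                    apms_only = TRUE), crap)
    expect_gte(more_m$total, base$total)
    expect_gte(more_p$total, base$total)
  }
})

test_that("thresholding discards single-evidence pairs and keeps replicated ones", {
  scored <- score_evidence(rbind(
    ev_row(partner = "A", n_methods = 1L, n_publications = 1L),  # total 2
    ev_row(partner = "B", n_methods = 2L, n_publications = 1L),  # total 3
    ev_row(partner = "C", n_methods = 2L, n_publications = 2L,
           apms_any = TRUE, apms_only = FALSE)                    # 4 + cs
  ), crapome_with(C = 0.8))  # C: ms2 ps2 cs -0.5 = 3.5
  parts <- total_and_threshold(scored)
  expect_setequal(parts$retained$partner, c("B", "C"))
  expect_setequal(parts$discarded$partner, "A")
  expect_equal(nrow(parts$retained) + nrow(parts$discarded), nrow(scored))
  # no single-method single-publication clean pair ever survives
  expect_false(any(parts$retained$n_methods == 1L &
                     parts$retained$n_publications == 1L &
                     parts$retained$cs == 0))
})

test_that("retention percentages reproduce the half-up one-decimal convention", {
  mk <- function(n, seed) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      ev_row(seed = seed, partner = sprintf("%s_X%03d", seed, i))
    }))
  }
  scored <- rbind(mk(57, "SA"), mk(7, "SB"))
  retained <- rbind(mk(38, "SA"), mk(4, "SB"))
  out <- retention_summary(scored, retained, c("SA", "SB"))
  expect_equal(out$n_reported, c(57L, 7L))
  expect_equal(out$n_retained, c(38L, 4L))
  expect_equal(out$retention_pct, c(66.7, 57.1))
  # zero retention keeps the seed with 0.0%
  out0 <- retention_summary(mk(5, "SC"), mk(0, "SC"), "SC")
  expect_equal(out0$retention_pct, 0)
})

test_that("the literature network keeps isolated seeds and dimer edges", {
  retained <- score_evidence(rbind(
    ev_row(seed = "P00001", partner = "P00001", n_methods = 2L),  # homodimer
    ev_row(seed = "P00001", partner = "P00002", n_methods = 2L),  # heterodimer
    ev_row(seed = "P00001", partner = "Q00001", n_methods = 2L)
  ), NULL)
  g <- build_literature_network(retained, seeds = c("P00001", "P00002", "P00003"))
  expect_setequal(igraph::V(g)$name[igraph::V(g)$role == "seed"],
                  c("P00001", "P00002", "P00003"))
  expect_equal(igraph::degree(g)[["P00003"]], 0)   # isolated seed retained
  dim <- dimer_edges(g)
  expect_equal(nrow(dim), 2L)
  expect_equal(sort(dim$homodimer), c(FALSE, TRUE))
  expect_equal(igraph::E(g)$provenance, rep("literature", 3))
})
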