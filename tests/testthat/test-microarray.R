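# Z-score hit calling, control subtraction and the experimental network.

spots <- function(bait, protein, z, bg_mean = 500, bg_sd = 50) {
  # two duplicate spots at the given per-spot z values
  data.frame(bait = bait, protein = rep(protein, each = 2),
             spot_index = rep(1:2, length(protein)),
             intensity = bg_mean + rep(z, each = 2) * bg_sd,
             spot_class = "probe", stringsAsFactors = FALSE)
}

test_that("compute_z averages duplicate-spot Z values and calls strict hits", {
  tab <- rbind(
    spots("S1", "A", 5),            # clear hit
    spots("S1", "B", 0),            # at background
    spots("S1", "C", 3)             # exactly at threshold: NOT a hit
  )
  # unequal duplicates: z of spots is averaged, not the intensities re-scored
  tab <- rbind(tab, data.frame(bait = "S1", protein = "D", spot_index = 1:2,
                               intensity = 500 + c(2, 6) * 50,
                               spot_class = "probe"))
  z <- compute_z(tab, bg_mean = 500, bg_sd = 50)
  z <- z[order(z$protein), ]
  expect_equal(z$z, c(5, 0, 3, 4))
  expect_equal(z$is_hit, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(z$n_spots, rep(2L, 4))
})

test_that("background can be estimated from designated background spots", {
  set.seed(7)
  bg <- data.frame(bait = "S1", protein = sprintf("BUF%02d", 1:40),
                   spot_index = 1L, intensity = rnorm(40, 500, 50),
                   spot_class = "background", stringsAsFactors = FALSE)
  tab <- rbind(spots("S1", c("A", "B"), c(8, 0)), bg)
  z <- compute_z(tab)
  expect_true(z$is_hit[z$protein == "A"])
  expect_false(z$is_hit[z$protein == "B"])
  expect_error(compute_z(spots("S1", "A", 5)), "background")
  expect_error(compute_z(spots("S1", "A", 5), bg_mean = 500, bg_sd = 0),
               "positive")
})

test_that("raising the threshold never increases positive counts", {
  set.seed(11)
  tab <- spots("S1", sprintf("P%02d", 1:50), runif(50, -2, 8))
  n <- vapply(c(2, 3, 4, 5), function(th) {
    sum(compute_z(tab, 500, 50, z_threshold = th)$is_hit)
  }, numeric(1))
  expect_true(all(diff(n) <= 0))
})

test_that("control subtraction removes GFP binders from seed hits", {
  seed_calls <- compute_z(spots("S1", c("A", "B", "C"), c(5, 5, 1)), 500, 50)
  gfp_calls <- compute_z(spots("GFP", c("B", "D"), c(5, 5)), 500, 50)
  out <- subtract_control(seed_calls, gfp_calls)
  expect_equal(out$positives$protein, "A")     # specific binder retained
  expect_equal(out$removed$protein, "B")       # sticky binder excluded
  # GFP-only hit D appears in no positive set
  expect_false("D" %in% out$positives$protein)
})

test_that("experimental network counts satisfy the tier identities", {
  positives <- list(
    S1 = data.frame(protein = c("A", "B", "C"), z = 5),
    S2 = data.frame(protein = c("B", "C", "D"), z = 5),
    S3 = data.frame(protein = c("C"), z = 5)
  )
  s <- experimental_summary(positives)
  expect_equal(s$n_interactions, 7L)
  expect_equal(s$n_nodes, 4L)
  expect_equal(unname(s$tiers), c(2L, 1L, 1L))
  # sum over tiers gives the node count; k-weighted sum the interactions
  expect_equal(sum(s$tiers), s$n_nodes)
  expect_equal(sum(seq_along(s$tiers) * s$tiers), s$n_interactions)
  g <- build_experimental_network(positives)
  expect_equal(igraph::ecount(g), 7)
  expect_equal(igraph::V(g)$tier[igraph::V(g)$name == "C"], 3L)
  # disjoint positives: node count equals interaction count, all tier 1
  disj <- list(S1 = data.frame(protein = "X", z = 5),
               S2 = data.frame(protein = "Y", z = 5))
  sd <- experimental_summary(disj)
  expect_equal(sd$n_nodes, sd$n_interactions)
  expect_equal(unname(sd$tiers), c(2L, 0L))
})

test_that("planted specific binders are recovered exactly after subtraction", {
  set.seed(3)
  prots <- sprintf("P%03d", 1:60)
  specific <- list(S1 = prots[1:8], S2 = prots[9:12])
  sticky <- prots[13:16]
  rows <- list()
  for (bait in c("S1", "S2", "GFP")) {
    z <- runif(length(prots), -2, 2)
    if (bait != "GFP") z[prots %in% specific[[bait]]] <- 5
    z[prots %in% sticky] <- 6
    rows[[bait]] <- spots(bait, prots, z)
  }
  tab <- do.call(rbind, rows)
  bg <- data.frame(bait = c("S1", "S2", "GFP"), bg_mean = 500, bg_sd = 50)
  pos <- call_positives(tab, seeds = c("S1", "S2"), control = "GFP",
                        background = bg)
  expect_setequal(pos$S1$protein, specific$S1)
  expect_setequal(pos$S2$protein, specific$S2)
})
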