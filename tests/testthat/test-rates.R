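test_that("branch length in a bin sums overlap and conserves tree length", {
  phy <- ape::read.tree(text = "(t1:2,t2:2);")
  expect_equal(branch_length_in_bin(phy, old = 1, young = 0), 2)
  expect_equal(branch_length_in_bin(phy, old = 5, young = 3), 0)
  phy2 <- rand_tree(15, crown = 9, seed = 81)
  bins <- seq(0, 10, by = 0.5)
  tot <- sum(vapply(seq_len(length(bins) - 1), function(i)
    branch_length_in_bin(phy2, bins[i + 1], bins[i]), 0))
  expect_equal(tot, sum(phy2$edge.length), tolerance = 1e-9)
  expect_error(branch_length_in_bin(phy, old = 0, young = 1), "old > young")
})

test_that("lineage counts track occupancy through a history", {
  h <- manual_history()  # two tips, branch 1: A -> AB (1.5) -> B (0.5)
  # at the present, counts equal the tip-range tallies
  L0 <- lineages_in_area_at(h, 0)
  expect_equal(unname(L0[1, ]), c(1, 2))  # t1 = B, t2 = AB
  # just after the root split both lineages are in A only
  L2 <- lineages_in_area_at(h, 1.9)
  expect_equal(unname(L2[1, ]), c(2, 0))
  # between the expansion and the contraction branch 1 occupies both areas
  L1 <- lineages_in_area_at(h, 1.0)
  expect_equal(unname(L1[1, ]), c(2, 1))
  # multi-area ranges count once per area: sum >= lineages alive
  expect_gte(sum(L1), 2)
  expect_error(lineages_in_area_at(h, 99), "outside")
})

test_that("rate formulas divide counts by the right denominators", {
  h <- manual_history()
  rs <- rates_through_time(list(h, h), bin_width = 1)
  sm <- rs$summary
  pick <- function(st, area, bin, col = "median", dest = NA) {
    r <- sm[sm$statistic == st & sm$area == area & sm$bin == bin &
              (is.na(dest) & is.na(sm$dest) | !is.na(sm$dest) & sm$dest %in% dest), ]
    r[[col]]
  }
  # bin 2 = (1, 2] Ma: Br = 2 lineage-Myr, one A -> B dispersal
  expect_equal(pick("colonization", "A", 2, dest = "B"), 1 / 2)
  expect_equal(pick("emigration", "A", 2), 1 / 2)
  expect_equal(pick("immigration", "B", 2), 1 / 2)
  # lambda: the root split (age 2, copy of A) falls in bin 2; L_A at the
  # bin's old edge (2 Ma) is 0, so lambda is missing there
  expect_true(is.na(pick("lambda", "A", 2)))
  # E_X = sum_Y c_XtoY per bin per replicate (identical denominators)
  for (b in unique(sm$bin)) {
    em <- rs$E[1, , b]
    cc <- apply(rs$c[1, , , b, drop = FALSE], 2, sum, na.rm = TRUE)
    ok <- !is.na(em)
    expect_equal(em[ok], cc[ok], tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("rates are conserved and quartile bands are ordered", {
  set.seed(91)
  cfg <- sim_config(n_tips = 50, n_areas = 3, d = 0.1, e = 0.02,
                    crown_age = 10, root_range = "A", seed = 91)
  phy <- simulate_chronogram(cfg)
  sim <- simulate_ranges(phy, cfg)
  fit <- fit_range_model(phy, sim$geography)
  hs <- stochastic_map(fit, n = 12, seed = 3)
  rs <- rates_through_time(hs, bin_width = 1)
  # global conservation: sum_X E_X = sum_X I_X per bin per replicate
  for (r in 1:12) for (b in seq_len(nrow(rs$bins))) {
    E <- rs$E[r, , b]; I <- rs$I[r, , b]
    if (all(is.na(E))) next
    expect_equal(sum(E, na.rm = TRUE), sum(I, na.rm = TRUE), tolerance = 1e-9)
  }
  sm <- rs$summary
  ok <- !is.na(sm$median)
  expect_true(all(sm$q25[ok] <= sm$median[ok] + 1e-12))
  expect_true(all(sm$median[ok] <= sm$q75[ok] + 1e-12))
  expect_true(all(sm$median[ok] >= 0))
})

test_that("relay summaries find phases and ignore rate rescaling", {
  h <- manual_history()
  rs <- rates_through_time(list(h, h), bin_width = 1)
  rel <- relay_summary(rs)
  expect_s3_class(rel$phases, "data.frame")
  # leaders are invariant to a common rescaling of all medians
  rs2 <- rs
  rs2$summary$median <- rs2$summary$median * 7.3
  rel2 <- relay_summary(rs2)
  expect_identical(rel$by_bin$leader, rel2$by_bin$leader)
  # a constant single-corridor history yields one emigration phase
  em <- rel$phases[rel$phases$statistic == "emigration", ]
  expect_identical(em$leader, "A")
  expect_identical(nrow(em), 1L)
})

test_that("an injected source switch is recovered at the right age", {
  # phase 1 (old): dispersal flows out of A; phase 2 (young): out of B
  mult_old <- matrix(0.02, 3, 3); diag(mult_old) <- 1
  mult_old[1, 2:3] <- 1
  mult_young <- matrix(0.02, 3, 3); diag(mult_young) <- 1
  mult_young[2, c(1, 3)] <- 1
  em <- epoch_model(c(40, 4, 0), list(mult_old, mult_young),
                    areas = LETTERS[1:3])
  cfg <- sim_config(n_tips = 120, n_areas = 3, d = 0.35, e = 0.01,
                    crown_age = 10, root_range = "A", epoch = em, seed = 55)
  phy <- simulate_chronogram(cfg)
  sim <- simulate_ranges(phy, cfg)
  rs <- rates_through_time(list(sim$history, sim$history), bin_width = 1)
  rel <- relay_summary(rs)
  d <- rel$by_bin[rel$by_bin$statistic == "emigration", ]
  d <- d[order(-d$old), ]
  switch_age <- d$old[match("B", d$leader)]
  expect_false(is.na(switch_age))
  expect_lte(abs(switch_age - 4), 1)
})
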