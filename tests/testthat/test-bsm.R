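test_that("stochastic maps are seed-deterministic and respect the tips", {
  phy <- rand_tree(8, crown = 6, seed = 51)
  g <- rand_geography(phy, 3, seed = 52)
  fit <- fit_range_model(phy, g)
  h1 <- stochastic_map(fit, n = 4, seed = 99)
  h2 <- stochastic_map(fit, n = 4, seed = 99)
  expect_identical(lapply(h1, `[[`, "events"), lapply(h2, `[[`, "events"))
  expect_identical(lapply(h1, `[[`, "clado"), lapply(h2, `[[`, "clado"))
  # tip ranges always equal the observed data (also a hard internal assert)
  obs <- decrates:::tip_masks(g, fit$phy$tip.label)
  sp <- fit$space
  for (h in h1)
    expect_identical(h$branch_end[seq_len(h$ntip)],
                     sp$labels[decrates:::state_index(sp, obs)])
  # every event age lies inside its branch interval
  bt <- decrates:::branch_table(fit$phy)
  for (h in h1) {
    for (i in seq_len(nrow(h$events))) {
      b <- h$events$branch[i]
      expect_lte(h$events$age[i], bt$old[bt$child == b])
      expect_gte(h$events$age[i], bt$young[bt$child == b])
    }
  }
})

test_that("zero rates yield event-free histories", {
  phy <- rand_tree(6, crown = 4, seed = 61)
  g <- geog_from_ranges(stats::setNames(rep(list(1), 6), phy$tip.label), 2)
  fit <- fit_range_model(phy, g)
  hs <- stochastic_map(fit, n = 5, seed = 1, d = 0, e = 0)
  expect_identical(sum(vapply(hs, function(h) nrow(h$events), 0L)), 0L)
})

test_that("node-state frequencies converge to the ancestral marginals", {
  phy <- rand_tree(6, crown = 5, seed = 71)
  g <- rand_geography(phy, 3, seed = 72)
  fit <- fit_range_model(phy, g)
  anc <- ancestral_ranges(fit)
  N <- 3000
  hs <- stochastic_map(fit, n = N, seed = 7)
  nodes <- which(!anc$is_tip)
  lev <- colnames(anc$probs)
  for (v in nodes) {
    freq <- table(factor(vapply(hs, function(h) h$node_state[v], ""),
                         levels = lev)) / N
    p <- anc$probs[v, ]
    se <- sqrt(pmax(p * (1 - p), 1e-12) / N)
    expect_true(all(abs(freq - p) <= 3.5 * se + 2 / N))
  }
})

test_that("endpoint-conditioned paths on a single branch are exact", {
  # two areas, e = 0: conditioned on A -> AB the path holds exactly one
  # expansion; conditioned on A -> A it holds none
  phy <- ape::read.tree(text = "(t1:3,t2:3);")
  g <- geog_from_ranges(list(t1 = c(1, 2), t2 = 1), 2)
  fit <- fit_range_model(phy, g)
  hs <- stochastic_map(fit, n = 200, seed = 13, d = 0.2, e = 0)
  for (h in hs) {
    ev1 <- h$events[h$events$branch == 1, ]  # branch to t1 ends in AB
    start <- h$branch_start[1]
    expect_identical(nrow(ev1), if (start == "AB") 0L else 1L)
    if (nrow(ev1)) {
      expect_identical(ev1$type, "expansion")
      expect_identical(ev1$to, "AB")
    }
    expect_identical(nrow(h$events[h$events$branch == 2 &
                                     h$events$type == "expansion", ]), 0L)
  }
})

test_that("expansion ages on a conditioned branch follow the analytic law", {
  # uniformized sampling against the closed-form density of the single
  # expansion time on an A -> AB bridge of length T with rate d, e = 0:
  # the jump time is exponential truncated to [0, T]
  phy <- ape::read.tree(text = "(t1:3,t2:3);")
  g <- geog_from_ranges(list(t1 = c(1, 2), t2 = 1), 2)
  fit <- fit_range_model(phy, g)
  d <- 0.4
  hs <- stochastic_map(fit, n = 2000, seed = 17, d = d, e = 0)
  jumps <- unlist(lapply(hs, function(h) {
    ev <- h$events[h$events$branch == 1 & h$events$type == "expansion", ]
    if (nrow(ev) == 1) 3 - ev$age else numeric(0)  # time since branch start
  }))
  expect_gt(length(jumps), 300)
  pexp_trunc <- function(q) (1 - exp(-d * q)) / (1 - exp(-d * 3))
  ks <- suppressWarnings(stats::ks.test(jumps, pexp_trunc))
  expect_gt(ks$p.value, 1e-3)
})

test_that("event counting implements the attribution rules", {
  h <- manual_history()
  ec <- count_events(h, bin_width = 1)
  # expansion {A} -> {A,B} at 1.5 Ma: d_AtoB += 1
  expect_equal(unname(ec$disp["A", "B", 2]), 1)
  expect_equal(unname(ec$dt["B", 2]), 1)
  expect_equal(unname(ec$df["A", 2]), 1)
  # contraction tallied separately
  expect_equal(unname(ec$extirpation["A", 1]), 1)
  # in situ speciation: copy of {A} keeps A in both daughters
  expect_equal(unname(ec$s["A", 2]), 1)
  expect_equal(sum(ec$s["B", ]), 0)
  # totals conserve: sum_X df_X = sum_Y dt_Y in every bin
  expect_equal(colSums(ec$df), colSums(ec$dt))
})

test_that("multi-area sources split dispersal mass fractionally", {
  h <- manual_history()
  h$events <- data.frame(branch = 1L, age = 1, type = "expansion",
                         area = "B", from = "AC", to = "ABC")
  h$areas <- c("A", "B", "C")
  ec <- count_events(h, bin_width = 2)
  expect_equal(unname(ec$disp["A", "B", 1]), 0.5)
  expect_equal(unname(ec$disp["C", "B", 1]), 0.5)
  expect_equal(unname(ec$dt["B", 1]), 1)
  expect_equal(sum(ec$df[, 1]), sum(ec$dt[, 1]))
})

test_that("vicariance contributes no dispersal but counts in situ speciation", {
  h <- manual_history()
  h$events <- h$events[0, ]
  h$clado <- data.frame(node = 3L, age = 2, type = "vicariance",
                        anc = "AB", left = "A", right = "B")
  ec <- count_events(h, bin_width = 1)
  expect_equal(sum(ec$disp), 0)
  expect_equal(unname(ec$s["A", 2]), 1)  # A retained by the left daughter
  expect_equal(unname(ec$s["B", 2]), 1)
})

test_that("flow summaries identify an induced dispersal corridor", {
  # one corridor (A -> B) with a 10x multiplier dominates the average flows
  mult <- matrix(0.05, 3, 3, dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  diag(mult) <- 1
  mult["A", "B"] <- 0.9
  em <- epoch_model(c(50, 0), mult, areas = LETTERS[1:3])
  cfg <- sim_config(n_tips = 60, n_areas = 3, d = 0.12, e = 0.005,
                    crown_age = 12, root_range = "A", epoch = em, seed = 77)
  phy <- simulate_chronogram(cfg)
  sim <- simulate_ranges(phy, cfg)
  fit <- fit_range_model(phy, sim$geography, "DEC", epoch = em)
  hs <- stochastic_map(fit, n = 25, seed = 5)
  fl <- summarize_flows(hs)
  offdiag <- fl$pair_mean; diag(offdiag) <- 0
  expect_identical(which(offdiag == max(offdiag), arr.ind = TRUE)[1, ],
                   c(row = 1L, col = 2L))
  expect_true(all(fl$pair_q25 <= fl$pair_mean + 1e-9))
})
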