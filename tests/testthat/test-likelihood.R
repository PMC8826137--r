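test_that("the two-tip hand-computed likelihood is reproduced", {
  phy <- ape::read.tree(text = "(t1:1,t2:1);")
  g <- geog_from_ranges(list(t1 = 1, t2 = 1), 2)
  # d = e = 0: only a root in {A} survives; flat prior over {A},{B},{A,B}
  expect_equal(exp(tree_log_likelihood(phy, g, 0, 0)), 1 / 3, tolerance = 1e-12)
  # two disjoint single-area tips are still reachable under DEC vicariance
  g2 <- geog_from_ranges(list(t1 = 1, t2 = 2), 2)
  expect_equal(exp(tree_log_likelihood(phy, g2, 0, 0)), 1 / 18,
               tolerance = 1e-12)
  # but impossible without cladogenetic range change: reported as -Inf
  expect_identical(tree_log_likelihood(phy, g2, 0, 0, "BAYAREALIKE"), -Inf)
})

test_that("pruning equals brute-force enumeration on small instances", {
  set.seed(101)
  fams <- c("DEC", "DIVALIKE", "BAYAREALIKE")
  for (rep in 1:6) {
    n <- sample(2:4, 1); na <- sample(2:3, 1)
    phy <- rand_tree(n, crown = runif(1, 1, 6))
    ranges <- lapply(seq_len(n), function(i)
      sort(sample.int(na, sample.int(na, 1))))
    names(ranges) <- phy$tip.label
    g <- geog_from_ranges(ranges, na)
    d <- runif(1, 0.01, 0.3); e <- runif(1, 0, 0.15)
    fam <- fams[1 + rep %% 3]
    orc <- oracle_lnL_marg(phy, ranges, d, e, fam, n_areas = na)
    expect_equal(tree_log_likelihood(phy, g, d, e, fam), orc$lnL,
                 tolerance = 1e-9)
  }
})

test_that("pruning equals brute force under a two-slice epoch model", {
  set.seed(202)
  mults <- list(matrix(c(1, 0.9, 0.1, 1), 2, 2), matrix(c(1, 0.2, 1.5, 1), 2, 2))
  for (rep in 1:3) {
    phy <- rand_tree(4, crown = 6)
    ranges <- lapply(1:4, function(i) sort(sample.int(2, sample.int(2, 1))))
    names(ranges) <- phy$tip.label
    g <- geog_from_ranges(ranges, 2)
    em <- epoch_model(c(8, 3, 0), mults)
    d <- runif(1, 0.05, 0.3); e <- runif(1, 0.01, 0.1)
    orc <- oracle_lnL_marg(phy, ranges, d, e, "DEC",
                           epoch_bounds = c(8, 3, 0), mults = mults)
    expect_equal(tree_log_likelihood(phy, g, d, e, "DEC", epoch = em),
                 orc$lnL, tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to tip order and daughter orientation", {
  set.seed(17)
  phy <- rand_tree(7, crown = 5)
  g <- rand_geography(phy, 3)
  l0 <- tree_log_likelihood(phy, g, 0.1, 0.04)
  perm <- sample(rownames(g$presence))
  g2 <- geography_table(g$presence[perm, ])
  expect_equal(tree_log_likelihood(phy, g2, 0.1, 0.04), l0, tolerance = 1e-12)
  phy_rot <- ape::rotateConstr(phy, rev(phy$tip.label))
  expect_equal(tree_log_likelihood(phy_rot, g, 0.1, 0.04), l0,
               tolerance = 1e-10)
})

test_that("branch propagation splits at epoch boundaries without effect when
           multipliers are neutral", {
  set.seed(23)
  phy <- rand_tree(9, crown = 9)
  g <- rand_geography(phy, 3)
  em1 <- epoch_model(c(12, 0), matrix(1, 3, 3))
  em3 <- epoch_model(c(12, 7, 3, 0), matrix(1, 3, 3))
  l1 <- tree_log_likelihood(phy, g, 0.12, 0.05, epoch = em1)
  l3 <- tree_log_likelihood(phy, g, 0.12, 0.05, epoch = em3)
  expect_equal(l3, l1, tolerance = 1e-10)
})

test_that("a range-size cap restricts the state space consistently", {
  set.seed(5)
  phy <- rand_tree(4, crown = 4)
  ranges <- list(1, 2, c(1, 2), 2)
  names(ranges) <- phy$tip.label
  g <- geog_from_ranges(ranges, 3)
  orc <- oracle_lnL_marg(phy, ranges, 0.1, 0.03, "DEC", max_size = 2, n_areas = 3)
  expect_equal(tree_log_likelihood(phy, g, 0.1, 0.03, max_range_size = 2),
               orc$lnL, tolerance = 1e-9)
})
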