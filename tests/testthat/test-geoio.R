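test_that("geography files parse, preserve order, and round-trip", {
  f <- withr::local_tempfile()
  writeLines(c("2 3 (A B C)", "t1 100", "t2 011"), f)
  g <- read_geography(f)
  expect_identical(g$areas, c("A", "B", "C"))
  expect_identical(rownames(g$presence), c("t1", "t2"))
  expect_identical(unname(g$presence["t1", ]), c(1L, 0L, 0L))
  expect_identical(unname(g$presence["t2", ]), c(0L, 1L, 1L))

  # order preservation with a permuted area header
  writeLines(c("2 3 (C A B)", "t1 100", "t2 011"), f)
  expect_identical(read_geography(f)$areas, c("C", "A", "B"))

  # randomized round-trips
  set.seed(71)
  for (rep in 1:5) {
    n <- sample(2:20, 1); na <- sample(2:6, 1)
    phy <- rand_tree(n)
    g0 <- rand_geography(phy, na)
    write_geography(g0, f)
    g1 <- read_geography(f)
    expect_identical(g1$presence, g0$presence)
    expect_identical(g1$areas, g0$areas)
  }
})

test_that("malformed geography files are rejected with line numbers", {
  f <- withr::local_tempfile()
  writeLines(c("3 3 (A B C)", "t1 100", "t2 011"), f)
  expect_error(read_geography(f), "declares 3 taxa")
  writeLines(c("2 3 (A B C)", "t1 100", "t2 01"), f)
  expect_error(read_geography(f), "line 3.*bad bit string")
  writeLines(c("2 3 (A B C)", "t1 100", "t1 011"), f)
  expect_error(read_geography(f), "duplicate taxon")
  writeLines(c("2 3 (A B C)", "t1 100", "t3 000"), f)
  expect_error(read_geography(f), "line 3.*empty range")
})

test_that("the packaged multiplier matrix has the documented entries", {
  em <- read_multipliers(system.file("extdata", "dispersal_multipliers.txt",
                                     package = "decrates"))
  expect_identical(em$boundaries, c(11, 7, 0))
  expect_identical(em$areas, LETTERS[1:6])
  # old slice (11-7 Ma): Mesoamerica <-> young Andes corridor
  expect_equal(em$multipliers[[1]]["B", "E"], 0.7)
  expect_equal(em$multipliers[[1]]["E", "B"], 0.7)
  # young slice (7-0 Ma): North America -> Amazonia separated by one region
  expect_equal(em$multipliers[[2]]["A", "C"], 0.1)
  expect_true(all(diag(em$multipliers[[1]]) == 1))
})

test_that("multiplier files round-trip and bad blocks are rejected", {
  em <- read_multipliers(system.file("extdata", "dispersal_multipliers.txt",
                                     package = "decrates"))
  f <- withr::local_tempfile()
  write_multipliers(em, f)
  em2 <- read_multipliers(f)
  expect_equal(em2$boundaries, em$boundaries)
  expect_equal(em2$multipliers, em$multipliers)

  writeLines(c("2-0", "1 0.5", "0.5 1"), f)
  expect_error(read_multipliers(f), "missing END")
  writeLines(c("2-0", "1 0.5 1", "0.5 1 1", "END"), f)
  expect_error(read_multipliers(f), "square")
  writeLines(c("3-0", "1 0.5", "0.5 1", "END", "9-5", "1 1", "1 1", "END"), f)
  expect_error(read_multipliers(f), "contiguous")
})

test_that("a single all-ones slice reproduces the unconstrained model", {
  set.seed(4)
  phy <- rand_tree(8, crown = 6)
  g <- rand_geography(phy, 3)
  em <- epoch_model(c(10, 0), matrix(1, 3, 3))
  l0 <- tree_log_likelihood(phy, g, 0.08, 0.03)
  l1 <- tree_log_likelihood(phy, g, 0.08, 0.03, epoch = em)
  expect_equal(l1, l0, tolerance = 1e-10)
})

test_that("chronograms are validated and round-trip with age precision", {
  f <- withr::local_tempfile()
  writeLines("((t1:1,t2:1):1,t3:2);", f)
  phy <- read_chronogram(f)
  expect_equal(crown_age(phy), 2)
  writeLines("((t1:1,t2:2):1,t3:2);", f)
  expect_error(read_chronogram(f), "not ultrametric")

  big <- rand_tree(134, crown = 8.6, seed = 20)
  write_chronogram(big, f)
  back <- read_chronogram(f)
  expect_equal(sort(node_ages(back)), sort(node_ages(big)), tolerance = 1e-9)
  expect_identical(sort(back$tip.label), sort(big$tip.label))
})

test_that("event logs round-trip through the TSV schema", {
  set.seed(11)
  phy <- rand_tree(6, crown = 5)
  g <- rand_geography(phy, 3)
  fit <- fit_range_model(phy, g, "DEC")
  hs <- stochastic_map(fit, n = 3, seed = 2)
  f <- withr::local_tempfile()
  write_event_log(hs, f)
  log <- read_event_log(f)
  expect_named(log, c("replicate", "branch_id", "age_Ma", "event_type",
                      "range_before", "range_after"))
  n_recorded <- sum(vapply(hs, function(h) nrow(h$events) + nrow(h$clado), 0L))
  expect_identical(nrow(log), n_recorded)
})
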