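test_that("overlap-family distances follow the counting formulas", {
  A <- c("x", "y", "z"); B <- c("y", "z", "w")
  tx <- toy5 # unused by the overlap family (no lookup happens)
  expect_equal(set_distance(tx, A, B, ss_method = "jaccard"), 0.5)
  expect_equal(set_distance(tx, A, B, ss_method = "dice"), 1 / 3,
               tolerance = 1e-12)
  expect_equal(set_distance(tx, A, B, ss_method = "cosine"), 1 - 2 / 3,
               tolerance = 1e-12)
  expect_equal(set_distance(tx, A, B, ss_method = "overlap"), 1 - 2 / 3,
               tolerance = 1e-12)
  for (ss in c("dice", "jaccard", "cosine", "overlap")) {
    expect_equal(set_distance(tx, A, A, ss_method = ss), 0)
  }
  expect_error(set_distance(tx, character(0), A, ss_method = "dice"), "empty")
})

test_that("CS-based set distances reproduce the TOY5 hand values", {
  A <- c("A1a1", "A1b"); B <- "A1a2"
  expect_equal(set_distance(toy5, A, B, ss_method = "closest_pair",
                            cs_method = "wu"), (0.2 + 1 / 3 + 0.2) / 3,
               tolerance = 1e-12)
  expect_equal(set_distance(toy5, A, B, ss_method = "nonshared_avg",
                            cs_method = "wu"), (0.2 + 1 / 3 + (0.2 + 1 / 3) / 2) / 3,
               tolerance = 1e-12)
  expect_equal(set_distance(toy5, A, B, ss_method = "allpairs_avg",
                            cs_method = "wu"), (0.2 + 1 / 3) / 2,
               tolerance = 1e-12)
  expect_equal(set_distance(toy5, A, B, ss_method = "bipartite",
                            cs_method = "wu"), 0.2, tolerance = 1e-12)
  # single-code sets reduce to the code-level distance
  expect_equal(set_distance(toy5, "A1a1", "B1a", ss_method = "closest_pair",
                            cs_method = "wu"), 7 / 9, tolerance = 1e-12)
  expect_error(set_distance(toy5, A, character(0), ss_method = "bipartite"),
               "empty")
})

test_that("identity sets give zero except for the all-pairs mean", {
  A <- c("A1a1", "A1a2", "B1a")
  for (ss in c("dice", "jaccard", "cosine", "overlap",
               "closest_pair", "nonshared_avg", "bipartite")) {
    expect_equal(set_distance(toy5, A, A, ss_method = ss, cs_method = "wu"), 0,
                 info = ss)
  }
  # allpairs_avg(A, A) is the exact mean of the n^2 pairwise distances
  m <- concept_distance_matrix(toy5, A, cs_method = "wu")
  d <- set_distance(toy5, A, A, ss_method = "allpairs_avg", cs_method = "wu")
  expect_equal(d, mean(m), tolerance = 1e-12)
  expect_gt(d, 0)
})

test_that("duplicate codes are collapsed before computing", {
  expect_equal(
    set_distance(toy5, c("A1a1", "A1a1", "A1b"), "A1a2",
                 ss_method = "allpairs_avg", cs_method = "wu"),
    set_distance(toy5, c("A1a1", "A1b"), "A1a2",
                 ss_method = "allpairs_avg", cs_method = "wu"))
})

test_that("every set distance is symmetric on random sets", {
  withr::local_seed(21)
  tx <- bench_taxonomy()
  cost <- concept_distance_matrix(tx, tx$codes[tx$n_leaves == 1L & tx$level > 1L],
                                  cs_method = "wu")
  for (rep in 1:40) {
    A <- random_code_set(tx); B <- random_code_set(tx)
    for (ss in c("dice", "jaccard", "cosine", "overlap",
                 "closest_pair", "nonshared_avg", "allpairs_avg", "bipartite")) {
      expect_equal(set_distance(tx, A, B, ss_method = ss, cost = cost),
                   set_distance(tx, B, A, ss_method = ss, cost = cost),
                   tolerance = 1e-12, info = ss)
    }
  }
})

test_that("closest-pair and bipartite never exceed the all-pairs mean", {
  withr::local_seed(31)
  tx <- bench_taxonomy()
  leaves <- tx$codes[tx$n_leaves == 1L & tx$level > 1L]
  cost <- concept_distance_matrix(tx, leaves, cs_method = "wu")
  n_checked_eq <- 0L
  for (rep in 1:1000) {
    A <- random_code_set(tx)
    B <- random_code_set(tx)
    ap <- set_distance(tx, A, B, ss_method = "allpairs_avg", cost = cost)
    cp <- set_distance(tx, A, B, ss_method = "closest_pair", cost = cost)
    expect_lte(cp, ap + 1e-12)
    if (length(unique(A)) == length(unique(B))) {
      bp <- set_distance(tx, A, B, ss_method = "bipartite", cost = cost)
      expect_lte(bp, ap + 1e-12)
      n_checked_eq <- n_checked_eq + 1L
    }
  }
  expect_gt(n_checked_eq, 50L) # the equal-size branch was actually exercised
})

test_that("a shared pool of distant codes dilutes averages but not the matching", {
  tx <- bench_taxonomy()
  a1 <- "N1.1.1.1"; b1 <- "N1.1.1.2"      # close core pair (distance 0.2)
  pool <- paste0("N6.", c("1.1.1", "2.1.1", "3.1.1", "4.1.2", "1.2.1"))
  d_core <- concept_distance(tx, a1, b1, cs_method = "wu")
  ap0 <- set_distance(tx, a1, b1, ss_method = "allpairs_avg", cs_method = "wu")
  A <- c(a1, pool); B <- c(b1, pool)
  ap1 <- set_distance(tx, A, B, ss_method = "allpairs_avg", cs_method = "wu")
  # the average is pulled up toward the background mean ...
  expect_gt(ap1, ap0)
  expect_gt(ap1, 0.4)
  # ... while the minimum matching still contains the core pair at its
  # original distance (pool codes match themselves at zero)
  cost <- concept_distance_matrix(tx, A, B, cs_method = "wu")
  h <- hungarian_min_matching(cost)
  expect_equal(h$total, d_core, tolerance = 1e-12)
  expect_equal(set_distance(tx, A, B, ss_method = "bipartite",
                            cs_method = "wu"), d_core / length(A),
               tolerance = 1e-12)
})

test_that("dispatch honours the method contract", {
  # overlap-family ignores the code-level configuration entirely
  expect_equal(
    set_distance(toy5, c("A1a1", "A1b"), "A1a2", ss_method = "jaccard",
                 cs_method = "wu"),
    set_distance(toy5, c("A1a1", "A1b"), "A1a2", ss_method = "jaccard",
                 cs_method = "li"))
  expect_error(set_distance(toy5, "A1a1", "A1b", ss_method = "nope"),
               "arg")
})
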