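test_that("a patient is assigned to the nearer prototype", {
  fit <- protoclass(crafted_cohort(), toy5, cs_method = "wu",
                    ss_method = "bipartite", k = 1)
  target <- data.frame(patient_id = "t", age = 30, hlos = 5,
                       codes = "A1a1", stringsAsFactors = FALSE)
  # d(A1a1, A1a2) = 0.2 < d(A1a1, B1a) = 7/9
  expect_equal(unname(predict(fit, target)), "short")
  d <- predict(fit, target, type = "distance")
  expect_equal(d$d_short, 0.2, tolerance = 1e-12)
  expect_equal(d$d_long, 7 / 9, tolerance = 1e-12)
  # a patient identical to one prototype wins that label outright
  clone <- data.frame(patient_id = "c", age = 70, hlos = 30,
                      codes = "B1a", stringsAsFactors = FALSE)
  expect_equal(unname(predict(fit, clone)), "long")
  # codes outside the taxonomy are named in the error
  bad <- data.frame(patient_id = "b", age = 30, hlos = 5,
                    codes = "Z9", stringsAsFactors = FALSE)
  expect_error(predict(fit, bad), "Z9")
})

test_that("exact distance ties break toward short, with a warning", {
  fit <- protoclass(crafted_cohort(list(young_short = "A1a2",
                                        old_short = "A1a2",
                                        young_long = "A1a2",
                                        old_long = "A1a2")),
                    toy5, cs_method = "wu", k = 1)
  target <- data.frame(patient_id = "t", age = 30, hlos = 30,
                       codes = "A1a1", stringsAsFactors = FALSE)
  expect_warning(lab <- predict(fit, target), "tie")
  expect_equal(unname(lab), "short")
})

test_that("evaluation reduces to the correct confusion arithmetic", {
  fit <- protoclass(crafted_cohort(), toy5, cs_method = "wu", k = 1)
  # four test patients near the short prototype, two near the long one,
  # with deliberately wrong gold labels mixed in
  test <- data.frame(
    patient_id = paste0("t", 1:6),
    age = c(30, 30, 70, 70, 30, 70),
    hlos = c(5, 30, 5, 30, 5, 30),    # gold: S L S L S L
    codes = c("A1a1", "A1a1", "A1a2", "B1a", "B1", "B1a"),
    stringsAsFactors = FALSE)
  ev <- evaluate_hlos(fit, test)
  # predictions: A1a1->short, A1a1->short, A1a2->short, B1a->long,
  #              B1->long (d to B1a smaller), B1a->long
  expect_equal(unlist(ev[c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 1, fn = 1, tn = 2), ignore_attr = TRUE)
  expect_equal(ev$n_test, 6)
  expect_equal(ev$precision, 2 / 3, tolerance = 1e-12)
  expect_equal(ev$recall, 2 / 3, tolerance = 1e-12)
  expect_equal(ev$fscore, 2 / 3, tolerance = 1e-12)
  # harmonic-mean identity, e.g. P = 0.8, R = 0.6 -> F = 0.6857
  expect_equal(2 * 0.8 * 0.6 / (0.8 + 0.6), 0.6857, tolerance = 1e-4)
  # invariant to test-set order
  ev2 <- evaluate_hlos(fit, test[sample(6), ])
  expect_equal(ev2[-1], ev[-1])
  expect_error(evaluate_hlos(fit, test[0, ]), "empty")
})

test_that("sweeps emit one tidy row per triple and size", {
  tx <- bench_taxonomy()
  cohort <- gen_cohort(tx, n_per_stratum = c(40, 40, 20, 20), seed = 3)
  sp <- split_cohort(cohort, 0.7, seed = 3)
  tr <- triple_preset()[c(4, 10), ] # two bipartite triples
  sw <- hlos_sweep(sp$train, sp$test, tx, triples = tr, ks = c(1, 5, 10))
  expect_equal(nrow(sw), 6L)
  expect_equal(sort(unique(sw$k)), c(1, 5, 10))
  # confusion counts always sum to the test-set size, and the F-score
  # re-derives from the confusion matrix on every row
  expect_true(all(sw$tp + sw$fp + sw$fn + sw$tn == sw$n_test))
  p <- sw$tp / (sw$tp + sw$fp)
  r <- sw$tp / (sw$tp + sw$fn)
  expect_equal(sw$fscore, ifelse(p + r == 0, 0, 2 * p * r / (p + r)),
               tolerance = 1e-12)
  expect_error(hlos_sweep(sp$train, sp$test, tx, triples = tr, ks = c(5, 1)),
               "ascending")
})

test_that("the ten-triple preset matches the studied grid", {
  tr <- triple_preset()
  expect_equal(nrow(tr), 10L)
  expect_setequal(tr$name, c("<1,2,5>", "<1,2,6>", "<1,2,7>", "<1,2,8>",
                             "<2,2,5>", "<2,2,6>", "<2,2,7>", "<2,2,8>",
                             "<1,3,8>", "<1,4,8>"))
  expect_true(all(tr$alpha == 0.2 & tr$beta == 0.6))
  expect_error(triple_preset("everything"), "unknown preset")
})

test_that("set-method curves over prototype sizes correlate as expected", {
  tx <- bench_taxonomy()
  # sizes spanning the core-only and background-diluted regimes, so the
  # curves actually vary
  cohort <- gen_cohort(tx, n_per_stratum = c(120, 20, 80, 20), seed = 5)
  s <- stratify(cohort)
  pa <- build_prototype(tx, s, "young_short")
  pb <- build_prototype(tx, s, "young_long")
  ks <- c(5, 20, 40, 60, 80)
  ks <- ks[ks <= min(nrow(pa), nrow(pb))]
  res <- ss_correlation(tx, pa, pb, ks)
  expect_equal(dim(res$correlation), c(4L, 4L))
  expect_equal(unname(diag(res$correlation)), rep(1, 4))
  expect_equal(res$correlation, t(res$correlation))
  # the two averaging formulations respond almost identically
  expect_gt(res$correlation["allpairs_avg", "nonshared_avg"], 0.9)
  # a duplicated method correlates perfectly with itself
  res2 <- ss_correlation(tx, pa, pb, ks,
                         ss_methods = c("allpairs_avg", "allpairs_avg"))
  expect_equal(unname(res2$correlation[1, 2]), 1, tolerance = 1e-12)
  expect_error(ss_correlation(tx, pa, pb, ks = c(1, 2)), "three")
})

test_that("classical MDS preserves the geometry it is given", {
  # three equidistant points embed as an equilateral triangle
  d3 <- matrix(1, 3, 3); diag(d3) <- 0
  xy <- mds_embed(d3, 2)
  emb <- as.matrix(stats::dist(xy))
  expect_equal(emb[upper.tri(emb)], rep(1, 3), tolerance = 1e-9)

  # colinear 1-D points are reproduced exactly in one dimension
  pts <- c(0, 1, 2.5, 7)
  dm <- abs(outer(pts, pts, "-"))
  x1 <- mds_embed(dm, 1)
  expect_equal(as.matrix(stats::dist(x1)), dm, tolerance = 1e-9,
               ignore_attr = TRUE)

  expect_error(mds_embed(matrix(c(0, 1, 2, 0), 2), 1), "symmetric")
  d0 <- d3; diag(d0) <- 0.1
  expect_error(mds_embed(d0, 1), "zero diagonal")
})

test_that("TOY5 subtrees cluster in the MDS embedding", {
  codes <- setdiff(toy5$codes, "root")
  m <- concept_distance_matrix(toy5, codes, cs_method = "wu")
  xy <- mds_embed(m, 2)
  emb <- as.matrix(stats::dist(xy))
  in_a <- startsWith(codes, "A")
  within <- c(emb[in_a, in_a][upper.tri(emb[in_a, in_a])],
              emb[!in_a, !in_a][upper.tri(emb[!in_a, !in_a])])
  between <- emb[in_a, !in_a]
  expect_lt(mean(within), mean(between))
})
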