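test_that("effect-size threshold rule reproduces the design arithmetic", {
  r38 <- effect_size_threshold(38, 0.5)
  expect_equal(r38$t, sqrt(38) * 0.5, tolerance = 1e-12)
  expect_equal(r38$t, 3.082, tolerance = 1e-3)
  expect_equal(r38$threshold, 3)
  expect_equal(effect_size_threshold(4, 0.5)$t, 1)
  expect_equal(effect_size_threshold(100, 0.3)$t, 3)
  expect_error(effect_size_threshold(1, 0.5), "n_subjects")
})

test_that("edgewise t matches the hand-computed pooled statistic", {
  mask <- conn_mask(matrix(c(0, 1, 1, 0), 2, 2))
  mk <- function(v) matrix(c(0, v, v, 0), 2, 2)
  g1 <- lapply(c(1, 2, 3), mk)
  g2 <- lapply(c(4, 5, 6), mk)
  tm <- edgewise_t(g1, g2, mask)
  expect_equal(tm[1, 2], -3.674, tolerance = 1e-3)
  expect_equal(tm[1, 2], t.test(c(1, 2, 3), c(4, 5, 6),
                                var.equal = TRUE)$statistic[[1]],
               tolerance = 1e-12)
  # swap of contrast negates; identical groups give zero (flagged)
  expect_equal(edgewise_t(g1, g2, mask, "group2>group1")[1, 2], 3.674,
               tolerance = 1e-3)
  g_const <- lapply(c(1, 1, 1), mk)
  expect_message(tm0 <- edgewise_t(g_const, g_const, mask),
                 "zero-pooled-variance")
  expect_equal(tm0[1, 2], 0)
  expect_equal(unname(edgewise_t(g1, g1, mask)[1, 2]), 0)
})

test_that("suprathreshold components match a union-find oracle", {
  # constructed case: edges (1,2),(2,3),(4,5) -> components of 2 and 1 edges
  tm <- matrix(0, 6, 6)
  tm[1, 2] <- tm[2, 3] <- tm[4, 5] <- 5
  tm <- tm + t(tm)
  comps <- components_above_threshold(tm, 3)
  expect_equal(vapply(comps, `[[`, numeric(1), "size"), c(2, 1))
  expect_equal(comps[[1]]$nodes, 1:3)
  expect_equal(components_above_threshold(tm, 10), list())

  set.seed(6)
  for (rep in 1:5) {
    r <- matrix(rnorm(15^2), 15, 15); r <- (r + t(r)); diag(r) <- 0
    comps <- components_above_threshold(r, 1.5)
    sizes <- sort(vapply(comps, `[[`, numeric(1), "size"), decreasing = TRUE)
    sup <- which(upper.tri(r) & r > 1.5, arr.ind = TRUE)
    expect_equal(sizes, as.numeric(components_unionfind(sup, 15)))
  }
})

test_that("raising the threshold never grows a component", {
  set.seed(8)
  r <- matrix(rnorm(20^2), 20, 20); r <- r + t(r); diag(r) <- 0
  for (thr in c(0.5, 1, 1.5, 2)) {
    lo <- components_above_threshold(r, thr)
    hi <- components_above_threshold(r, thr + 0.5)
    n_lo <- sum(vapply(lo, `[[`, numeric(1), "size"))
    n_hi <- sum(vapply(hi, `[[`, numeric(1), "size"))
    expect_lte(n_hi, n_lo)
  }
})

test_that("permutation test recovers a planted component", {
  mask <- generate_mask(30, 0.3, seed = 2)
  sc <- generate_sc_cohort(mask, 19, effect_sd_units = 2, seed = 31)
  res <- nbs_test(sc$group1, sc$group2, mask, 3, 1000, seed = 1)
  expect_gt(length(res$components), 0)
  expect_lt(res$p_values[1], 0.05)
  planted <- paste(sc$planted_edges$source, sc$planted_edges$target)
  found <- paste(res$components[[1]]$edges$source,
                 res$components[[1]]$edges$target)
  jaccard <- length(intersect(planted, found)) /
    length(union(planted, found))
  expect_gte(jaccard, 0.5)
  # seeded reproducibility; add-one estimator is never zero
  res2 <- nbs_test(sc$group1, sc$group2, mask, 3, 1000, seed = 1)
  expect_identical(res$p_values, res2$p_values)
  expect_true(all(res$p_values >= 1 / 1001))
})

test_that("a component never seen in permutations gets the add-one bound", {
  mask <- generate_mask(20, 0.4, seed = 3)
  sc <- generate_sc_cohort(mask, 10, effect_sd_units = 12, noise_sd = 0.05,
                           seed = 7)
  res <- nbs_test(sc$group1, sc$group2, mask, 5, 500, seed = 2)
  expect_gt(length(res$components), 0)
  big <- which.max(vapply(res$components, `[[`, numeric(1), "size"))
  if (sum(res$null_max_size >= res$components[[big]]$size) == 0)
    expect_equal(res$p_values[big], 1 / 501)
})

test_that("tiny designs switch to exhaustive enumeration", {
  mask <- conn_mask(matrix(c(0, 1, 1, 0), 2, 2))
  mk <- function(v) matrix(c(0, v, v, 0), 2, 2)
  g1 <- lapply(c(1.0, 1.1, 1.2), mk)
  g2 <- lapply(c(2.0, 2.1, 2.2), mk)
  expect_message(res <- nbs_test(g1, g2, mask, 1, 100, seed = 1),
                 "exhaustively")
  expect_equal(res$n_permutations, choose(6, 3))
})
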