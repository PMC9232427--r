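test_that("generated masks have exact link counts and are connected", {
  m <- generate_mask(40, 0.3, seed = 1)
  expect_equal(sum(m$mask) / 2, 234)  # round(0.3 * 780)
  g <- igraph::graph_from_adjacency_matrix(m$mask, mode = "undirected")
  expect_true(igraph::is_connected(g))
  expect_identical(generate_mask(40, 0.3, seed = 1)$mask, m$mask)
  expect_identical(generate_mask(12, 1, seed = 2)$mask, 1 - diag(12))
  expect_error(generate_mask(40, 0.01, seed = 1), "too few")
})

test_that("group/condition parameter sets differ only on planted links", {
  mask <- generate_mask(20, 0.3, seed = 2)
  gen <- generate_group_ec(mask, n_planted_links = 10, seed = 3)
  reg <- gen$registry
  expect_equal(sum(reg$set == "group"), 10)
  expect_equal(sum(reg$set == "condition"), 10)
  # planted sets are disjoint and inside the mask
  keys <- paste(reg$source, reg$target)
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(mask$mask[cbind(reg$source, reg$target)] == 1))

  d_group <- gen$params$g2_c1$ec - gen$params$g1_c1$ec
  idx_group <- reg[reg$set == "group", c("source", "target")]
  expect_true(all(d_group[as.matrix(idx_group)] > 0))
  d_zero <- d_group
  d_zero[as.matrix(idx_group)] <- 0
  expect_true(all(d_zero == 0))

  # zero effects make the group sets identical
  gen0 <- generate_group_ec(mask, effect_scale = 0, seed = 3)
  expect_identical(gen0$params$g1_c1$ec, gen0$params$g2_c1$ec)

  # stability margin holds across seeds
  margins <- vapply(1:25, function(s) {
    g <- generate_group_ec(mask, seed = s)
    max(vapply(g$params, function(p)
      attr(build_state_matrix(p), "max_re_eig"), numeric(1)))
  }, numeric(1))
  expect_true(all(margins <= -0.05 + 1e-10))
})

test_that("cohort simulation produces labeled, reproducible sessions", {
  mask <- generate_mask(12, 0.4, seed = 4)
  gen <- generate_group_ec(mask, n_planted_links = 5, seed = 4)
  cohort <- simulate_cohort(gen, n_subjects_per_group = 3, n_samples = 60,
                            seed = 9)
  expect_length(cohort$sessions, 12)  # 3 + 3 subjects x 2 conditions
  expect_equal(nrow(cohort$meta), 12)
  expect_equal(table(cohort$meta$group), table(rep(c("group1", "group2"), 6)),
               ignore_attr = TRUE)
  s1 <- cohort$sessions[[1]]
  expect_equal(s1$dt, 2)
  expect_equal(dim(s1$data), c(60, 12))
  cohort2 <- simulate_cohort(gen, 3, 60, seed = 9)
  expect_identical(cohort$sessions[[5]]$data, cohort2$sessions[[5]]$data)
  # a subject's two sessions share the same fingerprint jitter:
  # EC difference between conditions equals the planted condition shift
  d <- cohort$subject_ec[[2]] - cohort$subject_ec[[1]]
  reg_c <- gen$registry[gen$registry$set == "condition", c("source", "target")]
  off <- d; off[as.matrix(reg_c)] <- 0
  expect_true(all(abs(off[cohort$subject_ec[[1]] > 0]) < 1e-12))
})

test_that("SC cohorts are symmetric, nonnegative, masked, with planted shift", {
  mask <- generate_mask(20, 0.4, seed = 5)
  sc <- generate_sc_cohort(mask, 6, effect_sd_units = 3, seed = 5)
  for (m in c(sc$group1, sc$group2)) {
    expect_identical(m, t(m))
    expect_true(all(diag(m) == 0))
    expect_true(all(m >= 0))
    expect_true(all(m[mask$mask == 0] == 0))
  }
  pe <- as.matrix(sc$planted_edges)
  expect_true(all(mask$mask[pe] == 1))
  # planted path is connected: 3 edges over 4 nodes
  expect_equal(length(unique(c(pe))), 4)
  mean1 <- Reduce(`+`, sc$group1) / 6
  mean2 <- Reduce(`+`, sc$group2) / 6
  expect_gt(mean(mean1[pe] - mean2[pe]), 0.1)

  sc0 <- generate_sc_cohort(mask, 6, effect_sd_units = 0, seed = 5)
  expect_identical(sc0$group1[[1]], t(sc0$group1[[1]]))
})

test_that("the synthetic parcellation covers the expected layout", {
  parc <- make_parcellation(100, 16)
  expect_equal(nrow(parc), 116)
  expect_equal(sum(parc$network == "subcortical"), 16)
  expect_equal(length(unique(parc$network)), 8)
  expect_equal(as.vector(table(parc$hemisphere)), c(58, 58))
  expect_false(anyDuplicated(parc$roi_name) > 0)
})
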