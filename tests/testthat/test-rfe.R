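# table with a handful of informative features among noise
planted_table <- function(n_per_class = 20, p = 25, informative = 1:5,
                          gap = 1.5, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * p), 2 * n_per_class, p)
  cls2 <- seq_len(n_per_class) + n_per_class
  x[cls2, informative] <- x[cls2, informative] + gap
  meta <- data.frame(subject_id = sprintf("s%02d", seq_len(2 * n_per_class)),
                     group = rep(c("a", "b"), each = n_per_class),
                     condition = "c1")
  feature_table(x, meta, "EC", zscore = FALSE)
}

test_that("RFE ranking is a permutation that finds the informative feature", {
  tab <- planted_table(p = 15, informative = 7, gap = 4, seed = 2)
  rk <- rfe_ranking(tab$features, tab$meta$group)
  expect_setequal(rk, 1:15)
  expect_equal(rk[1], 7)

  # one-shot elimination equals a single weight sort
  w <- train_mlr_predict(tab$features, tab$meta$group, NULL)$weights
  one_shot <- order(-rowSums(abs(w)), seq_len(15))
  expect_equal(rfe_ranking(tab$features, tab$meta$group, step = 14), one_shot)
})

test_that("accuracy-vs-k curve plateaus once the planted set is included", {
  tab <- planted_table(n_per_class = 25, p = 20, informative = 1:5,
                       gap = 1.5, seed = 4)
  curve <- accuracy_vs_k(tab, "group", k_grid = c(1, 3, 5, 10, 20),
                         n_repeats = 10, seed = 1)
  expect_equal(dim(attr(curve, "per_repeat")), c(10, 5))
  expect_true(all(!is.na(curve$mean_accuracy)))
  plateau <- curve$mean_accuracy[curve$k >= 5]
  expect_gt(min(plateau), curve$mean_accuracy[curve$k == 1])
  # the curve at k = p uses the full feature set
  expect_gt(curve$mean_accuracy[curve$k == 20], 0.7)
})

test_that("support selection applies the within-one-sd stability rule", {
  curve <- data.frame(k = c(2, 5, 10, 20),
                      mean_accuracy = c(0.60, 0.85, 0.86, 0.86),
                      sd_accuracy = c(0.05, 0.05, 0.02, 0.02))
  class(curve) <- c("rfe_curve", "data.frame")
  fi <- data.frame(source = 1:20, target = 21:40)
  sel <- select_support(curve, ranking = 1:20, feature_index = fi)
  expect_equal(sel$k, 5)  # first k on the plateau
  expect_false(sel$at_boundary)
  expect_equal(nrow(sel$links), 5)

  rising <- data.frame(k = c(2, 5, 10, 20),
                       mean_accuracy = c(0.5, 0.6, 0.7, 0.9),
                       sd_accuracy = c(0.01, 0.01, 0.01, 0.01))
  class(rising) <- c("rfe_curve", "data.frame")
  expect_message(select_support(rising, 1:20, fi), "no plateau")
  sel2 <- suppressMessages(select_support(rising, 1:20, fi))
  expect_equal(sel2$k, 20)
  expect_true(sel2$at_boundary)
  expect_error(select_support(rising[0, ], 1:20, fi), "empty")
})

test_that("selection is deterministic and annotated from the parcellation", {
  parc <- make_parcellation(32, 8)
  curve <- data.frame(k = c(3, 6), mean_accuracy = c(0.9, 0.9),
                      sd_accuracy = c(0.02, 0.02))
  class(curve) <- c("rfe_curve", "data.frame")
  fi <- data.frame(source = c(1, 5, 17, 2, 21, 40),
                   target = c(2, 9, 3, 11, 35, 1))
  s1 <- select_support(curve, 1:6, fi, parc)
  s2 <- select_support(curve, 1:6, fi, parc)
  expect_identical(s1, s2)
  expect_equal(s1$links$source_roi, parc$roi_name[s1$links$source])
  tal <- support_tallies(s1$links)
  expect_equal(tal$n_links, 3)
  expect_equal(tal$within_left + tal$within_right + tal$inter_hemispheric, 3)
})

test_that("planted links are recovered in the selected support network", {
  hits <- vapply(1:10, function(s) {
    tab <- planted_table(n_per_class = 25, p = 20, informative = 1:5,
                         gap = 2, seed = s)
    rk <- rfe_ranking(tab$features, tab$meta$group)
    curve <- accuracy_vs_k(tab, "group", k_grid = c(2, 5, 10, 20),
                           n_repeats = 5, seed = s)
    fi <- data.frame(source = 1:20, target = 21:40)
    sel <- select_support(curve, rk, fi)
    sum(sel$links$source %in% 1:5)
  }, numeric(1))
  expect_gte(median(hits), 3)
})
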