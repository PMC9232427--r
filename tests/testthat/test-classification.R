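test_that("session z-scoring uses the population standard deviation", {
  z <- zscore_session(c(1, 2, 3))
  expect_equal(z, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)
  expect_equal(zscore_session(z), z, tolerance = 1e-12)  # idempotent
  expect_error(zscore_session(rep(2, 5)), "zero standard deviation")
})

test_that("1NN with correlation metric matches a brute-force scan", {
  set.seed(5)
  train <- matrix(rnorm(4 * 50), 4, 50)
  labels <- c("w", "x", "y", "z")
  expect_equal(knn1_predict(train, labels, train[3, ]), "y")
  # correlation is affine-invariant
  expect_equal(knn1_predict(train, labels, 2 * train[2, ] + 5), "x")
  test <- train[4, ] + rnorm(50, 0, 0.1)
  oracle <- labels[which.max(apply(train, 1, cor, y = test))]
  expect_equal(knn1_predict(train, labels, test), oracle)
  expect_error(knn1_predict(rbind(rep(1, 5), rnorm(5)), c("a", "b"),
                            rnorm(5)), "zero-variance")
})

test_that("MLR separates a separable cohort and is at chance when shuffled", {
  tab <- separable_table(n_per_class = 20, gap = 4, seed = 2)
  y <- tab$meta$group
  fit <- train_mlr_predict(tab$features, y, tab$features)
  expect_equal(mean(fit$labels == y), 1.0)
  expect_equal(dim(fit$weights), c(ncol(tab$features), 2))
  # duplicate train/test gives perfect accuracy trivially
  both <- c(1:10, 21:30)
  expect_equal(train_mlr_predict(tab$features[both, ], y[both],
                                 tab$features[both, ])$labels, y[both])
  expect_error(train_mlr_predict(tab$features, rep("a", 40), tab$features),
               "single class")

  # label shuffling: accuracy within the binomial 95% CI of chance
  set.seed(7)
  accs <- replicate(50, {
    ys <- sample(y)
    mean(train_mlr_predict(tab$features[1:30, ], ys[1:30],
                           tab$features[31:40, ])$labels == ys[31:40])
  })
  n_pred <- 50 * 10
  expect_lt(abs(mean(accs) - 0.5), 1.96 * sqrt(0.25 / n_pred) + 0.02)
})

test_that("repeated evaluation returns seeded, bounded test accuracies", {
  tab <- separable_table(n_per_class = 15, gap = 3, seed = 3)
  acc <- repeated_evaluation(tab, "group", n_repeats = 50, seed = 1)
  expect_length(acc, 50)
  expect_true(all(acc >= 0 & acc <= 1))
  expect_identical(acc, repeated_evaluation(tab, "group", n_repeats = 50,
                                            seed = 1))
  expect_gte(mean(acc), 0.95)  # separable construction

  sur <- repeated_evaluation(tab, "group", n_repeats = 50, seed = 1,
                             surrogate = TRUE)
  n_test <- 2 * max(1, round(0.2 * 15))
  expect_lt(abs(mean(sur) - 0.5), 1.96 * sqrt(0.25 / (50 * n_test)) + 0.05)

  # 1NN needs a class difference that dominates the correlation pattern
  set.seed(13)
  proto <- matrix(rnorm(2 * 40), 2, 40)
  xk <- proto[rep(1:2, each = 15), ] + matrix(rnorm(30 * 40, 0, 0.5), 30)
  tabk <- feature_table(xk, tab$meta, "EC")
  knn_acc <- repeated_evaluation(tabk, "group", classifier = "knn1",
                                 n_repeats = 10, seed = 2)
  expect_gte(mean(knn_acc), 0.9)
})

test_that("subject-aware splits keep a subject's sessions together", {
  set.seed(11)
  n_sub <- 16
  meta <- data.frame(subject_id = rep(sprintf("s%02d", 1:n_sub), each = 2),
                     group = rep(c("a", "b"), each = n_sub),
                     condition = rep(c("c1", "c2"), n_sub))
  x <- matrix(rnorm(2 * n_sub * 20), 2 * n_sub)
  x[meta$condition == "c2", 1:4] <- x[meta$condition == "c2", 1:4] + 3
  tab <- feature_table(x, meta, "EC")
  acc <- repeated_evaluation(tab, "condition", n_repeats = 10, seed = 3,
                             subject_aware = TRUE)
  expect_true(all(acc >= 0 & acc <= 1))
  expect_gt(mean(acc), 0.8)  # planted condition effect is strong
})

test_that("rank-sum comparison matches exact enumeration", {
  w <- wilcoxon_compare(c(1, 2), c(3, 4))
  expect_equal(w$p_value, 1 / 3, tolerance = 1e-12)
  same <- wilcoxon_compare(c(0.5, 0.6, 0.7), c(0.5, 0.6, 0.7))
  expect_gte(same$p_value, 0.99)
  far <- wilcoxon_compare(rep(0.5, 25) + runif(25, 0, 1e-3),
                          rep(0.9, 25) + runif(25, 0, 1e-3))
  expect_lt(far$p_value, 1e-6)
  expect_error(wilcoxon_compare(1, c(1, 2)), ">= 2")
})
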