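#' z-score a feature vector within a session
#'
#' Centers and scales one session's vectorized connectivity features using
#' the mean and the population standard deviation (divisor `n`) of that
#' vector, so every sample enters classification on a common scale.
#'
#' @param v numeric vector, length >= 2, nonconstant.
#' @return The z-scored vector.
#' @export
zscore_session <- function(v) {
  stop_if(length(v) < 2, "need at least 2 features")
  s <- sd_pop(v)
  stop_if(s == 0, "constant feature vector: zero standard deviation")
  (v - mean(v)) / s
}

#' Assemble a feature table of connectome vectors
#'
#' One row per session (sample), one column per link feature. Feature
#' vectors are z-scored per session by default, as done before
#' classification.
#'
#' @param features numeric matrix (samples x features) or list of equal
#'   length vectors.
#' @param meta data frame with columns `subject_id`, `group`, `condition`,
#'   one row per sample.
#' @param metric which connectivity measure the features are (`"EC"`,
#'   `"FC"` or `"SC"`).
#' @param feature_index optional link-identity table from [feature_index].
#' @param zscore z-score each row ([zscore_session])?
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, meta, metric = c("EC", "FC", "SC"),
                          feature_index = NULL, zscore = TRUE) {
  metric <- match.arg(metric)
  if (is.list(features) && !is.data.frame(features))
    features <- do.call(rbind, features)
  features <- as.matrix(features)
  stop_if(nrow(features) != nrow(meta),
          "features (%d rows) and meta (%d rows) disagree",
          nrow(features), nrow(meta))
  need <- c("subject_id", "group", "condition")
  stop_if(!all(need %in% names(meta)), "meta must have columns %s",
          paste(need, collapse = ", "))
  if (zscore) features <- t(apply(features, 1, zscore_session))
  structure(list(features = unname(features), meta = meta, metric = metric,
                 feature_index = feature_index),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d %s features (%d subjects)\n",
              nrow(x$features), ncol(x$features), x$metric,
              length(unique(x$meta$subject_id))))
  invisible(x)
}

#' First-nearest-neighbour prediction with a correlation metric
#'
#' Predicts the label of each test vector as the label of the training
#' sample with the highest Pearson correlation (correlation as inverse
#' distance). Exact ties are broken by first occurrence in a seeded shuffle
#' of the training samples and reported via a message.
#'
#' @param train_x training matrix (samples x features).
#' @param train_labels labels, one per training row.
#' @param test_x test matrix or a single vector.
#' @param seed seed for the tie-breaking shuffle.
#' @return Character vector of predicted labels.
#' @export
knn1_predict <- function(train_x, train_labels, test_x, seed = 1L) {
  train_x <- as.matrix(train_x)
  if (is.null(dim(test_x))) test_x <- matrix(test_x, nrow = 1)
  stop_if(nrow(train_x) < 1, "need at least one training sample")
  stop_if(length(train_labels) != nrow(train_x),
          "one label per training sample required")
  stop_if(any(apply(train_x, 1, sd_pop) == 0) || any(apply(test_x, 1, sd_pop) == 0),
          "zero-variance feature vector: correlation undefined")
  cm <- cor(t(train_x), t(test_x))  # train x test correlations
  set.seed(seed)
  shuffle <- sample(nrow(train_x))
  apply(cm, 2, function(cc) {
    best <- which(cc == max(cc))
    if (length(best) > 1) {
      message("knn1_predict: correlation tie broken by seeded shuffle order")
      best <- best[which.min(match(best, shuffle))]
    }
    as.character(train_labels[best])
  })
}

#' Multinomial logistic regression: train and predict
#'
#' Ridge-regularized multinomial logistic regression (glmnet, `alpha = 0`)
#' with a fixed penalty, the linear classifier whose per-feature weights
#' drive recursive feature elimination. The default `lambda = 1/n_train`
#' corresponds to unit-strength L2 regularization of the summed log-loss.
#'
#' @param train_x,train_y training matrix and labels (>= 2 classes).
#' @param test_x matrix of test samples.
#' @param lambda ridge penalty; default `1 / nrow(train_x)`.
#' @return List with `labels` (predicted test labels) and `weights`
#'   (features x classes coefficient matrix, intercepts excluded).
#' @export
train_mlr_predict <- function(train_x, train_y, test_x,
                              lambda = 1 / nrow(train_x)) {
  train_x <- as.matrix(train_x)
  train_y <- as.character(train_y)
  stop_if(length(unique(train_y)) < 2, "training set has a single class")
  p <- ncol(train_x)
  if (p == 1) {  # glmnet needs >= 2 columns; pad with an ignored constant
    train_x <- cbind(train_x, 0)
    if (!is.null(test_x)) test_x <- cbind(as.matrix(test_x), 0)
  }
  fit <- glmnet::glmnet(train_x, factor(train_y), family = "multinomial",
                        alpha = 0, lambda = lambda, standardize = FALSE)
  w <- sapply(coef(fit), function(b) as.numeric(b)[-1])  # drop intercepts
  w <- w[seq_len(p), , drop = FALSE]
  labels <- character(0)
  if (!is.null(test_x) && nrow(as.matrix(test_x)) > 0)
    labels <- as.character(predict(fit, as.matrix(test_x), type = "class"))
  list(labels = labels, weights = w)
}

# stratified test indices: round(test_fraction * n) per class, at least 1
stratified_test_idx <- function(labels, test_fraction) {
  unlist(lapply(split(seq_along(labels), labels), function(idx) {
    k <- max(1L, as.integer(round_half_away(test_fraction * length(idx))))
    idx[sample.int(length(idx), k)]
  }), use.names = FALSE)
}

#' Repeated train/test evaluation of connectome classifiers
#'
#' Runs `n_repeats` independent stratified 80/20 splits (default) of the
#' sessions, fits the classifier on the training portion and reports only
#' test-set accuracy, as in the repeated-split protocol. Tasks: classify
#' `condition` within one group, or `group` within one condition. In
#' surrogate mode the training labels are permuted within each repeat
#' (identical pipeline otherwise), giving the chance-level baseline.
#'
#' @param table a [feature_table] (features already z-scored per session).
#' @param task `"condition"` or `"group"`: the label to predict.
#' @param within optional value of the other factor to subset sessions on
#'   (e.g. `task = "condition", within = "meditator"`).
#' @param classifier `"mlr"` or `"knn1"`.
#' @param n_repeats number of random splits (50 in the reference protocol).
#' @param test_fraction held-out fraction per split.
#' @param seed RNG seed; accuracies are reproducible given the seed.
#' @param surrogate permute training labels (chance baseline)?
#' @param subject_aware if `TRUE`, the split is over subjects, keeping both
#'   sessions of a subject on the same side (relevant for condition
#'   classification where each subject contributes two sessions).
#' @param lambda ridge penalty for the MLR.
#' @return Numeric vector of `n_repeats` test accuracies in `[0, 1]`.
#' @export
repeated_evaluation <- function(table, task = c("condition", "group"),
                                within = NULL, classifier = c("mlr", "knn1"),
                                n_repeats = 50L, test_fraction = 0.2,
                                seed = 1L, surrogate = FALSE,
                                subject_aware = FALSE, lambda = NULL) {
  stopifnot(inherits(table, "feature_table"))
  task <- match.arg(task)
  classifier <- match.arg(classifier)
  meta <- table$meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(within)) {
    other <- if (task == "condition") "group" else "condition"
    keep <- meta[[other]] == within
  }
  x <- table$features[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  y <- as.character(meta[[task]])
  stop_if(length(unique(y)) < 2, "need >= 2 classes for task '%s'", task)
  set.seed(seed)
  acc <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    repeat {
      if (subject_aware) {
        subj <- unique(meta$subject_id)
        subj_lab <- y[match(subj, meta$subject_id)]
        test_subj <- subj[stratified_test_idx(subj_lab, test_fraction)]
        test <- which(meta$subject_id %in% test_subj)
      } else {
        test <- stratified_test_idx(y, test_fraction)
      }
      train <- setdiff(seq_along(y), test)
      if (length(unique(y[train])) >= 2) break
      message("repeated_evaluation: single-class training split, resampled")
    }
    y_train <- y[train]
    if (surrogate) y_train <- sample(y_train)
    pred <- if (classifier == "mlr") {
      train_mlr_predict(x[train, , drop = FALSE], y_train,
                        x[test, , drop = FALSE],
                        lambda = lambda %||% (1 / length(train)))$labels
    } else {
      knn1_predict(x[train, , drop = FALSE], y_train,
                   x[test, , drop = FALSE], seed = seed + r)
    }
    acc[r] <- mean(pred == y[test])
  }
  acc
}

#' Compare two accuracy distributions (Wilcoxon rank-sum)
#'
#' Two-sided Mann-Whitney/Wilcoxon rank-sum test, used to compare
#' classifier/feature combinations and to test accuracies against the
#' surrogate baseline.
#'
#' @param acc_a,acc_b numeric vectors (length >= 2).
#' @return List with `statistic` (rank-sum W) and `p_value`.
#' @export
wilcoxon_compare <- function(acc_a, acc_b) {
  stop_if(length(acc_a) < 2 || length(acc_b) < 2,
          "each accuracy distribution needs >= 2 values")
  wt <- suppressWarnings(wilcox.test(acc_a, acc_b, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
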