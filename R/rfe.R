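#' Recursive feature elimination ranking with the MLR
#'
#' Repeatedly fits the ridge multinomial logistic regression and removes
#' the `step` features with the smallest importance (magnitude of the
#' weights summed over classes) until none remain. Features eliminated last
#' rank first; the returned ranking is a permutation of all feature
#' indices.
#'
#' @param train_x training matrix (samples x features).
#' @param train_y labels (>= 2 classes).
#' @param step features removed per iteration (default 1).
#' @param lambda ridge penalty; default `1 / nrow(train_x)`.
#' @return Integer vector of feature indices, most important first.
#' @export
rfe_ranking <- function(train_x, train_y, step = 1L, lambda = NULL) {
  train_x <- as.matrix(train_x)
  stop_if(length(unique(train_y)) < 2, "training set has a single class")
  stop_if(step < 1, "`step` must be >= 1")
  p <- ncol(train_x)
  lambda <- lambda %||% (1 / nrow(train_x))
  remaining <- seq_len(p)
  eliminated <- integer(0)
  while (length(remaining) > 1) {
    w <- train_mlr_predict(train_x[, remaining, drop = FALSE], train_y,
                           test_x = NULL, lambda = lambda)$weights
    importance <- rowSums(abs(w))
    k <- min(step, length(remaining) - 1L)
    drop_local <- order(importance, seq_along(importance))[seq_len(k)]
    # least important eliminated first; within a round, lowest importance first
    eliminated <- c(eliminated, remaining[drop_local])
    remaining <- remaining[-drop_local]
  }
  c(remaining, rev(eliminated))
}

#' Classification accuracy as a function of the number of top features
#'
#' For each repeat, draws a stratified train/test split, recomputes the RFE
#' ranking on the training set only, and evaluates MLR test accuracy using
#' the top-`k` ranked features for every `k` in `k_grid` (the ten-fold
#' repeated cross-validation of the signature-extraction step).
#'
#' @param table a [feature_table].
#' @param task,within,test_fraction,seed,lambda as in [repeated_evaluation].
#' @param k_grid increasing vector of feature counts (each `<= p`).
#' @param n_repeats number of splits (10 in the reference protocol).
#' @param step RFE elimination step.
#' @return An object of class `rfe_curve`: data frame with columns `k`,
#'   `mean_accuracy`, `sd_accuracy`, plus attribute `per_repeat`
#'   (repeats x k matrix).
#' @export
accuracy_vs_k <- function(table, task = c("group", "condition"), within = NULL,
                          k_grid, n_repeats = 10L, test_fraction = 0.2,
                          seed = 1L, step = 1L, lambda = NULL) {
  stopifnot(inherits(table, "feature_table"))
  task <- match.arg(task)
  stop_if(length(k_grid) == 0, "`k_grid` must be non-empty")
  p <- ncol(table$features)
  stop_if(any(k_grid < 1 | k_grid > p), "`k_grid` values must be in 1..%d", p)
  meta <- table$meta
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(within)) {
    other <- if (task == "condition") "group" else "condition"
    keep <- meta[[other]] == within
  }
  x <- table$features[keep, , drop = FALSE]
  y <- as.character(meta[[task]][keep])
  set.seed(seed)
  acc <- matrix(NA_real_, n_repeats, length(k_grid))
  for (r in seq_len(n_repeats)) {
    repeat {
      test <- stratified_test_idx(y, test_fraction)
      train <- setdiff(seq_along(y), test)
      if (length(unique(y[train])) >= 2) break
    }
    ranking <- rfe_ranking(x[train, , drop = FALSE], y[train], step = step,
                           lambda = lambda)
    for (j in seq_along(k_grid)) {
      feats <- ranking[seq_len(k_grid[j])]
      pred <- train_mlr_predict(x[train, feats, drop = FALSE], y[train],
                                x[test, feats, drop = FALSE],
                                lambda = lambda %||% (1 / length(train)))$labels
      acc[r, j] <- mean(pred == y[test])
    }
  }
  curve <- data.frame(k = k_grid,
                      mean_accuracy = colMeans(acc),
                      sd_accuracy = apply(acc, 2, sd))
  attr(curve, "per_repeat") <- acc
  class(curve) <- c("rfe_curve", "data.frame")
  curve
}

#' Select the support network from an accuracy-vs-k curve
#'
#' Picks the smallest `k` whose mean accuracy is within
#' `tolerance * sd(accuracy at the maximum)` of the maximum mean accuracy
#' (performance "stable" with respect to adding features), then returns the
#' top-`k` links of the supplied ranking annotated with ROI, network and
#' hemisphere from the parcellation table. If no smaller `k` qualifies the
#' full feature set is selected and flagged.
#'
#' @param curve an `rfe_curve` from [accuracy_vs_k].
#' @param ranking feature ranking used for the final link list (typically
#'   [rfe_ranking] on all samples).
#' @param feature_index link identity table (`source`, `target` node
#'   indices) matching the feature columns, e.g. from [feature_index].
#' @param parcellation optional parcellation table ([read_parcellation])
#'   used to annotate links.
#' @param tolerance stability tolerance in units of the sd at the maximum
#'   (default 1.0).
#' @return List with `k`, `at_boundary` (no plateau before the largest
#'   `k`), and `links`: a data frame of the selected links (rank, source /
#'   target index, and ROI / network / hemisphere annotations when a
#'   parcellation is given).
#' @export
select_support <- function(curve, ranking, feature_index, parcellation = NULL,
                           tolerance = 1.0) {
  stop_if(nrow(curve) == 0, "empty accuracy curve")
  stop_if(all(is.na(curve$mean_accuracy)), "all-NaN accuracy curve")
  i_max <- which.max(curve$mean_accuracy)
  floor_acc <- curve$mean_accuracy[i_max] - tolerance * curve$sd_accuracy[i_max]
  ok <- which(curve$mean_accuracy >= floor_acc)
  i_sel <- ok[which.min(curve$k[ok])]
  k <- curve$k[i_sel]
  at_boundary <- k == max(curve$k) && length(ok) == 1 && i_sel == nrow(curve)
  if (at_boundary)
    message("select_support: no plateau before the largest k; selected the full set")
  top <- ranking[seq_len(k)]
  links <- data.frame(rank = seq_len(k),
                      source = feature_index$source[top],
                      target = feature_index$target[top])
  if (!is.null(parcellation)) {
    links$source_roi <- parcellation$roi_name[links$source]
    links$target_roi <- parcellation$roi_name[links$target]
    links$source_network <- parcellation$network[links$source]
    links$target_network <- parcellation$network[links$target]
    links$source_hemisphere <- parcellation$hemisphere[links$source]
    links$target_hemisphere <- parcellation$hemisphere[links$target]
  }
  list(k = k, at_boundary = at_boundary, links = links)
}

#' Hemisphere and network tallies of a support network
#'
#' Summarizes an annotated support-network edge list: how many links lie
#' entirely within each hemisphere (e.g. "8 out of 15 edges within the
#' left hemisphere") and the count of links per source/target network pair.
#'
#' @param links annotated link table from [select_support].
#' @return List with `n_links`, `within_left`, `within_right`,
#'   `inter_hemispheric`, and `network_pairs` (a table).
#' @export
support_tallies <- function(links) {
  stop_if(is.null(links$source_hemisphere),
          "links must be annotated with a parcellation")
  both_l <- links$source_hemisphere == "L" & links$target_hemisphere == "L"
  both_r <- links$source_hemisphere == "R" & links$target_hemisphere == "R"
  list(n_links = nrow(links),
       within_left = sum(both_l),
       within_right = sum(both_r),
       inter_hemispheric = sum(!both_l & !both_r),
       network_pairs = table(paste(links$source_network, "->", links$target_network)))
}
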