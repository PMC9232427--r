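#' Primary t-threshold from a target effect size
#'
#' The component-forming threshold is tied to the smallest effect size of
#' interest: `t = sqrt(N) * d` with `N` the total number of subjects and
#' `d` the Cohen's coefficient. With `N = 38` and a medium effect
#' `d = 0.5` this gives 3.08, rounded to the default primary threshold 3.
#'
#' @param n_subjects total number of subjects (>= 2).
#' @param cohen_d target effect size (> 0), default 0.5 (medium).
#' @return List with `t` (exact value) and `threshold` (nearest integer,
#'   the default primary threshold).
#' @export
effect_size_threshold <- function(n_subjects, cohen_d = 0.5) {
  stop_if(n_subjects < 2, "`n_subjects` must be >= 2")
  stop_if(cohen_d <= 0, "`cohen_d` must be > 0")
  t_val <- sqrt(n_subjects) * cohen_d
  list(t = t_val, threshold = as.numeric(round_half_away(t_val)))
}

# subjects x edges matrix of upper-triangle mask edge values
edge_matrix <- function(sc_list, edges) {
  vals <- vapply(sc_list, function(m) m[edges], numeric(nrow(edges)))
  if (is.null(dim(vals))) matrix(vals, ncol = 1) else t(vals)
}

# vectorized pooled-variance two-sample t for each column
pooled_t <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colSums(x1^2) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2^2) - n2 * m2^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t_val <- (m1 - m2) / se
  t_val[se == 0] <- 0
  attr(t_val, "zero_variance") <- which(se == 0)
  t_val
}

#' Edgewise two-sample t statistics between groups of SC matrices
#'
#' Pooled-variance two-sample t per admissible edge, signed for the
#' requested one-sided contrast (positive where the favored group is
#' larger). Edges with zero pooled variance get `t = 0` and are flagged.
#'
#' @param sc_group1,sc_group2 lists of symmetric subject SC matrices
#'   (>= 2 per group).
#' @param mask a [conn_mask]: the edge universe of the analysis (the
#'   intersected group mask in the reference analysis).
#' @param contrast `"group1>group2"` or `"group2>group1"`.
#' @return Symmetric t matrix (zero outside the mask) with attribute
#'   `edges`: data frame `source`, `target`, `t`.
#' @export
edgewise_t <- function(sc_group1, sc_group2, mask,
                       contrast = c("group1>group2", "group2>group1")) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(mask, "conn_mask"))
  stop_if(length(sc_group1) < 2 || length(sc_group2) < 2,
          "need >= 2 subjects per group")
  n <- mask$n_nodes
  stop_if(!all(vapply(c(sc_group1, sc_group2),
                      function(m) is_square(m) && nrow(m) == n, logical(1))),
          "all SC matrices must be %d x %d", n, n)
  edges <- which(upper.tri(mask$mask) & mask$mask == 1, arr.ind = TRUE)
  x1 <- edge_matrix(sc_group1, edges)
  x2 <- edge_matrix(sc_group2, edges)
  t_val <- pooled_t(x1, x2)
  if (length(attr(t_val, "zero_variance")))
    message(sprintf("edgewise_t: %d zero-pooled-variance edge(s) set to t = 0",
                    length(attr(t_val, "zero_variance"))))
  if (contrast == "group2>group1") t_val <- -t_val
  tm <- matrix(0, n, n)
  tm[edges] <- t_val
  tm <- tm + t(tm)
  attr(tm, "edges") <- data.frame(source = edges[, 1], target = edges[, 2],
                                  t = as.numeric(t_val))
  tm
}

# edge counts of connected components of an undirected edge list
component_sizes <- function(edge_df, n_nodes) {
  if (nrow(edge_df) == 0) return(integer(0))
  g <- igraph::graph_from_data_frame(edge_df[, c("source", "target")],
                                     directed = FALSE,
                                     vertices = data.frame(name = seq_len(n_nodes)))
  comp <- igraph::components(g)
  memb <- comp$membership[as.character(edge_df$source)]
  sort(as.integer(table(memb)), decreasing = TRUE)
}

#' Connected components of suprathreshold edges
#'
#' Builds the graph of edges with `t > threshold` (strict) and returns its
#' connected components with component size measured in edges.
#'
#' @param t_matrix symmetric edgewise t matrix (e.g. from [edgewise_t]).
#' @param threshold primary threshold.
#' @return List of components, sorted by decreasing edge count; each has
#'   `edges` (data frame `source`, `target`, `t`), `nodes`, `size`.
#' @export
components_above_threshold <- function(t_matrix, threshold) {
  stop_if(!is_square(t_matrix), "`t_matrix` must be square")
  n <- nrow(t_matrix)
  sup <- which(upper.tri(t_matrix) & t_matrix > threshold, arr.ind = TRUE)
  if (nrow(sup) == 0) return(list())
  edge_df <- data.frame(source = sup[, 1], target = sup[, 2],
                        t = t_matrix[sup])
  g <- igraph::graph_from_data_frame(edge_df[, 1:2], directed = FALSE,
                                     vertices = data.frame(name = seq_len(n)))
  memb <- igraph::components(g)$membership
  comp_of_edge <- memb[as.character(edge_df$source)]
  comps <- lapply(unname(split(seq_len(nrow(edge_df)), comp_of_edge)),
                  function(idx) {
    e <- edge_df[idx, , drop = FALSE]
    rownames(e) <- NULL
    list(edges = e,
         nodes = sort(unique(c(e$source, e$target))),
         size = nrow(e))
  })
  comps[order(-vapply(comps, `[[`, integer(1), "size"))]
}

#' Network-based statistic with permutation FWER control
#'
#' Tests whether any connected component of edges exceeding the primary
#' threshold is larger than expected under exchangeability of group
#' labels. The null distribution of the maximal component extent (edge
#' count) is built from seeded random permutations of the group labels;
#' each observed component gets the family-wise-corrected p-value
#' `p = (1 + #[perm max size >= observed size]) / (1 + n_permutations)`
#' (add-one estimator, never exactly 0). When fewer distinct label
#' assignments exist than requested permutations, all of them are
#' enumerated instead (reported via a message).
#'
#' @inheritParams edgewise_t
#' @param threshold primary t threshold (see [effect_size_threshold]).
#' @param n_permutations number of label permutations (>= 100; 10000 in
#'   the reference analysis).
#' @param seed RNG seed.
#' @return An object of class `nbs_result`: `components` (as in
#'   [components_above_threshold]), `p_values`, `threshold_t`,
#'   `n_permutations`, `contrast`, `null_max_size`.
#' @export
nbs_test <- function(sc_group1, sc_group2, mask, threshold,
                     n_permutations = 10000L, seed = 1L,
                     contrast = c("group1>group2", "group2>group1")) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(mask, "conn_mask"))
  stop_if(n_permutations < 100, "`n_permutations` must be >= 100")
  n <- mask$n_nodes
  n1 <- length(sc_group1); n2 <- length(sc_group2); N <- n1 + n2
  tm <- edgewise_t(sc_group1, sc_group2, mask, contrast)
  observed <- components_above_threshold(tm, threshold)

  edges <- which(upper.tri(mask$mask) & mask$mask == 1, arr.ind = TRUE)
  x_all <- rbind(edge_matrix(sc_group1, edges), edge_matrix(sc_group2, edges))
  sign_flip <- if (contrast == "group2>group1") -1 else 1

  set.seed(seed)
  n_distinct <- suppressWarnings(choose(N, n1))
  exhaustive <- is.finite(n_distinct) && n_distinct <= n_permutations
  perm_sets <- if (exhaustive) {
    message(sprintf("nbs_test: only %d distinct permutations; enumerating exhaustively",
                    n_distinct))
    asplit(utils::combn(N, n1), 2)
  } else {
    lapply(seq_len(n_permutations), function(i) sample.int(N, n1))
  }
  null_max <- vapply(perm_sets, function(idx1) {
    t_perm <- sign_flip * pooled_t(x_all[idx1, , drop = FALSE],
                                   x_all[-idx1, , drop = FALSE])
    sup <- which(t_perm > threshold)
    if (length(sup) <= 1) return(length(sup))
    max(component_sizes(data.frame(source = edges[sup, 1],
                                   target = edges[sup, 2]), n))
  }, numeric(1))

  n_perm_used <- length(perm_sets)
  p_values <- vapply(observed, function(comp) {
    (1 + sum(null_max >= comp$size)) / (1 + n_perm_used)
  }, numeric(1))
  structure(list(components = observed, p_values = p_values,
                 threshold_t = threshold, n_permutations = n_perm_used,
                 contrast = contrast, null_max_size = null_max),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("nbs_result (%s, t > %g, %d permutations): %d component(s)\n",
              x$contrast, x$threshold_t, x$n_permutations, length(x$components)))
  for (i in seq_along(x$components))
    cat(sprintf("  component %d: %d edges, %d nodes, p = %.4g\n", i,
                x$components[[i]]$size, length(x$components[[i]]$nodes),
                x$p_values[i]))
  invisible(x)
}

#' Tidy edge table of an NBS result
#'
#' @param x an `nbs_result`.
#' @return Data frame with one row per suprathreshold edge: component id,
#'   size, p-value, contrast, source, target, t.
#' @export
nbs_edge_table <- function(x) {
  stopifnot(inherits(x, "nbs_result"))
  if (length(x$components) == 0)
    return(data.frame(component = integer(0), size = integer(0),
                      p_value = numeric(0), contrast = character(0),
                      source = integer(0), target = integer(0), t = numeric(0)))
  do.call(rbind, lapply(seq_along(x$components), function(i) {
    e <- x$components[[i]]$edges
    data.frame(component = i, size = x$components[[i]]$size,
               p_value = x$p_values[i], contrast = x$contrast,
               source = e$source, target = e$target, t = e$t)
  }))
}
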