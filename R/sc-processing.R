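#' Binary anatomical admissibility mask
#'
#' A symmetric, zero-diagonal 0/1 matrix of admissible anatomical
#' connections, obtained by density-thresholding a structural connectivity
#' (SC) matrix. The mask constrains which directed effective-connectivity
#' weights may be nonzero.
#'
#' @param mask square binary matrix, symmetric with zero diagonal.
#' @return An object of class `conn_mask` with fields `mask` and `density`
#'   (fraction of admissible undirected pairs among `n(n-1)/2`).
#' @export
conn_mask <- function(mask) {
  mask <- unname(as.matrix(mask))
  stop_if(!is_square(mask), "`mask` must be square")
  stop_if(!all(mask %in% c(0, 1)), "`mask` must be binary")
  stop_if(any(mask != t(mask)), "`mask` must be symmetric")
  stop_if(any(diag(mask) != 0), "`mask` diagonal must be 0")
  n <- nrow(mask)
  structure(list(mask = mask, density = sum(mask) / (n * (n - 1)), n_nodes = n),
            class = "conn_mask")
}

#' @export
print.conn_mask <- function(x, ...) {
  cat(sprintf("conn_mask: %d nodes, %d undirected links, density %.3f\n",
              x$n_nodes, sum(x$mask) / 2, x$density))
  invisible(x)
}

#' Symmetrize a structural connectivity matrix
#'
#' Probabilistic tractography does not capture fiber directionality, so SC
#' matrices are symmetrized by averaging with their transpose.
#'
#' @param sc square nonnegative matrix.
#' @return `(sc + t(sc)) / 2`.
#' @export
symmetrize_sc <- function(sc) {
  stop_if(!is_square(sc), "`sc` must be square")
  stop_if(any(sc < 0), "`sc` must be nonnegative")
  (sc + t(sc)) / 2
}

#' Density-threshold an SC matrix into a binary mask
#'
#' Keeps the `k = round(density * n(n-1)/2)` largest off-diagonal
#' upper-triangle weights (rounding half away from zero) and returns the
#' symmetric binary mask. Ties straddling the cutoff are broken by
#' (row, column) lexicographic order and reported via a message.
#'
#' @param sc symmetric nonnegative matrix.
#' @param density target fraction of retained undirected pairs, in (0, 1].
#' @return A [conn_mask].
#' @export
threshold_density_mask <- function(sc, density = 0.30) {
  stop_if(!is_square(sc), "`sc` must be square")
  stop_if(max(abs(sc - t(sc))) > 1e-12 * max(1, max(abs(sc))),
          "`sc` must be symmetric (see symmetrize_sc)")
  stop_if(!(density > 0 && density <= 1), "`density` must be in (0, 1]")
  n <- nrow(sc)
  n_pairs <- n * (n - 1) / 2
  k <- as.integer(round_half_away(density * n_pairs))
  ut <- which(upper.tri(sc), arr.ind = TRUE)
  w <- sc[ut]
  ord <- order(-w, ut[, 1], ut[, 2])
  if (k >= 1 && k < n_pairs && w[ord[k]] == w[ord[k + 1]])
    message(sprintf("threshold_density_mask: ties at the cutoff weight %g broken by (row, column) order",
                    w[ord[k]]))
  keep <- ord[seq_len(k)]
  m <- matrix(0, n, n)
  m[ut[keep, , drop = FALSE]] <- 1
  conn_mask(m + t(m))
}

#' Intersect two admissibility masks
#'
#' Elementwise AND of two masks of equal size: a link is admissible only if
#' it is above threshold in both groups. The intersection of two 30%-density
#' group masks is how the shared analysis mask is built (a ~27% density
#' outcome on the original cohort).
#'
#' @param a,b [conn_mask] objects of the same size.
#' @return A [conn_mask] with recomputed density.
#' @export
intersect_masks <- function(a, b) {
  stopifnot(inherits(a, "conn_mask"), inherits(b, "conn_mask"))
  stop_if(a$n_nodes != b$n_nodes, "mask size mismatch (%d vs %d)",
          a$n_nodes, b$n_nodes)
  conn_mask(a$mask * b$mask)
}

#' Index table of vectorized connectome features
#'
#' Fixed, documented ordering of the entries returned by
#' [vectorize_features]: `lower_triangle` walks rows `i = 2..n` and within
#' each row columns `j < i` (row-major over the strict lower triangle);
#' `masked_directed` walks all ordered pairs `(source, target)` with
#' `mask = 1` in row-major order.
#'
#' @param n number of nodes.
#' @param mode `"lower_triangle"` or `"masked_directed"`.
#' @param mask a [conn_mask], required for `masked_directed`.
#' @return Data frame with columns `source`, `target` (1-based indices).
#' @export
feature_index <- function(n, mode = c("lower_triangle", "masked_directed"),
                          mask = NULL) {
  mode <- match.arg(mode)
  if (mode == "lower_triangle") {
    idx <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
    ord <- order(idx[, 1], idx[, 2])  # row-major over rows 2..n
    data.frame(source = idx[ord, 1], target = idx[ord, 2])
  } else {
    stop_if(is.null(mask), "`masked_directed` mode requires a mask")
    stopifnot(inherits(mask, "conn_mask"))
    idx <- which(t(mask$mask) == 1, arr.ind = TRUE)  # row-major over mask
    data.frame(source = idx[, 2], target = idx[, 1])
  }
}

#' Vectorize a connectivity matrix into a feature vector
#'
#' `lower_triangle` (for symmetric SC/FC matrices) returns the
#' `n(n-1)/2` strictly-sub-diagonal entries; a 116-node connectome yields
#' 6670 features. `masked_directed` (for EC matrices) returns the entries at
#' all ordered pairs where the mask admits a link, i.e. twice the undirected
#' link count. Ordering follows [feature_index].
#'
#' @param m square matrix; must be symmetric for `lower_triangle`.
#' @param mode `"lower_triangle"` or `"masked_directed"`.
#' @param mask a [conn_mask] (for `masked_directed`).
#' @return Numeric feature vector.
#' @export
vectorize_features <- function(m, mode = c("lower_triangle", "masked_directed"),
                               mask = NULL) {
  mode <- match.arg(mode)
  stop_if(!is_square(m), "`m` must be square")
  fi <- feature_index(nrow(m), mode, mask)
  if (mode == "lower_triangle")
    stop_if(max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))),
            "`lower_triangle` mode requires a symmetric matrix")
  m[cbind(fi$source, fi$target)]
}

#' Rebuild a matrix from a feature vector
#'
#' Exact inverse of [vectorize_features] on the retained entries; entries
#' not covered by the vectorization are 0 (for `lower_triangle` the upper
#' triangle mirrors the lower).
#'
#' @param v feature vector as produced by [vectorize_features].
#' @param n number of nodes.
#' @inheritParams vectorize_features
#' @return Square matrix.
#' @export
devectorize_features <- function(v, n, mode = c("lower_triangle", "masked_directed"),
                                 mask = NULL) {
  mode <- match.arg(mode)
  fi <- feature_index(n, mode, mask)
  stop_if(length(v) != nrow(fi), "length(v) = %d does not match %d features",
          length(v), nrow(fi))
  m <- matrix(0, n, n)
  m[cbind(fi$source, fi$target)] <- v
  if (mode == "lower_triangle") m <- m + t(m)
  m
}
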