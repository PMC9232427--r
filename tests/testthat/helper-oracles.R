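# Independent oracles and small fixture builders used across the suite.

# Lyapunov solution via Kronecker vectorization: A Q + Q A' + S = 0
lyap_kron <- function(A, S) {
  n <- nrow(A)
  matrix(solve(kronecker(diag(n), A) + kronecker(A, diag(n)), -as.vector(S)), n)
}

# stationary covariance by fine-step numerical integration of
# Q = int_0^Inf exp(A s) S exp(A' s) ds  (midpoint rule, Matrix::expm)
lyap_integral <- function(A, S, h = 0.01, t_max = 60) {
  Eh <- as.matrix(Matrix::expm(A * h))
  Ek <- as.matrix(Matrix::expm(A * h / 2))  # midpoint
  Q <- matrix(0, nrow(A), ncol(A))
  for (k in seq_len(round(t_max / h))) {
    Q <- Q + Ek %*% S %*% t(Ek) * h
    Ek <- Eh %*% Ek
  }
  Q
}

# connected components of an undirected edge list by union-find
components_unionfind <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comp_of_edge <- vapply(seq_len(nrow(edges)), function(r) find(edges[r, 1]),
                         integer(1))
  sort(as.integer(table(comp_of_edge)), decreasing = TRUE)
}

# random stable MOU parameters on a random mask (sample-unit scale)
random_stable_params <- function(n, density = 0.3, seed = 1, tau_x = 1,
                                 scale = 0.08, sdlog = 1) {
  mask <- generate_mask(n, density, seed = seed)
  set.seed(seed + 500)
  idx <- which(mask$mask == 1, arr.ind = TRUE)
  ec <- matrix(0, n, n)
  ec[idx] <- rlnorm(nrow(idx), log(scale), sdlog)
  p <- mou_params(ec, 1, tau_x)
  while (attr(build_state_matrix(p), "max_re_eig") > -0.05) {
    ec <- ec * 0.9
    p <- mou_params(ec, 1, tau_x)
  }
  list(params = p, mask = mask)
}

# cohort with planted separable class structure for classifier tests
separable_table <- function(n_per_class = 20, p = 30, gap = 4, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_per_class * p), n_per_class),
             matrix(rnorm(n_per_class * p), n_per_class))
  x[seq_len(n_per_class), 1:3] <- x[seq_len(n_per_class), 1:3] + gap
  meta <- data.frame(
    subject_id = sprintf("s%02d", seq_len(2 * n_per_class)),
    group = rep(c("a", "b"), each = n_per_class),
    condition = "c1")
  feature_table(x, meta, "EC")
}
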