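#' Random connected admissibility mask
#'
#' Draws a symmetric binary mask with exactly
#' `round(density * n(n-1)/2)` undirected links, guaranteed connected:
#' up to 100 re-draws, after which the components of the last draw are
#' bridged (and surplus links removed) to restore the link count, with a
#' message. Stands in for a tractography-derived, density-thresholded SC
#' mask.
#'
#' @param n_nodes number of nodes (>= 3).
#' @param density fraction of undirected pairs retained, in (0, 1].
#' @param seed RNG seed.
#' @return A [conn_mask].
#' @export
generate_mask <- function(n_nodes, density = 0.30, seed = 1L) {
  stop_if(n_nodes < 3, "`n_nodes` must be >= 3")
  stop_if(!(density > 0 && density <= 1), "`density` must be in (0, 1]")
  n_pairs <- n_nodes * (n_nodes - 1) / 2
  k <- as.integer(round_half_away(density * n_pairs))
  stop_if(k < n_nodes - 1,
          "density %.3f gives %d links: too few to connect %d nodes",
          density, k, n_nodes)
  ut <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
  set.seed(seed)
  mask_from <- function(sel) {
    m <- matrix(0, n_nodes, n_nodes)
    m[ut[sel, , drop = FALSE]] <- 1
    m + t(m)
  }
  connected <- function(m) {
    g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
    igraph::is_connected(g)
  }
  for (i in seq_len(100)) {
    sel <- sample.int(n_pairs, k)
    m <- mask_from(sel)
    if (connected(m)) return(conn_mask(m))
  }
  message("generate_mask: bridging components after 100 draws")
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
  memb <- igraph::components(g)$membership
  reps <- vapply(split(seq_len(n_nodes), memb), `[`, integer(1), 1)
  for (i in seq_len(length(reps) - 1)) {
    m[reps[i], reps[i + 1]] <- m[reps[i + 1], reps[i]] <- 1
    # remove a surplus link that is not a bridge of the new graph
    gg <- igraph::graph_from_adjacency_matrix(m, mode = "undirected")
    br <- igraph::bridges(gg)
    el <- igraph::as_edgelist(gg, names = FALSE)
    removable <- setdiff(seq_len(nrow(el)), br)
    drop_e <- el[removable[length(removable)], ]
    m[drop_e[1], drop_e[2]] <- m[drop_e[2], drop_e[1]] <- 0
  }
  conn_mask(m)
}

# directed (source, target) entries admitted by a mask, row-major
directed_entries <- function(mask) {
  fi <- feature_index(mask$n_nodes, "masked_directed", mask)
  as.matrix(fi)
}

#' Group- and condition-level MOU parameters with planted differences
#'
#' Builds the four parameter sets of a two-group, two-condition design on a
#' shared mask. Baseline directed weights are log-normal with median
#' `base_scale` and log-sd `sdlog` over the admitted links (connectome
#' weights are heavy-tailed); group 2 adds
#' `effect_scale` on `n_planted_links` directed links (the group
#' signature), and condition 2 adds `condition_shift` on a disjoint set of
#' the same size (the condition signature). If any of the four systems is
#' not stable with margin `stab_margin`, all weights are rescaled uniformly
#' by 0.9 (up to 20 times, with a message).
#'
#' Planted group links are placed preferentially (70%) within the first
#' half of the nodes, emulating a lateralized effect, unless
#' `lateralize = FALSE`.
#'
#' @param mask a [conn_mask].
#' @param base_scale median baseline weight (1/s).
#' @param sdlog log-sd of the baseline weight distribution.
#' @param n_planted_links planted links per signature.
#' @param effect_scale group-difference increment (1/s).
#' @param condition_shift condition-difference increment (1/s).
#' @param tau_x,sigma time constant (s) and input variance of all sets.
#' @param lateralize place group links preferentially in one hemisphere?
#' @param stab_margin required `-max Re(eig)`.
#' @param seed RNG seed.
#' @return List with `params` (named list `g1_c1`, `g1_c2`, `g2_c1`,
#'   `g2_c2` of [mou_params]), `registry` (data frame: `set`, `source`,
#'   `target`), `mask`, and `rescale_factor`.
#' @export
generate_group_ec <- function(mask, base_scale = 0.04, sdlog = 1.0,
                              n_planted_links = 20L,
                              effect_scale = 0.20, condition_shift = 0.20,
                              tau_x = 2, sigma = 1, lateralize = TRUE,
                              stab_margin = 0.05, seed = 1L) {
  stopifnot(inherits(mask, "conn_mask"))
  entries <- directed_entries(mask)
  stop_if(n_planted_links > nrow(entries),
          "n_planted_links exceeds the %d directed mask entries", nrow(entries))
  set.seed(seed)
  n <- mask$n_nodes
  base <- matrix(0, n, n)
  base[entries] <- stats::rlnorm(nrow(entries), log(base_scale), sdlog)

  left <- seq_len(floor(n / 2))
  in_left <- entries[, 1] %in% left & entries[, 2] %in% left
  pick_planted <- function(pool_idx, k) pool_idx[sample.int(length(pool_idx), k)]
  if (lateralize && sum(in_left) > 0) {
    k_left <- min(sum(in_left), ceiling(0.7 * n_planted_links))
    sel <- pick_planted(which(in_left), k_left)
    if (k_left < n_planted_links)
      sel <- c(sel, pick_planted(setdiff(seq_len(nrow(entries)), sel),
                                 n_planted_links - k_left))
  } else {
    sel <- pick_planted(seq_len(nrow(entries)), n_planted_links)
  }
  sel_cond <- pick_planted(setdiff(seq_len(nrow(entries)), sel), n_planted_links)

  add_at <- function(m, idx, delta) { m[entries[idx, , drop = FALSE]] <-
    m[entries[idx, , drop = FALSE]] + delta; m }
  ec_sets <- list(
    g1_c1 = base,
    g1_c2 = add_at(base, sel_cond, condition_shift),
    g2_c1 = add_at(base, sel, effect_scale),
    g2_c2 = add_at(add_at(base, sel, effect_scale), sel_cond, condition_shift))

  f <- 1
  for (r in 0:20) {
    stop_if(r == 20, "stability unreachable after 20 uniform rescalings")
    margins <- vapply(ec_sets, function(ec)
      cpp_max_re_eig(t(f * ec) - diag(n) / tau_x), numeric(1))
    if (max(margins) <= -stab_margin) break
    f <- f * 0.9
    message(sprintf("generate_group_ec: rescaling weights by %.3f for stability", f))
  }
  params <- lapply(ec_sets, function(ec) mou_params(f * ec, sigma, tau_x))
  registry <- rbind(
    data.frame(set = "group", source = entries[sel, 1], target = entries[sel, 2]),
    data.frame(set = "condition", source = entries[sel_cond, 1],
               target = entries[sel_cond, 2]))
  list(params = params, registry = registry, mask = mask, rescale_factor = f)
}

#' Simulate a full two-group, two-condition cohort of sessions
#'
#' For each subject a fingerprint jitter (Gaussian on the admitted links,
#' weights truncated at zero) is drawn once and applied to that subject's
#' group/condition parameter sets; each session is then an Euler-Maruyama
#' simulation sampled at the repetition time `tr`. With 19 subjects per
#' group and two conditions this yields 76 labeled sessions.
#'
#' @param gen output of [generate_group_ec].
#' @param n_subjects_per_group subjects per group (default 19).
#' @param n_samples time points per session (default 500, about one
#'   15-minute scan at TR = 2 s).
#' @param subject_noise_sd sd of the subject jitter on the weights.
#' @param tr output sampling period in seconds.
#' @param seed RNG seed.
#' @return List with `sessions` (list of [ts_session]), `meta`
#'   (data frame: `subject_id`, `group`, `condition`) and `subject_ec`
#'   (list of the true per-session EC matrices, for validation).
#' @export
simulate_cohort <- function(gen, n_subjects_per_group = 19L, n_samples = 500L,
                            subject_noise_sd = 0.01, tr = 2, seed = 1L) {
  mask <- gen$mask
  entries <- directed_entries(mask)
  tau_x <- gen$params$g1_c1$tau_x
  dt_int <- 0.05 * tau_x
  subsample <- as.integer(round(tr / dt_int))
  stop_if(subsample < 1, "`tr` smaller than the integration step")
  sessions <- list()
  meta <- list()
  subject_ec <- list()
  counter <- 0L
  for (g in 1:2) {
    for (s in seq_len(n_subjects_per_group)) {
      subj_id <- sprintf("g%d_s%02d", g, s)
      counter <- counter + 1L
      set.seed(seed + 1000L + counter)
      jitter <- matrix(0, mask$n_nodes, mask$n_nodes)
      jitter[entries] <- rnorm(nrow(entries), 0, subject_noise_sd)
      for (cnd in 1:2) {
        base <- gen$params[[sprintf("g%d_c%d", g, cnd)]]
        ok <- FALSE
        for (try in 0:10) {
          ec_subj <- pmax(base$ec + jitter, 0)
          diag(ec_subj) <- 0
          p_subj <- mou_params(ec_subj, base$sigma, base$tau_x)
          if (cpp_max_re_eig(build_state_matrix(p_subj)) < 0) { ok <- TRUE; break }
          message("simulate_cohort: unstable subject parameters, redrawing jitter")
          jitter <- jitter * 0.5
        }
        stop_if(!ok, "instability propagated from subject jitter")
        ses <- simulate_mou(p_subj, n_samples, dt_integration = dt_int,
                            subsample = subsample,
                            seed = seed + 10000L + counter * 10L + cnd,
                            subject_id = subj_id,
                            group = paste0("group", g),
                            condition = paste0("condition", cnd))
        sessions[[length(sessions) + 1L]] <- ses
        subject_ec[[length(subject_ec) + 1L]] <- p_subj$ec
        meta[[length(meta) + 1L]] <- data.frame(
          subject_id = subj_id, group = paste0("group", g),
          condition = paste0("condition", cnd))
      }
    }
  }
  list(sessions = sessions, meta = do.call(rbind, meta), subject_ec = subject_ec)
}

#' Random connected planted path within a mask
#'
#' Selects a connected chain of `n_edges` mask edges (a path over
#' `n_edges + 1` nodes), by default within the first half of the nodes,
#' mirroring a small left-lateralized subnetwork.
#'
#' @param mask a [conn_mask].
#' @param n_edges number of edges in the path (default 3).
#' @param within_left restrict to the first half of the nodes when
#'   possible?
#' @param seed RNG seed.
#' @return Data frame with columns `source`, `target` (`source < target`).
#' @export
planted_path_edges <- function(mask, n_edges = 3L, within_left = TRUE,
                               seed = 1L) {
  stopifnot(inherits(mask, "conn_mask"))
  set.seed(seed)
  n <- mask$n_nodes
  allowed <- if (within_left) seq_len(floor(n / 2)) else seq_len(n)
  sub <- mask$mask[allowed, allowed, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
  for (attempt in seq_len(200)) {
    start <- sample.int(nrow(sub), 1)
    path <- igraph::random_walk(g, start, steps = n_edges)
    path <- as.integer(path)
    if (length(path) == n_edges + 1 && !anyDuplicated(path)) {
      e <- cbind(allowed[path[-length(path)]], allowed[path[-1]])
      return(data.frame(source = pmin(e[, 1], e[, 2]),
                        target = pmax(e[, 1], e[, 2])))
    }
  }
  stop("could not find a connected planted path in the mask", call. = FALSE)
}

#' Synthetic per-subject SC cohort with a planted component
#'
#' Subject SC matrices are a shared baseline (uniform weights on the mask)
#' plus symmetric Gaussian edge noise, clipped at zero; group 1 has the
#' planted connected edges shifted upward by `effect_sd_units * noise_sd`.
#' Emulates the structural side of the analysis, where one group carries a
#' small strengthened subnetwork.
#'
#' @param mask a [conn_mask].
#' @param n_subjects_per_group subjects per group (default 19).
#' @param planted_edges data frame (`source`, `target`) of connected mask
#'   edges; default a random 3-edge path ([planted_path_edges]).
#' @param effect_sd_units planted shift in units of `noise_sd` (0 for a
#'   null cohort).
#' @param noise_sd sd of the edge noise.
#' @param base_range range of the baseline edge weights.
#' @param seed RNG seed.
#' @return List with `group1`, `group2` (lists of symmetric SC matrices),
#'   `planted_edges`, `mask`.
#' @export
generate_sc_cohort <- function(mask, n_subjects_per_group = 19L,
                               planted_edges = NULL, effect_sd_units = 2,
                               noise_sd = 0.1, base_range = c(0.5, 1.5),
                               seed = 1L) {
  stopifnot(inherits(mask, "conn_mask"))
  if (is.null(planted_edges))
    planted_edges <- planted_path_edges(mask, 3L, seed = seed)
  pe <- cbind(planted_edges$source, planted_edges$target)
  stop_if(any(mask$mask[pe] == 0), "planted edges must lie within the mask")
  set.seed(seed)
  n <- mask$n_nodes
  ut_idx <- which(upper.tri(mask$mask) & mask$mask == 1, arr.ind = TRUE)
  base <- matrix(0, n, n)
  base[ut_idx] <- runif(nrow(ut_idx), base_range[1], base_range[2])
  base <- base + t(base)
  shift <- matrix(0, n, n)
  shift[pe] <- effect_sd_units * noise_sd
  shift <- shift + t(shift)
  draw_subject <- function(mean_sc) {
    noise <- matrix(0, n, n)
    noise[ut_idx] <- rnorm(nrow(ut_idx), 0, noise_sd)
    pmax(mean_sc + noise + t(noise), 0) * (mask$mask > 0)
  }
  group1 <- lapply(seq_len(n_subjects_per_group), function(i) draw_subject(base + shift))
  group2 <- lapply(seq_len(n_subjects_per_group), function(i) draw_subject(base))
  list(group1 = group1, group2 = group2, planted_edges = planted_edges,
       mask = mask)
}

#' Synthetic parcellation label table
#'
#' Generates a parcellation table in the format the pipeline reads:
#' `n_cortical` cortical ROIs split evenly over the seven resting-state
#' networks and two hemispheres, plus `n_subcortical` subcortical ROIs.
#' With the defaults this reproduces the 100 + 16 = 116 ROI layout.
#'
#' @param n_cortical number of cortical ROIs (split across hemispheres).
#' @param n_subcortical number of subcortical ROIs.
#' @return Data frame with columns `roi_name`, `network`, `hemisphere`.
#' @export
make_parcellation <- function(n_cortical = 100L, n_subcortical = 16L) {
  networks <- c("visual", "somatomotor", "dorsal attention",
                "salience/ventral attention", "limbic", "control", "DMN")
  short <- c("Vis", "SomMot", "DorsAttn", "SalVentAttn", "Limbic", "Cont",
             "Default")
  per_hemi <- n_cortical %/% 2
  build_hemi <- function(h) {
    net_idx <- rep(seq_along(networks), length.out = per_hemi)
    net_idx <- sort(net_idx)
    counts <- ave(net_idx, net_idx, FUN = seq_along)
    data.frame(roi_name = sprintf("%sH_%s_%d", h, short[net_idx], counts),
               network = networks[net_idx], hemisphere = h)
  }
  sub_per_hemi <- n_subcortical %/% 2
  sub <- data.frame(
    roi_name = c(sprintf("LH_Subcort_%d", seq_len(sub_per_hemi)),
                 sprintf("RH_Subcort_%d", seq_len(n_subcortical - sub_per_hemi))),
    network = "subcortical",
    hemisphere = c(rep("L", sub_per_hemi), rep("R", n_subcortical - sub_per_hemi)))
  out <- rbind(build_hemi("L"), build_hemi("R"), sub)
  out$hemisphere <- substr(out$hemisphere, 1, 1)
  rownames(out) <- NULL
  out
}
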