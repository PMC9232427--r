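#' Fit the MOU model to one session
#'
#' Convenience wrapper chaining the empirical steps: optional narrowband
#' filtering, covariance estimation at the given lag, time-constant
#' estimation from the mean autocovariance (lags 0..2, in sampling-period
#' units), and the masked gradient-descent fit. The fit operates in
#' sampling-period units: the lag is in samples and `tau_x` is
#' `tau_seconds / dt`.
#'
#' @param session a [ts_session].
#' @param mask a [conn_mask].
#' @param band optional `c(low_hz, high_hz)` bandpass (e.g.
#'   `c(0.04, 0.07)`); `NULL` skips filtering.
#' @param lag covariance lag in samples (default 1).
#' @param tau_x time constant in samples; `NULL` (default) estimates it
#'   via [estimate_tau] with fallback 1 sample.
#' @param config fit settings ([fit_config]).
#' @return A `mou_fit` (see [fit_mou_ec]) with the estimated `tau_x`
#'   attached as `$tau_x` and the session identifiers as `$meta`.
#' @export
fit_session <- function(session, mask, band = NULL, lag = 1L, tau_x = NULL,
                        config = fit_config()) {
  stopifnot(inherits(session, "ts_session"))
  if (!is.null(band))
    session <- bandpass_filter(session, band[1], band[2])
  emp <- empirical_covariances(session, lag = lag)
  if (is.null(tau_x))
    tau_x <- as.numeric(estimate_tau(session_mean_autocov(session, 2L),
                                     tau_default = 1))
  fit <- fit_mou_ec(emp, mask, tau_x, config)
  fit$tau_x <- tau_x
  fit$meta <- data.frame(subject_id = session$subject_id,
                         group = session$group, condition = session$condition)
  fit
}

#' Feature matrices of a fitted cohort
#'
#' Builds the per-session feature vectors used for classification: EC
#' features are the fitted weights at all directed mask entries
#' (`masked_directed`), FC features the strictly-lower-triangle of the
#' empirical zero-lag covariance of the (filtered) session.
#'
#' @param fits list of `mou_fit` objects (one per session).
#' @param sessions the corresponding list of [ts_session] (already
#'   filtered if filtering is part of the analysis).
#' @param mask the [conn_mask] used in the fits.
#' @param meta data frame of session identifiers (`subject_id`, `group`,
#'   `condition`).
#' @return List of two [feature_table]s: `ec` and `fc` (z-scored per
#'   session).
#' @export
cohort_features <- function(fits, sessions, mask, meta) {
  ec <- t(vapply(fits, function(f)
    vectorize_features(f$params$ec, "masked_directed", mask),
    numeric(sum(mask$mask))))
  fc <- t(vapply(sessions, function(s)
    vectorize_features(empirical_covariances(s)$fc0, "lower_triangle"),
    numeric(ncol(sessions[[1]]$data) * (ncol(sessions[[1]]$data) - 1) / 2)))
  list(ec = feature_table(ec, meta, "EC",
                          feature_index(mask$n_nodes, "masked_directed", mask)),
       fc = feature_table(fc, meta, "FC",
                          feature_index(mask$n_nodes, "lower_triangle")))
}

#' Run the complete demo pipeline on a synthetic cohort
#'
#' End-to-end exercise of every stage on the demo profile: generate a
#' connected mask and group/condition MOU parameters with planted
#' differences, simulate the BOLD-like cohort and the per-subject SC
#' cohort, rebuild the analysis mask from the group-mean SC matrices
#' (density threshold + intersection), fit the MOU-EC model to every
#' session, classify conditions and groups from EC/FC/SC features with
#' surrogate baselines, extract an RFE support network, and run the
#' network-based statistic on the SC cohort for both contrasts. All
#' stages are seeded; outputs are deterministic given `seed`.
#'
#' Result tables are written to `outdir` as CSV: `demo_log.txt`,
#' `mask.csv`, `fit_summary.csv`, `accuracy.csv`, `rfe_support.csv`,
#' `nbs_components.csv`.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed for the whole run.
#' @param n_nodes,density,n_subjects_per_group,n_samples demo profile
#'   (defaults: 40 nodes, 0.30 density, 19 + 19 subjects, 500 samples).
#' @param n_repeats classification splits (default 50).
#' @param rfe_repeats RFE cross-validation repeats (default 10).
#' @param rfe_step RFE elimination step for the demo (default 5).
#' @param n_permutations NBS permutations (default 1000 for the demo).
#' @param band bandpass in Hz applied before covariance estimation.
#' @param fit fit settings ([fit_config]).
#' @return Invisibly, a list with all result tables and intermediate
#'   objects (`mask`, `gen`, `cohort`, `fits`, `features`, `accuracy`,
#'   `rfe`, `nbs`).
#' @export
run_demo_pipeline <- function(outdir, seed = 1L, n_nodes = 40L,
                              density = 0.30, n_subjects_per_group = 19L,
                              n_samples = 500L, n_repeats = 50L,
                              rfe_repeats = 10L, rfe_step = 5L,
                              n_permutations = 1000L, band = c(0.04, 0.07),
                              fit = fit_config()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    sprintf("mouec demo pipeline, package version %s",
            as.character(utils::packageVersion("mouec"))),
    sprintf("seed=%d n_nodes=%d density=%g n_subjects_per_group=%d n_samples=%d",
            seed, n_nodes, density, n_subjects_per_group, n_samples),
    sprintf("n_repeats=%d rfe_repeats=%d rfe_step=%d n_permutations=%d band=%g-%g Hz",
            n_repeats, rfe_repeats, rfe_step, n_permutations, band[1], band[2]))

  # --- synthetic ground truth and cohorts -------------------------------
  mask <- generate_mask(n_nodes, density, seed = seed)
  gen <- generate_group_ec(mask, seed = seed)
  cohort <- simulate_cohort(gen, n_subjects_per_group, n_samples, seed = seed)
  sc <- generate_sc_cohort(mask, n_subjects_per_group, seed = seed)

  # --- analysis mask rebuilt from the SC cohort, as in the real pipeline
  mean_sc1 <- symmetrize_sc(Reduce(`+`, sc$group1) / length(sc$group1))
  mean_sc2 <- symmetrize_sc(Reduce(`+`, sc$group2) / length(sc$group2))
  mask_g1 <- threshold_density_mask(mean_sc1, density)
  mask_g2 <- threshold_density_mask(mean_sc2, density)
  analysis_mask <- intersect_masks(mask_g1, mask_g2)
  log_lines <- c(log_lines, sprintf(
    "analysis mask: group densities %.3f / %.3f, intersected density %.3f",
    mask_g1$density, mask_g2$density, analysis_mask$density))
  write_matrix(analysis_mask$mask, file.path(outdir, "mask.csv"))

  # --- per-session filtering and EC fits --------------------------------
  filtered <- lapply(cohort$sessions, bandpass_filter, low_hz = band[1],
                     high_hz = band[2])
  fits <- lapply(filtered, fit_session, mask = analysis_mask, band = NULL,
                 config = fit)
  fit_summary <- cbind(cohort$meta, do.call(rbind, lapply(fits, function(f)
    data.frame(tau_x = f$tau_x, error = f$best_error,
               pearson_fc0 = f$trace$pearson_fc0[f$best_iter],
               pearson_fc1 = f$trace$pearson_fc1[f$best_iter],
               n_iter = nrow(f$trace)))))
  write.csv(fit_summary, file.path(outdir, "fit_summary.csv"), row.names = FALSE)

  # --- classification: conditions within group, groups within condition -
  feats <- cohort_features(fits, filtered, analysis_mask, cohort$meta)
  sc_feats <- feature_table(
    rbind(t(sapply(sc$group1, vectorize_features, mode = "lower_triangle")),
          t(sapply(sc$group2, vectorize_features, mode = "lower_triangle"))),
    data.frame(subject_id = unique(cohort$meta$subject_id),
               group = rep(c("group1", "group2"), each = n_subjects_per_group),
               condition = "structural"),
    "SC", feature_index(n_nodes, "lower_triangle"))

  eval_grid <- expand.grid(task = c("condition", "group"),
                           within = c("group1", "group2", "condition1", "condition2"),
                           metric = c("EC", "FC"), classifier = c("mlr", "knn1"),
                           surrogate = c(FALSE, TRUE), stringsAsFactors = FALSE)
  eval_grid <- eval_grid[(eval_grid$task == "condition" &
                            eval_grid$within %in% c("group1", "group2")) |
                         (eval_grid$task == "group" &
                            eval_grid$within %in% c("condition1", "condition2")), ]
  acc_rows <- lapply(seq_len(nrow(eval_grid)), function(i) {
    g <- eval_grid[i, ]
    tab <- if (g$metric == "EC") feats$ec else feats$fc
    acc <- repeated_evaluation(tab, task = g$task, within = g$within,
                               classifier = g$classifier, n_repeats = n_repeats,
                               seed = seed, surrogate = g$surrogate,
                               subject_aware = g$task == "condition")
    data.frame(task = g$task, within = g$within, metric = g$metric,
               classifier = g$classifier, surrogate = g$surrogate,
               rep = seq_along(acc), accuracy = acc)
  })
  # SC features enter the group tasks only (one matrix per subject)
  for (w in c("group")) for (cls in c("mlr", "knn1")) for (surr in c(FALSE, TRUE)) {
    acc <- repeated_evaluation(sc_feats, task = "group", classifier = cls,
                               n_repeats = n_repeats, seed = seed,
                               surrogate = surr)
    acc_rows[[length(acc_rows) + 1]] <-
      data.frame(task = "group", within = "structural", metric = "SC",
                 classifier = cls, surrogate = surr, rep = seq_along(acc),
                 accuracy = acc)
  }
  accuracy <- do.call(rbind, acc_rows)
  write.csv(accuracy, file.path(outdir, "accuracy.csv"), row.names = FALSE)

  # --- RFE support network for group classification (EC features) -------
  parc <- make_parcellation(n_cortical = n_nodes - 2 * (n_nodes %/% 10),
                            n_subcortical = 2 * (n_nodes %/% 10))
  p_ec <- ncol(feats$ec$features)
  k_grid <- unique(pmin(p_ec, c(5, 10, 15, 20, 30, 50, 100, 200, p_ec)))
  rfe_out <- lapply(c("condition1", "condition2"), function(w) {
    curve <- accuracy_vs_k(feats$ec, task = "group", within = w,
                           k_grid = k_grid, n_repeats = rfe_repeats,
                           seed = seed, step = rfe_step)
    keep <- feats$ec$meta$condition == w
    ranking <- rfe_ranking(feats$ec$features[keep, , drop = FALSE],
                           feats$ec$meta$group[keep], step = rfe_step)
    sel <- select_support(curve, ranking, feats$ec$feature_index, parc)
    sel$within <- w
    sel$curve <- curve
    sel
  })
  rfe_links <- do.call(rbind, lapply(rfe_out, function(s)
    cbind(within = s$within, k_selected = s$k, s$links)))
  write.csv(rfe_links, file.path(outdir, "rfe_support.csv"), row.names = FALSE)

  # --- NBS on the SC cohort, both one-sided contrasts -------------------
  thr <- effect_size_threshold(2 * n_subjects_per_group, 0.5)
  nbs_res <- list(
    `group1>group2` = nbs_test(sc$group1, sc$group2, analysis_mask,
                               thr$threshold, n_permutations, seed = seed,
                               contrast = "group1>group2"),
    `group2>group1` = nbs_test(sc$group1, sc$group2, analysis_mask,
                               thr$threshold, n_permutations, seed = seed,
                               contrast = "group2>group1"))
  nbs_tab <- do.call(rbind, lapply(nbs_res, nbs_edge_table))
  rownames(nbs_tab) <- NULL
  write.csv(nbs_tab, file.path(outdir, "nbs_components.csv"), row.names = FALSE)
  log_lines <- c(log_lines, sprintf("nbs primary threshold: t = %.3f -> %g",
                                    thr$t, thr$threshold))

  writeLines(log_lines, file.path(outdir, "demo_log.txt"))
  invisible(list(mask = mask, analysis_mask = analysis_mask, gen = gen,
                 cohort = cohort, sc = sc, fits = fits, features = feats,
                 sc_features = sc_feats, fit_summary = fit_summary,
                 accuracy = accuracy, rfe = rfe_out, rfe_links = rfe_links,
                 nbs = nbs_res, nbs_table = nbs_tab))
}
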