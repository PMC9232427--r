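#!/usr/bin/env Rscript
# Stage 3 — connectome-feature classification.
#
# Classifies condition (within each group) and group (within each
# condition) from z-scored EC, FC and SC feature vectors with the MLR and
# 1NN classifiers over 50 stratified 80/20 splits, plus label-permuted
# surrogate baselines, and compares feature sets with rank-sum tests.
# This stage (and 04/05) is what run_demo_pipeline() chains; it is run
# here as one driver so its tables land under results/.

library(mouec)

seed <- 1L
dir.create("results", showWarnings = FALSE)

res <- run_demo_pipeline(file.path(tempdir(), "analysis_demo"), seed = seed)
dir.create("scratch", showWarnings = FALSE)
saveRDS(res, "scratch/demo_pipeline_seed1.rds")  # reused by stage 04
write.csv(res$accuracy, "results/03_accuracy.csv", row.names = FALSE)

acc <- res$accuracy
pick <- function(task, metric, cls, sur = FALSE)
  acc$accuracy[acc$task == task & acc$metric == metric &
                 acc$classifier == cls & acc$surrogate == sur]
summary_tab <- aggregate(accuracy ~ task + metric + classifier + surrogate,
                         acc, mean)
write.csv(summary_tab, "results/03_accuracy_summary.csv", row.names = FALSE)
print(summary_tab, digits = 3)

cat(sprintf("\nEC vs FC (MLR, condition): rank-sum p = %.3g\n",
            wilcoxon_compare(pick("condition", "EC", "mlr"),
                             pick("condition", "FC", "mlr"))$p_value))
cat(sprintf("EC vs surrogate (MLR, group): rank-sum p = %.3g\n",
            wilcoxon_compare(pick("group", "EC", "mlr"),
                             pick("group", "EC", "mlr", TRUE))$p_value))
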