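#!/usr/bin/env Rscript
# Stage 1 — synthetic study cohort.
#
# Generates the shared anatomical mask, the group/condition MOU parameter
# sets with planted effective-connectivity differences, the BOLD-like
# sessions (2 groups x 19 subjects x 2 conditions, 500 volumes at TR = 2 s)
# and the per-subject structural matrices with a planted 3-edge component.
# Writes a small summary of the generated design; the cohort itself is
# regenerated deterministically by later stages from the same seed, so no
# bulky intermediates are stored.

library(mouec)

seed <- 1L
dir.create("results", showWarnings = FALSE)

mask <- generate_mask(40, 0.30, seed = seed)
gen <- generate_group_ec(mask, seed = seed)
cohort <- simulate_cohort(gen, n_subjects_per_group = 19, n_samples = 500,
                          seed = seed)
sc <- generate_sc_cohort(mask, 19, seed = seed)

cat(sprintf("mask: %d nodes, %d links (density %.3f)\n",
            mask$n_nodes, sum(mask$mask) / 2, mask$density))
cat(sprintf("EC sets rescaled by %.3f for stability; planted %d group and %d condition links\n",
            gen$rescale_factor, sum(gen$registry$set == "group"),
            sum(gen$registry$set == "condition")))
cat(sprintf("cohort: %d sessions; SC cohort: %d + %d subjects, planted edges %s\n",
            length(cohort$sessions), length(sc$group1), length(sc$group2),
            paste(sprintf("%d-%d", sc$planted_edges$source,
                          sc$planted_edges$target), collapse = ", ")))

write.csv(cbind(seed = seed, gen$registry), "results/01_planted_links.csv",
          row.names = FALSE)
write_matrix(mask$mask, "results/01_mask.csv")
write.csv(cohort$meta, "results/01_cohort_sessions.csv", row.names = FALSE)
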