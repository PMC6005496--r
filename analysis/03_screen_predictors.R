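#!/usr/bin/env Rscript
# Collinearity and sample-size screening per predictor group.
#
# On the 1 km full-extent grid: samples the virtual species' presences,
# draws the first pseudo-absence set, scores every candidate by
# cross-validated single-predictor AUC, and applies the screening rules
# (pairwise Spearman < 0.8, iterative VIF < 4, at most floor(m/5) and at
# most six predictors). Writes the correlation matrix and the selection
# with per-candidate reasons under results/screening/<group>/.

library(efasdm)

seed <- 1
cfg <- landscape_config(seed = derive_seed(seed, "landscape"))
bundle <- generate_landscape(cfg)
efa <- compute_efa_stack(bundle$satellite)
stack <- derive_predictors(bundle, 1, NULL, efa)
species <- define_virtual_species(stack, c("TmDQ", "PpWM"), c(-2, 2),
                                  prevalence_target = 0.15)
recs <- sample_occurrences(species, 91, seed = derive_seed(seed, "occ"))
occ <- aggregate_occurrences(recs, stack$layers[[1]])

for (gname in c("CLI", "LC", "EFAs")) {
  gstack <- subset_stack(stack, groups = gname)
  grid <- gstack$layers[[1]]
  valid <- stack_valid_cells(gstack)
  pa <- generate_pseudo_absences(valid, occ$grid_id, grid, n_sets = 1,
                                 seed = derive_seed(seed, gname))
  cells <- c(occ$grid_id, pa[[1]]$cells)
  labels <- rep(c(1, 0), each = nrow(occ))
  feats <- stack_values(gstack, cells)
  pr <- priority_auc(feats, labels, seed = derive_seed(seed, "prio"))
  rep_ <- select_predictors(feats, m = nrow(occ), pr, max_predictors = 6)
  write_screening_report(rep_, file.path("results/screening", gname))
  cat(sprintf("%s: m = %d, cap = %d -> %s\n", gname, rep_$m,
              min(rep_$cap, 6), paste(rep_$selected, collapse = " ")))
}
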