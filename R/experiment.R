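# Stable per-combination seeds: a small deterministic string hash folded
# into the master seed, kept below 2^31.
stable_hash <- function(label) {
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible sub-seed from a master seed and a label
#' @param seed master integer seed
#' @param label character label of the component
#' @return integer seed < 2^31
#' @export
derive_seed <- function(seed, label) {
  as.integer((as.numeric(seed) * 48271 + stable_hash(label)) %% 2147483647)
}

#' Aggregate occurrence records to an analysis grid
#'
#' One presence per occupied cell (deduplication); records outside the grid
#' extent are dropped and counted.
#'
#' @param records data.frame with `x`, `y` (km).
#' @param grid target analysis raster_grid.
#' @return data.frame of presence cells (`row`, `col`, `grid_id`, `x`, `y`
#'   cell centers) with attributes `n_records` (records inside the extent)
#'   and `n_dropped` (records outside).
#' @export
aggregate_occurrences <- function(records, grid) {
  loc <- locate_cells(grid, records$x, records$y)
  dropped <- is.na(loc$row)
  loc <- loc[!dropped, , drop = FALSE]
  nr <- nrow(grid$values)
  ids <- unique(loc$row + (loc$col - 1L) * nr)
  rows <- (ids - 1L) %% nr + 1L
  cols <- (ids - 1L) %/% nr + 1L
  out <- data.frame(
    row = rows, col = cols, grid_id = ids,
    x = grid$xmin + (cols - 0.5) * grid$cellsize,
    y = grid$ymin + (nr - rows + 0.5) * grid$cellsize)
  attr(out, "n_records") <- sum(!dropped)
  attr(out, "n_dropped") <- sum(dropped)
  out
}

#' Experiment configuration for the multi-scale comparison
#'
#' Drives the full matrix of extent x grain x predictor-group combinations
#' over one synthetic landscape and one virtual species. The default matrix
#' mirrors a sub-continental / regional / local nesting at two grains: the
#' full extent at the coarse grain, its quarter window at both grains, and a
#' 1/16 window at the fine grain, with presence-record counts of 30 / 30 /
#' 91 / 62.
#'
#' @param landscape a [landscape_config()].
#' @param species_drivers predictor codes driving the virtual species.
#' @param species_coefficients logistic-scale coefficients (same order).
#' @param species_prevalence target mean true suitability.
#' @param combos data.frame with columns `label`, `extent`, `grain_km`,
#'   `n_records`.
#' @param extents named list of windows (`rows`, `cols` fine-grain ranges).
#' @param groups named list mapping predictor-set labels to group tags.
#' @param n_pa_sets,n_runs pseudo-absence sets and repeated runs per set.
#' @param learners learner names of the run design.
#' @param auc_min ensemble member filter.
#' @param seed master seed; every stage derives its own seed from it.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(landscape = landscape_config(),
                              species_drivers = c("TmDQ", "PpWM"),
                              species_coefficients = c(-2, 2),
                              species_prevalence = 0.15,
                              combos = NULL, extents = NULL,
                              groups = list(CLI = "CLI", LC = "LC",
                                            `CLI+LC` = c("CLI", "LC"),
                                            EFAs = "EFAs"),
                              n_pa_sets = 5, n_runs = 5,
                              learners = c("glm_quad", "glmnet_ridge",
                                           "rf", "sre"),
                              auc_min = 0.7, seed = 1) {
  nr <- landscape$nrow; nc <- landscape$ncol
  if (is.null(extents))
    extents <- list(
      IP = list(rows = 1:nr, cols = 1:nc),
      NW = list(rows = 1:(nr / 2), cols = 1:(nc / 2)),
      NP = list(rows = (nr / 8 + 1):(nr / 8 + nr / 4),
                cols = (nc / 8 + 1):(nc / 8 + nc / 4)))
  if (is.null(combos))
    combos <- data.frame(
      label = c("IP_5km", "NW_5km", "NW_1km", "NP_1km"),
      extent = c("IP", "NW", "NW", "NP"),
      grain_km = c(5, 5, 1, 1) * landscape$fine_cell_km,
      n_records = c(30, 30, 91, 62))
  structure(list(landscape = landscape, species_drivers = species_drivers,
                 species_coefficients = species_coefficients,
                 species_prevalence = species_prevalence,
                 combos = combos, extents = extents, groups = groups,
                 n_pa_sets = n_pa_sets, n_runs = n_runs,
                 learners = learners, auc_min = auc_min, seed = seed),
            class = "experiment_config")
}

#' Screen, fit and ensemble one predictor group
#'
#' The per-group core of the pipeline: pseudo-absence generation, priority
#' scoring, collinearity screening, the full pseudo-absence x run x learner
#' model matrix, member filtering and ensembling, and permutation
#' importance on the ensemble.
#'
#' @param stack a [predictor_stack()] restricted to the group's candidates.
#' @param presence_cells presence cell ids on the stack's grid.
#' @param n_pa_sets,n_runs,learners run design.
#' @param seed integer seed for this group.
#' @param auc_min member AUC filter (default 0.7).
#' @param rho_threshold,vif_threshold screening thresholds.
#' @param pinned predictors pinned into the selection (expert override).
#' @param max_predictors final-set size limit (default 6, the study design).
#' @return list: `screening` (screening_report), `runs` (model_runs),
#'   `ensemble` (ensemble_result or no_ensemble), `importance` (data.frame
#'   or NULL), `features`, `labels` (pooled records), `valid_cells`.
#' @export
fit_group_ensemble <- function(stack, presence_cells, n_pa_sets = 5,
                               n_runs = 5,
                               learners = c("glm_quad", "glmnet_ridge",
                                            "rf", "sre"),
                               seed = 1, auc_min = 0.7,
                               rho_threshold = 0.8, vif_threshold = 4,
                               pinned = character(0), max_predictors = 6) {
  grid <- stack$layers[[1]]
  valid <- stack_valid_cells(stack)
  pa_sets <- generate_pseudo_absences(valid, presence_cells, grid,
                                      n_sets = n_pa_sets,
                                      seed = derive_seed(seed, "pa"),
                                      min_dist = stack$grain)
  m <- length(presence_cells)
  scr_cells <- c(presence_cells, pa_sets[[1]]$cells)
  scr_labels <- rep(c(1, 0), c(m, m))
  scr_feats <- stack_values(stack, scr_cells)
  priorities <- priority_auc(scr_feats, scr_labels,
                             seed = derive_seed(seed, "priority"))
  screening <- select_predictors(scr_feats, m = m,
                                 priority_scores = priorities,
                                 rho_threshold = rho_threshold,
                                 vif_threshold = vif_threshold,
                                 pinned = pinned,
                                 max_predictors = max_predictors)
  sel <- screening$selected
  sel_stack <- subset_stack(stack, names_ = sel)
  map_feats <- stack_values(sel_stack, valid)

  runs <- list(); maps <- list()
  for (pa in seq_len(n_pa_sets)) {
    cells <- c(presence_cells, pa_sets[[pa]]$cells)
    feats <- stack_values(sel_stack, cells)
    labels <- rep(c(1, 0), c(m, m))
    for (run in seq_len(n_runs)) {
      for (L in learners) {
        s <- derive_seed(seed, sprintf("fit/%d/%d/%s", pa, run, L))
        r <- fit_and_evaluate(feats, labels, L, split_seed = s,
                              pa_set_id = pa, run_id = run)
        pm <- r$model$predict(r$fitted, map_feats)
        mv <- rep(NA_real_, length(grid$values))
        mv[valid] <- pm
        runs[[length(runs) + 1]] <- r
        maps[[length(maps) + 1]] <-
          raster_grid(matrix(mv, nrow(grid$values), ncol(grid$values)),
                      xmin = grid$xmin, ymin = grid$ymin,
                      cellsize = grid$cellsize)
      }
    }
  }
  pooled_cells <- c(presence_cells,
                    unique(unlist(lapply(pa_sets, `[[`, "cells"))))
  pooled_feats <- stack_values(sel_stack, pooled_cells)
  pooled_labels <- rep(c(1, 0), c(m, length(pooled_cells) - m))
  ensemble <- build_ensemble(runs, maps, pooled_feats, pooled_labels,
                             auc_min = auc_min)
  importance <- NULL
  if (inherits(ensemble, "ensemble_result")) {
    feats1 <- stack_values(sel_stack, scr_cells)
    importance <- variable_importance(
      function(d) ensemble_predict(ensemble, d), feats1,
      n_permutations = 5, seed = derive_seed(seed, "importance"))
  }
  list(screening = screening, runs = runs, ensemble = ensemble,
       importance = importance, features = pooled_feats,
       labels = pooled_labels, valid_cells = valid, pa_sets = pa_sets)
}

#' AUC of a suitability map against fresh virtual presences
#'
#' Samples fresh presence cells proportionally to true suitability and an
#' equal number of background cells uniformly, then scores the map values by
#' rank AUC — the with-known-truth analogue of held-out evaluation.
#'
#' @param cont continuous suitability raster_grid on the analysis grid.
#' @param truth true-suitability raster_grid on the same grid.
#' @param n_fresh presences (and background cells) to draw.
#' @param seed integer seed.
#' @return AUC.
#' @export
evaluate_on_truth <- function(cont, truth, n_fresh = 100, seed = 1) {
  if (!same_grid(cont, truth)) stop("maps are not on one grid")
  w <- as.vector(truth$values); s <- as.vector(cont$values)
  ok <- which(!is.na(w) & !is.na(s))
  n_fresh <- min(n_fresh, floor(length(ok) / 2))
  set.seed(seed)
  pres <- sample(ok, n_fresh, prob = w[ok])
  bg <- sample(setdiff(ok, pres), n_fresh)
  auc_mw(c(s[pres], s[bg]), rep(c(1, 0), c(n_fresh, n_fresh)))
}

#' Run the full multi-scale comparison experiment
#'
#' Executes, for every extent x grain combination and predictor group:
#' landscape generation, EFA/bioclim/landscape-metric derivation,
#' aggregation to the analysis grid, occurrence sampling and aggregation,
#' screening, the pseudo-absence x run x learner model matrix, ensembling,
#' importance, and pairwise map comparison of each group against the
#' EFA-based ensemble. Failures of one combination are logged and the others
#' continue.
#'
#' @param config an [experiment_config()].
#' @param outdir output directory for the CSV/JSON report (NULL = do not
#'   write).
#' @param write_maps also write ensemble maps as ESRI ASCII grids.
#' @return object of class `comparative_report`: `scores`, `importance`,
#'   `comparisons`, `runs` (data.frames), `manifest` (list), `details`
#'   (per combo/group fitted objects).
#' @export
run_experiment <- function(config, outdir = NULL, write_maps = FALSE) {
  ls_cfg <- config$landscape
  ls_cfg$seed <- derive_seed(config$seed, "landscape")
  bundle <- generate_landscape(ls_cfg)
  efa_fine <- compute_efa_stack(bundle$satellite)
  fine_stack <- derive_predictors(bundle, ls_cfg$fine_cell_km, NULL, efa_fine)
  species <- define_virtual_species(fine_stack, config$species_drivers,
                                    config$species_coefficients,
                                    prevalence_target = config$species_prevalence)

  scores <- list(); importance <- list(); comparisons <- list()
  runs_log <- list(); details <- list(); failures <- list()
  for (ci in seq_len(nrow(config$combos))) {
    cmb <- config$combos[ci, ]
    res <- tryCatch(
      run_combo(config, cmb, bundle, efa_fine, species),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[cmb$label]] <- conditionMessage(res)
      next
    }
    scores[[cmb$label]] <- res$scores
    importance[[cmb$label]] <- res$importance
    comparisons[[cmb$label]] <- res$comparisons
    runs_log[[cmb$label]] <- res$runs
    details[[cmb$label]] <- res$details
  }
  bind <- function(l) if (length(l)) do.call(rbind, unname(l)) else NULL
  report <- structure(list(
    scores = bind(scores), importance = bind(importance),
    comparisons = bind(comparisons), runs = bind(runs_log),
    manifest = list(seed = config$seed,
                    landscape_seed = ls_cfg$seed,
                    n_pa_sets = config$n_pa_sets, n_runs = config$n_runs,
                    learners = config$learners,
                    species_drivers = config$species_drivers,
                    combos = config$combos$label,
                    failures = failures),
    details = details), class = "comparative_report")
  if (!is.null(outdir)) {
    write_report(report, outdir)
    if (write_maps) {
      mdir <- file.path(outdir, "maps")
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      for (cmb in names(details)) for (g in names(details[[cmb]])) {
        ens <- details[[cmb]][[g]]$ensemble
        if (!inherits(ens, "ensemble_result")) next
        tag <- paste(cmb, gsub("[^A-Za-z]", "", g), sep = "_")
        write_ascii_grid(ens$continuous,
                         file.path(mdir, paste0(tag, "_suitability.asc")))
        write_ascii_grid(ens$binary,
                         file.path(mdir, paste0(tag, "_binary.asc")))
      }
    }
  }
  report
}

run_combo <- function(config, cmb, bundle, efa_fine, species) {
  window <- config$extents[[cmb$extent]]
  stack <- derive_predictors(bundle, cmb$grain_km, window, efa_fine)
  grid <- stack$layers[[1]]
  truth_fine <- crop_grid(species$truth_map, window$rows, window$cols)
  truth <- if (abs(cmb$grain_km - bundle$config$fine_cell_km) < 1e-9)
    truth_fine else aggregate_to_grid(truth_fine, cmb$grain_km, "mean")
  cseed <- derive_seed(config$seed, cmb$label)
  sp_c <- species
  sp_c$truth_map <- truth_fine
  recs <- sample_occurrences(sp_c, cmb$n_records,
                             seed = derive_seed(cseed, "occ"))
  occ <- aggregate_occurrences(recs, grid)

  scores <- list(); importance <- list(); runs_log <- list()
  details <- list()
  for (gname in names(config$groups)) {
    gstack <- subset_stack(stack, groups = config$groups[[gname]])
    fit <- fit_group_ensemble(gstack, occ$grid_id,
                              n_pa_sets = config$n_pa_sets,
                              n_runs = config$n_runs,
                              learners = config$learners,
                              seed = derive_seed(cseed, gname),
                              auc_min = config$auc_min)
    details[[gname]] <- fit
    ens <- fit$ensemble
    ok <- inherits(ens, "ensemble_result")
    scores[[gname]] <- data.frame(
      combo = cmb$label, group = gname,
      m = length(occ$grid_id),
      n_runs_total = length(fit$runs),
      n_members = if (ok) length(ens$members) else 0L,
      auc_median = if (ok) ens$auc_median else NA_real_,
      auc_iqr = if (ok) ens$auc_iqr else NA_real_,
      tss_median = if (ok) ens$tss_median else NA_real_,
      tss_iqr = if (ok) ens$tss_iqr else NA_real_,
      threshold = if (ok) ens$threshold else NA_real_,
      truth_auc = if (ok) evaluate_on_truth(
        ens$continuous, truth, seed = derive_seed(cseed, "fresh")) else NA_real_,
      selected = paste(fit$screening$selected, collapse = " "))
    if (ok && !is.null(fit$importance)) {
      top <- fit$importance[fit$importance$contribution > 0.1, , drop = FALSE]
      if (nrow(top))
        importance[[gname]] <- cbind(combo = cmb$label, group = gname,
                                     top[order(-top$contribution), ])
    }
    runs_log[[gname]] <- do.call(rbind, lapply(fit$runs, function(r)
      data.frame(combo = cmb$label, group = gname, pa_set = r$pa_set_id,
                 run = r$run_id, learner = r$learner, auc = r$auc,
                 tss = r$tss, threshold = r$threshold)))
  }

  comparisons <- list()
  if (inherits(details[["EFAs"]]$ensemble, "ensemble_result")) {
    efa_ens <- details[["EFAs"]]$ensemble
    for (gname in setdiff(names(config$groups), "EFAs")) {
      ens <- details[[gname]]$ensemble
      if (!inherits(ens, "ensemble_result")) next
      ov <- overlay_stats(ens$binary, efa_ens$binary)
      sp_cor <- spearman_maps(ens$continuous, efa_ens$continuous)
      comparisons[[gname]] <- data.frame(
        combo = cmb$label, pair = paste0(gname, " vs EFAs"),
        fuzzy_kappa = fuzzy_kappa(ens$binary, efa_ens$binary),
        spearman_rho = sp_cor$rho, spearman_p = sp_cor$p_value,
        morans_i_A = morans_i(ens$continuous),
        morans_i_B = morans_i(efa_ens$continuous),
        area_A_only = ov$area_A_only, area_B_only = ov$area_B_only,
        area_overlaid = ov$area_overlaid, area_total = ov$area_total_union,
        pct_A_only = ov$pct_A_only, pct_B_only = ov$pct_B_only,
        pct_overlaid = ov$pct_overlaid)
    }
  }
  list(scores = do.call(rbind, unname(scores)),
       importance = if (length(importance))
         do.call(rbind, unname(importance)) else NULL,
       comparisons = if (length(comparisons))
         do.call(rbind, unname(comparisons)) else NULL,
       runs = do.call(rbind, unname(runs_log)),
       details = details)
}

#' Write a comparative report to CSV + JSON
#' @param report a comparative_report
#' @param outdir output directory (created if needed)
#' @return invisibly, the files written
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wcsv <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  wcsv(report$scores, "scores.csv")
  wcsv(report$importance, "importance.csv")
  wcsv(report$comparisons, "comparisons.csv")
  wcsv(report$runs, "runs.csv")
  mp <- file.path(outdir, "manifest.json")
  jsonlite::write_json(report$manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(c(files, mp))
}

#' One replicate of the driver-recovery experiment
#'
#' Generates a landscape, defines a virtual species driven by two EFA
#' predictors with strong coefficients among the 24 EFA candidates, and runs
#' screening + ensemble on presence/pseudo-absence data. Reports whether
#' screening recovered both true drivers, whether they hold the top-2
#' normalized importance contributions, and the ensemble AUC against fresh
#' virtual presences.
#'
#' @param seed integer replicate seed.
#' @param drivers two EFA predictor codes.
#' @param coefficients their logistic-scale coefficients.
#' @param prevalence target mean true suitability (narrow-ranged default).
#' @param n_records presence records sampled.
#' @param nrow,ncol landscape size (fine cells).
#' @param n_pa_sets,n_runs,learners run design of the replicate.
#' @return list: `screening_hit`, `top2_hit`, `truth_auc`, `selected`,
#'   `importance`.
#' @export
driver_recovery_trial <- function(seed, drivers = c("EVIdmxc", "EVIdmnc"),
                                  coefficients = c(4, -4), prevalence = 0.1,
                                  n_records = 60, nrow = 40, ncol = 40,
                                  n_pa_sets = 3, n_runs = 2,
                                  learners = c("glm_quad", "glmnet_ridge")) {
  cfg <- landscape_config(nrow = nrow, ncol = ncol, n_years = 2,
                          seed = derive_seed(seed, "landscape"))
  bundle <- generate_landscape(cfg)
  efa <- compute_efa_stack(bundle$satellite)
  stack <- predictor_stack(efa, rep("EFAs", length(efa)))
  species <- define_virtual_species(stack, drivers, coefficients,
                                    prevalence_target = prevalence)
  recs <- sample_occurrences(species, n_records,
                             seed = derive_seed(seed, "occ"))
  occ <- aggregate_occurrences(recs, stack$layers[[1]])
  fit <- fit_group_ensemble(stack, occ$grid_id, n_pa_sets = n_pa_sets,
                            n_runs = n_runs, learners = learners,
                            seed = derive_seed(seed, "fit"))
  selected <- fit$screening$selected
  screening_hit <- all(drivers %in% selected)
  top2_hit <- FALSE; truth_auc <- NA_real_
  if (inherits(fit$ensemble, "ensemble_result")) {
    imp <- fit$importance[order(-fit$importance$contribution), ]
    top2_hit <- all(drivers %in% imp$predictor[seq_len(min(2, nrow(imp)))])
    truth_auc <- evaluate_on_truth(fit$ensemble$continuous,
                                   species$truth_map,
                                   seed = derive_seed(seed, "fresh"))
  }
  list(screening_hit = screening_hit, top2_hit = top2_hit,
       truth_auc = truth_auc, selected = selected,
       importance = fit$importance)
}

#' One replicate of the EFA vs climate+land-cover comparison
#'
#' On a landscape whose satellite dynamics are climate-driven (the default
#' generator coupling) and a virtual species driven by climate, fits the
#' EFA-group and the combined climate+land-cover-group ensembles on the same
#' presence data and returns both member-median AUCs and both
#' fresh-presence AUCs.
#'
#' @param seed integer replicate seed.
#' @param n_records presence records.
#' @param nrow,ncol landscape size.
#' @param n_pa_sets,n_runs,learners run design.
#' @return list: `auc_efa`, `auc_clilc` (member medians), `truth_auc_efa`,
#'   `truth_auc_clilc`.
#' @export
h1_trial <- function(seed, n_records = 60, nrow = 40, ncol = 40,
                     n_pa_sets = 3, n_runs = 2,
                     learners = c("glm_quad", "glmnet_ridge")) {
  cfg <- landscape_config(nrow = nrow, ncol = ncol, n_years = 2,
                          seed = derive_seed(seed, "landscape"))
  bundle <- generate_landscape(cfg)
  efa <- compute_efa_stack(bundle$satellite)
  stack <- derive_predictors(bundle, cfg$fine_cell_km, NULL, efa)
  species <- define_virtual_species(stack, c("TmDQ", "PpWM"), c(-2, 2),
                                    prevalence_target = 0.2)
  recs <- sample_occurrences(species, n_records,
                             seed = derive_seed(seed, "occ"))
  occ <- aggregate_occurrences(recs, stack$layers[[1]])
  one <- function(groups, tag) {
    fit_group_ensemble(subset_stack(stack, groups = groups), occ$grid_id,
                       n_pa_sets = n_pa_sets, n_runs = n_runs,
                       learners = learners,
                       seed = derive_seed(seed, tag))
  }
  f_efa <- one("EFAs", "EFAs")
  f_cl <- one(c("CLI", "LC"), "CLI+LC")
  g <- function(f, what) if (inherits(f$ensemble, "ensemble_result"))
    f$ensemble[[what]] else NA_real_
  ta <- function(f) if (inherits(f$ensemble, "ensemble_result"))
    evaluate_on_truth(f$ensemble$continuous, species$truth_map,
                      seed = derive_seed(seed, "fresh")) else NA_real_
  list(auc_efa = g(f_efa, "auc_median"), auc_clilc = g(f_cl, "auc_median"),
       truth_auc_efa = ta(f_efa), truth_auc_clilc = ta(f_cl))
}
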