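#' Rank-based AUC (Mann-Whitney formulation)
#'
#' `AUC = U / (n1 * n0)` with U from the rank sum of the positive scores;
#' ties contribute 1/2.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC upper-left-corner threshold
#'
#' Returns the probability threshold minimizing the straight-line distance
#' between the ROC curve and the (0, 1) corner of the unit square,
#' `sqrt((1 - sens)^2 + (1 - spec)^2)`, searched over the midpoints of
#' consecutive sorted unique scores; ties take the lower threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector (both classes required).
#' @return the threshold tau.
#' @export
threshold_roc_corner <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes required")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("all scores equal: no discriminating threshold")
  cand <- (u[-1] + u[-length(u)]) / 2
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  d <- vapply(cand, function(tau) {
    pos <- scores >= tau
    sens <- sum(pos & labels == 1) / n1
    spec <- sum(!pos & labels == 0) / n0
    sqrt((1 - sens)^2 + (1 - spec)^2)
  }, numeric(1))
  cand[which.min(d)]  # which.min: earliest (lowest threshold) on tie
}

#' True Skill Statistic at a threshold
#' @param scores,labels as in [auc_mw()]
#' @param tau probability threshold
#' @return sensitivity + specificity - 1
#' @export
tss_at <- function(scores, labels, tau) {
  labels <- as.integer(labels)
  pos <- scores >= tau
  sens <- sum(pos & labels == 1) / sum(labels == 1)
  spec <- sum(!pos & labels == 0) / sum(labels == 0)
  sens + spec - 1
}

#' Seeded pseudo-absence sets
#'
#' Draws `n_sets` independent sets of background cells treated as absences,
#' each with exactly as many cells as there are presences, never overlapping
#' the presence cells, and with all pairwise cell-center distances at least
#' `min_dist` (default: one grain). Rejection sampling over a bounded number
#' of rounds; an explicit error names the binding constraint if the grid
#' cannot satisfy it.
#'
#' @param valid_cells integer cell ids available as background.
#' @param presence_cells integer presence cell ids.
#' @param grid the analysis raster_grid (for cell geometry).
#' @param n_sets number of sets (default 30).
#' @param seed integer seed.
#' @param min_dist minimum pairwise center distance in km (default the
#'   grain).
#' @param max_rounds rejection rounds before giving up.
#' @return list of `pseudo_absence_set` objects: `set_id`, `cells`, `seed`.
#' @export
generate_pseudo_absences <- function(valid_cells, presence_cells, grid,
                                     n_sets = 30, seed = 1,
                                     min_dist = grid$cellsize,
                                     max_rounds = 50) {
  pool <- setdiff(valid_cells, presence_cells)
  n <- length(presence_cells)
  if (length(pool) < n)
    stop("only ", length(pool), " unoccupied cells for ", n, " pseudo-absences")
  nr <- nrow(grid$values)
  cx <- ((pool - 1L) %/% nr + 0.5) * grid$cellsize
  cy <- (nr - (pool - 1L) %% nr - 0.5) * grid$cellsize
  set.seed(seed)
  lapply(seq_len(n_sets), function(s) {
    for (round in seq_len(max_rounds)) {
      ord <- sample.int(length(pool))
      sel <- integer(0)
      for (i in ord) {
        if (length(sel) &&
            min(sqrt((cx[i] - cx[sel])^2 + (cy[i] - cy[sel])^2)) < min_dist - 1e-9)
          next
        sel <- c(sel, i)
        if (length(sel) == n) break
      }
      if (length(sel) == n)
        return(structure(list(set_id = s, cells = pool[sel], seed = seed),
                         class = "pseudo_absence_set"))
    }
    stop("cannot place ", n, " pseudo-absences with pairwise distance >= ",
         min_dist, " km on this grid (minimum-distance constraint binding)")
  })
}

# ---- learner registry -----------------------------------------------------

learner_env <- new.env(parent = emptyenv())

#' Register or fetch learners
#'
#' The registry holds presence/pseudo-absence learners, each a list with
#' `fit(x, y)` returning a model object and `predict(model, x)` returning
#' probabilities in `[0, 1]` (`x` a numeric data.frame, `y` a 0/1 vector).
#' Ten families are pre-registered, echoing the usual ensemble-SDM toolbox:
#' `glm_quad` (logistic regression with quadratic terms), `glmnet_ridge`
#' (ridge-penalized logistic), `gam_spline` (additive logistic with spline
#' smooths), `tree` (recursive partitioning), `rf` (random forest), `gbm`
#' (gradient-boosted trees), `nnet` (single-hidden-layer network),
#' `fda_quad` (linear discriminant on a quadratic basis), `mars_hinge`
#' (adaptive hinge-basis logistic) and `sre` (rectilinear surface range
#' envelope: presence iff every predictor lies within its central 95%
#' presence quantile range).
#'
#' @param name learner name.
#' @param learner for `register_learner`, a list with `fit` and `predict`.
#' @return `get_learner` returns the learner; `list_learners` the registered
#'   names.
#' @export
register_learner <- function(name, learner) {
  stopifnot(is.function(learner$fit), is.function(learner$predict))
  assign(name, learner, envir = learner_env)
  invisible(name)
}

#' @rdname register_learner
#' @export
get_learner <- function(name) {
  if (!exists(name, envir = learner_env)) stop("unknown learner: ", name)
  get(name, envir = learner_env)
}

#' @rdname register_learner
#' @export
list_learners <- function() sort(ls(learner_env))

clamp01 <- function(p) pmin(pmax(as.numeric(p), 0), 1)

quad_formula <- function(nms) {
  stats::as.formula(paste("y ~",
    paste(c(nms, sprintf("I(%s^2)", nms)), collapse = " + ")))
}

hinge_basis <- function(x, knots) {
  out <- list()
  for (nm in names(knots)) {
    for (k in knots[[nm]]) {
      out[[sprintf("%s_h%g", nm, k)]] <- pmax(0, x[[nm]] - k)
      out[[sprintf("%s_g%g", nm, k)]] <- pmax(0, k - x[[nm]])
    }
  }
  cbind(as.matrix(x), do.call(cbind, out))
}

register_default_learners <- function() {
  register_learner("glm_quad", list(
    fit = function(x, y) {
      d <- cbind(y = y, x)
      suppressWarnings(stats::glm(quad_formula(names(x)), data = d,
                                  family = stats::binomial()))
    },
    predict = function(m, x) {
      clamp01(suppressWarnings(
        stats::predict(m, newdata = x, type = "response")))
    }))

  register_learner("glmnet_ridge", list(
    fit = function(x, y)
      suppressWarnings(
        glmnet::glmnet(as.matrix(x), y, family = "binomial", alpha = 0,
                       lambda = c(1, 0.1, 0.02))),
    predict = function(m, x)
      clamp01(stats::predict(m, as.matrix(x), s = 0.02, type = "response"))))

  register_learner("gam_spline", list(
    fit = function(x, y) {
      k <- max(3, min(5, floor(length(y) / (2 * length(x)))))
      terms <- vapply(names(x), function(nm) {
        if (length(unique(x[[nm]])) > k) sprintf("s(%s, k = %d)", nm, k)
        else nm
      }, character(1))
      d <- cbind(y = y, x)
      mgcv::gam(stats::as.formula(paste("y ~", paste(terms, collapse = "+"))),
                data = d, family = stats::binomial(), method = "REML")
    },
    predict = function(m, x)
      clamp01(stats::predict(m, newdata = x, type = "response"))))

  register_learner("tree", list(
    fit = function(x, y)
      rpart::rpart(y ~ ., data = cbind(y = factor(y), x), method = "class",
                   control = rpart::rpart.control(minsplit = 5, cp = 0.01)),
    predict = function(m, x) clamp01(stats::predict(m, x)[, "1"])))

  register_learner("rf", list(
    fit = function(x, y)
      randomForest::randomForest(x, factor(y), ntree = 200),
    predict = function(m, x) clamp01(stats::predict(m, x, type = "prob")[, "1"])))

  register_learner("gbm", list(
    fit = function(x, y)
      xgboost::xgboost(as.matrix(x), factor(y), nrounds = 40,
                       max_depth = 2, learning_rate = 0.3, nthreads = 1,
                       verbosity = 0),
    predict = function(m, x) {
      p <- stats::predict(m, as.matrix(x), type = "response")
      if (is.matrix(p)) p <- p[, ncol(p)]
      clamp01(p)
    }))

  register_learner("nnet", list(
    fit = function(x, y)
      nnet::nnet(as.matrix(x), y, size = 3, decay = 0.05, maxit = 200,
                 trace = FALSE, entropy = TRUE),
    predict = function(m, x) clamp01(stats::predict(m, as.matrix(x)))))

  register_learner("fda_quad", list(
    fit = function(x, y) {
      b <- cbind(as.matrix(x), as.matrix(x)^2)
      list(lda = MASS::lda(b, grouping = factor(y)))
    },
    predict = function(m, x) {
      b <- cbind(as.matrix(x), as.matrix(x)^2)
      clamp01(stats::predict(m$lda, b)$posterior[, "1"])
    }))

  register_learner("mars_hinge", list(
    fit = function(x, y) {
      knots <- lapply(x, function(v)
        unique(stats::quantile(v, c(0.25, 0.5, 0.75))))
      b <- hinge_basis(x, knots)
      list(knots = knots,
           net = suppressWarnings(
             glmnet::glmnet(b, y, family = "binomial", alpha = 1,
                            lambda = c(0.2, 0.05, 0.01))))
    },
    predict = function(m, x)
      clamp01(stats::predict(m$net, hinge_basis(x, m$knots), s = 0.01,
                             type = "response"))))

  register_learner("sre", list(
    fit = function(x, y)
      lapply(x[y == 1, , drop = FALSE],
             stats::quantile, probs = c(0.025, 0.975)),
    predict = function(m, x) {
      inside <- rep(TRUE, nrow(x))
      for (nm in names(m))
        inside <- inside & x[[nm]] >= m[[nm]][1] & x[[nm]] <= m[[nm]][2]
      as.numeric(inside)
    }))
}

# ---- fitting and ensembling ----------------------------------------------

#' Fit one learner and evaluate it on a held-out split
#'
#' Splits the records into 80% calibration / 20% evaluation (resampling the
#' split, bounded retries, if a half misses a class), fits the learner on the
#' calibration half and scores the held-out half: rank-formulation AUC, the
#' ROC-corner threshold tau on the held-out scores, and TSS at tau. When the
#' held-out scores admit no discriminating threshold (all equal), tau falls
#' back to 0.5 with TSS evaluated there.
#'
#' @param features numeric data.frame of records x predictors.
#' @param labels 0/1 vector (1 = presence).
#' @param learner learner name (see [register_learner()]) or learner object.
#' @param split_seed seed for the split and any stochastic fitting.
#' @param eval_fraction held-out fraction (default 0.2).
#' @param pa_set_id,run_id bookkeeping ids stored on the result.
#' @return object of class `model_run`: learner, ids, `auc`, `tss`,
#'   `threshold`, `model`, `calib_idx`, `eval_idx`.
#' @export
fit_and_evaluate <- function(features, labels, learner, split_seed = 1,
                             eval_fraction = 0.2, pa_set_id = NA,
                             run_id = NA) {
  lname <- if (is.character(learner)) learner else "custom"
  L <- if (is.character(learner)) get_learner(learner) else learner
  n <- length(labels)
  set.seed(split_seed)
  for (try_ in 1:20) {
    ev <- sample.int(n, max(2, round(eval_fraction * n)))
    if (length(unique(labels[ev])) == 2 &&
        length(unique(labels[-ev])) == 2) break
    if (try_ == 20) stop("cannot find a split with both classes in both halves")
  }
  model <- L$fit(features[-ev, , drop = FALSE], labels[-ev])
  p <- L$predict(model, features[ev, , drop = FALSE])
  auc <- auc_mw(p, labels[ev])
  tau <- tryCatch(threshold_roc_corner(p, labels[ev]),
                  error = function(e) 0.5)
  structure(list(learner = lname, pa_set_id = pa_set_id, run_id = run_id,
                 auc = auc, tss = tss_at(p, labels[ev], tau),
                 threshold = tau, model = L, fitted = model,
                 calib_idx = setdiff(seq_len(n), ev), eval_idx = ev),
            class = "model_run")
}

#' Build an ensemble from member model runs
#'
#' Keeps the runs with held-out AUC at or above `auc_min` (default 0.7),
#' takes the cellwise median of the member probability maps as the
#' continuous ensemble map, summarizes member scores as median and
#' interquartile range, derives the ensemble threshold from the ROC corner
#' of the pooled-calibration ensemble scores, and binarizes the map at that
#' threshold.
#'
#' @param runs list of [fit_and_evaluate()] results.
#' @param member_maps list of raster_grids (one probability map per run).
#' @param features,labels the full record table the runs were fitted on
#'   (used for the ensemble threshold).
#' @param auc_min member filter (default 0.7).
#' @param statistic "median" (default) or "mean" cellwise summary.
#' @return object of class `ensemble_result`, or of class `no_ensemble` when
#'   no run passes the filter.
#' @export
build_ensemble <- function(runs, member_maps, features, labels,
                           auc_min = 0.7, statistic = c("median", "mean")) {
  statistic <- match.arg(statistic)
  keep <- vapply(runs, function(r) r$auc >= auc_min, logical(1))
  if (!any(keep))
    return(structure(list(reason = sprintf(
      "no member reached AUC >= %g (best %.3f)", auc_min,
      max(vapply(runs, `[[`, numeric(1), "auc")))), class = "no_ensemble"))
  runs <- runs[keep]; member_maps <- member_maps[keep]
  g0 <- member_maps[[1]]
  arr <- vapply(member_maps, function(g) as.vector(g$values),
                numeric(length(g0$values)))
  summ <- if (statistic == "median") {
    apply(arr, 1, stats::median)
  } else rowMeans(arr)
  cont <- raster_grid(matrix(summ, nrow(g0$values), ncol(g0$values)),
                      xmin = g0$xmin, ymin = g0$ymin, cellsize = g0$cellsize)
  aucs <- vapply(runs, `[[`, numeric(1), "auc")
  tsss <- vapply(runs, `[[`, numeric(1), "tss")
  memb_pred <- vapply(runs, function(r)
    r$model$predict(r$fitted, features), numeric(nrow(features)))
  ens_scores <- apply(memb_pred, 1, stats::median)
  tau <- tryCatch(threshold_roc_corner(ens_scores, labels),
                  error = function(e) 0.5)
  binary <- raster_grid((cont$values >= tau) * 1, xmin = g0$xmin,
                        ymin = g0$ymin, cellsize = g0$cellsize)
  binary$values[is.na(cont$values)] <- NA
  structure(list(
    members = runs,
    auc_median = stats::median(aucs), auc_iqr = stats::IQR(aucs),
    tss_median = stats::median(tsss), tss_iqr = stats::IQR(tsss),
    continuous = cont, threshold = tau, binary = binary,
    statistic = statistic
  ), class = "ensemble_result")
}

#' Predict ensemble suitability for new records
#' @param ensemble an ensemble_result
#' @param newdata numeric data.frame of records x predictors
#' @return numeric vector of ensemble probabilities (member median)
#' @export
ensemble_predict <- function(ensemble, newdata) {
  p <- vapply(ensemble$members, function(r)
    r$model$predict(r$fitted, newdata), numeric(nrow(newdata)))
  apply(p, 1, stats::median)
}

#' Permutation variable importance
#'
#' For each predictor: the mean over permutations of
#' `1 - |cor(reference_predictions, shuffled_predictions)|`, where the
#' shuffled predictions come from re-predicting with the focal column
#' permuted — 0 means no importance, 1 high importance. Contributions are
#' the importances normalized to sum to 1. A constant prediction vector
#' yields importance 0 with a warning.
#'
#' @param predict_fun function(data.frame) -> numeric predictions (e.g. a
#'   closure over [ensemble_predict()]).
#' @param features the calibration records.
#' @param n_permutations permutations per predictor (default 5).
#' @param seed integer seed.
#' @return data.frame: predictor, importance, contribution.
#' @export
variable_importance <- function(predict_fun, features, n_permutations = 5,
                                seed = 1) {
  set.seed(seed)
  ref <- predict_fun(features)
  imp <- vapply(names(features), function(nm) {
    if (stats::sd(ref) == 0) {
      warning("constant prediction vector: importance of ", nm, " set to 0")
      return(0)
    }
    mean(vapply(seq_len(n_permutations), function(p) {
      shuf <- features
      shuf[[nm]] <- sample(shuf[[nm]])
      pred <- predict_fun(shuf)
      if (stats::sd(pred) == 0) return(1)
      1 - abs(stats::cor(ref, pred))
    }, numeric(1)))
  }, numeric(1))
  contribution <- if (sum(imp) > 0) imp / sum(imp) else imp
  data.frame(predictor = names(features), importance = unname(imp),
             contribution = unname(contribution))
}

#' Ensemble response curve of one predictor
#'
#' Sweeps the focal predictor over its observed range at `n_points` while
#' holding every other predictor at its median, and records the ensemble
#' suitability.
#'
#' @param ensemble an ensemble_result.
#' @param predictor focal predictor name.
#' @param features calibration records (defines ranges and medians).
#' @param n_points sweep resolution (default 50).
#' @return data.frame with columns `value` and `suitability`.
#' @export
response_curve <- function(ensemble, predictor, features, n_points = 50) {
  if (!predictor %in% names(features)) stop("unknown predictor: ", predictor)
  sweep_v <- seq(min(features[[predictor]]), max(features[[predictor]]),
                 length.out = n_points)
  base <- as.data.frame(lapply(features, function(v)
    rep(stats::median(v), n_points)))
  base[[predictor]] <- sweep_v
  data.frame(value = sweep_v, suitability = ensemble_predict(ensemble, base))
}
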