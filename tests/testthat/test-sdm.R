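test_that("pseudo-absence sets satisfy count, overlap and spacing constraints", {
  g <- rg(matrix(0, 20, 20), cellsize = 2)
  valid <- 1:400
  pres <- c(5, 50, 123, 200, 307, 399, 21, 88, 150, 266)
  sets <- generate_pseudo_absences(valid, pres, g, n_sets = 5, seed = 3,
                                   min_dist = 4)
  expect_length(sets, 5)
  for (s in sets) {
    expect_length(s$cells, 10)
    expect_length(intersect(s$cells, pres), 0)
    cc <- cell_centers(g)
    xy <- cc[match(s$cells, cc$row + (cc$col - 1) * 20), ]
    d <- as.matrix(dist(cbind(xy$x, xy$y)))
    diag(d) <- Inf
    expect_gte(min(d), 4)  # all-pairs oracle
  }
  # determinism
  sets2 <- generate_pseudo_absences(valid, pres, g, n_sets = 5, seed = 3,
                                    min_dist = 4)
  expect_identical(lapply(sets, `[[`, "cells"), lapply(sets2, `[[`, "cells"))
})

test_that("infeasible spacing fails with an explicit constraint message", {
  g <- rg(matrix(0, 4, 4))
  expect_error(generate_pseudo_absences(1:16, 1:2, g, n_sets = 1, seed = 1,
                                        min_dist = 10, max_rounds = 3),
               "minimum-distance")
  expect_error(generate_pseudo_absences(1:5, 1:4, g, n_sets = 1, seed = 1),
               "unoccupied")
})

test_that("rank AUC matches the all-pairs count on random score sets", {
  expect_equal(auc_mw(c(1, 2, 3, 10, 11, 12), c(0, 0, 0, 1, 1, 1)), 1)
  for (i in 1:100) {
    set.seed(i)
    labels <- c(rep(1, 8), rep(0, 12))
    scores <- round(runif(20), 2)  # rounding forces ties
    expect_equal(auc_mw(scores, labels), oracle_auc(scores, labels))
  }
})

test_that("AUC of random scores sits inside the permutation null band", {
  set.seed(41)
  labels <- rep(c(1, 0), 100)
  scores <- rnorm(200)
  null_q <- quantile(vapply(1:500, function(i)
    auc_mw(scores, sample(labels)), numeric(1)), c(0.005, 0.995))
  expect_gt(auc_mw(scores, labels), null_q[1])
  expect_lt(auc_mw(scores, labels), null_q[2])
})

test_that("ROC-corner threshold matches exhaustive search and its tie rule", {
  expect_equal(threshold_roc_corner(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 0.5)
  for (i in 1:100) {
    set.seed(i + 1000)
    labels <- rbinom(15, 1, 0.5)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(15), 2)
    if (length(unique(scores)) < 2) next
    expect_equal(threshold_roc_corner(scores, labels),
                 oracle_roc_corner(scores, labels))
  }
  expect_error(threshold_roc_corner(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)),
               "all scores equal")
  expect_error(threshold_roc_corner(runif(5), rep(1, 5)), "both classes")
})

test_that("a separable predictor earns a perfect run", {
  set.seed(42)
  x <- data.frame(p = c(rnorm(30, -4), rnorm(30, 4)))
  y <- rep(c(0, 1), each = 30)
  run <- fit_and_evaluate(x, y, "glm_quad", split_seed = 7)
  expect_equal(run$auc, 1)
  expect_equal(run$tss, 1)
  expect_true(run$threshold > 0 && run$threshold < 1)
})

test_that("every registered learner yields valid probabilities", {
  set.seed(43)
  x <- data.frame(a = c(rnorm(40, -1), rnorm(40, 1)), b = rnorm(80))
  y <- rep(c(0, 1), each = 40)
  for (L in list_learners()) {
    run <- fit_and_evaluate(x, y, L, split_seed = 11)
    expect_true(run$auc >= 0 && run$auc <= 1, info = L)
    p <- run$model$predict(run$fitted, x)
    expect_true(all(p >= 0 & p <= 1), info = L)
  }
})

fake_run <- function(auc, tss = 0.5) {
  structure(list(learner = "fake", pa_set_id = 1, run_id = 1, auc = auc,
                 tss = tss, threshold = 0.5,
                 model = list(predict = function(m, x) rep(0.6, nrow(x))),
                 fitted = NULL), class = "model_run")
}

test_that("the ensemble is the cellwise median of passing members", {
  maps <- lapply(c(0.2, 0.5, 0.9), function(v) rg(matrix(v, 3, 3)))
  runs <- lapply(c(0.8, 0.9, 0.75), fake_run)
  feats <- data.frame(a = rnorm(20))
  labels <- rep(c(1, 0), 10)
  ens <- build_ensemble(runs, maps, feats, labels)
  expect_equal(ens$continuous$values, matrix(0.5, 3, 3))

  one <- build_ensemble(runs[1], maps[1], feats, labels)
  expect_equal(one$continuous$values, maps[[1]]$values)

  # 12 synthetic members vs a cellwise sorting oracle
  set.seed(44)
  mm <- lapply(1:12, function(i) rg(matrix(runif(25), 5, 5)))
  rr <- lapply(round(runif(12, 0.7, 1), 3), fake_run)
  e12 <- build_ensemble(rr, mm, feats, labels)
  arr <- sapply(mm, function(g) as.vector(g$values))
  oracle <- apply(arr, 1, function(v) sort(v)[6:7] |> mean())
  expect_equal(as.vector(e12$continuous$values), oracle)
  expect_equal(e12$auc_median, median(sapply(rr, `[[`, "auc")))
})

test_that("members below the AUC filter are excluded or the ensemble refused", {
  maps <- lapply(c(0.3, 0.8), function(v) rg(matrix(v, 2, 2)))
  runs <- lapply(c(0.65, 0.72), fake_run)
  feats <- data.frame(a = rnorm(10)); labels <- rep(c(1, 0), 5)
  ens <- build_ensemble(runs, maps, feats, labels)
  expect_length(ens$members, 1)
  none <- build_ensemble(lapply(c(0.5, 0.6), fake_run), maps, feats, labels)
  expect_s3_class(none, "no_ensemble")
  expect_match(none$reason, "no member")
})

test_that("permutation importance separates used from unused predictors", {
  set.seed(45)
  f <- data.frame(used = rnorm(1000), unused = rnorm(1000))
  pf <- function(d) plogis(2 * d$used)  # identity-style single-driver model
  imp <- variable_importance(pf, f, n_permutations = 5, seed = 2)
  expect_equal(imp$importance[imp$predictor == "unused"], 0)
  expect_gt(imp$importance[imp$predictor == "used"], 0.9)
  expect_equal(sum(imp$contribution), 1)
  expect_true(all(imp$importance >= 0 & imp$importance <= 1))
})

test_that("constant predictions warn and give zero importance", {
  f <- data.frame(a = rnorm(50))
  expect_warning(imp <- variable_importance(function(d) rep(0.5, nrow(d)), f),
                 "constant prediction")
  expect_equal(imp$importance, 0)
})

test_that("response curves reflect the fitted relationship", {
  set.seed(46)
  x <- data.frame(p = rnorm(200), q = rnorm(200))
  y <- rbinom(200, 1, plogis(2 * x$p))
  runs <- list(fit_and_evaluate(x, y, "glm_quad", split_seed = 3))
  maps <- list(rg(matrix(0.5, 2, 2)))
  ens <- build_ensemble(runs, maps, x, y, auc_min = 0.5)
  rc <- response_curve(ens, "p", x, n_points = 30)
  expect_true(all(rc$suitability >= 0 & rc$suitability <= 1))
  # positive generative coefficient: overall increasing
  expect_gt(cor(rc$value, rc$suitability), 0.9)
  expect_gt(rc$suitability[30], rc$suitability[1])
  expect_error(response_curve(ens, "zzz", x), "unknown predictor")
})
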