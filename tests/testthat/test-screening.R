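test_that("spearman matrix honours monotone invariance and flags constants", {
  x <- rnorm(30)
  f <- data.frame(x = x, y = 2 * x + 1, z = -x)
  rho <- spearman_matrix(f)
  expect_equal(rho["x", "y"], 1)
  expect_equal(rho["x", "z"], -1)
  expect_equal(diag(rho), c(x = 1, y = 1, z = 1))
  expect_error(spearman_matrix(data.frame(a = 1:5, b = rep(2, 5))),
               "constant column")
  expect_error(spearman_matrix(f[1:2, ]), "at least 3 rows")
})

test_that("spearman matrix equals the rank-then-Pearson oracle", {
  set.seed(21)
  f <- as.data.frame(matrix(rnorm(40 * 10), 40, 10))
  got <- spearman_matrix(f)
  oracle <- cor(apply(f, 2, rank))
  expect_equal(unname(got), unname(oracle))
})

test_that("VIFs behave at the independence and collinearity extremes", {
  set.seed(22)
  f <- as.data.frame(matrix(rnorm(500 * 4), 500, 4))
  expect_true(all(vif_values(f) < 1.1))  # independent columns: VIF ~ 1

  f$V5 <- f$V1 + f$V2  # exact collinearity
  v <- vif_values(f)
  expect_true(all(is.infinite(v[c("V1", "V2", "V5")])))
  flt <- vif_filter(f, threshold = 4)
  expect_length(flt$dropped, 1)
  expect_true(all(vif_values(f[, flt$kept]) < 4))
})

test_that("VIF equals 1/(1 - R2) from an independent least-squares fit", {
  set.seed(23)
  base <- matrix(rnorm(50 * 2), 50, 2)
  f <- data.frame(a = base[, 1], b = base[, 2],
                  c = base[, 1] + rnorm(50, 0, 0.5),
                  d = base[, 2] - base[, 1] + rnorm(50, 0, 0.8),
                  e = rnorm(50))
  v <- vif_values(f)
  fs <- as.data.frame(scale(f))
  for (nm in names(f)) {
    r2 <- summary(lm(reformulate(setdiff(names(f), nm), nm), data = fs))$r.squared
    expect_equal(unname(v[nm]), 1 / (1 - r2), tolerance = 1e-8)
  }
})

test_that("the record cap follows floor(m/5), with 30 records allowing six", {
  set.seed(24)
  f <- as.data.frame(matrix(rnorm(60 * 10), 60, 10))
  pr <- setNames(seq(1, 0.1, length.out = 10), names(f))
  rep30 <- select_predictors(f, m = 30, pr)
  expect_equal(rep30$cap, 6)
  expect_lte(length(rep30$selected), 6)
  expect_equal(select_predictors(f, m = 34, pr)$cap, 6)
  expect_equal(select_predictors(f, m = 10, pr)$cap, 2)
  expect_error(select_predictors(f, m = 4, pr), "at least 5 records")
})

test_that("correlated duplicates keep only the higher-priority candidate", {
  set.seed(25)
  x <- rnorm(40)
  f <- data.frame(best = x, dup = x * 3 + 2, other = rnorm(40))
  pr <- c(best = 0.9, dup = 0.8, other = 0.5)
  rep_ <- select_predictors(f, m = 30, pr)
  expect_true("best" %in% rep_$selected)
  expect_false("dup" %in% rep_$selected)
  expect_match(rep_$reasons[["dup"]], "rho")
})

test_that("selection is invariant to candidate order and obeys its invariants", {
  set.seed(26)
  f <- as.data.frame(matrix(rnorm(80 * 8), 80, 8))
  f$V2 <- f$V1 * 2 + rnorm(80, 0, 0.1)   # a near-duplicate pair
  pr <- setNames(runif(8, 0.5, 1), names(f))
  sel1 <- select_predictors(f, m = 40, pr)$selected
  perm <- sample(names(f))
  sel2 <- select_predictors(f[, perm], m = 40, pr[perm])$selected
  expect_setequal(sel1, sel2)

  rep_ <- select_predictors(f, m = 40, pr)
  rho <- rep_$spearman_matrix[rep_$selected, rep_$selected, drop = FALSE]
  diag(rho) <- 0
  expect_true(all(abs(rho) < 0.8))
  expect_true(all(rep_$vif < 4))
  expect_lte(length(rep_$selected), rep_$cap)
})

test_that("pinned predictors are selected first", {
  set.seed(27)
  f <- as.data.frame(matrix(rnorm(50 * 5), 50, 5))
  pr <- setNames(c(0.9, 0.8, 0.7, 0.6, 0.5), names(f))
  rep_ <- select_predictors(f, m = 30, pr, pinned = "V5")
  expect_equal(rep_$selected[1], "V5")
})
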