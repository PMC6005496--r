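test_that("fuzzy kappa is 1 for identical maps and symmetric in its arguments", {
  set.seed(51)
  m <- matrix(rbinom(144, 1, 0.4), 12, 12)
  a <- rg(m)
  expect_equal(fuzzy_kappa(a, a), 1)
  b <- rg(matrix(rbinom(144, 1, 0.4), 12, 12))
  expect_equal(fuzzy_kappa(a, b), fuzzy_kappa(b, a))
  expect_lte(fuzzy_kappa(a, b), 1)
})

test_that("radius zero reduces fuzzy kappa to Cohen's kappa", {
  for (i in 1:100) {
    set.seed(i)
    a <- matrix(rbinom(64, 1, runif(1, 0.3, 0.7)), 8, 8)
    b <- matrix(rbinom(64, 1, runif(1, 0.3, 0.7)), 8, 8)
    if (length(unique(as.vector(a))) < 2 || length(unique(as.vector(b))) < 2)
      next
    expect_equal(fuzzy_kappa(rg(a), rg(b), radius = 0),
                 oracle_cohen_kappa(as.vector(a), as.vector(b)),
                 tolerance = 1e-10, info = paste("seed", i))
  }
})

test_that("distance tolerance rewards near-miss agreement", {
  cb <- outer(1:10, 1:10, function(r, c) (r + c) %% 2)
  shifted <- cbind(cb[, -1], cb[, 1])
  k0 <- fuzzy_kappa(rg(cb), rg(shifted), radius = 0)
  k4 <- fuzzy_kappa(rg(cb), rg(shifted), halving_distance = 2, radius = 4)
  expect_gt(k4, k0)
})

test_that("fuzzy kappa decreases as independent label noise is added", {
  set.seed(52)
  base <- matrix(rbinom(225, 1, 0.5), 15, 15)
  noise_levels <- seq(0.05, 1, length.out = 20)
  mean_kappa <- vapply(noise_levels, function(nl) {
    mean(vapply(1:10, function(s) {
      set.seed(1000 + s)
      flip <- matrix(rbinom(225, 1, nl), 15, 15)
      noisy <- (base + flip) %% 2
      fuzzy_kappa(rg(base), rg(noisy))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(cor(noise_levels, mean_kappa, method = "spearman"), -0.9)
})

test_that("fuzzy kappa validates its inputs", {
  a <- rg(matrix(0:1, 4, 4))
  expect_error(fuzzy_kappa(a, rg(matrix(0, 5, 5))), "one grid")
  expect_error(fuzzy_kappa(rg(matrix(1, 4, 4), categories = c("x", "y")),
                           rg(matrix(1, 4, 4), categories = c("p", "q"))),
               "category sets differ")
})

test_that("Moran's I detects gradients, checkerboards and randomness", {
  grad <- rg(outer(1:12, 1:12, `+`) + matrix(rnorm(144, 0, 0.1), 12, 12))
  expect_gt(morans_i(grad), 0)

  cb <- outer(1:8, 1:8, function(r, c) (r + c) %% 2)
  expect_lt(morans_i(rg(cb)), 0)
  expect_equal(morans_i(rg(cb)), oracle_morans_i(cb))

  set.seed(53)
  vals <- as.vector(grad$values)
  null_i <- vapply(1:200, function(i)
    morans_i(rg(matrix(sample(vals), 12, 12))), numeric(1))
  perm_i <- morans_i(rg(matrix(sample(vals), 12, 12)))
  expect_true(perm_i > quantile(null_i, 0.001) &
                perm_i < quantile(null_i, 0.999))
  expect_error(morans_i(rg(matrix(3, 5, 5))), "constant")
})

test_that("Moran's I equals the double-sum oracle on random rasters", {
  for (i in 1:20) {
    set.seed(i)
    m <- matrix(rnorm(64), 8, 8)
    expect_equal(morans_i(rg(m)), oracle_morans_i(m))
  }
})

test_that("map-level Spearman behaves on identity, negation and randomness", {
  set.seed(54)
  a <- rg(matrix(runif(100), 10, 10))
  expect_equal(spearman_maps(a, a)$rho, 1)
  neg <- rg(-a$values)
  expect_equal(spearman_maps(a, neg)$rho, -1)
  b <- rg(matrix(runif(100), 10, 10))
  got <- spearman_maps(a, b)
  expect_equal(got$rho, cor(as.vector(a$values), as.vector(b$values),
                            method = "spearman"))
  expect_true(got$p_value >= 0 && got$p_value <= 1)
  expect_error(spearman_maps(a, rg(matrix(1, 10, 10))), "constant")
})

test_that("overlay accounting reproduces published-table arithmetic", {
  ov <- overlay_from_areas(4425, 17450, 7925)
  expect_equal(ov$area_total_union, 29800)
  expect_equal(round(ov$pct_overlaid, 1), 26.6)  # cell printed at 1 decimal
  expect_equal(ov$area_A_only + ov$area_B_only + ov$area_overlaid,
               ov$area_total_union)
})

test_that("overlay areas equal direct cell counting on random binary maps", {
  set.seed(55)
  for (i in 1:10) {
    a <- matrix(rbinom(900, 1, 0.4), 30, 30)
    b <- matrix(rbinom(900, 1, 0.4), 30, 30)
    ov <- overlay_stats(rg(a, cellsize = 5), rg(b, cellsize = 5))
    expect_equal(ov$area_A_only, sum(a == 1 & b == 0) * 25)
    expect_equal(ov$area_B_only, sum(a == 0 & b == 1) * 25)
    expect_equal(ov$area_overlaid, sum(a == 1 & b == 1) * 25)
    expect_equal(ov$area_A_only + ov$area_B_only + ov$area_overlaid,
                 ov$area_total_union)
  }
  ident <- rg(matrix(rbinom(100, 1, 0.5), 10, 10))
  ov <- overlay_stats(ident, ident)
  expect_equal(ov$area_A_only, 0)
  expect_equal(ov$area_B_only, 0)
  expect_equal(ov$area_overlaid, ov$area_total_union)
})
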