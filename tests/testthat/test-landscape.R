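test_that("identical config and seed give bit-identical landscapes", {
  cfg <- landscape_config(nrow = 15, ncol = 15, n_years = 1, seed = 42)
  b1 <- generate_landscape(cfg)
  b2 <- generate_landscape(cfg)
  expect_identical(b1, b2)
})

test_that("physical ranges and climate order hold across a 20-seed sweep", {
  for (seed in 1:20) {
    b <- generate_landscape(
      landscape_config(nrow = 12, ncol = 12, n_years = 1, seed = seed,
                       climate_noise_sd = 1, satellite_noise_sd = 0.1))
    expect_true(all(b$satellite$EVI$values >= -1 & b$satellite$EVI$values <= 1))
    expect_true(all(b$satellite$LST$values >= -25 & b$satellite$LST$values <= 45))
    expect_true(all(b$satellite$ALB$values >= 0 & b$satellite$ALB$values <= 1))
    for (m in 1:12) {
      expect_true(all(b$monthly_tmax[[m]]$values >= b$monthly_tmean[[m]]$values))
      expect_true(all(b$monthly_tmean[[m]]$values >= b$monthly_tmin[[m]]$values))
      expect_true(all(b$monthly_precip[[m]]$values >= 0))
    }
  }
})

test_that("noise-free cover-independent harmonic peaks at the configured day", {
  classes <- c("agric", "forest", "scrubs", "bs")
  sp <- default_sat_params(classes)
  sp$evi_base[] <- 0.4; sp$evi_amp[] <- 0.2; sp$evi_peak_doy[] <- 193
  sp$evi_precip_coef <- 0; sp$evi_temp_coef <- 0
  b <- generate_landscape(
    landscape_config(nrow = 10, ncol = 10, n_years = 1, seed = 5,
                     satellite_noise_sd = 0, climate_noise_sd = 0,
                     sat_params = sp))
  evi <- b$satellite$EVI$values
  # every cell's series identical
  expect_true(all(apply(evi, 2, function(col) max(col) - min(col)) < 1e-12))
  # brute-force scan: maximum attained at the composite nearest the peak day
  peak_idx <- which.max(evi[1, ])
  doys <- b$satellite$EVI$doy
  expect_equal(doys[peak_idx], doys[which.min(abs(doys - 193))])
})

test_that("virtual species truth is the logistic of standardized drivers", {
  b <- small_bundle()
  efa <- small_efa()
  stack <- predictor_stack(efa, rep("EFAs", length(efa)))

  sp0 <- define_virtual_species(stack, "EVIav", 0, intercept = 0)
  expect_true(all(abs(sp0$truth_map$values - 0.5) < 1e-12))

  # saturation: coefficient 50 approximates an indicator of driver > mean
  sp_sat <- define_virtual_species(stack, "EVIav", 50)
  v <- efa$EVIav$values
  ind <- (v > mean(v)) * 1
  agree <- mean((sp_sat$truth_map$values > 0.5) == ind)
  expect_gt(agree, 0.99)

  # two-driver cellwise oracle
  sp2 <- define_virtual_species(stack, c("EVIav", "LSTmn"), c(1.5, -0.7),
                                intercept = 0.3)
  z <- function(g) (g$values - mean(g$values)) / sd(g$values)
  oracle <- plogis(0.3 + 1.5 * z(efa$EVIav) - 0.7 * z(efa$LSTmn))
  expect_equal(sp2$truth_map$values, oracle)
  expect_true(all(sp2$truth_map$values >= 0 & sp2$truth_map$values <= 1))
  expect_named(sp2$coefficients, c("EVIav", "LSTmn"))

  expect_error(define_virtual_species(stack, "nope", 1), "unknown driver")
})

test_that("prevalence targeting solves the intercept", {
  stack <- predictor_stack(small_efa(), rep("EFAs", 24))
  sp <- define_virtual_species(stack, "EVIav", 2, prevalence_target = 0.1)
  expect_equal(sp$prevalence, 0.1, tolerance = 1e-6)
})

test_that("occurrence sampling follows the truth map", {
  # degenerate support: all mass in one cell
  m <- matrix(0, 5, 5); m[3, 4] <- 0.9
  sp <- list(truth_map = rg(m))
  occ <- sample_occurrences(sp, 1, seed = 1)
  expect_equal(c(occ$row, occ$col), c(3, 4))
  expect_error(sample_occurrences(sp, 2, seed = 1), "exceeds")

  # two-cell map 0.8 / 0.2: selection ratio ~ 4:1 (binomial 99% CI)
  m2 <- matrix(c(0.8, 0.2), 1, 2)
  sp2 <- list(truth_map = rg(m2))
  hits <- vapply(1:10000, function(s)
    sample_occurrences(sp2, 1, seed = s)$col == 1, logical(1))
  p_hat <- mean(hits)
  expect_true(abs(p_hat - 0.8) < 2.58 * sqrt(0.8 * 0.2 / 10000))

  # constant truth: uniform cell frequencies (chi-square GOF, n = 5000)
  m3 <- matrix(0.5, 2, 5)
  sp3 <- list(truth_map = rg(m3))
  draws <- vapply(1:5000, function(s) {
    o <- sample_occurrences(sp3, 1, seed = s); o$grid_id
  }, numeric(1))
  gof <- chisq.test(tabulate(draws, 10))
  expect_gt(gof$p.value, 0.001)
})

test_that("coarsening the grid never increases presence-cell counts", {
  b <- small_bundle()
  stack <- predictor_stack(small_efa(), rep("EFAs", 24))
  sp <- define_virtual_species(stack, "EVIav", 2, prevalence_target = 0.3)
  recs <- sample_occurrences(sp, 80, seed = 11)
  fine_grid <- stack$layers[[1]]
  coarse_grid <- aggregate_to_grid(fine_grid, 5, "mean")
  n_fine <- nrow(aggregate_occurrences(recs, fine_grid))
  n_coarse <- nrow(aggregate_occurrences(recs, coarse_grid))
  expect_lte(n_coarse, n_fine)
})

test_that("generator rejects invalid configurations", {
  expect_error(landscape_config(nrow = 5), "10 x 10")
  expect_error(landscape_config(n_years = 0), "n_years")
  expect_error(landscape_config(climate_noise_sd = -1), "nonnegative")
  expect_error(landscape_config(composite_interval_days = 60), "12 composites")
})
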