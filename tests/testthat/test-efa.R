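test_that("annual metrics of a constant series collapse to the constant", {
  doy <- seq(1, 365, by = 16)
  am <- annual_metrics(doy, rep(0.5, length(doy)))
  expect_equal(unname(am[c("mean", "max", "min")]), c(0.5, 0.5, 0.5))
  expect_equal(unname(am["sd"]), 0)
  # tie-break: first composite day
  expect_equal(unname(am["sin_dmax"]), sin(2 * pi * 1 / 365))
  expect_equal(unname(am["sin_dmin"]), sin(2 * pi * 1 / 365))
})

test_that("phenology anchors: early-April peak on sine, January peak on cosine", {
  doy <- seq(11, 365, by = 16)  # calendar containing day 91
  vals <- 0.3 + 0.3 * cos(2 * pi * (doy - 91) / 365)
  am <- annual_metrics(doy, vals)
  expect_equal(unname(am["sin_dmax"]), 0.9999, tolerance = 1e-3)
  s2 <- series_with_peak(1)     # day 1 is on the default calendar
  am2 <- annual_metrics(s2$doy, s2$values)
  expect_equal(unname(am2["cos_dmax"]), 1, tolerance = 1e-3)
})

test_that("annual metrics equal a brute-force scan on random series", {
  doy <- seq(1, 365, by = 16)
  for (i in 1:100) {
    set.seed(i)
    vals <- round(runif(23, -1, 1), 3)  # rounding invites argmax ties
    expect_equal(annual_metrics(doy, vals), oracle_annual_metrics(doy, vals))
  }
})

test_that("annual metrics reject short series and propagate nodata", {
  expect_error(annual_metrics(1:11, rnorm(11)), "at least 12")
  expect_true(all(is.na(annual_metrics(seq(1, 365, 16), rep(NA_real_, 23)))))
  expect_error(annual_metrics(seq(1, 365, 16), c(NA, rnorm(22))), "masked")
})

test_that("shifting a series by c shifts levels, not seasonality or phenology", {
  s <- series_with_peak(130)
  set.seed(4)
  vals <- s$values + rnorm(23, 0, 0.05)
  a <- annual_metrics(s$doy, vals)
  b <- annual_metrics(s$doy, vals + 0.37)
  expect_equal(unname(b[c("mean", "max", "min")]),
               unname(a[c("mean", "max", "min")]) + 0.37)
  expect_equal(b[c("sd", "sin_dmax", "cos_dmax", "sin_dmin", "cos_dmin")],
               a[c("sd", "sin_dmax", "cos_dmax", "sin_dmin", "cos_dmin")])
})

test_that("advancing the peak by a quarter year rotates the phenology vector", {
  doy <- seq(1, 365, by = 5)  # fine calendar limits argmax snapping
  mk <- function(peak) annual_metrics(doy, cos(2 * pi * (doy - peak) / 365))
  a <- mk(100)
  b <- mk(100 + 365 / 4)
  rot <- c(cos(pi / 2) * a["sin_dmax"] + sin(pi / 2) * a["cos_dmax"],
           -sin(pi / 2) * a["sin_dmax"] + cos(pi / 2) * a["cos_dmax"])
  expect_equal(unname(b[c("sin_dmax", "cos_dmax")]), unname(rot),
               tolerance = 0.05)  # residual 5-day snapping of the argmax
})

make_series <- function(values_by_year, doy, dimension = "EVI") {
  ny <- length(values_by_year)
  grid <- rg(matrix(0, 2, 2))
  satellite_series(dimension,
                   year = rep(seq_len(ny), each = length(doy)),
                   doy = rep(doy, ny),
                   values = do.call(cbind, values_by_year), grid = grid)
}

test_that("interannual averaging is idempotent for identical years", {
  doy <- seq(1, 365, by = 16)
  set.seed(9)
  one_year <- matrix(runif(4 * 23), 4, 23)
  s <- make_series(list(one_year, one_year, one_year), doy)
  st3 <- compute_efa_stack(list(s))
  st1 <- compute_efa_stack(list(make_series(list(one_year), doy)))
  for (nm in names(st3)) expect_equal(st3[[nm]]$values, st1[[nm]]$values)
})

test_that("phenology averages sine components across years, not dates", {
  doy <- seq(1, 365, by = 16)
  y1 <- matrix(rep(series_with_peak(91)$values, each = 4), 4, 23)
  y2 <- matrix(rep(series_with_peak(274)$values, each = 4), 4, 23)
  st <- compute_efa_stack(list(make_series(list(y1, y2), doy)))
  d1 <- doy[which.max(y1[1, ])]; d2 <- doy[which.max(y2[1, ])]
  oracle <- (sin(2 * pi * d1 / 365) + sin(2 * pi * d2 / 365)) / 2
  expect_equal(st$EVIdmxs$values[1, 1], oracle)
  expect_lt(abs(st$EVIdmxs$values[1, 1]), 0.1)  # opposed peaks cancel
})

test_that("a full synthetic bundle yields 24 rasters obeying the invariants", {
  st <- small_efa()
  expect_length(st, 24)
  expect_setequal(names(st),
                  as.vector(outer(c("EVI", "LST", "ALB"),
                                  c("av", "mx", "mn", "sd", "dmxs", "dmxc",
                                    "dmns", "dmnc"), paste0)))
  for (dim_ in c("EVI", "LST", "ALB")) {
    expect_true(all(st[[paste0(dim_, "mn")]]$values <=
                      st[[paste0(dim_, "av")]]$values + 1e-12))
    expect_true(all(st[[paste0(dim_, "av")]]$values <=
                      st[[paste0(dim_, "mx")]]$values + 1e-12))
    expect_true(all(st[[paste0(dim_, "sd")]]$values >= 0))
    for (ph in c("dmxs", "dmxc", "dmns", "dmnc"))
      expect_true(all(abs(st[[paste0(dim_, ph)]]$values) <= 1))
  }
  # single-year stack: sin^2 + cos^2 = 1 exactly before interannual averaging
  one <- compute_efa_stack(small_bundle()$satellite, years = 1)
  expect_equal(one$EVIdmxs$values^2 + one$EVIdmxc$values^2,
               matrix(1, 40, 40))
})

test_that("series constructor enforces ordering and coverage", {
  g <- rg(matrix(0, 1, 1))
  expect_error(satellite_series("EVI", c(1, 1), c(30, 10),
                                matrix(0, 1, 2), g), "ordered")
  expect_error(satellite_series("EVI", 1, 1, matrix(0, 1, 1), g),
               "12 composites")
  s <- make_series(list(matrix(0, 4, 23)), seq(1, 365, 16))
  expect_error(compute_efa_stack(list(s), years = 2), "missing year")
})
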