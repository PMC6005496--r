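#' Configuration of the synthetic landscape generator
#'
#' Bundles every tunable of the virtual-landscape generator: grid size and
#' grain, number of simulated years, satellite composite calendar, noise
#' levels, climate gradients and per-class satellite seasonal parameters.
#' The defaults emulate a NW-Iberian mountain landscape: an oceanic climate
#' with annual temperatures of roughly 5-15 degC outside the high summits,
#' annual precipitation of 600-3000 mm increasing with elevation, and a patchy
#' four-class land cover (agriculture, forest, scrubland, bare soil).
#'
#' @param nrow,ncol grid dimensions at the finest grain (>= 10 each).
#' @param fine_cell_km cell size of the finest grain in km.
#' @param n_years number of simulated years (>= 1).
#' @param composite_interval_days days between satellite composites; must give
#'   at least 12 composites per year. Composites start on day-of-year 1.
#' @param seed integer seed; identical config + seed gives bit-identical output.
#' @param climate_noise_sd spatial noise sd of monthly temperature (degC) and
#'   relative noise of monthly precipitation.
#' @param satellite_noise_sd per-composite noise sd of the satellite signals
#'   (EVI/albedo units; degC for LST uses 10x this value).
#' @param landcover_classes class labels, lowest-field-value first.
#' @param landcover_props target class proportions (same length, sums to 1).
#' @param landcover_smoothing smoothing length (fine cells) of the Gaussian
#'   random field thresholded into classes; larger = larger patches.
#' @param lc_subgrid integer subdivision factor of the land-cover raster
#'   relative to the fine grain (default 4, i.e. 250 m land cover under a
#'   1 km analysis grain), so landscape metrics always see a cover map
#'   strictly finer than any analysis grid.
#' @param terrain_smoothing smoothing length (cells) of the elevation field.
#' @param elev_range_m numeric length-2, elevation range in metres.
#' @param lapse_temp_c_per_km temperature lapse rate (degC per km of
#'   elevation; negative = cooling).
#' @param precip_gradient_mm_per_100m extra annual precipitation per 100 m of
#'   elevation.
#' @param sat_params per-class satellite seasonal parameters; see
#'   [default_sat_params()]. Pass a modified copy to decouple the satellite
#'   signal from land cover or climate.
#' @return object of class `landscape_config`.
#' @export
landscape_config <- function(nrow = 80, ncol = 80, fine_cell_km = 1,
                             n_years = 2, composite_interval_days = 16,
                             seed = 1,
                             climate_noise_sd = 0.5,
                             satellite_noise_sd = 0.02,
                             landcover_classes = c("agric", "forest",
                                                   "scrubs", "bs"),
                             landcover_props = c(0.30, 0.35, 0.25, 0.10),
                             landcover_smoothing = 4,
                             lc_subgrid = 4,
                             terrain_smoothing = 10,
                             elev_range_m = c(0, 2200),
                             lapse_temp_c_per_km = -6.5,
                             precip_gradient_mm_per_100m = 50,
                             sat_params = default_sat_params(landcover_classes)) {
  if (nrow < 10 || ncol < 10) stop("grid must be at least 10 x 10 cells")
  if (n_years < 1) stop("n_years must be >= 1")
  if (fine_cell_km <= 0) stop("cell size must be positive")
  if (365 %/% composite_interval_days < 12)
    stop("composite interval must give at least 12 composites per year")
  if (climate_noise_sd < 0 || satellite_noise_sd < 0)
    stop("noise levels must be nonnegative")
  if (lc_subgrid < 1 || lc_subgrid != round(lc_subgrid))
    stop("lc_subgrid must be a positive integer")
  if (length(landcover_props) != length(landcover_classes) ||
      abs(sum(landcover_props) - 1) > 1e-8)
    stop("landcover_props must match the classes and sum to 1")
  structure(as.list(environment()), class = "landscape_config")
}

#' Default per-class satellite seasonal parameters
#'
#' For each land-cover class: EVI mean level, seasonal amplitude and peak
#' day-of-year; albedo base level; plus coupling coefficients that tie the
#' EVI level to standardized annual precipitation and temperature (the
#' regional-scale climate control of ecosystem functioning) and the LST
#' seasonal cycle to air temperature. Set amplitudes/couplings to zero and
#' all classes equal to obtain a land-cover- and climate-independent signal.
#'
#' @param classes land-cover class labels.
#' @return a list with per-class vectors and scalar couplings.
#' @export
default_sat_params <- function(classes = c("agric", "forest", "scrubs", "bs")) {
  pick <- function(x, default) {
    out <- rep(default, length(classes))
    names(out) <- classes
    known <- intersect(names(x), classes)
    out[known] <- x[known]
    out
  }
  list(
    evi_base = pick(c(agric = 0.42, forest = 0.55, scrubs = 0.38, bs = 0.10), 0.35),
    evi_amp = pick(c(agric = 0.22, forest = 0.12, scrubs = 0.15, bs = 0.03), 0.10),
    evi_peak_doy = pick(c(agric = 130, forest = 190, scrubs = 160, bs = 200), 180),
    alb_base = pick(c(agric = 0.18, forest = 0.10, scrubs = 0.15, bs = 0.30), 0.15),
    alb_amp = 0.02,
    evi_precip_coef = 0.08,  # EVI level per sd of annual precipitation
    evi_temp_coef = 0.04,    # EVI level per sd of annual mean temperature
    lst_offset = 2,          # surface minus air temperature (degC)
    lst_amp = 9,             # LST seasonal amplitude (degC)
    lst_peak_doy = 196
  )
}

# Smoothed Gaussian random field via FFT circular convolution of white noise
# with a Gaussian kernel; standardized to mean 0, sd 1. Uses the current RNG
# stream (caller controls the seed).
gauss_field <- function(nr, nc, smoothing) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (smoothing <= 0) return((z - mean(z)) / stats::sd(z))
  dr <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dc <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  k <- exp(-outer(dr^2, dc^2, "+") / (2 * smoothing^2))
  k <- k / sum(k)
  sm <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Generate a virtual landscape
#'
#' Builds terrain, monthly climate normals, categorical land cover and three
#' satellite composite time series (EVI-like, LST-like, albedo-like) with the
#' statistical structure of temperate-mountain remote-sensing inputs:
#' elevation-lapsed temperature, orographic precipitation, winter-wet
#' seasonality, a patchy land-cover mosaic, and per-cell seasonal harmonics
#' whose level, amplitude and phase depend on land cover and climate, plus
#' noise, clipped to physical ranges (EVI in [-1, 1], LST in [-25, 45] degC,
#' albedo in [0, 1]).
#'
#' @param config a [landscape_config()].
#' @return a `landscape_bundle`: list with `elevation`, `monthly_tmean`,
#'   `monthly_tmax`, `monthly_tmin`, `monthly_precip` (lists of 12
#'   raster_grids), `landcover` (categorical raster_grid at the land-cover
#'   sub-grid), `landcover_modal` (fine-grain modal class) and `satellite`
#'   (named list of three [satellite_series()]).
#' @export
generate_landscape <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(config$seed)
  nr <- config$nrow; nc <- config$ncol
  cell <- config$fine_cell_km
  grd <- function(m, cats = NULL) raster_grid(m, cellsize = cell, categories = cats)

  # terrain
  ef <- gauss_field(nr, nc, config$terrain_smoothing)
  er <- config$elev_range_m
  elev_m <- (ef - min(ef)) / (max(ef) - min(ef)) * (er[2] - er[1]) + er[1]
  elev_km <- elev_m / 1000

  # land cover: quantile-thresholded smoothed field on a sub-grid strictly
  # finer than the fine grain; fine-grain modal class drives the satellite
  # harmonics
  f <- as.integer(config$lc_subgrid)
  lf <- gauss_field(nr * f, nc * f, config$landcover_smoothing * f)
  qs <- stats::quantile(lf, cumsum(config$landcover_props)[-length(config$landcover_props)])
  lc_sub <- matrix(1L + findInterval(lf, qs), nr * f, nc * f)
  classes <- config$landcover_classes
  nclass <- length(classes)
  sub_block <- (row(lc_sub) - 1L) %/% f + 1L +
    (((col(lc_sub) - 1L) %/% f)) * nr
  counts <- vapply(seq_len(nclass),
                   function(k) {
                     cnt <- tapply(lc_sub == k, sub_block, sum)
                     out <- integer(nr * nc)
                     out[as.integer(names(cnt))] <- cnt
                     out
                   }, integer(nr * nc))
  lc <- matrix(max.col(counts, ties.method = "first"), nr, nc)

  # monthly climate normals
  months <- 1:12
  t_sea <- 13 + 6.5 * cos(2 * pi * (months - 7) / 12)     # sea-level tmean, peak July
  p_sea <- 75 * (1 + 0.8 * cos(2 * pi * (months - 1) / 12)) # monthly precip, peak January
  precip_elev <- config$precip_gradient_mm_per_100m * elev_m / 100 / 12
  tmean <- tmax <- tmin <- precip <- vector("list", 12)
  for (m in months) {
    tm <- t_sea[m] + config$lapse_temp_c_per_km * elev_km +
      matrix(stats::rnorm(nr * nc, 0, config$climate_noise_sd), nr, nc)
    half_rng <- pmax(4 + matrix(stats::rnorm(nr * nc, 0, config$climate_noise_sd), nr, nc), 0)
    pp <- pmax((p_sea[m] + precip_elev) *
                 exp(matrix(stats::rnorm(nr * nc, 0, config$climate_noise_sd / 5), nr, nc)), 0)
    tmean[[m]] <- grd(tm)
    tmax[[m]] <- grd(tm + half_rng)
    tmin[[m]] <- grd(tm - half_rng)
    precip[[m]] <- grd(pp)
  }

  ann_t <- Reduce(`+`, lapply(tmean, function(g) g$values)) / 12
  ann_p <- Reduce(`+`, lapply(precip, function(g) g$values))
  zt <- (ann_t - mean(ann_t)) / stats::sd(ann_t)
  zp <- (ann_p - mean(ann_p)) / stats::sd(ann_p)

  # satellite composite calendar: fixed-interval composites from day 1
  doys <- seq(1L, 365L, by = config$composite_interval_days)
  years <- seq_len(config$n_years)
  year_v <- rep(years, each = length(doys))
  doy_v <- rep(doys, times = length(years))
  ncomp <- length(year_v)
  ncell <- nr * nc

  sp <- config$sat_params
  evi_mu <- sp$evi_base[lc] + sp$evi_precip_coef * zp + sp$evi_temp_coef * zt
  evi_amp <- sp$evi_amp[lc]
  evi_peak <- sp$evi_peak_doy[lc]
  lst_mu <- ann_t + sp$lst_offset
  alb_mu <- sp$alb_base[lc]

  harm <- function(doy, peak) cos(2 * pi * (doy - peak) / 365)
  evi <- lst <- alb <- matrix(NA_real_, ncell, ncomp)
  for (j in seq_len(ncomp)) {
    d <- doy_v[j]
    evi[, j] <- as.vector(evi_mu + evi_amp * harm(d, evi_peak)) +
      stats::rnorm(ncell, 0, config$satellite_noise_sd)
    lst[, j] <- as.vector(lst_mu + sp$lst_amp * harm(d, sp$lst_peak_doy)) +
      stats::rnorm(ncell, 0, 10 * config$satellite_noise_sd)
    alb[, j] <- as.vector(alb_mu + sp$alb_amp * harm(d, sp$lst_peak_doy)) +
      stats::rnorm(ncell, 0, config$satellite_noise_sd)
  }
  evi <- pmin(pmax(evi, -1), 1)
  lst <- pmin(pmax(lst, -25), 45)
  alb <- pmin(pmax(alb, 0), 1)

  template <- grd(matrix(NA_real_, nr, nc))
  structure(list(
    config = config,
    elevation = grd(elev_m),
    monthly_tmean = tmean, monthly_tmax = tmax, monthly_tmin = tmin,
    monthly_precip = precip,
    landcover = raster_grid(lc_sub, cellsize = cell / f, categories = classes),
    landcover_modal = grd(lc, cats = classes),
    satellite = list(
      EVI = satellite_series("EVI", year_v, doy_v, evi, template),
      LST = satellite_series("LST", year_v, doy_v, lst, template),
      ALB = satellite_series("ALB", year_v, doy_v, alb, template)
    )
  ), class = "landscape_bundle")
}

#' Define a virtual species with known truth
#'
#' True habitat suitability is a logistic function of standardized predictors:
#' `truth = plogis(intercept + sum(coef_j * z_j))`, where `z_j` is predictor
#' `j` centred and scaled over its valid cells. The known truth map enables
#' recovery experiments: screening and importance should rediscover the
#' drivers, and ensembles should rank fresh presences above background.
#'
#' @param predictors a [predictor_stack()] (or named list of raster_grids on
#'   one grid).
#' @param driver_names predictor names driving the species (non-zero
#'   coefficients); must exist in `predictors`.
#' @param coefficients numeric, same length/order as `driver_names`.
#' @param intercept logistic-scale intercept; ignored when
#'   `prevalence_target` is given.
#' @param prevalence_target optional fraction in (0,1); the intercept is then
#'   solved so the mean truth over valid cells equals it.
#' @return object of class `virtual_species` with fields `driver_names`,
#'   `coefficients`, `intercept`, `truth_map` (raster_grid in `[0, 1]`),
#'   `prevalence`.
#' @export
define_virtual_species <- function(predictors, driver_names, coefficients,
                                   intercept = 0, prevalence_target = NULL) {
  layers <- if (inherits(predictors, "predictor_stack")) predictors$layers else predictors
  missing_ <- setdiff(driver_names, names(layers))
  if (length(missing_))
    stop("unknown driver name(s): ", paste(missing_, collapse = ", "))
  if (length(coefficients) != length(driver_names))
    stop("coefficients must match driver_names")
  g0 <- layers[[driver_names[1]]]
  lp <- matrix(0, nrow(g0$values), ncol(g0$values))
  valid <- !is.na(g0$values)
  for (i in seq_along(driver_names)) {
    g <- layers[[driver_names[i]]]
    if (!same_grid(g, g0)) stop("driver rasters are not on one grid")
    v <- g$values
    z <- (v - mean(v, na.rm = TRUE)) / stats::sd(v, na.rm = TRUE)
    valid <- valid & !is.na(v)
    lp <- lp + coefficients[i] * z
  }
  lp[!valid] <- NA_real_
  if (!is.null(prevalence_target)) {
    f <- function(b0) mean(stats::plogis(b0 + lp[valid])) - prevalence_target
    intercept <- stats::uniroot(f, c(-50, 50), tol = 1e-10)$root
  }
  truth <- stats::plogis(intercept + lp)
  structure(list(
    driver_names = driver_names,
    coefficients = stats::setNames(coefficients, driver_names),
    intercept = intercept,
    truth_map = raster_grid(truth, xmin = g0$xmin, ymin = g0$ymin,
                            cellsize = g0$cellsize),
    prevalence = mean(truth[valid])
  ), class = "virtual_species")
}

#' Sample presence-only occurrence records of a virtual species
#'
#' Presence cells are drawn without replacement with probability proportional
#' to true suitability, emulating presence-only records already aggregated to
#' grid cells (no true absences are ever emitted). An optional bias raster
#' multiplies the sampling weight (spatial recording bias); the default is
#' unbiased.
#'
#' @param species a [define_virtual_species()] result.
#' @param n_records number of presence cells (<= number of valid cells with
#'   positive suitability).
#' @param seed integer seed.
#' @param bias optional raster_grid of nonnegative sampling weights on the
#'   same grid.
#' @return an `occurrence_table` data.frame: species, x, y, row, col,
#'   grid_id, year.
#' @export
sample_occurrences <- function(species, n_records, seed = 1, bias = NULL) {
  truth <- species$truth_map
  w <- as.vector(truth$values)
  if (!is.null(bias)) {
    if (!same_grid(bias, truth)) stop("bias raster not on the species grid")
    w <- w * as.vector(bias$values)
  }
  ok <- which(!is.na(w) & w > 0)
  if (n_records > length(ok))
    stop("n_records exceeds the ", length(ok), " available cells")
  set.seed(seed)
  pick <- ok[sample.int(length(ok), n_records, replace = FALSE, prob = w[ok])]
  nr <- nrow(truth$values)
  rows <- (pick - 1L) %% nr + 1L
  cols <- (pick - 1L) %/% nr + 1L
  out <- data.frame(
    species = "virtual",
    x = truth$xmin + (cols - 0.5) * truth$cellsize,
    y = truth$ymin + (nr - rows + 0.5) * truth$cellsize,
    row = rows, col = cols,
    grid_id = pick,
    year = sample(seq_len(max(1L, 16L)), n_records, replace = TRUE)
  )
  class(out) <- c("occurrence_table", class(out))
  out
}

#' Write landscape rasters and occurrences to disk
#'
#' Every raster goes out as an ESRI ASCII grid; satellite stacks additionally
#' get a CSV sidecar of acquisition dates (year, day-of-year per band file).
#'
#' @param bundle a landscape_bundle
#' @param dir output directory (created if needed)
#' @return invisibly, the vector of files written
#' @export
write_landscape <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  wr <- function(grid, name) {
    p <- file.path(dir, paste0(name, ".asc"))
    write_ascii_grid(grid, p)
    files <<- c(files, p)
  }
  wr(bundle$elevation, "elevation")
  wr(bundle$landcover, "landcover")
  for (m in 1:12) {
    wr(bundle$monthly_tmean[[m]], sprintf("tmean_%02d", m))
    wr(bundle$monthly_tmax[[m]], sprintf("tmax_%02d", m))
    wr(bundle$monthly_tmin[[m]], sprintf("tmin_%02d", m))
    wr(bundle$monthly_precip[[m]], sprintf("precip_%02d", m))
  }
  for (dim_ in names(bundle$satellite)) {
    s <- bundle$satellite[[dim_]]
    meta <- data.frame(band = seq_along(s$year), year = s$year, doy = s$doy,
                       date = sprintf("%04d-%03d", s$year, s$doy))
    for (j in seq_along(s$year))
      wr(series_band(s, j), sprintf("%s_%04d_%03d", dim_, s$year[j], s$doy[j]))
    mp <- file.path(dir, paste0(dim_, "_bands.csv"))
    utils::write.csv(meta, mp, row.names = FALSE)
    files <- c(files, mp)
  }
  invisible(files)
}
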