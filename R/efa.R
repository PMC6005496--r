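#' Satellite composite time series
#'
#' A dated stack of composite rasters for one dimension of ecosystem
#' functioning: EVI (carbon-gain dynamics, dimensionless), LST (sensible-heat
#' dynamics, degC) or ALB (shortwave albedo, radiative balance,
#' dimensionless). Values are stored as a cells x composites matrix (cells in
#' column-major raster order) with parallel `year` and `doy` vectors;
#' composites must be strictly ordered by (year, day-of-year) with at least
#' 12 composites per year.
#'
#' @param dimension one of "EVI", "LST", "ALB".
#' @param year,doy integer vectors, one entry per composite.
#' @param values numeric matrix, cells x composites.
#' @param grid template raster_grid carrying the geometry.
#' @return object of class `satellite_series`.
#' @export
satellite_series <- function(dimension = c("EVI", "LST", "ALB"),
                             year, doy, values, grid) {
  dimension <- match.arg(dimension)
  if (length(year) != length(doy) || ncol(values) != length(year))
    stop("year/doy/values dimensions disagree")
  ord <- order(year, doy)
  if (!identical(ord, seq_along(year)))
    stop("composites must be ordered by (year, day_of_year)")
  if (anyDuplicated(cbind(year, doy)))
    stop("duplicate composite dates")
  if (min(table(year)) < 12)
    stop("need at least 12 composites per year")
  structure(list(dimension = dimension, year = as.integer(year),
                 doy = as.integer(doy), values = values, grid = grid),
            class = "satellite_series")
}

#' Extract one composite of a series as a raster
#' @param series a satellite_series
#' @param j composite index
#' @return raster_grid
#' @export
series_band <- function(series, j) {
  g <- series$grid
  raster_grid(matrix(series$values[, j], nrow(g$values), ncol(g$values)),
              xmin = g$xmin, ymin = g$ymin, cellsize = g$cellsize)
}

#' Annual seasonal-dynamics metrics of one cell's series
#'
#' The eight per-year summary metrics of a satellite time series: annual mean
#' (surrogate of the annual total), annual maximum and minimum (extremes),
#' seasonal standard deviation (seasonality), and sine and cosine of the
#' dates of maximum and minimum (phenology). The phenology angle is
#' `theta = 2*pi*day_of_year/365` (leap days folded into day 365), so sine
#' near +1 marks a March/April timing, sine near -1 September/October, cosine
#' +1 December/January and cosine -1 June/July. Argmax/argmin ties take the
#' earliest day of year.
#'
#' @param doy integer day-of-year of each composite (>= 12 values, one year).
#' @param values numeric composite values, same length.
#' @return named numeric vector: mean, max, min, sd, sin_dmax, cos_dmax,
#'   sin_dmin, cos_dmin. All-NA input returns all-NA (nodata propagates).
#' @export
annual_metrics <- function(doy, values) {
  if (length(doy) != length(values)) stop("doy and values differ in length")
  if (length(values) < 12) stop("need at least 12 composites in the year")
  nm <- c("mean", "max", "min", "sd", "sin_dmax", "cos_dmax",
          "sin_dmin", "cos_dmin")
  if (all(is.na(values)))
    return(stats::setNames(rep(NA_real_, 8), nm))
  if (anyNA(values)) stop("missing composite values must be masked upstream")
  doy <- pmin(doy, 365L)
  dmax <- doy[which.max(values)]   # which.max: earliest on tie
  dmin <- doy[which.min(values)]
  th <- function(d) 2 * pi * d / 365
  stats::setNames(
    c(mean(values), max(values), min(values), stats::sd(values),
      sin(th(dmax)), cos(th(dmax)), sin(th(dmin)), cos(th(dmin))),
    nm)
}

# Vectorized annual metrics over a cells x composites matrix for one year.
annual_metrics_matrix <- function(values, doy) {
  doy <- pmin(doy, 365L)
  n <- ncol(values)
  mu <- rowMeans(values)
  mx <- do.call(pmax, asplit(values, 2))
  mn <- do.call(pmin, asplit(values, 2))
  sdv <- sqrt(pmax(0, rowSums((values - mu)^2) / (n - 1)))
  imax <- max.col(values, ties.method = "first")
  imin <- max.col(-values, ties.method = "first")
  th <- function(d) 2 * pi * d / 365
  list(mean = mu, max = mx, min = mn, sd = sdv,
       sin_dmax = sin(th(doy[imax])), cos_dmax = cos(th(doy[imax])),
       sin_dmin = sin(th(doy[imin])), cos_dmin = cos(th(doy[imin])))
}

# Table-3-style code for a metric of one dimension: av, mx, mn, sd,
# dmxs, dmxc, dmns, dmnc (printed codes EVImx, EVImn, EVIdmxs, LSTsd,
# LSTmn, ALBmx follow this scheme).
efa_code <- function(dimension, metric) {
  suffix <- c(mean = "av", max = "mx", min = "mn", sd = "sd",
              sin_dmax = "dmxs", cos_dmax = "dmxc",
              sin_dmin = "dmns", cos_dmin = "dmnc")[metric]
  paste0(dimension, suffix)
}

#' Ecosystem Functional Attributes from satellite series
#'
#' Computes, per cell and dimension, the interannual mean of the eight annual
#' seasonal-dynamics metrics — 24 candidate predictor rasters in total
#' (8 metrics x 3 dimensions). The interannual mean of the phenology metrics
#' averages each year's sine/cosine components (vector averaging), not the
#' dates themselves, so two opposed peak timings cancel toward 0.
#'
#' @param series named list of three [satellite_series()] (EVI, LST, ALB) on
#'   one grid.
#' @param years integer vector of years to use; default all years present in
#'   every series.
#' @return named list of 24 raster_grids with codes `EVIav, EVImx, EVImn,
#'   EVIsd, EVIdmxs, EVIdmxc, EVIdmns, EVIdmnc` and likewise for LST and ALB.
#' @export
compute_efa_stack <- function(series, years = NULL) {
  g0 <- series[[1]]$grid
  for (s in series) if (!same_grid(s$grid, g0)) stop("series grids differ")
  if (is.null(years))
    years <- Reduce(intersect, lapply(series, function(s) unique(s$year)))
  if (!length(years)) stop("no common years across series")
  out <- list()
  metrics <- c("mean", "max", "min", "sd", "sin_dmax", "cos_dmax",
               "sin_dmin", "cos_dmin")
  for (s in series) {
    acc <- stats::setNames(vector("list", 8), metrics)
    for (y in years) {
      sel <- s$year == y
      if (!any(sel)) stop("series ", s$dimension, " is missing year ", y)
      am <- annual_metrics_matrix(s$values[, sel, drop = FALSE], s$doy[sel])
      for (m in metrics)
        acc[[m]] <- if (is.null(acc[[m]])) am[[m]] else acc[[m]] + am[[m]]
    }
    for (m in metrics) {
      v <- acc[[m]] / length(years)
      out[[efa_code(s$dimension, m)]] <-
        raster_grid(matrix(v, nrow(g0$values), ncol(g0$values)),
                    xmin = g0$xmin, ymin = g0$ymin, cellsize = g0$cellsize)
    }
  }
  out
}
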