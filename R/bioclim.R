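#' Bioclimatic predictors from monthly climate normals
#'
#' Derives the six climate predictors used for model calibration from 12
#' monthly rasters of mean/max/min temperature and precipitation:
#' \describe{
#'   \item{TmWQ}{mean temperature (degC) of the wettest quarter — the three
#'     consecutive months (wrap-around across the year boundary allowed) with
#'     the highest cumulative precipitation; ties take the earliest-starting
#'     window.}
#'   \item{TmDQ}{mean temperature of the driest quarter, ties likewise.}
#'   \item{TAR}{temperature annual range: the mean over the twelve months of
#'     the monthly (tmax - tmin) difference.}
#'   \item{PpWM, PpDM}{precipitation (mm) of the wettest / driest month.}
#'   \item{PS}{precipitation seasonality: 100 x sd/mean of the monthly
#'     precipitation totals (coefficient of variation, %).}
#' }
#'
#' @param monthly_tmean,monthly_tmax,monthly_tmin,monthly_precip lists of 12
#'   raster_grids (January first) on one grid.
#' @return named list of six raster_grids: TmWQ, TmDQ, TAR, PpWM, PpDM, PS.
#' @export
derive_bioclim <- function(monthly_tmean, monthly_tmax, monthly_tmin,
                           monthly_precip) {
  for (l in list(monthly_tmean, monthly_tmax, monthly_tmin, monthly_precip))
    if (length(l) != 12) stop("each climate variable needs 12 monthly rasters")
  g0 <- monthly_tmean[[1]]
  stack_m <- function(l) {
    for (g in l) if (!same_grid(g, g0)) stop("monthly rasters not on one grid")
    matrix(vapply(l, function(g) as.vector(g$values),
                  numeric(length(g0$values))), ncol = 12)
  }
  tme <- stack_m(monthly_tmean)
  tmx <- stack_m(monthly_tmax)
  tmn <- stack_m(monthly_tmin)
  pp <- stack_m(monthly_precip)
  if (any(pp < 0, na.rm = TRUE)) stop("negative precipitation")

  # 12 wrap-around quarters: window starting at month m covers m, m+1, m+2
  W <- matrix(0, 12, 12)
  for (m in 1:12) W[(c(m, m + 1, m + 2) - 1) %% 12 + 1, m] <- 1
  psum <- pp %*% W          # cells x 12 window precip totals
  tq <- (tme %*% W) / 3     # cells x 12 window mean temperatures
  wet <- max.col(psum, ties.method = "first")
  dry <- max.col(-psum, ties.method = "first")
  idx <- seq_len(nrow(psum))
  out_v <- list(
    TmWQ = tq[cbind(idx, wet)],
    TmDQ = tq[cbind(idx, dry)],
    TAR = rowMeans(tmx - tmn),
    PpWM = apply(pp, 1, max),
    PpDM = apply(pp, 1, min),
    PS = 100 * apply(pp, 1, stats::sd) / rowMeans(pp)
  )
  lapply(out_v, function(v)
    raster_grid(matrix(v, nrow(g0$values), ncol(g0$values)),
                xmin = g0$xmin, ymin = g0$ymin, cellsize = g0$cellsize))
}
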