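#' Lightweight planar raster grid
#'
#' A `raster_grid` is a matrix of cell values on a regular planar grid with a
#' km-based coordinate system: `values[r, c]` covers the square whose lower-left
#' corner is `(xmin + (c-1)*cellsize, ymin + (nrow-r)*cellsize)`, i.e. row 1 is
#' the top of the map. `NA` marks nodata. All spatial stages of the pipeline
#' exchange this container.
#'
#' @param values numeric or integer matrix (row 1 = northern edge).
#' @param xmin,ymin coordinates of the lower-left corner, in km.
#' @param cellsize cell edge length in km (> 0).
#' @param categories optional character vector of category labels for
#'   categorical rasters; `values` then holds integer codes indexing it.
#' @return an object of class `raster_grid`.
#' @export
raster_grid <- function(values, xmin = 0, ymin = 0, cellsize = 1,
                        categories = NULL) {
  if (!is.matrix(values)) stop("`values` must be a matrix")
  if (!is.numeric(cellsize) || length(cellsize) != 1 || cellsize <= 0)
    stop("`cellsize` must be a single positive number")
  structure(
    list(values = values, xmin = xmin, ymin = ymin,
         cellsize = cellsize, categories = categories),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("raster_grid: %d x %d cells, cellsize %g km, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xmin, x$ymin))
  if (!is.null(x$categories))
    cat("  categorical:", paste(x$categories, collapse = ", "), "\n")
  else if (length(v))
    cat(sprintf("  range [%.4g, %.4g], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.raster_grid <- function(x) dim(x$values)

#' Test that two rasters share one grid
#' @param a,b raster_grid objects
#' @return logical
#' @export
same_grid <- function(a, b) {
  identical(dim(a$values), dim(b$values)) &&
    isTRUE(all.equal(c(a$xmin, a$ymin, a$cellsize),
                     c(b$xmin, b$ymin, b$cellsize)))
}

#' Cell-center coordinates of every cell
#' @param grid a raster_grid
#' @return data.frame with columns row, col, x, y (km)
#' @export
cell_centers <- function(grid) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  rows <- rep(seq_len(nr), times = nc)
  cols <- rep(seq_len(nc), each = nr)
  data.frame(
    row = rows, col = cols,
    x = grid$xmin + (cols - 0.5) * grid$cellsize,
    y = grid$ymin + (nr - rows + 0.5) * grid$cellsize
  )
}

#' Map point coordinates to grid cells
#' @param grid a raster_grid
#' @param x,y point coordinates (km)
#' @return data.frame with row, col (NA for points outside the extent)
#' @export
locate_cells <- function(grid, x, y) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((x - grid$xmin) / grid$cellsize) + 1L
  row <- nr - floor((y - grid$ymin) / grid$cellsize)
  bad <- col < 1L | col > nc | row < 1L | row > nr
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Aggregate a raster to a coarser grain
#'
#' Continuous rasters are block-averaged (nodata excluded from each block
#' mean); categorical rasters are expanded to one per-class fraction raster
#' per category.
#'
#' @param raster a raster_grid at the fine grain.
#' @param target_grain new cell size in km; must be an integer multiple of the
#'   source cell size, dividing both dimensions exactly.
#' @param method "mean" for continuous input, "fraction_by_class" for
#'   categorical input.
#' @return for "mean", a raster_grid; for "fraction_by_class", a named list of
#'   raster_grids (fractions in `[0, 1]`), one per category.
#' @export
aggregate_to_grid <- function(raster, target_grain,
                              method = c("mean", "fraction_by_class")) {
  method <- match.arg(method)
  f <- target_grain / raster$cellsize
  if (abs(f - round(f)) > 1e-9 || f < 1)
    stop("target grain must be an integer multiple of the source cell size")
  f <- as.integer(round(f))
  v <- raster$values
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% f != 0 || nc %% f != 0)
    stop("grain ratio must divide the raster dimensions")
  NR <- nr %/% f; NC <- nc %/% f
  block_row <- (seq_len(nr) - 1L) %/% f + 1L
  block_col <- (seq_len(nc) - 1L) %/% f + 1L
  idx <- block_row[row(v)] + (block_col[col(v)] - 1L) * NR

  out_grid <- function(vals) raster_grid(matrix(vals, NR, NC),
                                         xmin = raster$xmin, ymin = raster$ymin,
                                         cellsize = target_grain)
  if (method == "mean") {
    sums <- tapply(ifelse(is.na(v), 0, v), idx, sum)
    cnts <- tapply(!is.na(v), idx, sum)
    full_s <- full_c <- numeric(NR * NC)
    full_s[as.integer(names(sums))] <- sums
    full_c[as.integer(names(cnts))] <- cnts
    out_grid(ifelse(full_c > 0, full_s / full_c, NA_real_))
  } else {
    cats <- raster$categories
    if (is.null(cats)) cats <- as.character(sort(unique(v[!is.na(v)])))
    valid <- tapply(!is.na(v), idx, sum)
    full_valid <- numeric(NR * NC)
    full_valid[as.integer(names(valid))] <- valid
    out <- lapply(seq_along(cats), function(k) {
      hits <- tapply(!is.na(v) & v == k, idx, sum)
      full_h <- numeric(NR * NC)
      full_h[as.integer(names(hits))] <- hits
      out_grid(ifelse(full_valid > 0, full_h / full_valid, NA_real_))
    })
    names(out) <- cats
    out
  }
}

#' Read or write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS tools. Coordinates
#' are written in km (the pipeline's planar CRS).
#'
#' @param grid a raster_grid
#' @param path file path (.asc)
#' @param digits significant digits written
#' @return `write_ascii_grid` returns `path` invisibly; `read_ascii_grid`
#'   returns a raster_grid.
#' @export
write_ascii_grid <- function(grid, path, digits = 8) {
  v <- grid$values
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", grid$xmin),
    sprintf("yllcorner %.10g", grid$ymin),
    sprintf("cellsize %.10g", grid$cellsize),
    "NODATA_value -9999"
  ), con)
  vv <- signif(v, digits)
  vv[is.na(vv)] <- -9999
  writeLines(apply(vv, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path) {
  hdr <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(hdr, "\\s+"))
  h <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  body <- scan(path, skip = 6, quiet = TRUE)
  m <- matrix(body, nrow = h[["nrows"]], ncol = h[["ncols"]], byrow = TRUE)
  m[m == h[["nodata_value"]]] <- NA_real_
  raster_grid(m, xmin = h[["xllcorner"]], ymin = h[["yllcorner"]],
              cellsize = h[["cellsize"]])
}
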