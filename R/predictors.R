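#' Named predictor stack on one analysis grid
#'
#' @param layers named list of raster_grids sharing one grid.
#' @param groups character vector, one group per layer, each in
#'   `c("CLI", "LC", "EFAs")`.
#' @return object of class `predictor_stack` with `layers`, `groups`,
#'   `grain` (cell size, km).
#' @export
predictor_stack <- function(layers, groups) {
  if (is.null(names(layers)) || anyDuplicated(names(layers)))
    stop("layers must be uniquely named")
  if (length(groups) != length(layers))
    stop("one group per layer required")
  if (!all(groups %in% c("CLI", "LC", "EFAs")))
    stop("groups must be CLI, LC or EFAs")
  g0 <- layers[[1]]
  for (g in layers) if (!same_grid(g, g0)) stop("layers not on one grid")
  structure(list(layers = layers,
                 groups = stats::setNames(groups, names(layers)),
                 grain = g0$cellsize),
            class = "predictor_stack")
}

#' @export
print.predictor_stack <- function(x, ...) {
  cat(sprintf("predictor_stack: %d layers at %g km grain\n",
              length(x$layers), x$grain))
  for (grp in unique(x$groups))
    cat(sprintf("  %s: %s\n", grp,
                paste(names(x$groups)[x$groups == grp], collapse = " ")))
  invisible(x)
}

#' Subset a predictor stack by group or name
#' @param stack a predictor_stack
#' @param groups groups to keep (e.g. `c("CLI", "LC")` for the combined set)
#' @param names_ layer names to keep (applied after the group filter)
#' @return predictor_stack
#' @export
subset_stack <- function(stack, groups = NULL, names_ = NULL) {
  keep <- names(stack$layers)
  if (!is.null(groups)) keep <- keep[stack$groups[keep] %in% groups]
  if (!is.null(names_)) keep <- intersect(keep, names_)
  if (!length(keep)) stop("no layers left after subsetting")
  predictor_stack(stack$layers[keep], unname(stack$groups[keep]))
}

#' Crop a raster to a rectangular window of cells
#' @param grid a raster_grid
#' @param rows,cols integer ranges of rows/columns to keep
#' @return raster_grid with adjusted origin
#' @export
crop_grid <- function(grid, rows, cols) {
  nr <- nrow(grid$values)
  v <- grid$values[rows, cols, drop = FALSE]
  raster_grid(v,
              xmin = grid$xmin + (min(cols) - 1) * grid$cellsize,
              ymin = grid$ymin + (nr - max(rows)) * grid$cellsize,
              cellsize = grid$cellsize, categories = grid$categories)
}

#' Extract predictor values at grid cells
#' @param stack a predictor_stack
#' @param cell_ids cell indices (column-major) into the stack's grid
#' @return data.frame, one column per predictor
#' @export
stack_values <- function(stack, cell_ids) {
  as.data.frame(lapply(stack$layers,
                       function(g) as.vector(g$values)[cell_ids]))
}

#' Cell ids of jointly valid cells of a stack
#' @param stack a predictor_stack
#' @return integer vector of column-major cell indices with no NA layer
#' @export
stack_valid_cells <- function(stack) {
  ok <- !is.na(as.vector(stack$layers[[1]]$values))
  for (g in stack$layers[-1]) ok <- ok & !is.na(as.vector(g$values))
  which(ok)
}

#' Derive the full 36-predictor stack for one grain and extent window
#'
#' Runs the three predictor pipelines over a window of the synthetic
#' landscape and aggregates everything to the analysis grain: 6 bioclim
#' predictors (CLI) from the monthly climate, 6 landscape metrics (LC: four
#' class fractions, SHDI, AREAmean) from the sub-grid land cover, and 24
#' satellite seasonal-dynamics metrics (EFAs). Continuous fine-grain rasters
#' are block-averaged to the grain; landscape metrics are computed directly
#' at the grain from the sub-grid cover.
#'
#' @param bundle a [generate_landscape()] result.
#' @param grain analysis cell size in km (integer multiple of the fine cell).
#' @param window list with `rows` and `cols` (fine-grain index ranges), or
#'   NULL for the full extent.
#' @param efa_fine optional precomputed [compute_efa_stack()] result at the
#'   fine grain (saves recomputation across windows/grains).
#' @return a [predictor_stack()] at the analysis grain.
#' @export
derive_predictors <- function(bundle, grain, window = NULL, efa_fine = NULL) {
  fine <- bundle$config$fine_cell_km
  if (is.null(window))
    window <- list(rows = seq_len(bundle$config$nrow),
                   cols = seq_len(bundle$config$ncol))
  cw <- function(g) crop_grid(g, window$rows, window$cols)
  agg <- function(g) if (abs(grain - fine) < 1e-9) g else
    aggregate_to_grid(g, grain, "mean")

  cli <- derive_bioclim(lapply(bundle$monthly_tmean, cw),
                        lapply(bundle$monthly_tmax, cw),
                        lapply(bundle$monthly_tmin, cw),
                        lapply(bundle$monthly_precip, cw))
  cli <- lapply(cli, agg)

  f <- as.integer(round(fine / bundle$landcover$cellsize))
  lc_window <- crop_grid(bundle$landcover,
                         ((min(window$rows) - 1) * f + 1):(max(window$rows) * f),
                         ((min(window$cols) - 1) * f + 1):(max(window$cols) * f))
  lc <- landscape_metrics(lc_window, grain)

  if (is.null(efa_fine)) efa_fine <- compute_efa_stack(bundle$satellite)
  efa <- lapply(efa_fine, function(g) agg(cw(g)))

  predictor_stack(c(cli, lc, efa),
                  c(rep("CLI", length(cli)), rep("LC", length(lc)),
                    rep("EFAs", length(efa))))
}

#' Write every layer of a stack as ESRI ASCII grids
#' @param stack a predictor_stack
#' @param dir output directory
#' @return invisibly, the files written
#' @export
write_stack <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(names(stack$layers), function(nm) {
    p <- file.path(dir, paste0(nm, ".asc"))
    write_ascii_grid(stack$layers[[nm]], p)
    p
  }, character(1))
  invisible(files)
}
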