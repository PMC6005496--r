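#' Landscape composition and configuration metrics per analysis cell
#'
#' From a categorical land-cover raster strictly finer than the analysis
#' grain, computes per analysis cell: the fraction of cell area in each
#' class, Shannon's diversity index `SHDI = -sum(p_i * ln(p_i))` over the
#' classes present, and the mean patch area `AREAmean` (km^2) of
#' 8-neighbour-connected same-class patches clipped at the analysis-cell
#' boundary (per-cell FRAGSTATS-style computation).
#'
#' @param landcover categorical raster_grid (integer codes, `categories`
#'   labels).
#' @param analysis_grain analysis cell size in km; must be an integer
#'   multiple (> 1x) of the land-cover cell size.
#' @return named list of raster_grids: one fraction raster per class (named
#'   by class label), plus `SHDI` and `AREAmean`.
#' @export
landscape_metrics <- function(landcover, analysis_grain) {
  v <- landcover$values
  classes <- landcover$categories
  if (is.null(classes)) stop("landcover raster must carry category labels")
  if (any(!is.na(v) & (v < 1 | v > length(classes))))
    stop("unknown land-cover class code")
  f <- analysis_grain / landcover$cellsize
  if (abs(f - round(f)) > 1e-9 || f < 2)
    stop("land-cover resolution must be strictly finer than the analysis grain")
  f <- as.integer(round(f))
  nr <- nrow(v); nc <- ncol(v)
  if (nr %% f != 0 || nc %% f != 0)
    stop("analysis grain must divide the land-cover raster dimensions")
  NR <- nr %/% f; NC <- nc %/% f
  block <- (row(v) - 1L) %/% f + 1L + ((col(v) - 1L) %/% f) * NR
  nblock <- NR * NC
  cell_area <- landcover$cellsize^2

  # class fractions relative to total block area (nodata keeps the sum < 1)
  fracs <- vapply(seq_along(classes), function(k) {
    cnt <- tapply(!is.na(v) & v == k, block, sum)
    out <- numeric(nblock)
    out[as.integer(names(cnt))] <- cnt
    out / f^2
  }, numeric(nblock))
  if (!is.matrix(fracs)) fracs <- matrix(fracs, nrow = nblock)

  valid_frac <- rowSums(fracs)
  shdi <- vapply(seq_len(nblock), function(b) {
    p <- fracs[b, ]
    if (valid_frac[b] == 0) return(NA_real_)
    p <- p[p > 0] / valid_frac[b]
    -sum(p * log(p))
  }, numeric(1))

  # one global connected-component labelling with edges restricted to
  # same class AND same analysis block (patches clipped at cell boundaries)
  id <- matrix(seq_len(nr * nc), nr, nc)
  edges <- list()
  offs <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))  # 8-neighbour
  for (o in offs) {
    ri <- seq_len(nr); ci <- seq_len(nc)
    r1 <- ri[ri + o[1] >= 1 & ri + o[1] <= nr]
    c1 <- ci[ci + o[2] >= 1 & ci + o[2] <= nc]
    a <- id[r1, c1, drop = FALSE]
    b <- id[r1 + o[1], c1 + o[2], drop = FALSE]
    keep <- !is.na(v[a]) & !is.na(v[b]) & v[a] == v[b] & block[a] == block[b]
    edges[[length(edges) + 1]] <- cbind(a[keep], b[keep])
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nr * nc - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  valid_cells <- which(!is.na(v))
  patch_of_cell <- comp[valid_cells]
  patch_sizes <- tabulate(patch_of_cell)
  patch_block <- integer(max(patch_of_cell))
  patch_block[patch_of_cell] <- block[valid_cells]
  area_mean <- vapply(seq_len(nblock), function(b) {
    sz <- patch_sizes[patch_block == b & patch_sizes > 0]
    if (!length(sz)) return(NA_real_)
    mean(sz) * cell_area
  }, numeric(1))

  out_g <- function(vals) raster_grid(matrix(vals, NR, NC),
                                      xmin = landcover$xmin,
                                      ymin = landcover$ymin,
                                      cellsize = analysis_grain)
  out <- lapply(seq_along(classes), function(k) out_g(fracs[, k]))
  names(out) <- classes
  out$SHDI <- out_g(shdi)
  out$AREAmean <- out_g(area_mean)
  out
}
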