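#' Fuzzy kappa agreement of two categorical maps
#'
#' Chance-corrected agreement that tolerates near-miss locations. Each
#' cell's fuzzy membership in category c is the largest distance-decayed
#' weight `2^(-d / halving_distance)` over the cells of that category within
#' `radius` (Euclidean cell distance; the cell itself has weight 1). The
#' one-way similarity of map A against map B at a cell is B's fuzzy
#' membership in A's crisp category; the cell similarity is the minimum of
#' the two one-way similarities. The observed mean similarity P_obs is
#' corrected by the expected similarity P_exp under random relocation of all
#' grid squares, computed from the category proportions and the ordered
#' neighbourhood weights, giving `kappa = (P_obs - P_exp) / (1 - P_exp)`.
#' At `radius = 0` this reduces exactly to Cohen's kappa; identical maps
#' give kappa = 1. The expectation is the original category-proportion form;
#' the autocorrelation-aware expectation of the improved variant is not
#' implemented.
#'
#' @param mapA,mapB categorical raster_grids on one grid with the same
#'   category set (binary 0/1 maps are handled as two categories).
#' @param halving_distance distance (cells) at which membership halves
#'   (default 2).
#' @param radius neighbourhood radius in cells (default 4; 0 = crisp).
#' @return fuzzy kappa (<= 1).
#' @export
fuzzy_kappa <- function(mapA, mapB, halving_distance = 2, radius = 4) {
  if (!same_grid(mapA, mapB)) stop("maps are not on one grid")
  va <- mapA$values; vb <- mapB$values
  valid <- !is.na(va) & !is.na(vb)
  if (!any(valid)) stop("no jointly valid cells")
  if (!is.null(mapA$categories) && !is.null(mapB$categories) &&
      !identical(mapA$categories, mapB$categories))
    stop("category sets differ")
  cats <- sort(unique(c(va[valid], vb[valid])))

  r <- floor(radius)
  offs <- expand.grid(dr = -r:r, dc = -r:r)
  offs$d <- sqrt(offs$dr^2 + offs$dc^2)
  offs <- offs[offs$d <= radius + 1e-9, ]
  offs$w <- 2^(-offs$d / halving_distance)
  offs <- offs[order(-offs$w), ]

  nr <- nrow(va); nc <- ncol(va)
  shift_max <- function(ind, dr, dc, cur) {
    # running max of a shifted indicator (cells outside stay as-is)
    rs <- seq_len(nr); cs <- seq_len(nc)
    rsrc <- rs + dr; csrc <- cs + dc
    okr <- rsrc >= 1 & rsrc <= nr; okc <- csrc >= 1 & csrc <= nc
    out <- cur
    out[rs[okr], cs[okc]] <- pmax(cur[rs[okr], cs[okc], drop = FALSE],
                                  ind[rsrc[okr], csrc[okc], drop = FALSE])
    out
  }
  memberships <- function(v) {
    lapply(cats, function(cl) {
      ind <- matrix(0, nr, nc)
      ind[!is.na(v) & v == cl] <- 1
      mu <- matrix(0, nr, nc)
      for (k in seq_len(nrow(offs)))
        mu <- shift_max(ind * offs$w[k], offs$dr[k], offs$dc[k], mu)
      mu
    })
  }
  muA <- memberships(va); muB <- memberships(vb)
  sim_one_way <- function(crisp, mu_other) {
    s <- matrix(NA_real_, nr, nc)
    for (i in seq_along(cats)) {
      sel <- valid & crisp == cats[i]
      s[sel] <- mu_other[[i]][sel]
    }
    s
  }
  sAB <- sim_one_way(va, muB)
  sBA <- sim_one_way(vb, muA)
  p_obs <- mean(pmin(sAB, sBA)[valid])

  # expected membership under random relocation: neighbourhood cells sorted
  # by decreasing weight w_1 = 1 > w_2 >= ...; category with proportion p
  # attains its best weight w_j with probability p * (1 - p)^(j - 1)
  pA <- vapply(cats, function(cl) mean(va[valid] == cl), numeric(1))
  pB <- vapply(cats, function(cl) mean(vb[valid] == cl), numeric(1))
  e_mu <- function(p) {
    w <- offs$w
    sum(w * p * (1 - p)^(seq_along(w) - 1))
  }
  p_exp <- mean(c(sum(pA * vapply(pB, e_mu, numeric(1))),
                  sum(pB * vapply(pA, e_mu, numeric(1)))))
  (p_obs - p_exp) / (1 - p_exp)
}

#' Global Moran's I of a raster
#'
#' Queen-contiguity (8-neighbour) row-standardized weights over valid cells.
#'
#' @param map a raster_grid with at least two distinct valid values.
#' @return Moran's I.
#' @export
morans_i <- function(map) {
  v <- map$values
  valid <- !is.na(v)
  if (length(unique(v[valid])) < 2) stop("constant map")
  xbar <- mean(v[valid])
  z <- v - xbar
  z[!valid] <- 0
  nr <- nrow(v); nc <- ncol(v)
  nbr_sum <- matrix(0, nr, nc)   # sum of neighbour deviations
  nbr_cnt <- matrix(0, nr, nc)   # number of valid neighbours
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- seq_len(nr); cs <- seq_len(nc)
    okr <- rs + dr >= 1 & rs + dr <= nr
    okc <- cs + dc >= 1 & cs + dc <= nc
    nbr_sum[rs[okr], cs[okc]] <- nbr_sum[rs[okr], cs[okc], drop = FALSE] +
      z[rs[okr] + dr, cs[okc] + dc, drop = FALSE]
    nbr_cnt[rs[okr], cs[okc]] <- nbr_cnt[rs[okr], cs[okc], drop = FALSE] +
      valid[rs[okr] + dr, cs[okc] + dc, drop = FALSE]
  }
  use <- valid & nbr_cnt > 0
  # row-standardized: w_ij = 1/k_i, so sum_j w_ij z_j = nbr_sum/k_i and the
  # total weight W0 equals n; I = (n/W0) * num/den collapses to num/den
  num <- sum(z[use] * nbr_sum[use] / nbr_cnt[use])
  den <- sum(z[use]^2)
  num / den
}

#' Spearman agreement of two continuous maps
#'
#' @param contA,contB continuous raster_grids on one grid with >= 10 jointly
#'   valid cells.
#' @return list with `rho` and `p_value` (large-sample approximation).
#' @export
spearman_maps <- function(contA, contB) {
  if (!same_grid(contA, contB)) stop("maps are not on one grid")
  ok <- !is.na(contA$values) & !is.na(contB$values)
  if (sum(ok) < 10) stop("need at least 10 jointly valid cells")
  a <- contA$values[ok]; b <- contB$values[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) stop("constant map")
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Overlay-area accounting of two binary suitability maps
#'
#' Areas (km^2) suitable only in A, only in B, in both (overlaid) and in the
#' union, plus each part's percentage of the union (two decimals,
#' round-half-even). The three parts always sum exactly to the union.
#'
#' @param binA,binB binary (0/1) raster_grids on one grid.
#' @param cell_area_km2 area of one cell (default cellsize^2).
#' @return list of class `overlay_record`: `area_A_only`, `area_B_only`,
#'   `area_overlaid`, `area_total_union` and `pct_*` counterparts.
#' @export
overlay_stats <- function(binA, binB, cell_area_km2 = binA$cellsize^2) {
  if (!same_grid(binA, binB)) stop("maps are not on one grid")
  a <- binA$values == 1; b <- binB$values == 1
  ok <- !is.na(a) & !is.na(b)
  overlay_from_areas(sum(a & !b & ok) * cell_area_km2,
                     sum(b & !a & ok) * cell_area_km2,
                     sum(a & b & ok) * cell_area_km2)
}

#' @rdname overlay_stats
#' @param area_A_only,area_B_only,area_overlaid areas in km^2 (e.g. the
#'   partial/overlaid columns of a published overlay table).
#' @export
overlay_from_areas <- function(area_A_only, area_B_only, area_overlaid) {
  total <- area_A_only + area_B_only + area_overlaid
  pct <- function(a) round(100 * a / total, 2)
  structure(list(
    area_A_only = area_A_only, area_B_only = area_B_only,
    area_overlaid = area_overlaid, area_total_union = total,
    pct_A_only = pct(area_A_only), pct_B_only = pct(area_B_only),
    pct_overlaid = pct(area_overlaid)
  ), class = "overlay_record")
}
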