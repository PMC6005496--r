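# Shared fixtures and independent oracles for the test suite.

.fixture_env <- new.env()

# one moderately sized landscape, generated once per test run
small_bundle <- function() {
  if (is.null(.fixture_env$bundle))
    .fixture_env$bundle <- generate_landscape(
      landscape_config(nrow = 40, ncol = 40, n_years = 2, seed = 7))
  .fixture_env$bundle
}

small_efa <- function() {
  if (is.null(.fixture_env$efa))
    .fixture_env$efa <- compute_efa_stack(small_bundle()$satellite)
  .fixture_env$efa
}

rg <- function(m, cellsize = 1, categories = NULL)
  raster_grid(m, cellsize = cellsize, categories = categories)

# brute-force annual metrics: independent scalar-loop implementation
oracle_annual_metrics <- function(doy, values) {
  best_max <- -Inf; best_min <- Inf; dmax <- NA; dmin <- NA
  for (i in seq_along(values)) {
    if (values[i] > best_max) { best_max <- values[i]; dmax <- doy[i] }
    if (values[i] < best_min) { best_min <- values[i]; dmin <- doy[i] }
  }
  c(mean = sum(values) / length(values), max = best_max, min = best_min,
    sd = sqrt(sum((values - mean(values))^2) / (length(values) - 1)),
    sin_dmax = sin(2 * pi * dmax / 365), cos_dmax = cos(2 * pi * dmax / 365),
    sin_dmin = sin(2 * pi * dmin / 365), cos_dmin = cos(2 * pi * dmin / 365))
}

# exhaustive 12-window bioclim oracle for one cell
oracle_bioclim_cell <- function(tmean, tmax, tmin, precip) {
  sums <- sapply(1:12, function(m) sum(precip[(c(m, m + 1, m + 2) - 1) %% 12 + 1]))
  wet <- which.max(sums); dry <- which.min(sums)
  qmean <- function(m) mean(tmean[(c(m, m + 1, m + 2) - 1) %% 12 + 1])
  c(TmWQ = qmean(wet), TmDQ = qmean(dry), TAR = mean(tmax - tmin),
    PpWM = max(precip), PpDM = min(precip),
    PS = 100 * sd(precip) / mean(precip))
}

# all-pairs Mann-Whitney AUC oracle
oracle_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  tot <- 0
  for (a in s1) for (b in s0)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}

# exhaustive ROC-corner threshold oracle
oracle_roc_corner <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- Inf; best_tau <- NA
  for (tau in cand) {
    sens <- mean(scores[labels == 1] >= tau)
    spec <- mean(scores[labels == 0] < tau)
    d <- sqrt((1 - sens)^2 + (1 - spec)^2)
    if (d < best - 1e-12) { best <- d; best_tau <- tau }
  }
  best_tau
}

# Cohen's kappa from the contingency table of two categorical maps
oracle_cohen_kappa <- function(a, b) {
  cats <- sort(unique(c(a, b)))
  po <- mean(a == b)
  pe <- sum(sapply(cats, function(k) mean(a == k) * mean(b == k)))
  (po - pe) / (1 - pe)
}

# direct double-sum Moran's I with queen contiguity, row-standardized
oracle_morans_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  xbar <- mean(m); z <- m - xbar
  num <- 0; w0 <- 0
  for (r in 1:nr) for (c in 1:nc) {
    nbrs <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc)
        nbrs[[length(nbrs) + 1]] <- z[rr, cc]
    }
    k <- length(nbrs)
    for (v in nbrs) { num <- num + z[r, c] * v / k; w0 <- w0 + 1 / k }
  }
  (nr * nc / w0) * num / sum(z^2)
}

# flood-fill 8-neighbour connected components within one block
oracle_patch_sizes <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  seen <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (r0 in 1:nr) for (c0 in 1:nc) {
    if (seen[r0, c0] || is.na(m[r0, c0])) next
    queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE; size <- 0
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]; size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (seen[rr, cc] || is.na(m[rr, cc])) next
        if (m[rr, cc] == m[p[1], p[2]]) {
          seen[rr, cc] <- TRUE
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# synthetic series with a single peak at a chosen day (23 composites)
series_with_peak <- function(peak_doy, base = 0.3, amp = 0.3) {
  doy <- seq(1, 365, by = 16)
  vals <- base + amp * cos(2 * pi * (doy - peak_doy) / 365)
  list(doy = doy, values = vals)
}
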