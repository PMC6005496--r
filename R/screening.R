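#' Spearman rank-correlation matrix of candidate predictors
#'
#' @param features data.frame or matrix of cells x predictors (>= 3 rows).
#' @return symmetric matrix of pairwise Spearman rho (diagonal 1).
#' @export
spearman_matrix <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 3) stop("need at least 3 rows")
  const <- apply(x, 2, function(v) stats::sd(v) == 0 || all(is.na(v)))
  if (any(const))
    stop("constant column(s): ", paste(colnames(x)[const], collapse = ", "))
  stats::cor(x, method = "spearman")
}

#' Variance inflation factors
#'
#' `vif_values()` computes the VIF of each column as `1 / (1 - R2_j)` with
#' `R2_j` from the least-squares regression of column j on all others
#' (perfect collinearity gives `Inf`). `vif_filter()` applies the iterative
#' screening rule: recompute VIFs and drop the largest until all are below
#' the threshold.
#'
#' @param features data.frame or matrix of cells x predictors (rows >
#'   columns).
#' @return `vif_values`: named numeric vector of VIFs.
#' @export
vif_values <- function(features) {
  x <- scale(as.matrix(features))
  if (nrow(x) <= ncol(x)) stop("need more rows than columns")
  vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((x[, j] - mean(x[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(x))
}

#' @rdname vif_values
#' @param threshold VIF threshold (default 4).
#' @return `vif_filter`: list with `kept` (names), `dropped` (names in drop
#'   order), `vif` (final VIFs of the kept columns).
#' @export
vif_filter <- function(features, threshold = 4) {
  x <- as.data.frame(features)
  dropped <- character(0)
  repeat {
    if (ncol(x) < 2) break
    v <- vif_values(x)
    if (all(v < threshold)) break
    worst <- names(v)[which.max(v)]
    dropped <- c(dropped, worst)
    x <- x[, setdiff(colnames(x), worst), drop = FALSE]
  }
  list(kept = colnames(x), dropped = dropped,
       vif = if (ncol(x) >= 2) vif_values(x) else
         stats::setNames(rep(1, ncol(x)), colnames(x)))
}

#' Cross-validated single-predictor AUC priority scores
#'
#' The preliminary-test score used to rank candidates: for each candidate,
#' the k-fold cross-validated AUC of a one-predictor logistic regression on
#' the presence/pseudo-absence data.
#'
#' @param features data.frame of cells x candidates.
#' @param labels 0/1 vector (1 = presence).
#' @param k folds (default 4).
#' @param seed fold-assignment seed.
#' @return named numeric vector of mean CV AUCs.
#' @export
priority_auc <- function(features, labels, k = 4, seed = 1) {
  set.seed(seed)
  n <- length(labels)
  fold <- sample(rep_len(seq_len(k), n))
  vapply(names(features), function(nm) {
    x <- features[[nm]]
    aucs <- vapply(seq_len(k), function(f) {
      tr <- fold != f
      if (length(unique(labels[tr])) < 2 || length(unique(labels[!tr])) < 2)
        return(NA_real_)
      fit <- suppressWarnings(
        stats::glm(labels[tr] ~ x[tr], family = stats::binomial()))
      p <- stats::plogis(cbind(1, x[!tr]) %*% stats::coef(fit))
      auc_mw(as.vector(p), labels[!tr])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
}

#' Screen candidate predictors with the collinearity and sample-size rules
#'
#' Greedy selection by descending priority score, skipping any candidate
#' whose absolute Spearman correlation with an already-selected predictor
#' reaches `rho_threshold`; the survivors then pass an iterative VIF filter;
#' the result is truncated at the cap of `floor(m / 5)` predictors, where `m`
#' is the number of presence records. A pinned list mirrors expert judgement:
#' pinned candidates are selected first (still subject to the cap).
#'
#' @param features data.frame of cells x candidates (the presence +
#'   pseudo-absence cells the models will see).
#' @param m number of presence records.
#' @param priority_scores named numeric vector covering all candidates
#'   (higher = selected earlier), e.g. from [priority_auc()].
#' @param rho_threshold pairwise Spearman cutoff (default 0.8).
#' @param vif_threshold VIF cutoff (default 4).
#' @param pinned character vector of candidate names selected first.
#' @param max_predictors upper bound on the selected set regardless of `m`
#'   (default `Inf`); the study design uses six final predictors per model,
#'   so pipelines pass 6 here while the record cap `floor(m/5)` still binds
#'   for small samples.
#' @return object of class `screening_report`: `selected`, `cap`, `m`,
#'   `spearman_matrix`, `vif` (final VIFs), `reasons` (per-candidate
#'   exclusion reason or "selected").
#' @export
select_predictors <- function(features, m, priority_scores,
                              rho_threshold = 0.8, vif_threshold = 4,
                              pinned = character(0), max_predictors = Inf) {
  cands <- colnames(features)
  if (!length(cands)) stop("no candidate predictors")
  cap <- floor(m / 5)
  if (cap < 1)
    stop("m = ", m, " presence records allow no predictors ",
         "(cap floor(m/5) = 0); at least 5 records are required")
  cap_eff <- min(cap, max_predictors)
  if (!all(cands %in% names(priority_scores)))
    stop("priority scores missing for some candidates")
  rho <- spearman_matrix(features)
  order_names <- c(intersect(pinned, cands),
                   setdiff(cands[order(priority_scores[cands],
                                       decreasing = TRUE)], pinned))
  reasons <- stats::setNames(rep("not reached", length(cands)), cands)
  selected <- character(0)
  for (nm in order_names) {
    if (length(selected) &&
        any(abs(rho[nm, selected]) >= rho_threshold)) {
      clash <- selected[which.max(abs(rho[nm, selected]))]
      reasons[nm] <- sprintf("|rho| >= %.2f with %s", rho_threshold, clash)
      next
    }
    selected <- c(selected, nm)
    reasons[nm] <- "selected"
  }
  if (length(selected) >= 2) {
    vf <- vif_filter(features[, selected, drop = FALSE], vif_threshold)
    for (nm in vf$dropped) reasons[nm] <- sprintf("VIF >= %g", vif_threshold)
    selected <- selected[selected %in% vf$kept]
    final_vif <- vf$vif
  } else {
    final_vif <- stats::setNames(rep(1, length(selected)), selected)
  }
  if (length(selected) > cap_eff) {
    for (nm in selected[-seq_len(cap_eff)])
      reasons[nm] <- sprintf("over cap %d", cap_eff)
    selected <- selected[seq_len(cap_eff)]
  }
  structure(list(selected = selected, cap = cap, m = m,
                 spearman_matrix = rho,
                 vif = final_vif[names(final_vif) %in% selected],
                 priority = priority_scores[cands],
                 reasons = reasons),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("screening: %d/%d candidates selected (cap %d from m = %d)\n",
              length(x$selected), length(x$reasons), x$cap, x$m))
  cat("  ", paste(x$selected, collapse = " "), "\n")
  invisible(x)
}

#' Write a screening report as CSV files
#' @param report a screening_report
#' @param dir output directory
#' @return invisibly, the files written
#' @export
write_screening_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f1 <- file.path(dir, "spearman_matrix.csv")
  utils::write.csv(report$spearman_matrix, f1)
  f2 <- file.path(dir, "selection.csv")
  utils::write.csv(data.frame(
    predictor = names(report$reasons),
    priority = as.numeric(report$priority[names(report$reasons)]),
    vif = as.numeric(report$vif[names(report$reasons)]),
    reason = unname(report$reasons)
  ), f2, row.names = FALSE)
  invisible(c(f1, f2))
}
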