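## Five-metric evaluation suite (localization error, extent AUC, nMSE, PSNR,
## peak-time error) at the instant of maximum seed activity, plus one-way
## ANOVA and Tukey HSD comparison of methods.

#' Evaluation instant of a ground-truth seed region
#'
#' `t0 = argmax_t |X[seed, t]|` (first index on ties).
#'
#' @param X Nr x T ground-truth source matrix.
#' @param seed_region region row index.
#' @return integer time index.
#' @export
evaluation_instant <- function(X, seed_region) {
  row <- abs(X[seed_region, ])
  if (all(row == 0)) stopf("seed region has an all-zero row")
  which.max(row)
}

#' Localization error (mm)
#'
#' Euclidean distance between the positions of the maximum-|amplitude|
#' entries of the true and estimated source columns.
#'
#' @param x_col,xhat_col length-Nr amplitude columns at the evaluation
#'   instant.
#' @param positions Nr x 3 region centroid coordinates (mm).
#' @return distance in mm; an all-zero estimate is flagged (attribute
#'   `"degenerate"`) and measured against the first region.
#' @export
localization_error <- function(x_col, xhat_col, positions) {
  if (all(x_col == 0)) stopf("all-zero ground-truth column")
  s <- which.max(abs(x_col))
  degenerate <- all(xhat_col == 0)
  s_hat <- if (degenerate) 1L else which.max(abs(xhat_col))
  structure(sqrt(sum((positions[s, ] - positions[s_hat, ])^2)),
            degenerate = degenerate)
}

#' Extent AUC (%)
#'
#' Area under the ROC curve of the max-normalized absolute estimated
#' amplitudes against active-region membership, swept over all unique score
#' thresholds (trapezoidal; equivalent to the rank/Mann-Whitney AUC with
#' midrank tie handling). Reported in percent.
#'
#' @param x_col true column (unused except via `active_members`; kept for a
#'   uniform metric signature).
#' @param xhat_col estimated column.
#' @param active_members indices of truly active regions.
#' @return AUC in `[0, 100]`.
#' @export
extent_auc <- function(x_col, xhat_col, active_members) {
  n <- length(xhat_col)
  labels <- seq_len(n) %in% active_members
  if (all(labels) || !any(labels)) stopf("need both active and inactive regions")
  m <- max(abs(xhat_col))
  scores <- if (m > 0) abs(xhat_col) / m else rep(0, n)
  # ROC over all unique thresholds, trapezoid under (FPR, TPR)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  fp <- cumsum(!lab)
  last_of_block <- c(sc[-1] != sc[-n], TRUE)  # collapse tied scores
  tpr <- c(0, tp[last_of_block]) / sum(labels)
  fpr <- c(0, fp[last_of_block]) / sum(!labels)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  100 * auc
}

#' Normalized mean squared error at one instant
#'
#' Mean squared difference of the two columns after each full matrix is
#' scaled by its own global maximum absolute amplitude; positive rescaling
#' of either argument therefore cancels.
#'
#' @param x_col,xhat_col columns at the evaluation instant.
#' @param x_max,xhat_max global normalizers `max(|X|)`, `max(|X_hat|)`
#'   (default: the column maxima, appropriate when the column is the whole
#'   matrix).
#' @return non-negative scalar.
#' @export
nmse <- function(x_col, xhat_col, x_max = max(abs(x_col)),
                 xhat_max = max(abs(xhat_col))) {
  if (x_max == 0 || xhat_max == 0) stopf("zero normalizer in nMSE")
  mean((x_col / x_max - xhat_col / xhat_max)^2)
}

#' Peak signal-to-noise ratio (dB) over the whole epoch
#'
#' `10 log10(max(X_tilde)^2 / MSE(X_tilde, X_hat_tilde))` with both
#' matrices max-|amplitude| normalized; a perfect reconstruction is capped.
#'
#' @param X,X_hat Nr x T matrices.
#' @param cap_db cap for MSE = 0.
#' @return PSNR in dB.
#' @export
psnr <- function(X, X_hat, cap_db = 300) {
  mx <- max(abs(X))
  mh <- max(abs(X_hat))
  if (mx == 0) stopf("zero-signal ground truth")
  Xt <- X / mx
  Ht <- if (mh > 0) X_hat / mh else X_hat
  mse <- mean((Xt - Ht)^2)
  if (mse == 0) return(cap_db)
  min(cap_db, 10 * log10(max(Xt)^2 / mse))
}

#' Peak-time error (ms)
#'
#' Absolute difference between the instants of maximum summed absolute
#' amplitude, `t_max = argmax_t sum_i |X[i, t]|`, of truth and estimate.
#'
#' @param X,X_hat Nr x T matrices.
#' @param fs sampling rate (Hz).
#' @return error in ms; an all-zero estimate is flagged and scored with the
#'   full epoch length.
#' @export
time_error <- function(X, X_hat, fs) {
  if (all(X == 0)) stopf("all-zero ground truth")
  t1 <- which.max(colSums(abs(X)))
  if (all(X_hat == 0)) {
    return(structure(ncol(X) * 1000 / fs, degenerate = TRUE))
  }
  t2 <- which.max(colSums(abs(X_hat)))
  structure(abs(t1 - t2) * 1000 / fs, degenerate = FALSE)
}

# local maxima of |column| over the region adjacency graph
graph_local_maxima <- function(col, adjacency) {
  a <- abs(col)
  which(vapply(seq_along(a), function(i) {
    nb <- which(adjacency[i, ])
    length(nb) == 0 || all(a[i] >= a[nb])
  }, TRUE) & a > 0)
}

#' Evaluate one inverse solution against its ground truth
#'
#' Computes the five metrics of the suite. LE, AUC and nMSE are evaluated
#' at the instant of maximum seed activity (averaged over the per-seed
#' instants for multi-source samples), PSNR over the whole epoch and the
#' peak-time error from the summed absolute amplitude. For multi-source
#' samples each ground-truth seed is greedily matched to its nearest
#' estimated graph-local maximum (`le_mode = "greedy"`); the strict
#' single-global-maximum definition is available with `le_mode = "global"`.
#'
#' @param sample an `esi_sample`.
#' @param solution an `esi_solution` (or Nr x T matrix).
#' @param head the `esi_head` the sample was simulated on.
#' @param le_mode `"greedy"` or `"global"`.
#' @return a one-row `data.frame`: method, t0 (s), le_mm, auc_pct, nmse,
#'   psnr_db, time_error_ms, degenerate flag.
#' @export
evaluate_sample <- function(sample, solution, head,
                            le_mode = c("greedy", "global")) {
  le_mode <- match.arg(le_mode)
  X_hat <- if (inherits(solution, "esi_solution")) solution$X_hat
    else as.matrix(solution)
  method <- if (inherits(solution, "esi_solution")) solution$method else "matrix"
  X <- sample$X
  stopifnot(all(dim(X) == dim(X_hat)))
  centroids <- head$region_centroids
  seeds <- vapply(sample$active_regions, `[[`, 0, "seed")
  members <- sort(unique(unlist(lapply(sample$active_regions, `[[`,
                                       "members"))))
  t0s <- vapply(seeds, function(s) evaluation_instant(X, s), 0L)
  degenerate <- all(X_hat == 0)

  le_vals <- numeric(length(seeds))
  auc_vals <- numeric(length(seeds))
  nmse_vals <- numeric(length(seeds))
  x_max <- max(abs(X)); xh_max <- max(abs(X_hat))
  for (k in seq_along(seeds)) {
    t0 <- t0s[k]
    col_hat <- X_hat[, t0]
    if (le_mode == "global" || length(seeds) == 1 || degenerate) {
      le_vals[k] <- localization_error(X[, t0], col_hat, centroids)
    } else {
      peaks <- graph_local_maxima(col_hat, head$region_adjacency)
      if (length(peaks) == 0) peaks <- which.max(abs(col_hat))
      # keep the strongest local maximum per true source: spurious minor
      # peaks of a diffuse estimate must not be rewarded
      if (length(peaks) > length(seeds))
        peaks <- peaks[order(abs(col_hat[peaks]),
                             decreasing = TRUE)][seq_along(seeds)]
      # greedy: strongest true seeds claim their nearest estimated peak
      ord <- order(abs(X[cbind(seeds, t0s)]), decreasing = TRUE)
      claimed <- integer(0)
      d_k <- NA_real_
      for (kk in ord) {
        avail <- setdiff(peaks, claimed)
        if (length(avail) == 0) avail <- peaks
        d <- sqrt(rowSums((centroids[avail, , drop = FALSE] -
                             matrix(centroids[seeds[kk], ], length(avail), 3,
                                    byrow = TRUE))^2))
        pick <- avail[which.min(d)]
        claimed <- c(claimed, pick)
        if (kk == k) d_k <- min(d)
      }
      le_vals[k] <- d_k
    }
    auc_vals[k] <- if (length(members) >= length(col_hat)) NA_real_
      else if (max(abs(col_hat)) == 0) 50
      else extent_auc(X[, t0], col_hat, members)
    nmse_vals[k] <- if (xh_max == 0) mean((X[, t0] / x_max)^2)
      else nmse(X[, t0], X_hat[, t0], x_max, xh_max)
  }
  te <- time_error(X, X_hat, sample$fs)
  data.frame(method = method,
             t0 = (t0s[1] - 1) / sample$fs,
             le_mm = mean(le_vals),
             # NA when every region is active (extent undefined on very
             # small parcellations with high growth orders)
             auc_pct = if (all(is.na(auc_vals))) NA_real_
               else mean(auc_vals, na.rm = TRUE),
             nmse = mean(nmse_vals),
             psnr_db = psnr(X, X_hat),
             time_error_ms = as.numeric(te),
             degenerate = degenerate || isTRUE(attr(te, "degenerate")))
}

#' Evaluate a set of solutions over a dataset split
#'
#' @param dataset an `esi_dataset`.
#' @param solutions named list (by method) of lists of `esi_solution`s,
#'   aligned with `idx`.
#' @param head the head model.
#' @param idx sample indices (default the validation split).
#' @param ... passed to [evaluate_sample()].
#' @return a `data.frame` of per-sample metric rows.
#' @export
evaluate_solutions <- function(dataset, solutions, head,
                               idx = dataset$val_idx, ...) {
  rows <- list()
  for (method in names(solutions)) {
    sols <- solutions[[method]]
    for (j in seq_along(idx)) {
      row <- evaluate_sample(dataset$samples[[idx[j]]], sols[[j]], head, ...)
      row$method <- method
      row$sample <- idx[j]
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Compare methods with one-way ANOVA and Tukey HSD
#'
#' For each metric, a one-way ANOVA of the per-sample values across methods
#' followed by Tukey's honest significant difference test for pairwise
#' adjusted p-values.
#'
#' @param reports data frame from [evaluate_solutions()] (needs `method`
#'   plus metric columns).
#' @param metrics metric column names.
#' @return an `esi_comparison`: per-metric list with `f`, `p` and a
#'   `tukey` data frame of pairwise adjusted p-values.
#' @export
compare_methods <- function(reports,
                            metrics = c("le_mm", "auc_pct", "nmse",
                                        "psnr_db", "time_error_ms")) {
  methods <- unique(reports$method)
  if (length(methods) < 2) stopf("need at least two methods to compare")
  counts <- table(reports$method)
  if (any(counts < 2)) stopf("every method needs at least two samples")
  out <- list()
  for (m in metrics) {
    df <- data.frame(value = reports[[m]],
                     method = factor(reports$method))
    df <- df[is.finite(df$value), ]
    if (stats::var(df$value) == 0) {
      pairs_ <- t(utils::combn(levels(df$method), 2))
      out[[m]] <- list(f = 0, p = 1,
                       tukey = data.frame(pair = paste(pairs_[, 2],
                                                       pairs_[, 1],
                                                       sep = "-"),
                                          diff = 0, p_adj = 1))
      next
    }
    fit <- aov(value ~ method, data = df)
    an <- summary(fit)[[1]]
    tk <- TukeyHSD(fit)$method
    out[[m]] <- list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                     tukey = data.frame(pair = rownames(tk),
                                        diff = tk[, "diff"],
                                        p_adj = tk[, "p adj"]))
  }
  structure(list(metrics = out, methods = methods), class = "esi_comparison")
}

#' @export
print.esi_comparison <- function(x, ...) {
  cat("Method comparison (one-way ANOVA + Tukey HSD)\n")
  for (m in names(x$metrics)) {
    cat(sprintf("  %-14s F = %8.2f  p = %.3g\n", m, x$metrics[[m]]$f,
                x$metrics[[m]]$p))
  }
  invisible(x)
}
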