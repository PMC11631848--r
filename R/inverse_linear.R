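## Non-learning baselines: regularized minimum-norm estimation (MNE) and its
## standardized variant (sLORETA).
##
## Both act in the dual (sensor) space: K = L' (L L' + lam I)^-1, X_hat = K Y.
## The user-facing regularization weight is unitless; internally it is scaled
## by the mean sensor-space eigenvalue trace(L L')/Ne so that a given lambda
## transfers across head models. The "auto" rule maps an assumed sensor SNR
## (dB) to lambda = 1/SNR_linear, the standard minimum-norm heuristic.

resolve_lambda <- function(lambda, snr_assumed_db) {
  if (identical(lambda, "auto")) lambda <- 10^(-snr_assumed_db / 10)
  check_number(lambda, "lambda")
  if (lambda < 0) stopf("lambda must be >= 0")
  lambda
}

mn_kernel <- function(L, lambda) {
  ne <- nrow(L)
  gram <- tcrossprod(L)
  lam_scaled <- lambda * sum(diag(gram)) / ne
  G <- gram + diag(lam_scaled, ne)
  ok <- tryCatch({chol(G); TRUE}, error = function(e) FALSE)
  if (!ok)
    stopf("singular sensor-space system: lambda = 0 with fewer electrodes than sources requires regularization")
  list(K = t(solve(G, L)), lam_scaled = lam_scaled)  # K: Ns x Ne
}

new_esi_solution <- function(X_hat, method, config, extra = list()) {
  structure(c(list(X_hat = X_hat, method = method, config = config,
                   t_solve = Sys.time()), extra),
            class = "esi_solution")
}

#' Minimum-norm estimate (MNE)
#'
#' Tikhonov-regularized least squares with an l2 penalty on the sources,
#' solved in the dual form `X_hat = L'(LL' + lambda_scaled I)^-1 Y`.
#'
#' @param L Ne x Ns (regional) leadfield.
#' @param Y Ne x T EEG matrix (V).
#' @param lambda unitless regularization weight (>= 0) or `"auto"`.
#' @param snr_assumed_db assumed sensor SNR (dB) used by the `"auto"` rule
#'   `lambda = 10^(-SNR/10)`.
#' @return an `esi_solution` with the Ns x T estimate in `$X_hat`.
#' @export
mne_solve <- function(L, Y, lambda = "auto", snr_assumed_db = 5) {
  Y <- as.matrix(Y)
  if (nrow(L) != nrow(Y)) stopf("L and Y disagree on the electrode count")
  lambda <- resolve_lambda(lambda, snr_assumed_db)
  k <- mn_kernel(L, lambda)
  new_esi_solution(k$K %*% Y, "mne",
                   list(lambda = lambda, lambda_scaled = k$lam_scaled,
                        snr_assumed_db = snr_assumed_db))
}

#' sLORETA: standardized minimum-norm estimate
#'
#' Rescales the MNE estimate by the square root of the diagonal of its
#' resolution operator `S = KL`: `X_slor[j,] = X_mne[j,] / sqrt(S_jj)`. For a
#' noiseless single active source this standardization is exact: the largest
#' standardized amplitude sits at the true source (zero localization error).
#'
#' @inheritParams mne_solve
#' @return an `esi_solution`; sources with a null leadfield column
#'   (`S_jj = 0`) are excluded (rows set to 0) and listed in `$excluded`.
#' @export
sloreta_solve <- function(L, Y, lambda = "auto", snr_assumed_db = 5) {
  Y <- as.matrix(Y)
  if (nrow(L) != nrow(Y)) stopf("L and Y disagree on the electrode count")
  lambda <- resolve_lambda(lambda, snr_assumed_db)
  if (lambda <= 0) stopf("sLORETA requires lambda > 0")
  k <- mn_kernel(L, lambda)
  s_diag <- rowSums(k$K * t(L))  # diag(K L)
  excluded <- which(s_diag <= 0)
  scale <- ifelse(s_diag > 0, 1 / sqrt(pmax(s_diag, 1e-300)), 0)
  if (length(excluded))
    warning(sprintf("%d null leadfield column(s) excluded from sLORETA",
                    length(excluded)))
  new_esi_solution((k$K %*% Y) * scale, "sloreta",
                   list(lambda = lambda, lambda_scaled = k$lam_scaled,
                        snr_assumed_db = snr_assumed_db),
                   list(excluded = excluded))
}

#' @export
print.esi_solution <- function(x, ...) {
  cat(sprintf("ESI solution (%s): %d sources x %d time points\n",
              x$method, nrow(x$X_hat), ncol(x$X_hat)))
  if (!is.null(x$config$lambda))
    cat(sprintf("  lambda = %.4g (scaled %.4g)\n",
                x$config$lambda, x$config$lambda_scaled))
  invisible(x)
}
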