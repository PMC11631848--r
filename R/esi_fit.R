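## Umbrella modelling interface: one fitting function returning a classed
## object with the usual method set, covering both the closed-form linear
## solvers (nothing to train; the regularized kernel is the "fit") and the
## trainable networks.

#' Fit an ESI inverse operator
#'
#' Single entry point over the five methods of the benchmark. For
#' `"mne"`/`"sloreta"` the fit stores the head model and regularization
#' (solutions are closed-form); for `"cnn1d"`/`"lstm"`/`"deepsif"` the
#' network is built and trained on the supplied dataset.
#'
#' @param method method name.
#' @param head an `esi_head`.
#' @param dataset an `esi_dataset` (required for network methods).
#' @param train_cfg a [train_config()].
#' @param arch an optional [architecture_spec()] overriding the default
#'   architecture of `method`.
#' @param lambda,snr_assumed_db regularization controls for the linear
#'   methods.
#' @param init_seed weight-initialization seed for networks.
#' @return an `esi_fit` with `predict`, `print`, `summary`, `coef` and
#'   `residuals` methods.
#' @export
esi_fit <- function(method = c("mne", "sloreta", "cnn1d", "lstm", "deepsif"),
                    head, dataset = NULL, train_cfg = train_config(),
                    arch = NULL, lambda = "auto", snr_assumed_db = 5,
                    init_seed = 1) {
  method <- match.arg(method)
  obj <- list(method = method, head = head)
  if (method %in% c("mne", "sloreta")) {
    obj$lambda <- lambda
    obj$snr_assumed_db <- snr_assumed_db
  } else {
    if (is.null(dataset)) stopf("network methods require a dataset")
    if (is.null(arch))
      arch <- architecture_spec(method,
                                n_electrodes = nrow(head$electrode_positions),
                                n_sources = ncol(head$leadfield_regional))
    net <- build_model(arch, init_seed = init_seed)
    obj$net <- esi_train(net, dataset, train_cfg)
  }
  structure(obj, class = "esi_fit")
}

#' @export
predict.esi_fit <- function(object, Y, ...) {
  L <- object$head$leadfield_regional
  switch(object$method,
    mne = mne_solve(L, Y, object$lambda, object$snr_assumed_db),
    sloreta = sloreta_solve(L, Y, object$lambda, object$snr_assumed_db),
    predict(object$net, Y, L))
}

#' @export
print.esi_fit <- function(x, ...) {
  cat(sprintf("esi_fit: %s on %d-electrode / %d-region head\n", x$method,
              nrow(x$head$electrode_positions),
              ncol(x$head$leadfield_regional)))
  if (!is.null(x$net)) print(x$net)
  invisible(x)
}

#' @export
summary.esi_fit <- function(object, ...) {
  print(object)
  if (!is.null(object$net$history)) {
    h <- object$net$history
    cat(sprintf("  trained %d epoch(s); final train loss %.4f, best val loss %.4f\n",
                nrow(h), h$train_loss[nrow(h)], min(h$val_loss)))
  }
  invisible(object)
}

#' @export
coef.esi_fit <- function(object, ...) {
  if (object$method %in% c("mne", "sloreta")) {
    lambda <- resolve_lambda(object$lambda, object$snr_assumed_db)
    mn_kernel(object$head$leadfield_regional, lambda)$K
  } else {
    object$net$params
  }
}

#' @export
residuals.esi_fit <- function(object, Y, ...) {
  sol <- predict(object, Y)
  Y - object$head$leadfield_regional %*% sol$X_hat
}

#' @export
plot.esi_fit <- function(x, ...) {
  if (!is.null(x$net$history)) {
    h <- x$net$history
    graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                      lty = 1, col = c("black", "red"), xlab = "epoch",
                      ylab = "cosine loss", main = x$method, ...)
    graphics::legend("topright", c("train", "validation"), lty = 1,
                     col = c("black", "red"), bty = "n")
  } else {
    ev <- svd(x$head$leadfield_regional, nu = 0, nv = 0)$d
    plot(ev, log = "y", xlab = "index", ylab = "singular value",
         main = sprintf("%s: leadfield spectrum", x$method), ...)
  }
  invisible(x)
}
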