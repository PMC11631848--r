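## Learned inverse operators: a wide 1D-CNN, a two-layer bidirectional LSTM
## and a deepSIF-style spatial/temporal network, trained with a
## cosine-similarity loss on amplitude-normalized pairs and rescaled to
## physical units with global-field-power (GFP) scaling.

#' Normalize a (source, EEG) pair by the EEG peak amplitude
#'
#' Both matrices are divided by `alpha = max(|Y|)`, which preserves the
#' linear forward relationship between them.
#'
#' @param X Ns x T source matrix.
#' @param Y Ne x T EEG matrix, not all zero.
#' @return list with `X_tilde`, `Y_tilde`, `alpha`.
#' @export
normalize_pair <- function(X, Y) {
  alpha <- max(abs(Y))
  if (alpha == 0) stopf("cannot normalize an all-zero EEG matrix")
  list(X_tilde = X / alpha, Y_tilde = Y / alpha, alpha = alpha)
}

#' Cosine-similarity loss
#'
#' Negative mean cosine similarity of the per-time-point source patterns:
#' `-(1/T) sum_t cos(X[, t], X_hat[, t])`; lower is better, with minimum -1
#' exactly when every column pair is positively proportional. Columns where
#' either argument has zero norm contribute 0 and are counted in the
#' `"guarded_columns"` attribute.
#'
#' @param X,X_hat Ns x T matrices.
#' @return scalar in `[-1, 1]`.
#' @export
cosine_loss <- function(X, X_hat) {
  nx <- sqrt(colSums(X^2))
  np <- sqrt(colSums(X_hat^2))
  ok <- nx > 0 & np > 0
  cs <- numeric(ncol(X))
  cs[ok] <- colSums(X[, ok, drop = FALSE] * X_hat[, ok, drop = FALSE]) /
    (nx[ok] * np[ok])
  structure(-mean(cs), guarded_columns = sum(!ok))
}

# loss and gradient w.r.t. predictions over a batch (3D arrays)
cosine_loss_grad <- function(target, pred) {
  Tm <- mat3(target)
  Pm <- mat3(pred)
  nx <- sqrt(colSums(Tm^2))
  np <- sqrt(colSums(Pm^2))
  ok <- nx > 0 & np > 0
  n_col <- ncol(Tm)
  cs <- numeric(n_col)
  dP <- matrix(0, nrow(Pm), n_col)
  if (any(ok)) {
    Tn <- Tm[, ok, drop = FALSE]
    Pn <- Pm[, ok, drop = FALSE]
    ip <- colSums(Tn * Pn)
    cs[ok] <- ip / (nx[ok] * np[ok])
    dP[, ok] <- -(sweep(Tn, 2, nx[ok] * np[ok], "/") -
                    sweep(Pn, 2, ip / (nx[ok] * np[ok]^3), "*")) / n_col
  }
  list(loss = -mean(cs), grad = arr3(dP, dim(pred)[2], dim(pred)[3]))
}

#' Global-field-power rescaling of a normalized source estimate
#'
#' Restores physical amplitudes after cosine-loss training: each time column
#' is scaled by `std(Y[, t]) / std((L X_hat_tilde)[, t])` (standard
#' deviation over electrodes), so the re-projected estimate matches the
#' measured global field power at every instant. Columns whose re-projection
#' has zero variance keep scale 1 and are flagged.
#'
#' @param X_hat_tilde Ns x T normalized estimate.
#' @param Y Ne x T measured EEG (unnormalized).
#' @param L Ne x Ns leadfield.
#' @return Ns x T rescaled estimate with attribute `"flagged_columns"`.
#' @export
gfp_rescale <- function(X_hat_tilde, Y, L) {
  Yp <- L %*% X_hat_tilde
  sd_pop <- function(M) sqrt(colMeans(sweep(M, 2, colMeans(M))^2))
  s_y <- sd_pop(Y)
  s_p <- sd_pop(Yp)
  flagged <- which(s_p <= 0)
  scale <- ifelse(s_p > 0, s_y / pmax(s_p, 1e-300), 1)
  structure(sweep(X_hat_tilde, 2, scale, "*"), flagged_columns = flagged)
}

#' Architecture specification for a learned inverse operator
#'
#' @param kind one of `"cnn1d"`, `"lstm"`, `"deepsif"`.
#' @param n_electrodes,n_sources input/output spatial dimensions.
#' @param cnn_filters,cnn_kernel_t 1D-CNN: filter count and temporal kernel
#'   span (the spatial extent of the kernel is always all electrodes).
#' @param lstm_hidden,lstm_layers,lstm_dropout bi-LSTM: per-direction hidden
#'   size, layer count, inter-layer dropout rate.
#' @param deepsif_feature_dim deepSIF: lifted spatial feature dimension.
#' @return an `esi_arch` list.
#' @export
architecture_spec <- function(kind = c("cnn1d", "lstm", "deepsif"),
                              n_electrodes, n_sources,
                              cnn_filters = 2048, cnn_kernel_t = 5,
                              lstm_hidden = 85, lstm_layers = 2,
                              lstm_dropout = 0.2,
                              deepsif_feature_dim = 500) {
  kind <- match.arg(kind)
  stopifnot(n_electrodes > 0, n_sources > 0, cnn_filters > 0,
            cnn_kernel_t > 0, lstm_hidden > 0, lstm_layers > 0,
            lstm_dropout >= 0, lstm_dropout < 1, deepsif_feature_dim > 0)
  structure(list(kind = kind, n_electrodes = n_electrodes,
                 n_sources = n_sources, cnn_filters = cnn_filters,
                 cnn_kernel_t = cnn_kernel_t, lstm_hidden = lstm_hidden,
                 lstm_layers = lstm_layers, lstm_dropout = lstm_dropout,
                 deepsif_feature_dim = deepsif_feature_dim),
            class = "esi_arch")
}

#' Instantiate a learnable inverse operator
#'
#' Builds the parameter set of the requested architecture and reports the
#' layer list and parameter count. The operator maps an Ne x T EEG matrix to
#' an Ns x T source estimate for any T not shorter than the temporal kernel.
#'
#' @param spec an [architecture_spec()].
#' @param init_seed seed for weight initialization (uniform
#'   `+-1/sqrt(fan_in)`).
#' @return an `esi_net`.
#' @export
build_model <- function(spec, init_seed = 1) {
  stopifnot(inherits(spec, "esi_arch"))
  ne <- spec$n_electrodes; ns <- spec$n_sources
  params <- with_seed(init_seed, switch(spec$kind,
    cnn1d = {
      fan1 <- ne * spec$cnn_kernel_t
      list(W1 = init_mat(spec$cnn_filters, fan1),
           b1 = init_vec(spec$cnn_filters, fan1),
           W2 = init_mat(ns, spec$cnn_filters),
           b2 = init_vec(ns, spec$cnn_filters))
    },
    lstm = {
      h <- spec$lstm_hidden
      p <- list()
      d_in <- ne
      for (l in seq_len(spec$lstm_layers)) {
        fw <- init_lstm(d_in, h); bw <- init_lstm(d_in, h)
        p[[paste0("l", l, "f_Wx")]] <- fw$Wx
        p[[paste0("l", l, "f_Wh")]] <- fw$Wh
        p[[paste0("l", l, "f_b")]] <- fw$b
        p[[paste0("l", l, "b_Wx")]] <- bw$Wx
        p[[paste0("l", l, "b_Wh")]] <- bw$Wh
        p[[paste0("l", l, "b_b")]] <- bw$b
        d_in <- 2 * h
      }
      p$W_out <- init_mat(ns, 2 * h)
      p$b_out <- init_vec(ns, 2 * h)
      p
    },
    deepsif = {
      f <- spec$deepsif_feature_dim
      p <- list(W11 = init_mat(ne, ne), b11 = init_vec(ne, ne),
                W12 = init_mat(ne, ne), b12 = init_vec(ne, ne),
                W21 = init_mat(f, ne), b21 = init_vec(f, ne),
                W22 = init_mat(f, f), b22 = init_vec(f, f),
                Ws = init_mat(f, ne), bs = init_vec(f, ne),
                W3 = init_mat(f, f), b3 = init_vec(f, f))
      dims <- c(f, ns, ns, ns)
      for (l in 1:3) {
        lst <- init_lstm(dims[l], dims[l + 1])
        p[[paste0("t", l, "_Wx")]] <- lst$Wx
        p[[paste0("t", l, "_Wh")]] <- lst$Wh
        p[[paste0("t", l, "_b")]] <- lst$b
      }
      p
    }))
  n_par <- sum(vapply(params, length, 0L))
  layers <- switch(spec$kind,
    cnn1d = c(sprintf("temporal conv: %d filters, kernel %d x %d, ReLU",
                      spec$cnn_filters, ne, spec$cnn_kernel_t),
              sprintf("dense %d -> %d per time step", spec$cnn_filters, ns)),
    lstm = c(sprintf("%d bidirectional LSTM layer(s), hidden %d/direction, dropout %.2g",
                     spec$lstm_layers, spec$lstm_hidden, spec$lstm_dropout),
             sprintf("ReLU + dense %d -> %d per time step",
                     2 * spec$lstm_hidden, ns)),
    deepsif = c(sprintf("spatial: residual block %d -> %d, residual block %d -> %d (dense skip), dense %d -> %d, ELU",
                        ne, ne, ne, f <- spec$deepsif_feature_dim, f, f),
                sprintf("temporal: 3 LSTM layers, hidden %d", ns)))
  structure(list(spec = spec, params = params, init_seed = init_seed,
                 n_parameters = n_par, layers = layers, trained = FALSE,
                 history = NULL),
            class = "esi_net")
}

#' @export
print.esi_net <- function(x, ...) {
  cat(sprintf("esi_net (%s): %d electrodes -> %d sources, %s parameters%s\n",
              x$spec$kind, x$spec$n_electrodes, x$spec$n_sources,
              format(x$n_parameters, big.mark = ","),
              if (x$trained) " [trained]" else ""))
  for (l in x$layers) cat("  -", l, "\n")
  if (!is.null(x$history))
    cat(sprintf("  best validation loss %.4f at epoch %d of %d\n",
                min(x$history$val_loss), which.min(x$history$val_loss),
                nrow(x$history)))
  invisible(x)
}

## ---- forward / backward per architecture -------------------------------

net_forward <- function(model, Y3, training = FALSE) {
  p <- model$params
  spec <- model$spec
  switch(spec$kind,
    cnn1d = {
      emb <- lag_embed_fwd(Y3, spec$cnn_kernel_t)
      d1 <- dense_fwd(p$W1, p$b1, emb$out)
      r1 <- relu_fwd(d1$out)
      d2 <- dense_fwd(p$W2, p$b2, r1$out)
      list(out = d2$out, cache = list(emb = emb, d1 = d1, r1 = r1, d2 = d2))
    },
    lstm = {
      x <- Y3
      caches <- list()
      for (l in seq_len(spec$lstm_layers)) {
        fw <- lstm_fwd(p[[paste0("l", l, "f_Wx")]],
                       p[[paste0("l", l, "f_Wh")]],
                       p[[paste0("l", l, "f_b")]], x)
        bw <- lstm_fwd(p[[paste0("l", l, "b_Wx")]],
                       p[[paste0("l", l, "b_Wh")]],
                       p[[paste0("l", l, "b_b")]], rev_time(x))
        h <- array(0, c(2 * spec$lstm_hidden, dim(x)[2], dim(x)[3]))
        h[seq_len(spec$lstm_hidden), , ] <- fw$out
        h[-seq_len(spec$lstm_hidden), , ] <- rev_time(bw$out)
        drp <- if (l < spec$lstm_layers)
          dropout_fwd(h, spec$lstm_dropout, training)
        else list(out = h, mask = NULL)
        caches[[l]] <- list(fw = fw, bw = bw, drp = drp)
        x <- drp$out
      }
      r <- relu_fwd(x)
      d <- dense_fwd(p$W_out, p$b_out, r$out)
      list(out = d$out, cache = list(layers = caches, r = r, d = d))
    },
    deepsif = {
      d11 <- dense_fwd(p$W11, p$b11, Y3); e11 <- elu_fwd(d11$out)
      d12 <- dense_fwd(p$W12, p$b12, e11$out); e12 <- elu_fwd(d12$out)
      o1 <- e12$out + Y3
      d21 <- dense_fwd(p$W21, p$b21, o1); e21 <- elu_fwd(d21$out)
      d22 <- dense_fwd(p$W22, p$b22, e21$out); e22 <- elu_fwd(d22$out)
      dsk <- dense_fwd(p$Ws, p$bs, o1)
      o2 <- e22$out + dsk$out
      d3 <- dense_fwd(p$W3, p$b3, o2); e3 <- elu_fwd(d3$out)
      x <- e3$out
      tc <- list()
      for (l in 1:3) {
        lst <- lstm_fwd(p[[paste0("t", l, "_Wx")]],
                        p[[paste0("t", l, "_Wh")]],
                        p[[paste0("t", l, "_b")]], x)
        tc[[l]] <- lst
        x <- lst$out
      }
      list(out = x,
           cache = list(d11 = d11, e11 = e11, d12 = d12, e12 = e12,
                        d21 = d21, e21 = e21, d22 = d22, e22 = e22,
                        dsk = dsk, d3 = d3, e3 = e3, tc = tc))
    })
}

net_backward <- function(model, fwd, dOut) {
  p <- model$params
  spec <- model$spec
  cc <- fwd$cache
  g <- list()
  switch(spec$kind,
    cnn1d = {
      b2 <- dense_bwd(p$W2, dOut, cc$d2)
      dr <- relu_bwd(b2$dX, cc$r1)
      b1 <- dense_bwd(p$W1, dr, cc$d1)
      g$W2 <- b2$dW; g$b2 <- b2$db
      g$W1 <- b1$dW; g$b1 <- b1$db
      g
    },
    lstm = {
      bd <- dense_bwd(p$W_out, dOut, cc$d)
      g$W_out <- bd$dW; g$b_out <- bd$db
      dx <- relu_bwd(bd$dX, cc$r)
      for (l in rev(seq_len(spec$lstm_layers))) {
        lc <- cc$layers[[l]]
        dx <- dropout_bwd(dx, lc$drp)
        h <- spec$lstm_hidden
        dfw <- dx[seq_len(h), , , drop = FALSE]
        dbw <- rev_time(dx[-seq_len(h), , , drop = FALSE])
        bf <- lstm_bwd(p[[paste0("l", l, "f_Wx")]],
                       p[[paste0("l", l, "f_Wh")]], lc$fw, dfw)
        bb <- lstm_bwd(p[[paste0("l", l, "b_Wx")]],
                       p[[paste0("l", l, "b_Wh")]], lc$bw, dbw)
        g[[paste0("l", l, "f_Wx")]] <- bf$dWx
        g[[paste0("l", l, "f_Wh")]] <- bf$dWh
        g[[paste0("l", l, "f_b")]] <- bf$db
        g[[paste0("l", l, "b_Wx")]] <- bb$dWx
        g[[paste0("l", l, "b_Wh")]] <- bb$dWh
        g[[paste0("l", l, "b_b")]] <- bb$db
        dx <- bf$dX + rev_time(bb$dX)
      }
      g
    },
    deepsif = {
      dx <- dOut
      for (l in 3:1) {
        bl <- lstm_bwd(p[[paste0("t", l, "_Wx")]],
                       p[[paste0("t", l, "_Wh")]], cc$tc[[l]], dx)
        g[[paste0("t", l, "_Wx")]] <- bl$dWx
        g[[paste0("t", l, "_Wh")]] <- bl$dWh
        g[[paste0("t", l, "_b")]] <- bl$db
        dx <- bl$dX
      }
      de3 <- elu_bwd(dx, cc$e3)
      b3 <- dense_bwd(p$W3, de3, cc$d3)
      g$W3 <- b3$dW; g$b3 <- b3$db
      do2 <- b3$dX
      de22 <- elu_bwd(do2, cc$e22)
      b22 <- dense_bwd(p$W22, de22, cc$d22)
      g$W22 <- b22$dW; g$b22 <- b22$db
      de21 <- elu_bwd(b22$dX, cc$e21)
      b21 <- dense_bwd(p$W21, de21, cc$d21)
      g$W21 <- b21$dW; g$b21 <- b21$db
      bsk <- dense_bwd(p$Ws, do2, cc$dsk)
      g$Ws <- bsk$dW; g$bs <- bsk$db
      do1 <- b21$dX + bsk$dX
      de12 <- elu_bwd(do1, cc$e12)
      b12 <- dense_bwd(p$W12, de12, cc$d12)
      g$W12 <- b12$dW; g$b12 <- b12$db
      de11 <- elu_bwd(b12$dX, cc$e11)
      b11 <- dense_bwd(p$W11, de11, cc$d11)
      g$W11 <- b11$dW; g$b11 <- b11$db
      g
    })
}

## ---- training ----------------------------------------------------------

#' Training configuration
#'
#' Adam with default moments, the study's batch size of 8, an epoch budget
#' of 500 with early stopping after 20 epochs without validation
#' improvement, and gradient-norm clipping for LSTM training.
#'
#' @param batch_size mini-batch size.
#' @param max_epochs epoch budget.
#' @param early_stop_patience epochs without validation improvement before
#'   stopping (must be < `max_epochs`).
#' @param lr Adam learning rate.
#' @param grad_clip_norm global gradient-norm cap, applied when the
#'   architecture kind is `"lstm"`; `NULL` disables.
#' @param rng_seed seed governing shuffling and dropout.
#' @param verbose print per-epoch losses.
#' @return an `esi_train_config`.
#' @export
train_config <- function(batch_size = 8, max_epochs = 500,
                         early_stop_patience = 20, lr = 1e-3,
                         grad_clip_norm = 1, rng_seed = 1,
                         verbose = FALSE) {
  if (early_stop_patience >= max_epochs)
    stopf("early_stop_patience must be smaller than max_epochs")
  structure(list(batch_size = batch_size, max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience, lr = lr,
                 grad_clip_norm = grad_clip_norm,
                 rng_seed = as.integer(rng_seed), verbose = verbose),
            class = "esi_train_config")
}

# stack normalized samples into (feat, T, B) arrays
stack_pairs <- function(dataset, idx) {
  s1 <- dataset$samples[[idx[1]]]
  ne <- nrow(s1$Y); ns <- nrow(s1$X); t_len <- ncol(s1$Y)
  Y3 <- array(0, c(ne, t_len, length(idx)))
  X3 <- array(0, c(ns, t_len, length(idx)))
  for (j in seq_along(idx)) {
    np <- normalize_pair(dataset$samples[[idx[j]]]$X,
                         dataset$samples[[idx[j]]]$Y)
    Y3[, , j] <- np$Y_tilde
    X3[, , j] <- np$X_tilde
  }
  list(Y3 = Y3, X3 = X3)
}

eval_loss <- function(model, Y3, X3, chunk = 32) {
  n <- dim(Y3)[3]
  total <- 0
  for (start in seq(1, n, by = chunk)) {
    idx <- start:min(start + chunk - 1, n)
    out <- net_forward(model, Y3[, , idx, drop = FALSE],
                       training = FALSE)$out
    total <- total +
      cosine_loss_grad(X3[, , idx, drop = FALSE], out)$loss * length(idx)
  }
  total / n
}

#' Train a learned inverse operator
#'
#' Minimizes the cosine-similarity loss on amplitude-normalized pairs of
#' the dataset's training split with Adam; stops early when the validation
#' loss has not improved for `early_stop_patience` epochs and restores the
#' best weights. Gradient-norm clipping is applied for the LSTM
#' architecture. Fully deterministic given the configuration seed.
#'
#' @param model an [build_model()] result.
#' @param dataset an `esi_dataset` with train/validation splits.
#' @param cfg a [train_config()].
#' @return the trained `esi_net`, with a `$history` data frame of per-epoch
#'   train/validation losses.
#' @export
esi_train <- function(model, dataset, cfg = train_config()) {
  train_idx <- dataset$train_idx
  val_idx <- dataset$val_idx
  if (length(val_idx) == 0) stopf("dataset has no validation split")
  val <- stack_pairs(dataset, val_idx)
  state <- adam_init(model$params)
  best <- Inf; best_epoch <- 0; best_params <- model$params
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- with_seed(derive_seed(cfg$rng_seed, "shuffle", epoch),
                     sample(train_idx))
    set.seed(derive_seed(cfg$rng_seed, "dropout", epoch))
    epoch_loss <- 0
    n_seen <- 0
    for (start in seq(1, length(ord), by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1, length(ord))]
      batch <- stack_pairs(dataset, idx)
      fwd <- net_forward(model, batch$Y3, training = TRUE)
      lg <- cosine_loss_grad(batch$X3, fwd$out)
      if (!is.finite(lg$loss))
        stopf("training loss became non-finite at epoch %d; last good checkpoint is from epoch %d",
              epoch, best_epoch)
      grads <- net_backward(model, fwd, lg$grad)
      if (!is.null(cfg$grad_clip_norm) && model$spec$kind == "lstm")
        grads <- clip_grads(grads, cfg$grad_clip_norm)
      upd <- adam_step(model$params, grads, state, lr = cfg$lr)
      model$params <- upd$params
      state <- upd$state
      epoch_loss <- epoch_loss + lg$loss * length(idx)
      n_seen <- n_seen + length(idx)
    }
    val_loss <- eval_loss(model, val$Y3, val$X3)
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_loss = epoch_loss / n_seen,
                                   val_loss = val_loss))
    if (cfg$verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                      epoch_loss / n_seen, val_loss))
    if (val_loss < best) {
      best <- val_loss; best_epoch <- epoch; best_params <- model$params
    } else if (epoch - best_epoch >= cfg$early_stop_patience) {
      break
    }
  }
  model$params <- best_params
  model$trained <- TRUE
  model$history <- hist
  model$train_config <- cfg
  model
}

#' Apply a trained inverse operator to EEG data
#'
#' Normalizes the input by its own peak amplitude, runs the network and
#' restores physical units with [gfp_rescale()] against the unnormalized
#' input. An all-zero input returns the guarded all-zero solution.
#'
#' @param object a trained `esi_net`.
#' @param Y Ne x T EEG matrix (V).
#' @param L Ne x Ns regional leadfield used for the GFP re-projection.
#' @param ... unused.
#' @return an `esi_solution`.
#' @export
predict.esi_net <- function(object, Y, L, ...) {
  Y <- as.matrix(Y)
  if (nrow(Y) != object$spec$n_electrodes)
    stopf("input has %d electrodes but the model expects %d", nrow(Y),
          object$spec$n_electrodes)
  if (max(abs(Y)) == 0) {
    return(new_esi_solution(matrix(0, object$spec$n_sources, ncol(Y)),
                            object$spec$kind, list(guarded = "all-zero input")))
  }
  alpha <- max(abs(Y))
  Y3 <- array(Y / alpha, c(nrow(Y), ncol(Y), 1))
  out <- net_forward(object, Y3, training = FALSE)$out
  X_tilde <- matrix(out[, , 1], object$spec$n_sources, ncol(Y))
  X_hat <- gfp_rescale(X_tilde, Y, L)
  new_esi_solution(X_hat, object$spec$kind,
                   list(alpha = alpha,
                        flagged_columns = attr(X_hat, "flagged_columns")))
}
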