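test_that("pair normalization scales by the EEG peak and preserves linearity", {
  set.seed(30)
  X <- matrix(rnorm(6 * 10), 6, 10)
  Y <- matrix(rnorm(4 * 10), 4, 10)
  Y[2, 3] <- 2; Y[abs(Y) > 2] <- 1.5  # known max
  np <- normalize_pair(X, Y)
  expect_equal(np$alpha, 2)
  expect_equal(max(abs(np$Y_tilde)), 1)
  expect_equal(np$X_tilde, X / 2)
  np2 <- normalize_pair(np$X_tilde, np$Y_tilde)
  expect_equal(np2$alpha, 1)
  expect_equal(np2$Y_tilde, np$Y_tilde)
  head <- tiny_head()
  s <- simulate_sample_sereega(head, sereega_config(rng_seed = 3,
                                                    order_range = c(1, 2)), 4)
  npc <- normalize_pair(s$X, s$Y_clean)
  expect_lt(max(abs(head$leadfield_regional %*% npc$X_tilde -
                      s$Y_clean / npc$alpha)), 1e-12)
  expect_error(normalize_pair(X, Y * 0), "all-zero")
})

test_that("cosine loss hits its closed cases and invariances", {
  set.seed(31)
  X <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(as.numeric(cosine_loss(X, X)), -1)
  expect_equal(as.numeric(cosine_loss(X, 2.7 * X)), -1)
  # orthogonal columns -> 0
  Xo <- matrix(0, 4, 3); Xo[1, ] <- 1
  Ho <- matrix(0, 4, 3); Ho[2, ] <- 1
  expect_equal(as.numeric(cosine_loss(Xo, Ho)), 0)
  # bounded, column-scale invariant
  for (i in 1:20) {
    A <- matrix(rnorm(20), 4, 5); B <- matrix(rnorm(20), 4, 5)
    l <- as.numeric(cosine_loss(A, B))
    expect_gte(l, -1); expect_lte(l, 1)
    scales <- runif(5, 0.1, 5)
    expect_equal(as.numeric(cosine_loss(A, sweep(B, 2, scales, "*"))), l)
    expect_equal(as.numeric(cosine_loss(sweep(A, 2, scales, "*"), B)), l)
  }
  guarded <- cosine_loss(cbind(c(0, 0), c(1, 0)), cbind(c(1, 1), c(1, 1)))
  expect_equal(attr(guarded, "guarded_columns"), 1)
})

test_that("GFP rescaling restores amplitudes exactly on noiseless pairs", {
  head <- tiny_head()
  L <- head$leadfield_regional
  s <- simulate_sample_sereega(head, sereega_config(rng_seed = 5,
                                                    order_range = c(1, 2)), 6)
  Y <- s$Y_clean
  beta <- 37.5
  rec <- gfp_rescale(s$X / beta, Y, L)
  expect_lt(max(abs(rec - s$X)) / max(abs(s$X)), 1e-10)
  # re-projected GFP matches the measured GFP at every instant
  sdp <- function(M) sqrt(colMeans(sweep(M, 2, colMeans(M))^2))
  rnd <- matrix(rnorm(nrow(s$X) * ncol(s$X)), nrow(s$X))
  resc <- gfp_rescale(rnd, Y, L)
  expect_equal(sdp(L %*% resc), sdp(Y), tolerance = 1e-10)
  twice <- gfp_rescale(resc, Y, L)
  expect_equal(twice, resc, tolerance = 1e-12)
})

test_that("architectures produce Ns x T outputs at their stated sizes", {
  # published scale: 90 electrodes -> 994 regions, T = 500
  spec <- architecture_spec("cnn1d", 90, 994)
  m <- build_model(spec)
  expect_equal(dim(m$params$W1), c(2048, 450))
  expect_equal(dim(m$params$W2), c(994, 2048))
  out <- esibench:::net_forward(m, array(rnorm(90 * 500), c(90, 500, 1)))$out
  expect_equal(dim(out), c(994, 500, 1))
  expect_error(esibench:::net_forward(m, array(0, c(90, 3, 1))), "kernel")
  # LSTM output shape for different sequence lengths
  ml <- build_model(architecture_spec("lstm", 16, 24, lstm_hidden = 8))
  for (T_ in c(50, 500)) {
    out <- esibench:::net_forward(ml, array(rnorm(16 * T_), c(16, T_, 1)))$out
    expect_equal(dim(out), c(24, T_, 1))
  }
  # deepSIF lifts the spatial dimension to the feature size
  md <- build_model(architecture_spec("deepsif", 16, 24))
  expect_equal(nrow(md$params$W21), 500)
  expect_equal(nrow(md$params$Ws), 500)
  out <- esibench:::net_forward(md, array(rnorm(16 * 60), c(16, 60, 1)))$out
  expect_equal(dim(out), c(24, 60, 1))
})

test_that("analytic gradients match finite differences for every architecture", {
  ne <- 4; ns <- 5; T_ <- 7; B <- 2; eps <- 1e-6
  specs <- list(
    architecture_spec("cnn1d", ne, ns, cnn_filters = 6, cnn_kernel_t = 3),
    architecture_spec("lstm", ne, ns, lstm_hidden = 3, lstm_dropout = 0),
    architecture_spec("deepsif", ne, ns, deepsif_feature_dim = 6))
  set.seed(33)
  Y3 <- array(rnorm(ne * T_ * B), c(ne, T_, B))
  X3 <- array(rnorm(ns * T_ * B), c(ns, T_, B))
  for (spec in specs) {
    m <- build_model(spec, init_seed = 2)
    fwd <- esibench:::net_forward(m, Y3)
    lg <- esibench:::cosine_loss_grad(X3, fwd$out)
    gr <- esibench:::net_backward(m, fwd, lg$grad)
    for (nm in names(m$params)) {
      p <- m$params[[nm]]
      for (i in sample(length(p), min(4, length(p)))) {
        m2 <- m
        m2$params[[nm]][i] <- p[i] + eps
        up <- esibench:::cosine_loss_grad(X3,
                                          esibench:::net_forward(m2, Y3)$out)$loss
        m2$params[[nm]][i] <- p[i] - eps
        dn <- esibench:::cosine_loss_grad(X3,
                                          esibench:::net_forward(m2, Y3)$out)$loss
        fd <- (up - dn) / (2 * eps)
        expect_equal(gr[[nm]][i], fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("a small CNN overfits a small dataset", {
  head <- tiny_head()
  # fully learnable conditions: waveforms span the epoch, little noise
  cfg <- sereega_config(rng_seed = 71, order_range = c(1, 2),
                        center_range = c(0.45, 0.55),
                        width_range = c(0.3, 0.375), snr_db = 30)
  ds <- generate_dataset(head, cfg, 36, split = 8 / 9)  # 32 train
  net <- build_model(architecture_spec("cnn1d", 16, 24, cnn_filters = 64),
                     init_seed = 1)
  net <- esi_train(net, ds, train_config(max_epochs = 200,
                                         early_stop_patience = 199,
                                         rng_seed = 2))
  # the attainable cosine is bounded by the inverse problem's
  # ill-posedness even on training data; the asserted floor is the value
  # this configuration verifiably reaches (plateau ~ -0.78)
  expect_lte(min(net$history$train_loss), -0.75)
  expect_lt(min(net$history$train_loss),
            net$history$train_loss[1] - 0.3)
})

test_that("early stopping fires after exactly patience + 1 constant epochs", {
  # all-zero targets give a constant (guarded) loss and zero gradients
  samples <- lapply(1:12, function(i) {
    list(X = matrix(0, 5, 20), Y = matrix(rnorm(4 * 20), 4, 20))
  })
  ds <- structure(list(samples = samples, train_idx = 1:9, val_idx = 10:12,
                       generator = "stub", master_seed = 1),
                  class = "esi_dataset")
  net <- build_model(architecture_spec("cnn1d", 4, 5, cnn_filters = 4,
                                       cnn_kernel_t = 3))
  net <- esi_train(net, ds, train_config(max_epochs = 50,
                                         early_stop_patience = 6,
                                         rng_seed = 1))
  expect_equal(nrow(net$history), 7)
  expect_true(all(net$history$val_loss == net$history$val_loss[1]))
})

test_that("training is deterministic given the seed", {
  head <- tiny_head()
  cfg <- sereega_config(rng_seed = 72, order_range = c(1, 2))
  ds <- generate_dataset(head, cfg, 12, split = 0.75)
  run <- function() {
    net <- build_model(architecture_spec("lstm", 16, 24, lstm_hidden = 6),
                       init_seed = 4)
    esi_train(net, ds, train_config(max_epochs = 3, early_stop_patience = 2,
                                    rng_seed = 9))
  }
  n1 <- run(); n2 <- run()
  expect_identical(n1$history, n2$history)
  expect_identical(n1$params, n2$params)
})

test_that("prediction guards zero input and reproduces the GFP contract", {
  head <- tiny_head()
  L <- head$leadfield_regional
  cfg <- sereega_config(rng_seed = 73, order_range = c(1, 2))
  ds <- generate_dataset(head, cfg, 12, split = 0.75)
  net <- build_model(architecture_spec("cnn1d", 16, 24, cnn_filters = 16),
                     init_seed = 5)
  net <- esi_train(net, ds, train_config(max_epochs = 2,
                                         early_stop_patience = 1,
                                         rng_seed = 3))
  zero <- predict(net, matrix(0, 16, 40), L)
  expect_true(all(zero$X_hat == 0))
  Y <- ds$samples[[11]]$Y
  sol <- predict(net, Y, L)
  expect_equal(dim(sol$X_hat), c(24, 500))
  sdp <- function(M) sqrt(colMeans(sweep(M, 2, colMeans(M))^2))
  expect_equal(sdp(L %*% sol$X_hat), sdp(Y), tolerance = 1e-8)
  # scale consistency: prediction for c Y re-projects to the GFP of c Y
  sol2 <- predict(net, 3 * Y, L)
  expect_equal(sdp(L %*% sol2$X_hat), sdp(3 * Y), tolerance = 1e-8)
  expect_error(predict(net, matrix(0, 7, 10), L), "electrodes")
})
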