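test_that("evaluation instant picks the first maximal |seed| sample", {
  X <- matrix(0, 3, 10)
  X[2, ] <- er_waveform(1, 0.01, 0.012, (0:9) / 500)
  expect_equal(evaluation_instant(X, 2), 0.01 * 500 + 1)
  X[2, ] <- c(0, 3, 0, -3, 0, 0, 0, 0, 0, 0)
  expect_equal(evaluation_instant(X, 2), 2)   # tie: earlier index
  expect_equal(evaluation_instant(-X, 2), 2)  # sign-invariant
  expect_error(evaluation_instant(X, 1), "all-zero")
})

test_that("localization error matches the brute-force argmax rule", {
  pos <- rbind(c(0, 0, 0), c(3, 4, 0), c(10, 0, 0))
  expect_equal(as.numeric(localization_error(c(1, 0, 0), c(1, 0.1, 0), pos)), 0)
  expect_equal(as.numeric(localization_error(c(1, 0, 0), c(0.1, 1, 0), pos)), 5)
  set.seed(20)
  for (i in 1:50) {
    n <- sample(4:12, 1)
    p <- matrix(rnorm(3 * n), n, 3)
    x <- rnorm(n); xh <- rnorm(n)
    le <- localization_error(x, xh, p)
    s <- which.max(abs(x)); sh <- which.max(abs(xh))
    expect_equal(as.numeric(le), sqrt(sum((p[s, ] - p[sh, ])^2)))
  }
  deg <- localization_error(c(1, 0, 0), c(0, 0, 0), pos)
  expect_true(attr(deg, "degenerate"))
})

test_that("extent AUC reproduces the closed cases and the rank-pair oracle", {
  expect_equal(extent_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1), 1:2), 100)
  expect_equal(extent_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9), 1:2), 0)
  expect_equal(extent_auc(c(1, 1, 0), c(0.9, 0.1, 0.8), 1:2), 50)
  expect_error(extent_auc(c(1, 1), c(0.5, 0.5), 1:2), "both active")
  set.seed(21)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    lab <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (all(lab) || !any(lab)) next
    sc <- round(runif(n), 2) * sample(c(-1, 1), n, replace = TRUE)
    auc <- extent_auc(rep(1, n), sc, which(lab))
    r <- rank(abs(sc))
    u <- sum(r[lab]) - sum(lab) * (sum(lab) + 1) / 2
    expect_equal(auc, 100 * u / (sum(lab) * sum(!lab)), tolerance = 1e-10)
  }
})

test_that("nMSE cancels scale, counts sign flips and matches the loop", {
  set.seed(22)
  x <- rnorm(20); xh <- 3.7 * x
  expect_equal(nmse(x, xh), 0)
  flip <- nmse(x, -x)
  expect_equal(flip, 4 * sum((x / max(abs(x)))^2) / 20)
  for (i in 1:30) {
    a <- rnorm(15); b <- rnorm(15)
    ref <- mean((a / max(abs(a)) - b / max(abs(b)))^2)
    expect_equal(nmse(a, b), ref)
  }
  expect_error(nmse(x * 0, xh), "normalizer")
})

test_that("PSNR matches its analytic cases and the loop oracle", {
  set.seed(23)
  X <- matrix(rnorm(5 * 8), 5, 8)
  expect_equal(psnr(X, X), 300)
  # normalized peak 1, uniform |error| 0.1 -> 20 dB (both inputs already
  # max-normalized so the internal rescaling is a no-op)
  Xu <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  Xh <- matrix(c(0.9, 1, 1, 0.9), 2, 2)
  expect_equal(psnr(Xu, Xh), 20, tolerance = 1e-10)
  for (i in 1:20) {
    A <- matrix(rnorm(12), 3, 4); B <- matrix(rnorm(12), 3, 4)
    At <- A / max(abs(A)); Bt <- B / max(abs(B))
    ref <- 10 * log10(max(At)^2 / mean((At - Bt)^2))
    expect_equal(psnr(A, B), ref, tolerance = 1e-10)
  }
})

test_that("time error follows the summed-absolute-amplitude rule", {
  X <- matrix(0, 4, 100)
  X[2, ] <- er_waveform(1, 0.1, 0.1, (0:99) / 500)
  expect_equal(as.numeric(time_error(X, X, 500)), 0)
  Xs <- cbind(X[, 11:100], X[, 1:10])  # shift by 10 samples
  expect_equal(as.numeric(time_error(X, Xs, 500)), 20)
  set.seed(24)
  for (i in 1:20) {
    A <- matrix(rnorm(40), 4, 10); B <- matrix(rnorm(40), 4, 10)
    ref <- abs(which.max(colSums(abs(A))) - which.max(colSums(abs(B)))) * 2
    expect_equal(as.numeric(time_error(A, B, 500)), ref)
  }
  deg <- time_error(X, X * 0, 500)
  expect_true(attr(deg, "degenerate"))
  expect_equal(as.numeric(deg), 200)
})

test_that("all metrics are invariant to positive rescaling of the estimate", {
  head <- study_head()
  s <- simulate_sample_sereega(head, sereega_config(rng_seed = 61), 8)
  sol <- mne_solve(head$leadfield_regional, s$Y)
  r1 <- evaluate_sample(s, sol, head)
  sol2 <- sol; sol2$X_hat <- 7.3 * sol$X_hat
  r2 <- evaluate_sample(s, sol2, head)
  expect_equal(r1[c("le_mm", "auc_pct", "nmse", "psnr_db", "time_error_ms")],
               r2[c("le_mm", "auc_pct", "nmse", "psnr_db", "time_error_ms")])
  sol3 <- sol; sol3$X_hat <- -sol$X_hat  # sign flip: LE/AUC/TE unchanged
  r3 <- evaluate_sample(s, sol3, head)
  expect_equal(r1[c("le_mm", "auc_pct", "time_error_ms")],
               r3[c("le_mm", "auc_pct", "time_error_ms")])
})

test_that("a perfect and a null solution hit the guard contracts", {
  head <- study_head()
  # pick a sample whose two seeds are distinguishable local maxima of the
  # true field (when extended sources merge into one blob, even the exact
  # truth cannot score 0 under any per-seed matching rule)
  cfg <- sereega_config(rng_seed = 62)
  s <- NULL
  for (draw in 1:30) {
    cand <- simulate_sample_sereega(head, cfg, draw)
    seeds <- vapply(cand$active_regions, `[[`, 0, "seed")
    t0 <- which.max(abs(cand$X[seeds[1], ]))
    peaks <- esibench:::graph_local_maxima(cand$X[, t0],
                                           head$region_adjacency)
    if (all(seeds %in% peaks)) { s <- cand; break }
  }
  perfect <- evaluate_sample(s, s$X, head)
  expect_equal(perfect$le_mm, 0)
  expect_equal(perfect$auc_pct, 100)
  expect_equal(perfect$nmse, 0)
  expect_equal(perfect$psnr_db, 300)
  expect_equal(perfect$time_error_ms, 0)
  null <- evaluate_sample(s, s$X * 0, head)
  expect_true(null$degenerate)
  expect_equal(null$auc_pct, 50)
  expect_true(all(is.finite(unlist(null[c("le_mm", "auc_pct", "nmse",
                                          "psnr_db", "time_error_ms")]))))
})

test_that("ANOVA + Tukey comparison behaves on degenerate and separated data", {
  same <- data.frame(method = rep(c("a", "b"), each = 10),
                     le_mm = rep(1:10, 2), auc_pct = rep(50, 20),
                     nmse = rep(0.1, 20), psnr_db = rep(20, 20),
                     time_error_ms = rep(2, 20))
  cmp <- compare_methods(same)
  expect_equal(cmp$metrics$le_mm$f, 0)
  expect_equal(cmp$metrics$le_mm$tukey$p_adj, 1)
  set.seed(25)
  sep <- data.frame(method = rep(c("a", "b"), each = 100),
                    le_mm = c(rnorm(100, 5), rnorm(100, 50)))
  for (m in c("auc_pct", "nmse", "psnr_db", "time_error_ms"))
    sep[[m]] <- rnorm(200)
  cmp2 <- compare_methods(sep)
  expect_lt(cmp2$metrics$le_mm$p, 1e-6)
  tri <- rbind(sep, data.frame(method = "c", le_mm = rnorm(100, 20),
                               auc_pct = rnorm(100), nmse = rnorm(100),
                               psnr_db = rnorm(100),
                               time_error_ms = rnorm(100)))
  cmp3 <- compare_methods(tri)
  expect_equal(nrow(cmp3$metrics$le_mm$tukey), 3)
  expect_error(compare_methods(same[same$method == "a", ]), "two methods")
})
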