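## Event-related ("SEREEGA-style") simulator: extended active regions grown
## over the region adjacency graph, a shared Gaussian waveform per extended
## region with Gaussian distance decay of the amplitude, forward projection
## and exactly SNR-calibrated white sensor noise.

#' Configuration for the event-related simulator
#'
#' Defaults reproduce the study conditions: two extended regions of order
#' 1-3, amplitudes 0.5-1.5 nA.m divided by the mean region source count,
#' Gaussian centers 49-51 ms, widths 125-375 ms, 1 s epochs at 500 Hz, 5 dB
#' sensor SNR.
#'
#' @param n_regions_active number of extended sources per sample.
#' @param order_range inclusive integer range of the graph-growth order.
#' @param amplitude_range A.m interval, before division by the mean region
#'   size.
#' @param center_range,width_range seconds intervals for the Gaussian
#'   waveform center and full width (`w = 6 sigma`).
#' @param fs,duration sampling rate (Hz) and epoch length (s);
#'   `fs * duration` must be integral.
#' @param snr_db sensor signal-to-noise ratio, dB (Frobenius power ratio).
#' @param decay_sigma mm scale of the amplitude decay over centroid distance;
#'   `NULL` = mean centroid spacing of adjacent regions (about e^-1/2
#'   attenuation at first neighbours).
#' @param amplitude_divisor divisor applied to the drawn amplitude; `NULL` =
#'   the head's actual mean region source count.
#' @param rng_seed master seed for dataset generation.
#' @return a `sereega_config` list.
#' @export
sereega_config <- function(n_regions_active = 2, order_range = c(1, 3),
                           amplitude_range = c(0.5e-9, 1.5e-9),
                           center_range = c(0.049, 0.051),
                           width_range = c(0.125, 0.375),
                           fs = 500, duration = 1.0, snr_db = 5,
                           decay_sigma = NULL, amplitude_divisor = NULL,
                           rng_seed = 1) {
  n_t <- fs * duration
  if (abs(n_t - round(n_t)) > 1e-9) stopf("fs * duration must be integral")
  if (any(width_range <= 0)) stopf("widths must be positive")
  structure(list(n_regions_active = n_regions_active,
                 order_range = order_range,
                 amplitude_range = amplitude_range,
                 center_range = center_range, width_range = width_range,
                 fs = fs, duration = duration, snr_db = snr_db,
                 decay_sigma = decay_sigma,
                 amplitude_divisor = amplitude_divisor,
                 rng_seed = as.integer(rng_seed)),
            class = "sereega_config")
}

#' Grow an extended region over the adjacency graph
#'
#' Returns the seed region together with every region within graph distance
#' `order` (a breadth-first ball), the graph-based definition of an extended
#' cortical source.
#'
#' @param seed_region region id.
#' @param order integer >= 0.
#' @param adjacency symmetric logical adjacency matrix.
#' @return sorted integer vector of member region ids.
#' @export
grow_region <- function(seed_region, order, adjacency) {
  nr <- nrow(adjacency)
  if (!(seed_region %in% seq_len(nr))) stopf("unknown seed region id")
  if (order < 0) stopf("order must be >= 0")
  members <- seed_region
  frontier <- seed_region
  k <- 0
  while (k < order && length(frontier)) {
    nb <- which(apply(adjacency[frontier, , drop = FALSE], 2, any))
    frontier <- setdiff(nb, members)
    members <- union(members, frontier)
    k <- k + 1
  }
  sort(members)
}

#' Event-related Gaussian waveform
#'
#' `f(t) = a exp(-0.5 (6 (t - c) / w)^2)`: a Gaussian pulse of amplitude `a`,
#' center `c` (s) and full width `w = 6 sigma` (s).
#'
#' @param a amplitude (A.m).
#' @param c_ center (s).
#' @param w width (s), > 0.
#' @param t_grid sorted time grid (s).
#' @return amplitude vector.
#' @export
er_waveform <- function(a, c_, w, t_grid) {
  if (w <= 0) stopf("waveform width must be > 0")
  a * exp(-0.5 * (6 * (t_grid - c_) / w)^2)
}

#' Assign a shared waveform to an extended region with distance decay
#'
#' Every member region receives the seed waveform scaled by
#' `exp(-d^2 / (2 decay_sigma^2))` where `d` is the Euclidean centroid
#' distance to the seed; the seed keeps the full amplitude.
#'
#' @param members member region ids (must contain `seed_region`).
#' @param seed_region seed id.
#' @param waveform length-T amplitude vector.
#' @param centroids Nr x 3 region centroids (mm).
#' @param decay_sigma mm decay scale, > 0.
#' @return `length(members)` x T matrix of rows, ordered like `members`.
#' @export
assign_extended_activity <- function(members, seed_region, waveform,
                                     centroids, decay_sigma) {
  if (!(seed_region %in% members)) stopf("seed must be a member")
  if (decay_sigma <= 0) stopf("decay_sigma must be > 0")
  d <- sqrt(rowSums((centroids[members, , drop = FALSE] -
                       matrix(centroids[seed_region, ], length(members), 3,
                              byrow = TRUE))^2))
  outer(exp(-d^2 / (2 * decay_sigma^2)), waveform)
}

#' Add white sensor noise at an exact SNR
#'
#' Draws i.i.d. standard normal noise and rescales it so the realized
#' Frobenius power ratio `10 log10(||Y_clean||_F^2 / ||eps||_F^2)` equals
#' `snr_db` exactly.
#'
#' @param Y_clean Ne x T noiseless EEG, not all zero.
#' @param snr_db target SNR (dB).
#' @return list with `Y` (noisy) and `epsilon` (the scaled noise).
#' @export
add_noise <- function(Y_clean, snr_db) {
  nf <- frobenius(Y_clean)
  if (nf == 0) stopf("SNR undefined for an all-zero signal")
  check_number(snr_db, "snr_db")
  eps <- matrix(rnorm(length(Y_clean)), nrow(Y_clean))
  eps <- eps * (nf / (frobenius(eps) * 10^(snr_db / 20)))
  list(Y = Y_clean + eps, epsilon = eps)
}

# mean centroid distance over adjacent region pairs
mean_adjacent_spacing <- function(head) {
  idx <- which(head$region_adjacency & upper.tri(head$region_adjacency),
               arr.ind = TRUE)
  d <- sqrt(rowSums((head$region_centroids[idx[, 1], , drop = FALSE] -
                       head$region_centroids[idx[, 2], , drop = FALSE])^2))
  mean(d)
}

resolve_decay_sigma <- function(cfg, head) {
  if (is.null(cfg$decay_sigma)) mean_adjacent_spacing(head) else cfg$decay_sigma
}

resolve_amp_divisor <- function(cfg, head) {
  if (is.null(cfg$amplitude_divisor))
    mean(tabulate(head$parcellation)) else cfg$amplitude_divisor
}

#' Simulate one event-related sample
#'
#' Draws distinct seed regions, per-source growth orders and shared waveform
#' parameters, assembles the regional source matrix (overlapping extended
#' regions sum), projects through the regional leadfield and adds sensor
#' noise at the configured SNR.
#'
#' @param head an `esi_head`.
#' @param cfg a [sereega_config()].
#' @param rng_seed seed for this sample.
#' @return an `esi_sample` with fields `X` (Nr x T, A.m), `Y_clean`, `Y`
#'   (Ne x T, V), `active_regions` (list of seed/order/members), `snr_db`,
#'   `generator`, `rng_seed`, `fs`.
#' @export
simulate_sample_sereega <- function(head, cfg, rng_seed = cfg$rng_seed) {
  nr <- ncol(head$leadfield_regional)
  if (cfg$n_regions_active > nr) stopf("more active regions than regions")
  n_t <- round(cfg$fs * cfg$duration)
  t_grid <- (seq_len(n_t) - 1) / cfg$fs
  decay_sigma <- resolve_decay_sigma(cfg, head)
  divisor <- resolve_amp_divisor(cfg, head)
  with_seed(rng_seed, {
    seeds <- sample.int(nr, cfg$n_regions_active)
    X <- matrix(0, nr, n_t)
    active <- vector("list", cfg$n_regions_active)
    for (k in seq_along(seeds)) {
      order_k <- sample(seq(cfg$order_range[1], cfg$order_range[2]), 1)
      a <- runif(1, cfg$amplitude_range[1], cfg$amplitude_range[2]) / divisor
      c_ <- runif(1, cfg$center_range[1], cfg$center_range[2])
      w <- runif(1, cfg$width_range[1], cfg$width_range[2])
      members <- grow_region(seeds[k], order_k, head$region_adjacency)
      X[members, ] <- X[members, , drop = FALSE] +
        assign_extended_activity(members, seeds[k],
                                 er_waveform(a, c_, w, t_grid),
                                 head$region_centroids, decay_sigma)
      active[[k]] <- list(seed = seeds[k], order = order_k, members = members,
                          amplitude = a, center = c_, width = w)
    }
    Y_clean <- project_forward(head$leadfield_regional, X)
    noisy <- add_noise(Y_clean, cfg$snr_db)
    structure(list(X = X, Y_clean = Y_clean, Y = noisy$Y,
                   active_regions = active, snr_db = cfg$snr_db,
                   generator = "sereega", rng_seed = rng_seed, fs = cfg$fs),
              class = "esi_sample")
  })
}

#' Generate a train/validation dataset
#'
#' Simulates `n_samples` with per-sample seeds derived from the config's
#' master seed and splits deterministically by index (the first
#' `floor(split * n)` samples are the training set).
#'
#' @param head an `esi_head`.
#' @param cfg a [sereega_config()] or [nmm_config()].
#' @param n_samples number of samples (>= 2).
#' @param split training fraction in (0, 1).
#' @param bank a [build_spike_bank()] result; required for NMM configs.
#' @return an `esi_dataset`: list with `samples`, `train_idx`, `val_idx`,
#'   `generator`, `master_seed`.
#' @export
generate_dataset <- function(head, cfg, n_samples, split = 0.8, bank = NULL) {
  if (n_samples < 2) stopf("need at least 2 samples")
  if (split <= 0 || split >= 1) stopf("split must be in (0, 1)")
  gen <- if (inherits(cfg, "nmm_config")) "nmm" else "sereega"
  samples <- vector("list", n_samples)
  for (i in seq_len(n_samples)) {
    seed_i <- derive_seed(cfg$rng_seed, paste0(gen, "_sample"), i)
    samples[[i]] <- if (gen == "nmm") {
      if (is.null(bank)) stopf("NMM datasets require a spike bank")
      simulate_sample_nmm(head, bank, cfg, rng_seed = seed_i)
    } else {
      simulate_sample_sereega(head, cfg, rng_seed = seed_i)
    }
  }
  n_train <- floor(split * n_samples)
  structure(list(samples = samples,
                 train_idx = seq_len(n_train),
                 val_idx = seq(n_train + 1, n_samples),
                 generator = gen, master_seed = cfg$rng_seed),
            class = "esi_dataset")
}

#' @export
print.esi_dataset <- function(x, ...) {
  cat(sprintf("esi_dataset (%s): %d samples (%d train / %d validation)\n",
              x$generator, length(x$samples), length(x$train_idx),
              length(x$val_idx)))
  invisible(x)
}

#' Write / read a dataset container
#'
#' Array container (RDS) plus a JSON metadata sidecar (per-sample seeds,
#' active regions, orders, SNRs) and a CSV manifest.
#'
#' @param dataset an `esi_dataset`.
#' @param path file path; sidecars written to `<path>.json`, `<path>.csv`.
#' @rdname dataset_io
#' @export
write_dataset <- function(dataset, path) {
  saveRDS(dataset, path)
  meta <- lapply(seq_along(dataset$samples), function(i) {
    s <- dataset$samples[[i]]
    list(index = i, rng_seed = s$rng_seed, snr_db = s$snr_db,
         generator = s$generator,
         seeds = vapply(s$active_regions, `[[`, 0, "seed"),
         orders = vapply(s$active_regions, `[[`, 0, "order"))
  })
  jsonlite::write_json(list(generator = dataset$generator,
                            master_seed = dataset$master_seed,
                            samples = meta),
                       paste0(path, ".json"), auto_unbox = TRUE)
  manifest <- data.frame(
    index = seq_along(dataset$samples),
    split = ifelse(seq_along(dataset$samples) %in% dataset$train_idx,
                   "train", "validation"),
    snr_db = vapply(dataset$samples, `[[`, 0, "snr_db"))
  write.csv(manifest, paste0(path, ".csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname dataset_io
#' @export
read_dataset <- function(path) {
  x <- readRDS(path)
  class(x) <- "esi_dataset"
  x
}
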