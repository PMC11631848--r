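## Experiment orchestration: the in-domain benchmark (train and evaluate on
## one generator) and the cross-simulator out-of-domain protocol, with
## deterministic per-stage seeding, report rendering and provenance stamps.

#' Experiment configuration
#'
#' @param head_params arguments for [build_spherical_head()].
#' @param generator `"sereega"` or `"nmm"`.
#' @param generator_config a [sereega_config()] or [nmm_config()]; built
#'   with defaults (seeded from `master_seed`) when `NULL`.
#' @param methods methods to benchmark.
#' @param n_samples dataset size.
#' @param split training fraction.
#' @param train_cfg a [train_config()].
#' @param arch_overrides named list of [architecture_spec()] objects by
#'   method, for desk-scale network sizes.
#' @param le_mode localization-error convention, see [evaluate_sample()].
#' @param output_dir where reports are written (`NULL` = nowhere).
#' @param master_seed master seed; every stage derives its own seed from it.
#' @return an `esi_experiment_config`.
#' @export
experiment_config <- function(head_params = list(), generator = "sereega",
                              generator_config = NULL,
                              methods = c("mne", "sloreta"),
                              n_samples = 200, split = 0.8,
                              train_cfg = train_config(),
                              arch_overrides = list(),
                              le_mode = "greedy",
                              output_dir = NULL, master_seed = 1) {
  if (length(methods) == 0) stopf("methods must be non-empty")
  structure(list(head_params = head_params, generator = generator,
                 generator_config = generator_config, methods = methods,
                 n_samples = n_samples, split = split,
                 train_cfg = train_cfg, arch_overrides = arch_overrides,
                 le_mode = le_mode, output_dir = output_dir,
                 master_seed = as.integer(master_seed)),
            class = "esi_experiment_config")
}

resolve_generator_config <- function(cfg) {
  if (!is.null(cfg$generator_config)) return(cfg$generator_config)
  seed <- derive_seed(cfg$master_seed, "generator")
  if (cfg$generator == "nmm") nmm_config(rng_seed = seed)
  else sereega_config(rng_seed = seed)
}

default_sensor_snr <- function(gen_cfg) {
  if (inherits(gen_cfg, "nmm_config")) {
    if (!is.null(gen_cfg$fixed_sensor_snr_db)) gen_cfg$fixed_sensor_snr_db
    else mean(gen_cfg$sensor_snr_db_choices)
  } else gen_cfg$snr_db
}

fit_methods <- function(cfg, head, dataset, gen_cfg) {
  fits <- list()
  for (m in cfg$methods) {
    fits[[m]] <- if (m %in% c("mne", "sloreta")) {
      esi_fit(m, head, snr_assumed_db = default_sensor_snr(gen_cfg))
    } else {
      tc <- cfg$train_cfg
      tc$rng_seed <- derive_seed(cfg$master_seed, paste0("train_", m))
      esi_fit(m, head, dataset, train_cfg = tc,
              arch = cfg$arch_overrides[[m]],
              init_seed = derive_seed(cfg$master_seed, paste0("init_", m)))
    }
  }
  fits
}

predict_split <- function(fits, dataset, idx) {
  sols <- list()
  for (m in names(fits)) {
    sols[[m]] <- lapply(idx, function(i)
      predict(fits[[m]], dataset$samples[[i]]$Y))
  }
  sols
}

#' Run the in-domain benchmark
#'
#' Builds the head, generates a dataset, trains the listed networks on the
#' training split, solves the validation split with every method, evaluates
#' the five metrics and renders the per-method report plus the ANOVA/Tukey
#' comparison. Every artifact carries the configuration hash and seeds.
#'
#' @param cfg an [experiment_config()].
#' @param head,dataset,bank optionally reuse previously built stages.
#' @return an `esi_report_bundle`: fits, reports, summary table,
#'   comparison, provenance.
#' @export
run_in_domain <- function(cfg, head = NULL, dataset = NULL, bank = NULL) {
  t_start <- Sys.time()
  if (is.null(head)) {
    hp <- cfg$head_params
    hp$rng_seed <- hp$rng_seed %||% derive_seed(cfg$master_seed, "head")
    head <- do.call(build_spherical_head, hp)
  }
  gen_cfg <- resolve_generator_config(cfg)
  if (is.null(dataset)) {
    if (cfg$generator == "nmm" && is.null(bank))
      bank <- build_spike_bank(head, gen_cfg)
    dataset <- generate_dataset(head, gen_cfg, cfg$n_samples, cfg$split,
                                bank = bank)
  }
  fits <- fit_methods(cfg, head, dataset, gen_cfg)
  sols <- predict_split(fits, dataset, dataset$val_idx)
  reports <- evaluate_solutions(dataset, sols, head, le_mode = cfg$le_mode)
  reports$eval_generator <- dataset$generator
  comparison <- if (length(cfg$methods) >= 2) compare_methods(reports)
    else NULL
  bundle <- structure(list(
    head = head, dataset_generator = dataset$generator, fits = fits,
    reports = reports, summary = summarize_reports(reports),
    comparison = comparison,
    provenance = list(config_hash = config_hash(cfg),
                      master_seed = cfg$master_seed,
                      git = git_describe_string(),
                      elapsed_s = as.numeric(difftime(Sys.time(), t_start,
                                                      units = "secs")))),
    class = "esi_report_bundle")
  if (!is.null(cfg$output_dir))
    render_report(reports, comparison, cfg$output_dir,
                  provenance = bundle$provenance)
  bundle
}

#' Run the out-of-domain (cross-simulator) evaluation
#'
#' Reuses the models fitted by an in-domain run and evaluates them on a
#' dataset drawn from the other generator on the same head model. The
#' non-trained baselines are unchanged, so their metric values are
#' identical across the two report shapes on the same evaluation set.
#'
#' @param bundle an `esi_report_bundle` from [run_in_domain()].
#' @param cfg_eval an [experiment_config()] describing the evaluation
#'   generator (its head parameters must match the training head).
#' @param dataset,bank optionally reuse a pre-built evaluation dataset.
#' @return an `esi_report_bundle` for the cross-simulator evaluation.
#' @export
run_out_of_domain <- function(bundle, cfg_eval, dataset = NULL, bank = NULL) {
  head <- bundle$head
  gen_cfg <- resolve_generator_config(cfg_eval)
  if (is.null(dataset)) {
    if (cfg_eval$generator == "nmm" && is.null(bank))
      bank <- build_spike_bank(head, gen_cfg)
    dataset <- generate_dataset(head, gen_cfg, cfg_eval$n_samples,
                                cfg_eval$split, bank = bank)
  } else {
    s1 <- dataset$samples[[1]]
    if (nrow(s1$Y) != nrow(head$electrode_positions) ||
        nrow(s1$X) != ncol(head$leadfield_regional))
      stopf("evaluation dataset does not match the training head model")
  }
  sols <- predict_split(bundle$fits, dataset, dataset$val_idx)
  reports <- evaluate_solutions(dataset, sols, head,
                                le_mode = cfg_eval$le_mode)
  reports$eval_generator <- dataset$generator
  comparison <- if (length(bundle$fits) >= 2) compare_methods(reports)
    else NULL
  out <- structure(list(
    head = head, dataset_generator = dataset$generator,
    train_generator = bundle$dataset_generator,
    fits = bundle$fits, reports = reports,
    summary = summarize_reports(reports), comparison = comparison,
    provenance = list(config_hash = config_hash(cfg_eval),
                      master_seed = cfg_eval$master_seed,
                      git = git_describe_string())),
    class = "esi_report_bundle")
  if (!is.null(cfg_eval$output_dir))
    render_report(reports, comparison, cfg_eval$output_dir,
                  provenance = out$provenance)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

metric_directions <- c(le_mm = "down", auc_pct = "up", nmse = "down",
                       psnr_db = "up", time_error_ms = "down")

summarize_reports <- function(reports) {
  metrics <- names(metric_directions)
  methods <- unique(reports$method)
  rows <- list()
  for (m in metrics) {
    means <- vapply(methods, function(mm)
      mean(reports[[m]][reports$method == mm], na.rm = TRUE), 0)
    sds <- vapply(methods, function(mm)
      sd(reports[[m]][reports$method == mm], na.rm = TRUE), 0)
    best <- if (metric_directions[[m]] == "down") methods[which.min(means)]
      else methods[which.max(means)]
    rows[[m]] <- data.frame(metric = m, method = methods, mean = means,
                            sd = sds, direction = metric_directions[[m]],
                            best = methods == best, row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Render reports to CSV/JSON files
#'
#' Writes the per-sample metric table, the per-method mean table (with
#' direction annotations and a machine-readable best-method flag) and, when
#' present, the ANOVA/Tukey comparison, all stamped with provenance.
#'
#' @param reports per-sample metric data frame.
#' @param comparison an `esi_comparison` or `NULL`.
#' @param dir output directory (created if needed).
#' @param provenance named list stamped into the JSON sidecar.
#' @return the directory, invisibly.
#' @export
render_report <- function(reports, comparison, dir, provenance = list()) {
  if (is.null(reports) || nrow(reports) == 0) stopf("empty report input")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(reports, file.path(dir, "metrics_per_sample.csv"),
            row.names = FALSE)
  summ <- summarize_reports(reports)
  stopifnot(!any(is.na(summ$mean)))
  write.csv(summ, file.path(dir, "metrics_summary.csv"), row.names = FALSE)
  if (!is.null(comparison)) {
    comp_rows <- do.call(rbind, lapply(names(comparison$metrics), function(m) {
      tk <- comparison$metrics[[m]]$tukey
      data.frame(metric = m, f = comparison$metrics[[m]]$f,
                 p = comparison$metrics[[m]]$p, pair = tk$pair,
                 diff = tk$diff, p_adj = tk$p_adj, row.names = NULL)
    }))
    write.csv(comp_rows, file.path(dir, "comparison.csv"), row.names = FALSE)
    jsonlite::write_json(comparison$metrics, file.path(dir, "comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(c(provenance, list(written = Sys.time())),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.esi_report_bundle <- function(x, ...) {
  cat(sprintf("esi_report_bundle: %d method(s) evaluated on %s data\n",
              length(x$fits), x$dataset_generator))
  if (!is.null(x$train_generator))
    cat(sprintf("  (models trained on %s data)\n", x$train_generator))
  s <- x$summary
  for (m in unique(s$metric)) {
    sub <- s[s$metric == m, ]
    cat(sprintf("  %-14s %s\n", m,
                paste(sprintf("%s %.3g%s", sub$method, sub$mean,
                              ifelse(sub$best, "*", "")), collapse = "  ")))
  }
  invisible(x)
}
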