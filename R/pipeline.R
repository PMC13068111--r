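#' Run the full pipeline from a config
#'
#' One entry point wiring simulate -> train -> reconstruct -> evaluate ->
#' compare. The config is a YAML file (or an equivalent named list) with
#' blocks:
#'
#' ```yaml
#' seed: 7
#' out_dir: results/
#' simulate: {n_subjects: 10, preset: clean, duration_s: 90}
#' pipeline: {working_fs: 125, segment_len: 512, train_stride: 256}
#' model: {n_blocks: 5, hidden_units: 32, connection: dense}
#' baseline: {n_blocks: 1, connection: single}   # optional comparison model
#' train: {epochs: 10, batch_size: 32, learning_rate: 0.001}
#' split: {val_fraction: 0.15, test_fraction: 0.15}
#' ```
#'
#' Alternatively `data_dir:` (a cohort written by [write_cohort()]) replaces
#' the `simulate:` block. Artifacts written to `out_dir`: model
#' checkpoint(s), per-subject reconstruction CSVs, `metrics*.csv`,
#' `comparison.csv` (when a baseline is configured) and `run.json` echoing
#' the resolved config and seed.
#'
#' @param config Path to a YAML file, or a named list.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `model`, `metrics`, and (if configured)
#'   `baseline_model`, `baseline_metrics`, `comparison`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  need <- function(key, where = cfg) {
    if (is.null(where[[key]])) {
      abort(sprintf("config key missing or invalid: '%s'", key),
            class = "ppg2ecg_error_config")
    }
    where[[key]]
  }
  seed <- as.integer(cfg$seed %||% 1L)
  out_dir <- need("out_dir")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  pl <- do.call(pipeline_config, cfg$pipeline %||% list())

  if (!is.null(cfg$data_dir)) {
    records <- read_cohort(cfg$data_dir)
    say("loaded %d records from %s", length(records), cfg$data_dir)
  } else {
    sim <- need("simulate")
    records <- simulate_cohort(
      n_subjects = need("n_subjects", sim),
      preset = sim$preset %||% "clean",
      duration_s = sim$duration_s %||% 120,
      fs = pl$working_fs, seed = seed
    )
    say("simulated %d subjects (%s preset)", length(records),
        sim$preset %||% "clean")
  }

  sp <- cfg$split %||% list()
  splits <- make_splits(records,
                        val_fraction = sp$val_fraction %||% 0.2,
                        test_fraction = sp$test_fraction %||% 0.2,
                        seed = seed)
  ids <- vapply(records, function(r) r$subject_id, character(1))
  trainval <- records[ids %in% c(splits$train, splits$val)]
  test <- records[ids %in% splits$test]
  say("split: %d train / %d val / %d test subjects", length(splits$train),
      length(splits$val), length(splits$test))

  n_tv <- length(splits$train) + length(splits$val)
  tr_args <- cfg$train %||% list()
  tr_args$val_fraction <- length(splits$val) / n_tv
  tr_args$seed <- seed
  tcfg <- do.call(train_config, tr_args)

  fit_one <- function(margs, tag) {
    margs$input_len <- pl$segment_len
    margs$seed <- seed
    mcfg <- do.call(model_config, margs)
    say("training %s model (%d block(s), %d units) ...", mcfg$connection,
        mcfg$n_blocks, mcfg$hidden_units)
    mdl <- train_model(trainval, mcfg, tcfg, pl, quiet = quiet)
    save_model(mdl, file.path(out_dir, paste0("model_", tag, ".json")))
    mdl
  }
  model <- fit_one(cfg$model %||% list(), "main")

  metrics <- evaluate_cohort(model, test, pl)
  write.csv(tidy.metric_table(metrics), file.path(out_dir, "metrics_main.csv"),
            row.names = FALSE)
  for (rec in test) {
    pr <- prepare_record(rec, pl, align = TRUE)
    rc <- reconstruct_prepared(model, pr$ppg, pl)
    utils::write.table(
      data.frame(setNames(list(rc$samples), sprintf("ecg_recon@%gHz", rc$fs))),
      file.path(out_dir, paste0("recon_", rec$subject_id, ".csv")),
      row.names = FALSE, sep = ",", quote = FALSE
    )
  }

  out <- list(model = model, metrics = metrics, splits = splits)
  if (!is.null(cfg$baseline)) {
    baseline <- fit_one(cfg$baseline, "baseline")
    bmetrics <- evaluate_cohort(baseline, test, pl)
    write.csv(tidy.metric_table(bmetrics),
              file.path(out_dir, "metrics_baseline.csv"), row.names = FALSE)
    comparison <- compare_models(metrics, bmetrics)
    write.csv(comparison, file.path(out_dir, "comparison.csv"),
              row.names = FALSE)
    out$baseline_model <- baseline
    out$baseline_metrics <- bmetrics
    out$comparison <- comparison
  }

  run_info <- list(seed = seed, config = cfg,
                   config_hash = rlang::hash(cfg),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(run_info, file.path(out_dir, "run.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  say("artifacts written to %s", out_dir)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
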