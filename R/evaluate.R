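#' Evaluate a trained model on a cohort of test records
#'
#' For every subject: resample to the working rate, band-pass filter,
#' estimate and remove the systematic ECG-to-PPG latency of the *reference
#' record* (the physiological pulse-transit delay; removing it puts
#' reconstruction and reference on a common clock so the metrics measure
#' waveform fidelity and timing jitter rather than transit time), then
#' reconstruct the ECG from the PPG alone and score against the reference
#' processed onto the identical evaluation scale (per-segment normalized,
#' stitched). Metrics per subject: RMSE, Pearson r, and beat-timing error
#' from Pan-Tompkins peaks detected in both waveforms with tolerance-free
#' nearest matching. The cohort summary reports across-subject means with
#' 95% Student-t confidence intervals.
#'
#' The reconstruction path itself never reads the ECG channel; the
#' reference is used only for scoring.
#'
#' @param model A trained `dcblstm_model`.
#' @param records Test [paired_record]s (each must carry an ECG reference).
#' @param config A [pipeline_config()]; defaults to the model's.
#' @param align_reference Remove the record's transit latency before
#'   scoring (default TRUE; see above).
#' @return A `metric_table`: tibble with one row per subject
#'   (`subject_id`, `rmse`, `r`, `bte_s`, `n_beats_ref`, `n_beats_rec`)
#'   and the summary tibble attached as attribute `"summary"`.
#' @export
evaluate_cohort <- function(model, records, config = NULL,
                            align_reference = TRUE) {
  if (!length(records)) abort("empty test set.", class = "ppg2ecg_error_empty")
  if (is.null(config)) config <- model$pipeline
  if (is.null(config)) config <- pipeline_config()
  rows <- purrr::map(records, function(rec) {
    pr <- prepare_record(rec, config, align = align_reference)
    recon <- reconstruct_prepared(model, pr$ppg, config)
    ref <- reference_on_eval_scale(pr$ecg, model$config$input_len, config)
    m <- min(length(recon$samples), length(ref$samples))
    a <- recon$samples[seq_len(m)]
    b <- ref$samples[seq_len(m)]
    pk_rec <- pan_tompkins(bio_signal(a, config$working_fs, "rec"))
    pk_ref <- pan_tompkins(bio_signal(b, config$working_fs, "ref"))
    bte <- if (length(pk_rec) && length(pk_ref)) {
      beat_timing_error(pk_rec, pk_ref)
    } else NA_real_
    tibble::tibble(subject_id = rec$subject_id, rmse = rmse(a, b),
                   r = pearson_r(a, b), bte_s = bte,
                   n_beats_ref = length(pk_ref), n_beats_rec = length(pk_rec))
  })
  tab <- dplyr::bind_rows(rows)
  summ <- purrr::map(c("rmse", "r", "bte_s"), function(metric) {
    v <- tab[[metric]]
    s <- if (sum(is.finite(v)) >= 2L) {
      summarize_subjects(v)
    } else {
      c(mean = mean(v, na.rm = TRUE), ci_low = NA_real_, ci_high = NA_real_)
    }
    tibble::tibble(metric = metric, mean = s[["mean"]],
                   ci_low = s[["ci_low"]], ci_high = s[["ci_high"]])
  })
  structure(tab, summary = dplyr::bind_rows(summ),
            class = c("metric_table", class(tab)))
}

# inference on an already-filtered PPG at the working rate (avoids filtering
# twice when the caller has run prepare_record)
reconstruct_prepared <- function(model, ppg, config) {
  L <- model$config$input_len
  n <- length(ppg$samples)
  if (n < L) abort("PPG shorter than one segment.", class = "ppg2ecg_error_short_record")
  starts <- seq.int(1L, n - L + 1L, by = config$eval_stride)
  x <- vapply(starts, function(s) {
    normalize_segment(ppg$samples[s:(s + L - 1L)], config$norm_method)$values
  }, numeric(L))
  pred <- forward_model(model, x)
  bio_signal(stitch_segments(pred, config$eval_stride), config$working_fs,
             "ECG (reconstructed)")
}

# the reference ECG mapped onto the evaluation scale: cut at the evaluation
# stride, normalized per segment like the targets, stitched back
reference_on_eval_scale <- function(ecg, segment_len, config) {
  n <- length(ecg$samples)
  starts <- seq.int(1L, n - segment_len + 1L, by = config$eval_stride)
  segs <- lapply(starts, function(s) {
    normalize_segment(ecg$samples[s:(s + segment_len - 1L)],
                      config$norm_method)$values
  })
  bio_signal(stitch_segments(segs, config$eval_stride), config$working_fs,
             "ECG (reference)")
}

#' @export
print.metric_table <- function(x, ...) {
  NextMethod()
  s <- attr(x, "summary")
  if (!is.null(s)) {
    cat("\nCohort summary (mean [95% CI] across subjects):\n")
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %-6s %.4f [%.4f, %.4f]\n", s$metric[i], s$mean[i],
                  s$ci_low[i], s$ci_high[i]))
    }
  }
  invisible(x)
}

#' Per-subject rows of a metric table
#' @param x A `metric_table`.
#' @param ... Unused.
#' @export
tidy.metric_table <- function(x, ...) tibble::as_tibble(unclass(x))

#' Cohort summary of a metric table
#' @param x A `metric_table`.
#' @param ... Unused.
#' @export
glance.metric_table <- function(x, ...) {
  s <- attr(x, "summary")
  tidyr::pivot_wider(s, names_from = "metric",
                     values_from = c("mean", "ci_low", "ci_high"))
}

#' Compare two models' per-subject metrics
#'
#' Paired Wilcoxon signed-rank tests at the subject level on RMSE, r and
#' beat-timing error between two metric tables evaluated on the same
#' subjects. For each metric the one-sided p is directed at "model A
#' better" (smaller RMSE and beat-timing error, larger r).
#'
#' @param a,b `metric_table`s over identical subject sets.
#' @return Tibble: one row per metric with the Wilcoxon columns of
#'   [wilcoxon_paired()] plus `mean_a`, `mean_b`.
#' @export
compare_models <- function(a, b) {
  ta <- tidy.metric_table(a)
  tb <- tidy.metric_table(b)
  if (!identical(sort(ta$subject_id), sort(tb$subject_id))) {
    abort("metric tables cover different subjects.", class = "ppg2ecg_error_subjects")
  }
  tb <- tb[match(ta$subject_id, tb$subject_id), ]
  one <- function(metric, better_low) {
    va <- ta[[metric]]; vb <- tb[[metric]]
    # direct the one-sided test at "A better"; too few subjects for the
    # signed-rank null (< 5 non-zero pairs) yields NA p-values
    w <- tryCatch(
      if (better_low) wilcoxon_paired(vb, va) else wilcoxon_paired(va, vb),
      ppg2ecg_error_length = function(e) {
        tibble::tibble(n = length(va), w_pos = NA_real_, w_neg = NA_real_,
                       statistic = NA_real_, p_value = NA_real_,
                       p_one_sided = NA_real_, method = "insufficient_n")
      }
    )
    dplyr::bind_cols(tibble::tibble(metric = metric, mean_a = mean(va),
                                    mean_b = mean(vb)), w)
  }
  dplyr::bind_rows(one("rmse", TRUE), one("r", FALSE), one("bte_s", TRUE))
}

#' Plot per-subject metrics of one or two cohorts
#'
#' @param object A `metric_table`.
#' @param ... Unused.
#' @return A ggplot object: one panel per metric, one point per subject,
#'   with the cohort mean and 95% CI overlaid.
#' @export
autoplot.metric_table <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy.metric_table(object),
                              cols = c("rmse", "r", "bte_s"),
                              names_to = "metric", values_to = "value")
  s <- attr(object, "summary")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::geom_pointrange(data = s,
                             ggplot2::aes(x = .data$metric, y = .data$mean,
                                          ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             color = "firebrick") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Per-subject reconstruction metrics") +
    ggplot2::theme_minimal()
}

#' @export
autoplot <- function(object, ...) UseMethod("autoplot")

#' Plot a reconstruction against its reference
#'
#' @param recon,reference [bio_signal]s on a common scale.
#' @param window_s Time window to draw, seconds (from the start).
#' @return A ggplot object.
#' @export
plot_reconstruction <- function(recon, reference, window_s = 8) {
  m <- min(length(recon$samples), length(reference$samples),
           as.integer(window_s * recon$fs))
  df <- dplyr::bind_rows(
    tibble::tibble(time_s = (seq_len(m) - 1) / recon$fs,
                   value = reference$samples[seq_len(m)], which = "reference"),
    tibble::tibble(time_s = (seq_len(m) - 1) / recon$fs,
                   value = recon$samples[seq_len(m)], which = "reconstruction")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value,
                                   color = .data$which)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::scale_color_manual(values = c(reference = "steelblue",
                                           reconstruction = "darkorange")) +
    ggplot2::labs(x = "time (s)", y = "amplitude (normalized)", color = NULL) +
    ggplot2::theme_minimal()
}
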