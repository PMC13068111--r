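#' Pipeline configuration
#'
#' Central knob set for the preprocessing and inference chain. Both channels
#' are resampled to `working_fs` before anything else so the per-point
#' PPG-to-ECG regression is well defined across source datasets with
#' different native rates.
#'
#' @param working_fs Common working rate, Hz.
#' @param ppg_band,ecg_band Band-pass edges (Hz) for the PPG and ECG FIR
#'   filters. The PPG band keeps pulse morphology; the ECG band keeps QRS
#'   content.
#' @param n_taps FIR length (odd; type-I linear phase).
#' @param max_lag_s Cross-correlation search bound for cardiac-phase
#'   alignment, seconds (physiological pulse-transit delays fall well inside
#'   0.6 s).
#' @param segment_len Segment length in samples.
#' @param train_stride Stride between training segments (50% overlap by
#'   default).
#' @param eval_stride Stride at evaluation/inference (no overlap by default).
#' @param norm_method Per-segment normalisation, `"minmax"` or `"zscore"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(working_fs = 125, ppg_band = c(0.5, 8),
                            ecg_band = c(0.5, 40), n_taps = 401,
                            max_lag_s = 0.6, segment_len = 512,
                            train_stride = 256, eval_stride = 512,
                            norm_method = c("minmax", "zscore")) {
  norm_method <- match.arg(norm_method)
  structure(list(working_fs = working_fs, ppg_band = ppg_band,
                 ecg_band = ecg_band, n_taps = n_taps, max_lag_s = max_lag_s,
                 segment_len = as.integer(segment_len),
                 train_stride = as.integer(train_stride),
                 eval_stride = as.integer(eval_stride),
                 norm_method = norm_method),
            class = "pipeline_config")
}

#' Design a type-I linear-phase FIR filter
#'
#' Hamming-windowed design via [signal::fir1()]. A type-I kernel has odd
#' length and coefficients symmetric about the center, giving exactly linear
#' phase (constant group delay of `(n_taps - 1) / 2` samples). `band[1] == 0`
#' yields a low-pass design.
#'
#' @param fs Design sampling rate, Hz.
#' @param band `c(low, high)` edges in Hz, `0 <= low < high < fs / 2`.
#' @param n_taps Odd kernel length.
#' @return A list of class `fir_kernel` with `taps`, `fs`, `band`.
#' @export
design_fir <- function(fs, band, n_taps = 401) {
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) {
    abort("type-I FIR requires odd length (`n_taps` must be odd).",
          class = "ppg2ecg_error_even_taps")
  }
  if (length(band) != 2L || band[1] < 0 || band[1] >= band[2] || band[2] >= fs / 2) {
    abort("`band` must satisfy 0 <= low < high < fs/2.",
          class = "ppg2ecg_error_band")
  }
  nyq <- fs / 2
  taps <- if (band[1] <= 0) {
    signal::fir1(n_taps - 1L, band[2] / nyq, type = "low")
  } else {
    signal::fir1(n_taps - 1L, band / nyq, type = "pass")
  }
  taps <- as.numeric(taps)
  # enforce exact symmetry against floating-point asymmetry in the window
  taps <- (taps + rev(taps)) / 2
  structure(list(taps = taps, fs = fs, band = band), class = "fir_kernel")
}

#' Frequency response of an FIR kernel
#'
#' @param kernel A `fir_kernel`.
#' @param freqs_hz Frequencies at which to evaluate, Hz.
#' @return Complex response vector (same length as `freqs_hz`).
#' @export
fir_response <- function(kernel, freqs_hz) {
  n <- length(kernel$taps)
  vapply(freqs_hz, function(f) {
    w <- 2 * pi * f / kernel$fs
    sum(kernel$taps * exp(-1i * w * (seq_len(n) - 1)))
  }, complex(1))
}

#' Apply an FIR kernel with group-delay compensation
#'
#' Zero-phase filtering: the symmetric kernel is applied by full convolution
#' and the output is re-centered by the constant group delay
#' `(n_taps - 1) / 2`, so an in-band sinusoid leaves the filter with no phase
#' lag. Edges are zero-padded. Output length equals input length.
#'
#' @param signal A [bio_signal] whose `fs` matches the kernel design rate.
#' @param kernel A `fir_kernel` from [design_fir()].
#' @return Filtered [bio_signal].
#' @export
apply_fir <- function(signal, kernel) {
  stopifnot(inherits(signal, "bio_signal"), inherits(kernel, "fir_kernel"))
  if (!isTRUE(all.equal(signal$fs, kernel$fs))) {
    abort("kernel design rate does not match signal rate.",
          class = "ppg2ecg_error_fs_mismatch")
  }
  x <- signal$samples
  n <- length(x)
  delay <- (length(kernel$taps) - 1L) / 2L
  y_full <- stats::convolve(c(x, rep(0, length(kernel$taps) - 1L)),
                            rev(kernel$taps), type = "open")
  # 'open' convolve with rev gives plain convolution; centered slice:
  y <- y_full[(delay + 1L):(delay + n)]
  bio_signal(y, signal$fs, signal$label)
}

#' Estimate the ECG-to-PPG cardiac-phase lag
#'
#' The systolic upstroke is the PPG's sharpest temporal landmark, so the lag
#' is found by maximizing the normalized cross-correlation between the
#' z-scored ECG and the z-scored first difference of the PPG over
#' `0..max_lag_s * fs` samples, ties broken toward the smaller lag. The
#' returned lag is how far the PPG trails the ECG.
#'
#' Before correlating, the ECG is restricted to the QRS band (5-15 Hz,
#' zero-phase, so beat timing is untouched). Without this, the broad T wave
#' can sit closer to the systolic upstroke than the R wave does at high
#' heart rates and capture the correlation maximum at a spuriously small
#' lag.
#'
#' @param ecg,ppg [bio_signal]s at equal rates and lengths.
#' @param max_lag_s Search bound in seconds (default 0.6).
#' @return Integer lag in samples, in `[0, max_lag_s * fs]`.
#' @export
estimate_lag <- function(ecg, ppg, max_lag_s = 0.6) {
  ecg <- qrs_emphasis(ecg)
  estimate_lag_raw(ecg, ppg, max_lag_s)
}

# 5-15 Hz zero-phase band-pass when the rate allows it; identity otherwise
qrs_emphasis <- function(ecg) {
  n_taps <- as.integer(round(ecg$fs / 2))
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  if (ecg$fs <= 31 || length(ecg$samples) <= n_taps) return(ecg)
  if (sd(ecg$samples) < 1e-12) return(ecg)
  apply_fir(ecg, design_fir(ecg$fs, c(5, 15), n_taps))
}

estimate_lag_raw <- function(ecg, ppg, max_lag_s = 0.6) {
  stopifnot(inherits(ecg, "bio_signal"), inherits(ppg, "bio_signal"))
  if (!isTRUE(all.equal(ecg$fs, ppg$fs))) {
    abort("channels must share a sampling rate.", class = "ppg2ecg_error_fs_mismatch")
  }
  if (length(ecg$samples) != length(ppg$samples)) {
    abort("channels must have equal length.", class = "ppg2ecg_error_length")
  }
  if (max_lag_s < 0) abort("`max_lag_s` must be >= 0.", class = "ppg2ecg_error_lag")
  zs <- function(v) {
    s <- sd(v)
    if (!is.finite(s) || s < 1e-12) {
      abort("constant (zero-variance) input to lag estimation.",
            class = "ppg2ecg_error_constant")
    }
    (v - mean(v)) / s
  }
  e <- zs(ecg$samples)
  d <- zs(c(diff(ppg$samples), 0))
  max_lag <- as.integer(floor(max_lag_s * ecg$fs))
  n <- length(e)
  best_lag <- 0L
  best_r <- -Inf
  for (lag in 0:max_lag) {
    m <- n - lag
    if (m < 8L) break
    r <- suppressWarnings(cor(e[seq_len(m)], d[lag + seq_len(m)]))
    if (is.finite(r) && r > best_r + 1e-12) {
      best_r <- r
      best_lag <- lag
    }
  }
  best_lag
}

#' Remove the estimated latency from a paired record
#'
#' Advances the PPG channel by `lag_samples` and truncates both channels to
#' the common overlapping span; `true_r_peaks` falling outside the span are
#' dropped. Training-only: the inference path never calls this.
#'
#' @param record A [paired_record] with both channels at the same rate.
#' @param lag_samples Non-negative integer lag from [estimate_lag()].
#' @return Aligned [paired_record].
#' @export
align_record <- function(record, lag_samples) {
  stopifnot(inherits(record, "paired_record"))
  lag_samples <- as.integer(lag_samples)
  n <- min(length(record$ecg$samples), length(record$ppg$samples))
  if (lag_samples < 0L || lag_samples >= n) {
    abort("`lag_samples` must lie in [0, min channel length).",
          class = "ppg2ecg_error_lag")
  }
  keep <- n - lag_samples
  ecg <- bio_signal(record$ecg$samples[seq_len(keep)], record$ecg$fs,
                    record$ecg$label)
  ppg <- bio_signal(record$ppg$samples[lag_samples + seq_len(keep)],
                    record$ppg$fs, record$ppg$label)
  pk <- record$true_r_peaks
  if (!is.null(pk)) pk <- pk[pk >= 1L & pk <= keep]
  paired_record(ecg, ppg, record$subject_id, true_r_peaks = pk)
}

#' Per-segment amplitude normalisation
#'
#' `"minmax"` maps onto `[0, 1]` with `scale = max - min` (clamped to 1e-8
#' for constant segments); `"zscore"` maps to zero mean, unit sd. The
#' returned `denorm = c(offset, scale)` inverts the map:
#' `original = normalized * scale + offset`.
#'
#' @param values Non-empty numeric vector.
#' @param method `"minmax"` or `"zscore"`.
#' @return List with `values` (normalized) and `denorm = c(offset, scale)`.
#' @export
normalize_segment <- function(values, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  stopifnot(length(values) >= 1L)
  if (method == "minmax") {
    off <- min(values)
    sc <- max(values) - off
    if (sc < 1e-8) sc <- 1e-8
  } else {
    off <- mean(values)
    sc <- sd(values)
    if (!is.finite(sc) || sc < 1e-8) sc <- 1e-8
  }
  list(values = (values - off) / sc, denorm = c(offset = off, scale = sc))
}

#' Undo per-segment normalisation
#'
#' @param values Normalized numeric vector.
#' @param denorm `c(offset, scale)` from [normalize_segment()].
#' @return Restored numeric vector.
#' @export
denormalize_segment <- function(values, denorm) {
  values * denorm[["scale"]] + denorm[["offset"]]
}

#' Cut a record into fixed-length normalized segment pairs
#'
#' Produces `floor((N - length) / stride) + 1` aligned (PPG-input,
#' ECG-target) pairs; the trailing remainder is discarded. Each channel of
#' each segment is normalized independently and its de-normalisation
#' parameters retained.
#'
#' @param record A [paired_record], both channels at the working rate.
#' @param segment_len Segment length L in samples.
#' @param stride Stride in samples (>= 1).
#' @param norm_method Passed to [normalize_segment()].
#' @return A tibble with one row per segment: `subject_id`, `start_index`
#'   (1-based), list-columns `ppg_in` and `ecg_target` (length-L numeric),
#'   and list-columns `ppg_denorm`, `ecg_denorm`.
#' @export
segment_record <- function(record, segment_len = 512, stride = segment_len,
                           norm_method = "minmax") {
  stopifnot(inherits(record, "paired_record"))
  segment_len <- as.integer(segment_len)
  stride <- as.integer(stride)
  if (stride < 1L) abort("`stride` must be >= 1.", class = "ppg2ecg_error_stride")
  n <- min(length(record$ecg$samples), length(record$ppg$samples))
  if (n < segment_len) {
    abort("record shorter than segment.", class = "ppg2ecg_error_short_record")
  }
  starts <- seq.int(1L, n - segment_len + 1L, by = stride)
  rows <- purrr::map(starts, function(s) {
    idx <- s:(s + segment_len - 1L)
    p <- normalize_segment(record$ppg$samples[idx], norm_method)
    e <- normalize_segment(record$ecg$samples[idx], norm_method)
    tibble::tibble(subject_id = record$subject_id, start_index = s,
                   ppg_in = list(p$values), ecg_target = list(e$values),
                   ppg_denorm = list(p$denorm), ecg_denorm = list(e$denorm))
  })
  dplyr::bind_rows(rows)
}

#' Filter, align and resample a record for training
#'
#' The full training preprocessing chain on one record: resample both
#' channels to the working rate, band-pass filter each with its type-I FIR
#' kernel, estimate the cardiac-phase lag and remove it. Filtering precedes
#' alignment and segmentation in both training and inference.
#'
#' @param record A [paired_record].
#' @param config A [pipeline_config()].
#' @param align Apply cardiac-phase alignment (training) or not (inference
#'   never aligns).
#' @return A preprocessed [paired_record]; the estimated lag is attached as
#'   attribute `"lag_samples"`.
#' @export
prepare_record <- function(record, config = pipeline_config(), align = TRUE) {
  ecg <- resample_signal(record$ecg, config$working_fs)
  ppg <- resample_signal(record$ppg, config$working_fs)
  pk <- record$true_r_peaks
  if (!is.null(pk) && !isTRUE(all.equal(record$ecg$fs, config$working_fs))) {
    pk <- unique(pmax(1L, as.integer(round((pk - 1L) * config$working_fs /
                                             record$ecg$fs)) + 1L))
    pk <- pk[pk <= length(ecg$samples)]
  }
  ke <- design_fir(config$working_fs, config$ecg_band, config$n_taps)
  kp <- design_fir(config$working_fs, config$ppg_band, config$n_taps)
  ecg <- apply_fir(ecg, ke)
  ppg <- apply_fir(ppg, kp)
  n <- min(length(ecg$samples), length(ppg$samples))
  out <- paired_record(
    bio_signal(ecg$samples[seq_len(n)], ecg$fs, ecg$label),
    bio_signal(ppg$samples[seq_len(n)], ppg$fs, ppg$label),
    record$subject_id,
    true_r_peaks = if (is.null(pk)) NULL else pk[pk <= n]
  )
  lag <- 0L
  if (align) {
    lag <- estimate_lag(out$ecg, out$ppg, config$max_lag_s)
    out <- align_record(out, lag)
  }
  attr(out, "lag_samples") <- lag
  out
}
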