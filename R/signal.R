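#' Single-channel physiological signal
#'
#' A `bio_signal` couples an amplitude sequence with its sampling rate, the
#' minimal metadata the rest of the pipeline needs to stay unit-aware. ECG
#' channels are conventionally in millivolts; PPG channels are in arbitrary
#' optical units.
#'
#' @param samples Numeric vector of amplitudes; must be non-empty and finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param label Channel name, free text (e.g. `"II"`, `"PLETH"`).
#'
#' @return An object of class `bio_signal`: a list with elements `samples`,
#'   `fs` and `label`.
#' @examples
#' s <- bio_signal(sin(2 * pi * 1 * seq(0, 2, by = 1 / 125)), fs = 125, label = "PLETH")
#' s
#' @export
bio_signal <- function(samples, fs, label = "signal") {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    abort("`samples` must contain at least one value.", class = "ppg2ecg_error_empty_signal")
  }
  if (!all(is.finite(samples))) {
    abort("non-finite samples in signal.", class = "ppg2ecg_error_nonfinite")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a positive finite scalar (Hz).", class = "ppg2ecg_error_bad_fs")
  }
  structure(list(samples = samples, fs = as.numeric(fs), label = as.character(label)),
            class = "bio_signal")
}

#' @export
print.bio_signal <- function(x, ...) {
  cat(sprintf("<bio_signal> %s: %d samples @ %g Hz (%.2f s)\n",
              x$label, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.bio_signal <- function(x) length(x$samples)

#' @rdname bio_signal
#' @param x A `bio_signal`.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
as_tibble.bio_signal <- function(x, ...) {
  tibble::tibble(
    time_s = (seq_along(x$samples) - 1) / x$fs,
    value = x$samples,
    label = x$label
  )
}

#' Paired ECG/PPG record for one subject
#'
#' Holds one subject's synchronized ECG and PPG channels, each with its own
#' native sampling rate, plus (for simulated data) the ground-truth R-peak
#' sample indices into the ECG channel.
#'
#' @param ecg,ppg [bio_signal] objects.
#' @param subject_id Non-empty identifier.
#' @param true_r_peaks Optional integer vector of 1-based, strictly increasing
#'   sample indices into `ecg` marking true R-wave centers.
#'
#' @return An object of class `paired_record`.
#' @export
paired_record <- function(ecg, ppg, subject_id, true_r_peaks = NULL) {
  stopifnot(inherits(ecg, "bio_signal"), inherits(ppg, "bio_signal"))
  subject_id <- as.character(subject_id)
  if (length(subject_id) != 1L || !nzchar(subject_id)) {
    abort("`subject_id` must be a non-empty string.", class = "ppg2ecg_error_subject_id")
  }
  if (!is.null(true_r_peaks)) {
    true_r_peaks <- as.integer(true_r_peaks)
    if (length(true_r_peaks) > 1L && any(diff(true_r_peaks) <= 0L)) {
      abort("`true_r_peaks` must be strictly increasing.", class = "ppg2ecg_error_peaks")
    }
    if (length(true_r_peaks) &&
        (min(true_r_peaks) < 1L || max(true_r_peaks) > length(ecg$samples))) {
      abort("`true_r_peaks` indices outside the ECG channel.", class = "ppg2ecg_error_peaks")
    }
  }
  structure(list(subject_id = subject_id, ecg = ecg, ppg = ppg,
                 true_r_peaks = true_r_peaks),
            class = "paired_record")
}

#' @export
print.paired_record <- function(x, ...) {
  cat(sprintf("<paired_record> subject %s\n", x$subject_id))
  cat("  ecg: "); print(x$ecg)
  cat("  ppg: "); print(x$ppg)
  if (!is.null(x$true_r_peaks)) {
    cat(sprintf("  true R peaks: %d\n", length(x$true_r_peaks)))
  }
  invisible(x)
}

#' Resample a signal to a new rate
#'
#' Linear-interpolation resampling with FIR anti-alias low-pass filtering
#' (cutoff 0.45 of the target rate) applied first when downsampling. The
#' output duration matches the input duration to within one output sample
#' period, and constant signals pass through unchanged.
#'
#' @param signal A [bio_signal].
#' @param target_fs Target sampling rate in Hz.
#' @return A [bio_signal] at `target_fs`.
#' @export
resample_signal <- function(signal, target_fs) {
  stopifnot(inherits(signal, "bio_signal"))
  if (!is.numeric(target_fs) || length(target_fs) != 1L || target_fs <= 0) {
    abort("`target_fs` must be a positive scalar.", class = "ppg2ecg_error_bad_fs")
  }
  if (isTRUE(all.equal(target_fs, signal$fs))) {
    return(signal)
  }
  x <- signal$samples
  n <- length(x)
  if (target_fs < signal$fs && n > 31L) {
    # anti-alias before decimation; keep the kernel no longer than the signal
    n_taps <- min(101L, if (n %% 2L == 1L) n else n - 1L)
    kern <- design_fir(signal$fs, c(0, 0.45 * target_fs), n_taps = n_taps)
    x <- apply_fir(bio_signal(x, signal$fs, signal$label), kern)$samples
  }
  n_out <- max(1L, as.integer(round(n * target_fs / signal$fs)))
  t_in <- (seq_len(n) - 1) / signal$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  y <- approx(t_in, x, xout = t_out, rule = 2)$y
  bio_signal(y, target_fs, signal$label)
}
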