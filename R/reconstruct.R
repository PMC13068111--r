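#' Overlap-average stitching of reconstructed segments
#'
#' Combines an ordered list of length-L segments cut at a fixed stride back
#' into one sequence of length `(n - 1) * stride + L`. At `stride == L` this
#' is concatenation; at smaller strides, overlapping samples are averaged
#' with equal weight, which smooths segment-boundary artifacts.
#'
#' @param segments List of equal-length numeric vectors (or an `L x n`
#'   matrix).
#' @param stride Stride in samples, `1 <= stride <= L`.
#' @return Numeric vector.
#' @export
stitch_segments <- function(segments, stride) {
  if (is.matrix(segments)) {
    segments <- lapply(seq_len(ncol(segments)), function(i) segments[, i])
  }
  if (!length(segments)) abort("need at least one segment.", class = "ppg2ecg_error_empty")
  L <- length(segments[[1]])
  stride <- as.integer(stride)
  if (stride > L) abort("`stride` must be <= segment length.", class = "ppg2ecg_error_stride")
  n <- length(segments)
  total <- (n - 1L) * stride + L
  acc <- numeric(total)
  cnt <- numeric(total)
  for (i in seq_len(n)) {
    idx <- (i - 1L) * stride + seq_len(L)
    acc[idx] <- acc[idx] + segments[[i]]
    cnt[idx] <- cnt[idx] + 1
  }
  acc / cnt
}

#' Reconstruct an ECG waveform from PPG only
#'
#' The full inference path: resample the PPG to the working rate, band-pass
#' it with the type-I FIR kernel, cut into evaluation segments, normalize
#' each, run the trained model, and stitch the reconstructed segments back
#' together. No alignment step exists on this path (alignment is training
#' preprocessing only); no ECG information of any kind is consumed.
#'
#' The output is emitted on the per-segment normalized model scale. If
#' `calibration` is supplied (a labeled span of true ECG at the working
#' rate, e.g. a short clinical calibration strip), a single affine map is
#' fitted from the reconstruction onto it by least squares and applied, so
#' amplitudes are restored to mV.
#'
#' @param model A trained `dcblstm_model`.
#' @param ppg A [bio_signal] (PPG channel only), at least one segment long
#'   after resampling.
#' @param config A [pipeline_config()]; defaults to the one stored in the
#'   model.
#' @param calibration Optional numeric vector of reference ECG samples
#'   overlapping the start of the reconstruction, used only for amplitude
#'   calibration.
#' @return A [bio_signal] of the reconstructed ECG at the working rate,
#'   covering the tiled span `(n_segments - 1) * eval_stride + L`.
#' @export
reconstruct <- function(model, ppg, config = NULL, calibration = NULL) {
  stopifnot(inherits(model, "dcblstm_model"), inherits(ppg, "bio_signal"))
  if (is.null(config)) config <- model$pipeline
  if (is.null(config)) config <- pipeline_config()
  ppg <- resample_signal(ppg, config$working_fs)
  kern <- design_fir(config$working_fs, config$ppg_band, config$n_taps)
  ppg <- apply_fir(ppg, kern)
  L <- model$config$input_len
  n <- length(ppg$samples)
  if (n < L) abort("PPG shorter than one segment.", class = "ppg2ecg_error_short_record")
  stride <- config$eval_stride
  starts <- seq.int(1L, n - L + 1L, by = stride)
  x <- vapply(starts, function(s) {
    normalize_segment(ppg$samples[s:(s + L - 1L)], config$norm_method)$values
  }, numeric(L))
  pred <- forward_model(model, x)
  out <- stitch_segments(pred, stride)
  if (!is.null(calibration)) {
    m <- min(length(out), length(calibration))
    fit <- stats::lm.fit(cbind(1, out[seq_len(m)]), calibration[seq_len(m)])
    out <- fit$coefficients[1] + fit$coefficients[2] * out
  }
  bio_signal(out, config$working_fs, "ECG (reconstructed)")
}
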