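#' Ordered R-peak set
#'
#' @param indices Strictly increasing 1-based sample indices.
#' @param fs Sampling rate in Hz.
#' @return Object of class `peak_set`.
#' @export
peak_set <- function(indices, fs) {
  indices <- as.integer(indices)
  if (length(indices) > 1L && any(diff(indices) <= 0L)) {
    abort("peak indices must be strictly increasing.", class = "ppg2ecg_error_peaks")
  }
  structure(list(indices = indices, fs = as.numeric(fs)), class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks @ %g Hz\n", length(x$indices), x$fs))
  invisible(x)
}

#' @export
length.peak_set <- function(x) length(x$indices)

local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Pan-Tompkins QRS detection
#'
#' The classic real-time QRS detector stage chain: 5-15 Hz band-pass,
#' five-point derivative, squaring, 150 ms moving-window integration, then
#' an adaptive dual-threshold peak decision with a 200 ms refractory period,
#' 360 ms T-wave discrimination by slope comparison, and RR-guided
#' searchback at half threshold when a beat appears to have been missed.
#' Each accepted detection is refined to the local maximum of the
#' band-passed ECG within +/- 50 ms, so reported indices sit on the R wave
#' itself.
#'
#' @param ecg A [bio_signal]; `fs >= 100` Hz and duration >= 2 s.
#' @return A [peak_set()] of R-peak indices into `ecg`.
#' @references Pan J., Tompkins W.J. (1985) A real-time QRS detection
#'   algorithm. IEEE Trans. Biomed. Eng. 32(3):230-236.
#' @export
pan_tompkins <- function(ecg) {
  stopifnot(inherits(ecg, "bio_signal"))
  fs <- ecg$fs
  if (fs < 100) abort("Pan-Tompkins requires fs >= 100 Hz.", class = "ppg2ecg_error_bad_fs")
  n <- length(ecg$samples)
  if (n < 2 * fs) abort("signal shorter than 2 s.", class = "ppg2ecg_error_short_record")

  # stage 1: 5-15 Hz band-pass, zero phase (odd symmetric kernel ~0.5 s)
  n_taps <- as.integer(round(fs / 2))
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  bp <- apply_fir(ecg, design_fir(fs, c(5, 15), n_taps))$samples

  # stage 2: five-point derivative (centered to keep zero delay)
  d <- numeric(n)
  i <- 3:(n - 2)
  d[i] <- (2 * bp[i + 2] + bp[i + 1] - bp[i - 1] - 2 * bp[i - 2]) * fs / 8

  # stages 3-4: squaring and 150 ms moving-window integration (centered)
  sq <- d^2
  w <- max(1L, as.integer(round(0.150 * fs)))
  if (w %% 2L == 0L) w <- w + 1L
  mwi <- stats::filter(sq, rep(1 / w, w), sides = 2)
  mwi[is.na(mwi)] <- 0
  mwi <- as.numeric(mwi)

  refract <- as.integer(round(0.200 * fs))
  cand <- local_maxima(mwi)
  cand <- cand[mwi[cand] > 0]
  if (!length(cand)) return(peak_set(integer(0), fs))
  # consolidate: within any refractory-length neighbourhood only the tallest
  # integration peak is a candidate event, so noise bumps on a QRS flank
  # cannot claim the beat (greedy non-maximum suppression)
  ord <- cand[order(mwi[cand], decreasing = TRUE)]
  blocked <- logical(n)
  sel <- integer(0)
  for (idx in ord) {
    if (!blocked[idx]) {
      sel <- c(sel, idx)
      blocked[max(1L, idx - refract):min(n, idx + refract)] <- TRUE
    }
  }
  cand <- sort(sel)
  twave_win <- as.integer(round(0.360 * fs))
  # threshold initialisation from the first 2 s (learning phase)
  init_span <- seq_len(min(n, as.integer(2 * fs)))
  spk <- 0.25 * max(mwi[init_span])
  npk <- 0.5 * mean(mwi[init_span])
  peak_slope <- function(idx) {
    span <- max(1L, idx - as.integer(round(0.075 * fs))):min(n, idx)
    max(abs(d[span]))
  }

  qrs <- integer(0)
  last_qrs <- -Inf
  last_slope <- 0
  rr_hist <- numeric(0)
  noise_peaks_since <- integer(0)

  accept <- function(idx) {
    qrs <<- c(qrs, idx)
    spk <<- 0.125 * mwi[idx] + 0.875 * spk
    if (is.finite(last_qrs)) {
      rr_hist <<- tail(c(rr_hist, idx - last_qrs), 8L)
    }
    last_slope <<- peak_slope(idx)
    last_qrs <<- idx
    noise_peaks_since <<- integer(0)
  }

  for (idx in cand) {
    thr1 <- npk + 0.25 * (spk - npk)
    rr_avg <- if (length(rr_hist)) mean(rr_hist) else NA_real_
    # searchback: a beat seems missed; retry strongest rejected peak at thr/2
    if (!is.na(rr_avg) && (idx - last_qrs) > 1.66 * rr_avg &&
        length(noise_peaks_since)) {
      sb <- noise_peaks_since[which.max(mwi[noise_peaks_since])]
      if (mwi[sb] > 0.5 * thr1 && (sb - last_qrs) > refract) {
        accept(sb)
        thr1 <- npk + 0.25 * (spk - npk)
      }
    }
    if (idx - last_qrs <= refract) next
    if (mwi[idx] > thr1) {
      is_twave <- (idx - last_qrs) <= twave_win &&
        peak_slope(idx) < 0.5 * last_slope
      if (is_twave) {
        npk <- 0.125 * mwi[idx] + 0.875 * npk
        noise_peaks_since <- c(noise_peaks_since, idx)
      } else {
        accept(idx)
      }
    } else {
      npk <- 0.125 * mwi[idx] + 0.875 * npk
      noise_peaks_since <- c(noise_peaks_since, idx)
    }
  }

  # refine to the local maximum of the band-passed ECG within +/- 50 ms
  half <- as.integer(round(0.050 * fs))
  refined <- vapply(qrs, function(idx) {
    span <- max(1L, idx - half):min(n, idx + half)
    span[which.max(bp[span])]
  }, integer(1))
  refined <- sort(unique(refined))
  peak_set(refined, fs)
}

#' Match reconstructed R-peaks to reference R-peaks
#'
#' Every reconstructed peak is paired with the temporally nearest reference
#' peak, with no tolerance window; many-to-one matches are permitted and
#' equidistant ties break toward the earlier reference peak. This is a
#' directed matching (reconstruction onto reference).
#'
#' @param rec,ref [peak_set()]s at the same rate.
#' @return Tibble with `rec_index`, `ref_index` (sample indices) and
#'   `dt_s` (signed time difference `rec - ref`, seconds); empty if either
#'   set is empty.
#' @export
match_peaks <- function(rec, ref) {
  stopifnot(inherits(rec, "peak_set"), inherits(ref, "peak_set"))
  if (!isTRUE(all.equal(rec$fs, ref$fs))) {
    abort("peak sets at different rates.", class = "ppg2ecg_error_fs_mismatch")
  }
  if (!length(rec$indices) || !length(ref$indices)) {
    return(tibble::tibble(rec_index = integer(0), ref_index = integer(0),
                          dt_s = numeric(0)))
  }
  ref_i <- ref$indices
  pairs <- purrr::map(rec$indices, function(ri) {
    dd <- abs(ref_i - ri)
    j <- which(dd == min(dd))[1] # earlier reference wins ties
    tibble::tibble(rec_index = ri, ref_index = ref_i[j],
                   dt_s = (ri - ref_i[j]) / rec$fs)
  })
  dplyr::bind_rows(pairs)
}

#' Beat-timing error
#'
#' Mean absolute time difference, in seconds, over all matched beats
#' (reconstructed peak vs its nearest reference peak, no tolerance window).
#'
#' @param rec,ref Non-empty [peak_set()]s at the same rate.
#' @return Scalar seconds.
#' @export
beat_timing_error <- function(rec, ref) {
  if (!length(rec$indices) || !length(ref$indices)) {
    abort("beat-timing error undefined for empty peak sets.",
          class = "ppg2ecg_error_degenerate")
  }
  mean(abs(match_peaks(rec, ref)$dt_s))
}
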