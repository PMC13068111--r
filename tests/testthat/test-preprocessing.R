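test_that("FIR kernels are type-I: odd, symmetric, linear phase", {
  for (band in list(c(0.5, 8), c(0.5, 40), c(5, 15))) {
    k <- design_fir(125, band, 251)
    expect_identical(length(k$taps) %% 2L, 1L)
    expect_lt(max(abs(k$taps - rev(k$taps))), 1e-12)
    # constant group delay across the passband within 0.5 sample
    f <- seq(band[1] * 1.5, band[2] * 0.8, length.out = 9)
    gd <- fir_group_delay(k$taps, 125, f)
    expect_lt(max(abs(gd - (length(k$taps) - 1) / 2)), 0.5)
  }
  expect_error(design_fir(125, c(0.5, 8), 250), class = "ppg2ecg_error_even_taps")
  expect_error(design_fir(125, c(10, 70), 251), class = "ppg2ecg_error_band")
})

test_that("default PPG and ECG designs meet the band contract", {
  kp <- design_fir(125, c(0.5, 8))
  gain_db <- function(k, f) 20 * log10(Mod(fir_response(k, f)))
  expect_lt(abs(gain_db(kp, 4)), 1)                 # unity at band center
  expect_lt(gain_db(kp, 0.05), -20)                 # 0.1 * low edge
  expect_lt(gain_db(kp, 16), -20)                   # 2 * high edge
  ke <- design_fir(125, c(0.5, 40))
  expect_lt(abs(gain_db(ke, 10)), 1)
  expect_lt(gain_db(ke, 0.05), -20)
  expect_lt(gain_db(ke, 56.25), -20)                # 0.45 * fs
})

test_that("filtering is zero-phase and attenuates out-of-band power", {
  k <- design_fir(125, c(0.5, 8), 401)
  s <- sine_signal(2, fs = 125, dur_s = 8)
  y <- apply_fir(s, k)
  # interior cross-correlation peaks at lag 0
  i <- 300:700
  cc <- stats::ccf(y$samples[i], s$samples[i], lag.max = 4, plot = FALSE)
  expect_identical(as.integer(cc$lag[which.max(cc$acf)]), 0L)
  expect_gt(max(cc$acf), 0.99)

  t <- seq(0, 8, by = 1 / 125)
  noisy <- bio_signal(1 + sin(2 * pi * 30 * t), 125)
  yn <- apply_fir(noisy, k)$samples[i]
  pow_before <- mean(sin(2 * pi * 30 * t[i])^2)
  # remove any residual slow component before measuring 30 Hz power
  expect_lt(10 * log10(mean(yn^2) / pow_before), -20)

  z <- apply_fir(bio_signal(rep(0, 500), 125), k)
  expect_identical(max(abs(z$samples)), 0)
})

test_that("fs mismatch between kernel and signal is rejected", {
  k <- design_fir(125, c(0.5, 8), 101)
  expect_error(apply_fir(sine_signal(2, fs = 250), k),
               class = "ppg2ecg_error_fs_mismatch")
})

test_that("lag estimation recovers a constructed shift and the simulator PTT", {
  rec <- clean_record(duration_s = 30)
  # surrogate: ppg whose first difference is the ECG delayed by 30 samples
  e <- rec$ecg$samples
  shifted <- c(rep(0, 30), e[1:(length(e) - 30)])
  ppg_sur <- bio_signal(cumsum(c(0, shifted))[seq_along(e)], 125)
  expect_identical(estimate_lag(rec$ecg, ppg_sur), 30L)

  lag <- estimate_lag(rec$ecg, rec$ppg)
  expect_lte(abs(lag - 31L), 4L)
  # oracle equivalence: exhaustive scan over every admissible lag of the
  # same correlate (QRS-band ECG vs PPG first difference)
  zs <- function(v) (v - mean(v)) / sd(v)
  ez <- zs(ppg2ecg:::qrs_emphasis(rec$ecg)$samples)
  dz <- zs(c(diff(rec$ppg$samples), 0))
  n <- length(ez)
  scan <- vapply(0:75, function(l) {
    cor(ez[seq_len(n - l)], dz[l + seq_len(n - l)])
  }, numeric(1))
  expect_identical(lag, as.integer(which.max(scan) - 1L))

  expect_identical(estimate_lag(rec$ecg, rec$ppg, max_lag_s = 0), 0L)
  flat <- bio_signal(rep(1, length(rec$ppg$samples)), 125)
  expect_error(estimate_lag(flat, rec$ppg), class = "ppg2ecg_error_constant")
})

test_that("alignment truncates consistently and is idempotent", {
  rec <- clean_record(duration_s = 20)
  n <- length(rec$ecg$samples)
  a0 <- align_record(rec, 0L)
  expect_identical(a0$ecg$samples, rec$ecg$samples)
  a30 <- align_record(rec, 30L)
  expect_identical(length(a30$ecg$samples), n - 30L)
  expect_identical(length(a30$ppg$samples), n - 30L)
  expect_identical(a30$ppg$samples[1], rec$ppg$samples[31])
  expect_error(align_record(rec, n), class = "ppg2ecg_error_lag")

  lag <- estimate_lag(rec$ecg, rec$ppg)
  aligned <- align_record(rec, lag)
  expect_lte(estimate_lag(aligned$ecg, aligned$ppg), 2L)
})

test_that("segmentation counts, exhaustive tiling, and short-record error", {
  mk <- function(n) {
    paired_record(bio_signal(seq_len(n), 125), bio_signal(seq_len(n) + 1, 125), "s")
  }
  expect_identical(nrow(segment_record(mk(1024), 512, 512)), 2L)
  expect_identical(nrow(segment_record(mk(1024), 512, 256)), 3L)
  expect_error(segment_record(mk(500), 512, 512),
               class = "ppg2ecg_error_short_record")
  # tiling: at stride == length the index ranges cover [1, K * L] exactly
  segs <- segment_record(mk(1030), 512, 512)
  covered <- unlist(purrr::map(segs$start_index, ~ .x:(.x + 511)))
  expect_identical(covered, 1:1024)
})

test_that("normalisation round-trips and handles degenerate input", {
  nm <- normalize_segment(c(1, 2, 3), "minmax")
  expect_equal(nm$values, c(0, 0.5, 1))
  expect_equal(unname(nm$denorm), c(1, 2))
  cst <- normalize_segment(c(5, 5, 5), "minmax")
  expect_equal(cst$values, c(0, 0, 0))
  expect_equal(unname(cst$denorm[2]), 1e-8)
  set.seed(4)
  v <- rnorm(100)
  for (meth in c("minmax", "zscore")) {
    z <- normalize_segment(v, meth)
    expect_lt(max(abs(denormalize_segment(z$values, z$denorm) - v)), 1e-9)
  }
})
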