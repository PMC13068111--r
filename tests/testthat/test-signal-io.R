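test_that("bio_signal and paired_record enforce their invariants", {
  expect_error(bio_signal(numeric(0), 125), class = "ppg2ecg_error_empty_signal")
  expect_error(bio_signal(c(1, NA), 125), class = "ppg2ecg_error_nonfinite")
  expect_error(bio_signal(1:3, -5), class = "ppg2ecg_error_bad_fs")
  e <- bio_signal(1:10, 125, "II")
  p <- bio_signal(1:10, 125, "PLETH")
  expect_error(paired_record(e, p, ""), class = "ppg2ecg_error_subject_id")
  expect_error(paired_record(e, p, "s", true_r_peaks = c(5, 3)),
               class = "ppg2ecg_error_peaks")
  expect_error(paired_record(e, p, "s", true_r_peaks = c(2, 11)),
               class = "ppg2ecg_error_peaks")
  rec <- paired_record(e, p, "s", true_r_peaks = c(2, 7))
  expect_s3_class(rec, "paired_record")
})

test_that("toy CSV with per-column rates parses to a paired record", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ecg@125Hz,ppg@125Hz", "0,1", "0,1"), f)
  rec <- read_record(f, format = "csv")
  expect_equal(rec$ecg$samples, c(0, 0))
  expect_equal(rec$ppg$samples, c(1, 1))
  expect_equal(rec$ecg$fs, 125)
  expect_equal(rec$ppg$fs, 125)
})

test_that("CSV with a NaN sample is rejected as non-finite", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("ecg@125Hz,ppg@125Hz", "0,1", "NaN,1"), f)
  expect_error(read_record(f, format = "csv"), class = "ppg2ecg_error_nonfinite")
})

test_that("missing files and unmatched channels raise named errors", {
  expect_error(read_record(file.path(tempdir(), "nope.csv"), format = "csv"),
               class = "ppg2ecg_error_missing_file")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("foo@125Hz,bar@125Hz", "0,1"), f)
  expect_error(read_record(f, format = "csv"), class = "ppg2ecg_error_no_channel")
})

test_that("CSV write/read round-trips samples, rates and peak sidecar", {
  rec <- clean_record(duration_s = 10, noise_sd = 0.02)
  d <- withr::local_tempdir()
  f <- file.path(d, "sub.csv")
  write_record(rec, f, format = "csv")
  back <- read_record(f, format = "csv", subject_id = rec$subject_id)
  expect_equal(back$ecg$samples, rec$ecg$samples, tolerance = 1e-12)
  expect_equal(back$ppg$samples, rec$ppg$samples, tolerance = 1e-12)
  expect_identical(back$ecg$fs, rec$ecg$fs)
  expect_identical(back$true_r_peaks, rec$true_r_peaks)
})

test_that("WFDB format-16 bytes written independently are decoded correctly", {
  # construct header and .dat by hand: physical = (raw - baseline) / gain
  d <- withr::local_tempdir()
  raw_ecg <- c(100L, -200L, 300L)
  raw_ppg <- c(10L, 20L, 30L)
  writeLines(c("r1 2 125 3",
               "r1.dat 16 200(50)/mV 16 0 0 0 0 II",
               "r1.dat 16 100(0)/NU 16 0 0 0 0 PLETH"),
             file.path(d, "r1.hea"))
  writeBin(as.integer(rbind(raw_ecg, raw_ppg)), file.path(d, "r1.dat"),
           size = 2L, endian = "little")
  rec <- read_record(file.path(d, "r1"), format = "wfdb")
  expect_equal(rec$ecg$samples, (raw_ecg - 50) / 200)
  expect_equal(rec$ppg$samples, raw_ppg / 100)
  expect_equal(rec$ecg$fs, 125)
  expect_identical(rec$ecg$label, "II")
})

test_that("WFDB write/read round-trips at 16-bit quantisation", {
  rec <- clean_record(duration_s = 5)
  d <- withr::local_tempdir()
  write_record(rec, file.path(d, "rt"), format = "wfdb")
  back <- read_record(file.path(d, "rt"), format = "wfdb")
  # gain 1000 => half-LSB quantisation error bound 5e-4
  expect_lt(max(abs(back$ecg$samples - rec$ecg$samples)), 5.1e-4)
  expect_identical(back$ecg$fs, rec$ecg$fs)
  expect_identical(back$true_r_peaks, rec$true_r_peaks)
})

test_that("resampling preserves DC, duration, and sinusoid shape", {
  const <- bio_signal(rep(3, 250), 125)
  up <- resample_signal(const, 250)
  expect_lt(max(abs(up$samples - 3)), 1e-6)
  expect_lt(abs(length(up) / 250 - length(const) / 125), 1 / 250)

  s <- sine_signal(1, fs = 125, dur_s = 4)
  r <- resample_signal(s, 500)
  t_out <- (seq_along(r$samples) - 1) / 500
  interior <- which(t_out > 0.2 & t_out < 3.8)
  expect_lt(max(abs(r$samples[interior] - sin(2 * pi * t_out[interior]))), 1e-3)

  same <- resample_signal(s, 125)
  expect_identical(same$samples, s$samples)
})

test_that("downsampling applies anti-aliasing", {
  # a 30 Hz tone is above the 50 Hz target's Nyquist and must be removed,
  # while the in-band 2 Hz tone survives
  t <- seq(0, 4, by = 1 / 500)
  s <- bio_signal(sin(2 * pi * 30 * t) + sin(2 * pi * 2 * t), 500)
  dn <- resample_signal(s, 50)
  t_out <- (seq_along(dn$samples) - 1) / 50
  interior <- which(t_out > 0.5 & t_out < 3.5)
  resid <- dn$samples[interior] - sin(2 * pi * 2 * t_out[interior])
  expect_lt(sd(resid), 0.15)
})
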