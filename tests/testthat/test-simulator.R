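test_that("degenerate RR draw is exactly periodic and beat counts add up", {
  cfg <- sim_config(duration_s = 60, hr_mean = 60, hr_sd = 0, pvc_rate = 0,
                    seed = 1)
  set.seed(1)
  tr <- simulate_rr(cfg)
  expect_true(all(abs(tr$rr_s - 1.0) < 1e-12))
  expect_gte(length(tr$r_times_s), 58)
  expect_lte(length(tr$r_times_s), 61)
  expect_equal(tr$rr_s, diff(tr$r_times_s))
})

test_that("premature beats preserve the two-beat interval sum", {
  cfg <- sim_config(duration_s = 120, hr_mean = 70, hr_sd = 0, pvc_rate = 10,
                    seed = 5)
  set.seed(5)
  tr <- simulate_rr(cfg)
  pvc <- which(tr$beat_labels == "premature")
  pvc <- pvc[pvc > 1 & pvc < length(tr$r_times_s)]
  expect_gt(length(pvc), 0)
  for (i in pvc) {
    # shortened interval then compensatory pause: sum = 2 x base interval
    rr_in <- tr$r_times_s[i] - tr$r_times_s[i - 1]
    rr_out <- tr$r_times_s[i + 1] - tr$r_times_s[i]
    expect_equal(rr_in + rr_out, 2 * (rr_in / 0.65), tolerance = 1e-9)
  }
})

test_that("R-wave centers are the waveform argmax at the stored indices", {
  rec <- clean_record(duration_s = 30)
  x <- rec$ecg$samples
  for (pk in rec$true_r_peaks[2:(length(rec$true_r_peaks) - 1)]) {
    span <- (pk - 12):(pk + 12)
    expect_lte(abs(span[which.max(x[span])] - pk), 1)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(duration_s = 20, seed = 42, noise_sd = 0.05,
                    artifact_rate = 2, pvc_rate = 2)
  a <- simulate_record(cfg)
  b <- simulate_record(cfg)
  expect_identical(a$ecg$samples, b$ecg$samples)
  expect_identical(a$ppg$samples, b$ppg$samples)
  expect_identical(a$true_r_peaks, b$true_r_peaks)
})

test_that("PPG transit delay is recoverable by a brute-force lag scan", {
  rec <- clean_record(duration_s = 60, ptt_s = 0.25)
  zs <- function(v) (v - mean(v)) / sd(v)
  e <- zs(rec$ecg$samples)
  d <- zs(c(diff(rec$ppg$samples), 0))
  n <- length(e)
  scan <- vapply(0:75, function(l) {
    cor(e[seq_len(n - l)], d[l + seq_len(n - l)])
  }, numeric(1))
  expect_lte(abs((which.max(scan) - 1L) - round(0.25 * 125)), 1)
})

test_that("clean PPG is an exact sum of per-beat pulse templates", {
  cfg <- sim_config(duration_s = 20, hr_mean = 70, hr_sd = 0, ptt_jitter_s = 0,
                    noise_sd = 0, baseline_wander_amp = 0, artifact_rate = 0,
                    seed = 2)
  rec <- simulate_record(cfg)
  truth <- attr(rec, "truth")
  fs <- cfg$fs
  tt <- (seq_along(rec$ppg$samples) - 1) / fs
  manual <- numeric(length(tt))
  for (rt in truth$r_times_s) {
    apex <- rt + cfg$ptt_s + 0.02
    dt <- tt - apex
    pulse <- ifelse(dt < 0, exp(-dt^2 / (2 * 0.02^2)), exp(-dt^2 / (2 * 0.11^2)))
    keep <- abs(dt) < 5 * 0.02 | (dt >= 0 & dt < 6 * 0.11 + 0.4)
    dic <- 0.35 * exp(-(dt - 0.22)^2 / (2 * 0.10^2))
    manual <- manual + ifelse(keep, pulse + dic, 0)
  }
  expect_lt(max(abs(rec$ppg$samples - manual)), 1e-9)
})

test_that("doubling the noise level doubles the residual sd", {
  base <- sim_config(duration_s = 60, noise_sd = 0, baseline_wander_amp = 0,
                     ptt_jitter_s = 0, hr_sd = 0, seed = 9)
  clean <- simulate_record(base)
  sd_at <- function(ns) {
    cfg <- base
    cfg$noise_sd <- ns
    sd(simulate_record(cfg)$ppg$samples - clean$ppg$samples)
  }
  s1 <- sd_at(0.05)
  s2 <- sd_at(0.10)
  expect_lt(abs(s2 / s1 - 2), 0.1)
})

test_that("cohorts are reproducible, schema-stable and invariant-clean", {
  a <- simulate_cohort(5, preset = "icu", duration_s = 20, seed = 3)
  b <- simulate_cohort(5, preset = "icu", duration_s = 20, seed = 3)
  c2 <- simulate_cohort(5, preset = "icu", duration_s = 20, seed = 4)
  expect_identical(length(a), 5L)
  for (i in seq_along(a)) {
    expect_identical(a[[i]]$ecg$samples, b[[i]]$ecg$samples)
    expect_s3_class(a[[i]], "paired_record")
    expect_true(all(diff(a[[i]]$true_r_peaks) > 0))
  }
  expect_false(identical(a[[1]]$ecg$samples, c2[[1]]$ecg$samples))
  expect_identical(vapply(c2, function(r) r$subject_id, character(1)),
                   vapply(a, function(r) r$subject_id, character(1)))
})

test_that("cohort round-trips through the on-disk manifest format", {
  d <- withr::local_tempdir()
  recs <- simulate_cohort(3, preset = "clean", duration_s = 10, seed = 6)
  write_cohort(recs, d)
  back <- read_cohort(d)
  expect_identical(length(back), 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$ecg$samples, recs[[i]]$ecg$samples, tolerance = 1e-12)
    expect_identical(back[[i]]$true_r_peaks, recs[[i]]$true_r_peaks)
  }
})
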