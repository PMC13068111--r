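#' Simulator configuration
#'
#' Parameters of the paired ECG/PPG generator. `ptt_s` is the pulse transit
#' time measured from the R peak to the point of steepest systolic upstroke
#' of the PPG (the PPG's sharpest landmark, and the one cross-correlation
#' alignment locks onto). Three presets mirror qualitatively distinct data
#' regimes: `"clean"` (bench-quality sinus recordings), `"icu"` (complex
#' morphology with premature beats), `"ambulatory"` (motion artifacts,
#' heavy baseline wander).
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Record length, seconds.
#' @param hr_mean,hr_sd Heart rate mean / beat-to-beat sd, bpm.
#' @param ptt_s Pulse transit time, seconds.
#' @param ptt_jitter_s Per-beat transit-time jitter sd, seconds.
#' @param noise_sd White-noise sd relative to unit pulse/R amplitude.
#' @param baseline_wander_amp 0.2 Hz baseline-wander amplitude (relative).
#' @param artifact_rate Motion-artifact bursts per minute (PPG only).
#' @param pvc_rate Premature beats per minute (0 = sinus only).
#' @param seed Integer seed.
#' @param preset Optional preset name applied before explicit arguments.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(fs = 125, duration_s = 60, hr_mean = 70, hr_sd = 3,
                       ptt_s = 0.25, ptt_jitter_s = 0.005, noise_sd = 0.02,
                       baseline_wander_amp = 0.05, artifact_rate = 0,
                       pvc_rate = 0, seed = 1L, preset = NULL) {
  cfg <- list(fs = fs, duration_s = duration_s, hr_mean = hr_mean,
              hr_sd = hr_sd, ptt_s = ptt_s, ptt_jitter_s = ptt_jitter_s,
              noise_sd = noise_sd, baseline_wander_amp = baseline_wander_amp,
              artifact_rate = artifact_rate, pvc_rate = pvc_rate,
              seed = as.integer(seed))
  if (!is.null(preset)) {
    pre <- switch(match.arg(preset, c("clean", "icu", "ambulatory")),
      clean = list(hr_sd = 2, noise_sd = 0.02, baseline_wander_amp = 0.05,
                   artifact_rate = 0, pvc_rate = 0),
      icu = list(hr_sd = 5, noise_sd = 0.05, baseline_wander_amp = 0.15,
                 artifact_rate = 0.5, pvc_rate = 3),
      ambulatory = list(hr_sd = 4, noise_sd = 0.10, baseline_wander_amp = 0.3,
                        artifact_rate = 2, pvc_rate = 1)
    )
    supplied <- names(as.list(match.call()))[-1]
    for (k in setdiff(names(pre), supplied)) cfg[[k]] <- pre[[k]]
  }
  if (cfg$fs <= 0) abort("fs must be > 0.", class = "ppg2ecg_error_config")
  if (cfg$hr_mean < 30 || cfg$hr_mean > 220) {
    abort("hr_mean outside [30, 220] bpm.", class = "ppg2ecg_error_config")
  }
  if (cfg$ptt_s < 0 || cfg$artifact_rate < 0 || cfg$pvc_rate < 0) {
    abort("rates and ptt_s must be >= 0.", class = "ppg2ecg_error_config")
  }
  structure(cfg, class = "sim_config")
}

#' Draw an RR-interval sequence with optional premature beats
#'
#' RR intervals are `60 / N(hr_mean, hr_sd)` clipped to `[0.3, 2.0]` s.
#' With per-beat probability `pvc_rate * mean RR / 60`, a premature beat
#' shortens its interval by 35% and is followed by a compensatory pause
#' preserving the two-beat sum (the classic full compensatory pattern).
#'
#' @param config A [sim_config()]. RNG state is taken as-is; seed at the
#'   record level (see [simulate_record()]).
#' @return List of class `ground_truth`: `r_times_s` (strictly increasing
#'   R-peak times), `rr_s` (successive differences), `beat_labels`
#'   (`"normal"`/`"premature"`).
#' @export
simulate_rr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  mean_rr <- 60 / config$hr_mean
  p_pvc <- min(1, config$pvc_rate * mean_rr / 60)
  t <- 0.5 # first beat away from the record edge
  times <- c()
  labels <- c()
  margin <- 0.5
  repeat {
    hr <- rnorm(1, config$hr_mean, config$hr_sd)
    rr <- min(2.0, max(0.3, 60 / max(hr, 1)))
    if (p_pvc > 0 && rbinom(1, 1, p_pvc) == 1) {
      t1 <- t + 0.65 * rr
      t2 <- t1 + 1.35 * rr # 2-beat sum preserved: 0.65 + 1.35 = 2
      if (t2 > config$duration_s - margin) break
      times <- c(times, t1, t2)
      labels <- c(labels, "premature", "normal")
      t <- t2
    } else {
      t1 <- t + rr
      if (t1 > config$duration_s - margin) break
      times <- c(times, t1)
      labels <- c(labels, "normal")
      t <- t1
    }
  }
  if (length(times) < 2L) abort("record too short for two beats.",
                                class = "ppg2ecg_error_config")
  structure(list(r_times_s = times, rr_s = diff(times), beat_labels = labels),
            class = "ground_truth")
}

# Wave rendering constants: P, Q, R, S, T as Gaussians on each beat's phase
# axis (the sum-of-Gaussians morphology of the dynamical ECG model family),
# scaled to a ~1.5 mV R wave.
ecg_wave_angles <- c(P = -pi / 3, Q = -pi / 12, R = 0, S = pi / 12, T = pi / 2)
ecg_wave_amps <- c(P = 0.12, Q = -0.50, R = 1.50, S = -0.75, T = 0.30)
ecg_wave_widths <- c(P = 0.25, Q = 0.10, R = 0.10, S = 0.10, T = 0.40)

#' Render a synthetic ECG from ground-truth beat times
#'
#' Each beat is a sum of five Gaussian waves (P, Q, R, S, T) positioned on
#' the beat's phase axis; premature beats lose the P wave and get a 1.5x
#' wider QRS. White noise (`noise_sd` x 1.5 mV) and half-amplitude baseline
#' wander are added on top. Returned R-peak indices are the exact sample
#' positions of the R-wave centers.
#'
#' @param truth A `ground_truth` from [simulate_rr()].
#' @param config The same [sim_config()].
#' @return List: `signal` ([bio_signal], mV), `r_peaks` (1-based indices).
#' @export
synth_ecg <- function(truth, config) {
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  times <- truth$r_times_s
  k <- length(times)
  for (b in seq_len(k)) {
    rr_prev <- if (b > 1) times[b] - times[b - 1] else truth$rr_s[1]
    rr_next <- if (b < k) times[b + 1] - times[b] else truth$rr_s[length(truth$rr_s)]
    premature <- truth$beat_labels[b] == "premature"
    for (wv in names(ecg_wave_angles)) {
      if (premature && wv == "P") next
      rr_loc <- if (ecg_wave_angles[[wv]] < 0) rr_prev else rr_next
      width_mult <- if (premature && wv %in% c("Q", "R", "S")) 1.5 else 1
      mu <- times[b] + ecg_wave_angles[[wv]] / (2 * pi) * rr_loc
      sg <- ecg_wave_widths[[wv]] * width_mult / (2 * pi) * rr_loc
      span <- which(tt > mu - 5 * sg & tt < mu + 5 * sg)
      x[span] <- x[span] + ecg_wave_amps[[wv]] * exp(-(tt[span] - mu)^2 / (2 * sg^2))
    }
  }
  if (config$baseline_wander_amp > 0) {
    x <- x + 0.5 * config$baseline_wander_amp * sin(2 * pi * 0.2 * tt + runif(1, 0, 2 * pi))
  }
  if (config$noise_sd > 0) x <- x + rnorm(n, 0, config$noise_sd * 1.5)
  r_peaks <- pmin(n, pmax(1L, as.integer(round(times * fs)) + 1L))
  list(signal = bio_signal(x, fs, "ECG"), r_peaks = r_peaks)
}

#' Render a synthetic PPG from ground-truth beat times
#'
#' Each beat contributes an asymmetric systolic pulse (fast rise, slow
#' decay; steepest upstroke at `r_time + ptt_s + jitter`) plus a dicrotic
#' bump 0.22 s later at 0.35 relative amplitude. Additive disturbances:
#' 0.2 Hz baseline wander, white noise, and Poisson motion-artifact bursts
#' of 1-3 s at five times the noise level.
#'
#' @param truth A `ground_truth` from [simulate_rr()].
#' @param config The same [sim_config()].
#' @return A [bio_signal] (arbitrary units).
#' @export
synth_ppg <- function(truth, config) {
  fs <- config$fs
  n <- as.integer(round(config$duration_s * fs))
  tt <- (seq_len(n) - 1) / fs
  x <- numeric(n)
  sg_rise <- 0.02  # steep systolic upstroke; derivative peaks sg_rise before apex
  sg_fall <- 0.11
  sg_dic <- 0.10
  for (b in seq_along(truth$r_times_s)) {
    jit <- if (config$ptt_jitter_s > 0) rnorm(1, 0, config$ptt_jitter_s) else 0
    apex <- truth$r_times_s[b] + config$ptt_s + jit + sg_rise
    span <- which(tt > apex - 5 * sg_rise & tt < apex + 6 * sg_fall + 0.4)
    dt <- tt[span] - apex
    pulse <- ifelse(dt < 0, exp(-dt^2 / (2 * sg_rise^2)), exp(-dt^2 / (2 * sg_fall^2)))
    dic <- 0.35 * exp(-(dt - 0.22)^2 / (2 * sg_dic^2))
    x[span] <- x[span] + pulse + dic
  }
  if (config$baseline_wander_amp > 0) {
    x <- x + config$baseline_wander_amp * sin(2 * pi * 0.2 * tt + runif(1, 0, 2 * pi))
  }
  if (config$noise_sd > 0) x <- x + rnorm(n, 0, config$noise_sd)
  if (config$artifact_rate > 0) {
    n_ev <- stats::rpois(1, config$artifact_rate * config$duration_s / 60)
    amp <- 5 * max(config$noise_sd, 0.02)
    for (ev in seq_len(n_ev)) {
      len <- runif(1, 1, 3)
      start <- runif(1, 0, max(0, config$duration_s - len))
      span <- which(tt >= start & tt < start + len)
      x[span] <- x[span] + rnorm(length(span), 0, amp)
    }
  }
  bio_signal(x, fs, "PPG")
}

#' Simulate one paired record
#'
#' Seeds the RNG from `config$seed`, draws the beat sequence and renders
#' both channels, so equal configs give byte-identical records.
#'
#' @param config A [sim_config()].
#' @param subject_id Identifier.
#' @return A [paired_record] with `true_r_peaks` filled; the `ground_truth`
#'   is attached as attribute `"truth"`.
#' @export
simulate_record <- function(config = sim_config(), subject_id = "sim01") {
  set.seed(config$seed)
  truth <- simulate_rr(config)
  e <- synth_ecg(truth, config)
  p <- synth_ppg(truth, config)
  rec <- paired_record(e$signal, p, subject_id, true_r_peaks = e$r_peaks)
  attr(rec, "truth") <- truth
  rec
}

#' Simulate a cohort of paired records
#'
#' Per-subject physiology is drawn from uniform ranges (heart rate in
#' `hr_range` bpm, transit time in `ptt_range` s) under the cohort seed;
#' each subject then gets a derived record seed, so the whole cohort is
#' reproducible from `(n_subjects, preset, seed)`.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param preset `"clean"`, `"icu"` or `"ambulatory"`.
#' @param duration_s Record length per subject, seconds.
#' @param hr_range,ptt_range Uniform sampling ranges.
#' @param fs Sampling rate, Hz.
#' @param seed Cohort seed.
#' @return List of [paired_record]s.
#' @export
simulate_cohort <- function(n_subjects, preset = "clean", duration_s = 120,
                            hr_range = c(55, 95), ptt_range = c(0.2, 0.32),
                            fs = 125, seed = 1L) {
  stopifnot(n_subjects >= 1)
  set.seed(seed)
  hr <- runif(n_subjects, hr_range[1], hr_range[2])
  ptt <- runif(n_subjects, ptt_range[1], ptt_range[2])
  sub_seed <- sample.int(2^30, n_subjects)
  purrr::map(seq_len(n_subjects), function(i) {
    cfg <- sim_config(fs = fs, duration_s = duration_s, hr_mean = hr[i],
                      ptt_s = ptt[i], seed = sub_seed[i], preset = preset)
    simulate_record(cfg, subject_id = sprintf("sim%02d", i))
  })
}

#' Write a simulated cohort to disk
#'
#' Emits one CSV record plus `.rpeaks` sidecar per subject and a
#' `manifest.json` listing subjects and files.
#'
#' @param records List of [paired_record]s.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- purrr::map(records, function(r) {
    f <- file.path(dir, paste0(r$subject_id, ".csv"))
    write_record(r, f, format = "csv")
    list(subject_id = r$subject_id, file = basename(f),
         fs = r$ecg$fs, n_beats = length(r$true_r_peaks))
  })
  jsonlite::write_json(entries, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return List of [paired_record]s.
#' @export
read_cohort <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  purrr::map(seq_len(nrow(man)), function(i) {
    read_record(file.path(dir, man$file[i]), format = "csv",
                subject_id = man$subject_id[i])
  })
}
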