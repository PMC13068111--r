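# Shared fixtures built in code at test time.

sine_signal <- function(freq_hz, fs = 125, dur_s = 4, amp = 1, phase = 0) {
  t <- seq(0, dur_s, by = 1 / fs)
  bio_signal(amp * sin(2 * pi * freq_hz * t + phase), fs)
}

# noise-free, jitter-free simulated record with fixed physiology
clean_record <- function(duration_s = 60, hr_mean = 70, ptt_s = 0.25,
                         fs = 125, seed = 3, noise_sd = 0,
                         subject_id = "fix01") {
  simulate_record(
    sim_config(fs = fs, duration_s = duration_s, hr_mean = hr_mean,
               hr_sd = 0, ptt_s = ptt_s, ptt_jitter_s = 0,
               noise_sd = noise_sd, baseline_wander_amp = 0,
               artifact_rate = 0, pvc_rate = 0, seed = seed),
    subject_id = subject_id
  )
}

# tiny model for shape/oracle tests
tiny_model <- function(n_blocks = 2, hidden_units = 4, connection = "dense",
                       input_len = 16, seed = 11) {
  init_model(model_config(n_blocks = n_blocks, hidden_units = hidden_units,
                          connection = connection, input_len = input_len,
                          seed = seed))
}

# pure-R single-direction LSTM, an implementation-independent reference for
# the compiled recurrence
r_lstm_dir <- function(W, U, b, X, rev = FALSE) {
  # X: D x B x T array; returns H x B x T
  H <- ncol(U)
  d <- dim(X)
  B <- d[2]; T_ <- d[3]
  out <- array(0, c(H, B, T_))
  h <- matrix(0, H, B); cc <- matrix(0, H, B)
  ord <- if (rev) rev(seq_len(T_)) else seq_len(T_)
  sig <- function(z) 1 / (1 + exp(-z))
  for (t in ord) {
    z <- W %*% matrix(X[, , t], d[1], B) + U %*% h + b
    i <- sig(z[1:H, , drop = FALSE])
    f <- sig(z[(H + 1):(2 * H), , drop = FALSE])
    g <- tanh(z[(2 * H + 1):(3 * H), , drop = FALSE])
    o <- sig(z[(3 * H + 1):(4 * H), , drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    out[, , t] <- h
  }
  out
}


abind3 <- function(a, b) {
  # bind along the first (feature) axis, preserving B x T
  d <- dim(a)
  out <- array(0, c(d[1] + dim(b)[1], d[2], d[3]))
  out[seq_len(d[1]), , ] <- a
  out[d[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

# analytic group delay of an FIR kernel: tau(w) = Re(DFT(n*h) / DFT(h))
fir_group_delay <- function(taps, fs, freqs_hz) {
  n <- seq_along(taps) - 1
  vapply(freqs_hz, function(f) {
    w <- 2 * pi * f / fs
    num <- sum(n * taps * exp(-1i * w * n))
    den <- sum(taps * exp(-1i * w * n))
    Re(num / den)
  }, numeric(1))
}
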