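#' Pearson correlation between two waveforms
#'
#' Standard sample Pearson correlation. Constant input is an error (the
#' coefficient is undefined there), never silently zero.
#'
#' @param a,b Equal-length numeric vectors, length >= 2, both non-constant.
#' @return Scalar in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (length(a) != length(b)) abort("length mismatch.", class = "ppg2ecg_error_length")
  if (length(a) < 2L) abort("need length >= 2.", class = "ppg2ecg_error_length")
  if (sd(a) < 1e-14 || sd(b) < 1e-14) {
    abort("Pearson r undefined for constant input.",
          class = "ppg2ecg_error_constant")
  }
  cor(a, b)
}

#' Mean and Student-t confidence interval across subjects
#'
#' Cohort metrics are summarised as the across-subject mean with a
#' `mean +/- t[(1+level)/2, n-1] * sd / sqrt(n)` interval. With zero
#' variance the interval degenerates to the mean, as does `level = 0`.
#'
#' @param values Per-subject metric values (n >= 2).
#' @param level Confidence level, default 0.95.
#' @return Named numeric `c(mean, ci_low, ci_high)`.
#' @export
summarize_subjects <- function(values, level = 0.95) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2L) abort("need at least 2 subjects.", class = "ppg2ecg_error_length")
  m <- mean(values)
  half <- qt((1 + level) / 2, df = n - 1L) * sd(values) / sqrt(n)
  c(mean = m, ci_low = m - half, ci_high = m + half)
}

#' Paired Wilcoxon signed-rank test
#'
#' Signed-rank test on the paired differences `a - b` with tie-averaged
#' ranks and zero differences dropped. The null distribution is exact
#' (computed by dynamic programming over signed-rank sums, conditional on
#' the observed ranks) for `n <= 25` and a normal approximation with
#' continuity and tie corrections above. Two-sided by default; the
#' one-sided p (alternative: `a` tends to exceed `b`) is reported alongside.
#'
#' @param a,b Equal-length numeric vectors; at least 5 non-zero differences.
#' @return One-row tibble: `n` (non-zero pairs), `w_pos`, `w_neg`,
#'   `statistic` (`min(w_pos, w_neg)`), `p_value` (two-sided),
#'   `p_one_sided`, `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_paired <- function(a, b) {
  if (length(a) != length(b)) abort("length mismatch.", class = "ppg2ecg_error_length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) abort("all differences zero.", class = "ppg2ecg_error_degenerate")
  if (n < 5L) abort("need >= 5 non-zero differences.", class = "ppg2ecg_error_length")
  rk <- rank(abs(d)) # tie-averaged
  w_pos <- sum(rk[d > 0])
  w_neg <- sum(rk[d < 0])
  if (n <= 25L) {
    # exact distribution of the positive-rank sum over all 2^n sign vectors,
    # on doubled ranks so tie-averaged half-ranks stay integral
    r2 <- as.integer(round(2 * rk))
    total <- sum(r2)
    counts <- numeric(total + 1L) # counts[s + 1] = #assignments with sum s
    counts[1] <- 1
    for (r in r2) {
      shifted <- c(rep(0, r), counts[seq_len(total + 1L - r)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    cdf_at <- function(w) sum(probs[seq_len(min(length(probs), round(2 * w) + 1L))])
    p_le_neg <- cdf_at(w_neg)        # P(W- <= w_neg): evidence a > b
    p_le_min <- cdf_at(min(w_pos, w_neg))
    p_two <- min(1, 2 * p_le_min)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie_tab^3 - tie_tab) / 48
    z_min <- (min(w_pos, w_neg) - mu + 0.5) / sqrt(sig2)
    p_two <- min(1, 2 * pnorm(z_min))
    p_le_neg <- pnorm((w_neg - mu + 0.5) / sqrt(sig2))
    method <- "normal"
  }
  tibble::tibble(n = n, w_pos = w_pos, w_neg = w_neg,
                 statistic = min(w_pos, w_neg),
                 p_value = p_two, p_one_sided = p_le_neg, method = method)
}
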