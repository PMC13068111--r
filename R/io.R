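#' Read a paired ECG/PPG record
#'
#' Two formats are supported. `"csv"` is a self-describing two-column dialect
#' whose header declares the sampling rate per column as `name@<fs>Hz`
#' (e.g. `ecg@125Hz,ppg@125Hz`); columns may have different lengths (trailing
#' cells empty) when the channels were sampled at different rates. `"wfdb"`
#' reads a PhysioNet-style header/.dat pair in the 16-bit little-endian
#' sample format, the layout used by the bedside-monitor waveform databases.
#'
#' Channels are picked by case-insensitive name substring: ECG-like channels
#' match any of `ecg_names`, PPG-like channels any of `ppg_names`. A sidecar
#' file `<path>.rpeaks` (one 0-based ECG sample index per line), if present,
#' populates `true_r_peaks`. No resampling is performed on read.
#'
#' @param path Record path. For `"wfdb"`, the header path with or without the
#'   `.hea` extension; for `"csv"`, the CSV file.
#' @param format `"csv"` or `"wfdb"`.
#' @param subject_id Identifier for the record; defaults to the file stem.
#' @param ecg_names,ppg_names Channel-name substrings used for selection,
#'   overridable because waveform-database channel naming is inconsistent.
#' @return A [paired_record].
#' @export
read_record <- function(path, format = c("csv", "wfdb"), subject_id = NULL,
                        ecg_names = c("ECG", "II"),
                        ppg_names = c("PLETH", "PPG")) {
  format <- match.arg(format)
  if (is.null(subject_id)) {
    subject_id <- sub("\\.(csv|hea)$", "", basename(path))
  }
  rec <- switch(format,
    csv = read_record_csv(path, subject_id, ecg_names, ppg_names),
    wfdb = read_record_wfdb(path, subject_id, ecg_names, ppg_names)
  )
  side <- paste0(sub("\\.(csv|hea)$", "", path), ".rpeaks")
  if (file.exists(side)) {
    pk <- scan(side, what = integer(), quiet = TRUE)
    rec <- paired_record(rec$ecg, rec$ppg, rec$subject_id, true_r_peaks = pk + 1L)
  }
  rec
}

parse_channel_header <- function(h) {
  m <- regmatches(h, regexec("^(.*)@([0-9.]+)Hz$", h))[[1]]
  if (length(m) != 3L) {
    abort(sprintf("CSV header column '%s' does not match 'name@<fs>Hz'.", h),
          class = "ppg2ecg_error_header")
  }
  list(name = m[2], fs = as.numeric(m[3]))
}

pick_channel <- function(names, patterns) {
  hits <- which(Reduce(`|`, lapply(patterns, function(p) {
    grepl(p, names, ignore.case = TRUE)
  })))
  if (!length(hits)) {
    abort(sprintf("no channel matching any of: %s (channels: %s)",
                  paste(patterns, collapse = ", "), paste(names, collapse = ", ")),
          class = "ppg2ecg_error_no_channel")
  }
  hits[1]
}

read_record_csv <- function(path, subject_id, ecg_names, ppg_names) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "ppg2ecg_error_missing_file")
  }
  df <- read.csv(path, check.names = FALSE)
  heads <- lapply(names(df), parse_channel_header)
  ch_names <- vapply(heads, `[[`, character(1), "name")
  i_ecg <- pick_channel(ch_names, ecg_names)
  i_ppg <- pick_channel(ch_names, ppg_names)
  get_col <- function(i) {
    v <- df[[i]]
    # explicit NaN/Inf is invalid data; plain NA is only legal as trailing
    # padding from unequal column lengths
    if (any(is.nan(v)) || any(is.infinite(v))) {
      abort("non-finite samples in CSV column.", class = "ppg2ecg_error_nonfinite")
    }
    v <- v[seq_len(max(which(!is.na(v)), 0L))]
    if (anyNA(v)) {
      abort("non-finite samples in CSV column.", class = "ppg2ecg_error_nonfinite")
    }
    v
  }
  ecg <- bio_signal(get_col(i_ecg), heads[[i_ecg]]$fs, ch_names[i_ecg])
  ppg <- bio_signal(get_col(i_ppg), heads[[i_ppg]]$fs, ch_names[i_ppg])
  paired_record(ecg, ppg, subject_id)
}

# Minimal WFDB support: header lines
#   <record> <n_sig> <fs> <n_samples>
#   <file>.dat 16 <gain>(<baseline>)/<units> ... <name last field>
# and a .dat of interleaved 16-bit little-endian integers,
# physical = (raw - baseline) / gain.
read_record_wfdb <- function(path, subject_id, ecg_names, ppg_names) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) {
    abort(sprintf("file not found: %s", hea), class = "ppg2ecg_error_missing_file")
  }
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  n_sig <- as.integer(top[2])
  fs <- if (length(top) >= 3) as.numeric(top[3]) else 250
  sig_lines <- lines[1 + seq_len(n_sig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
    fmt <- f[2]
    if (fmt != "16") {
      abort(sprintf("unsupported WFDB sample format '%s' (only 16).", fmt),
            class = "ppg2ecg_error_wfdb_format")
    }
    spec <- f[3] # gain(baseline)/units, each part optional
    gain <- 200; baseline <- 0
    gm <- regmatches(spec, regexec("^([0-9.eE+-]+)", spec))[[1]]
    if (length(gm) == 2L && nzchar(gm[2])) gain <- as.numeric(gm[2])
    bm <- regmatches(spec, regexec("\\(([0-9-]+)\\)", spec))[[1]]
    if (length(bm) == 2L) baseline <- as.numeric(bm[2])
    list(file = f[1], gain = gain, baseline = baseline,
         name = f[length(f)])
  }
  sigs <- lapply(sig_lines, parse_sig)
  dat <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(dat)) {
    abort(sprintf("file not found: %s", dat), class = "ppg2ecg_error_missing_file")
  }
  raw <- readBin(dat, what = "integer", size = 2L, signed = TRUE,
                 endian = "little", n = file.info(dat)$size / 2)
  n_samp <- length(raw) %/% n_sig
  m <- matrix(raw[seq_len(n_samp * n_sig)], nrow = n_sig)
  ch_names <- vapply(sigs, `[[`, character(1), "name")
  build <- function(i) {
    v <- (m[i, ] - sigs[[i]]$baseline) / sigs[[i]]$gain
    if (!all(is.finite(v))) {
      abort("non-finite samples in WFDB record.", class = "ppg2ecg_error_nonfinite")
    }
    bio_signal(v, fs, ch_names[i])
  }
  i_ecg <- pick_channel(ch_names, ecg_names)
  i_ppg <- pick_channel(ch_names, ppg_names)
  paired_record(build(i_ecg), build(i_ppg), subject_id)
}

#' Write a paired record
#'
#' `"csv"` writes the two-column `name@<fs>Hz` dialect read by
#' [read_record()]; `"wfdb"` writes a header/.dat pair in 16-bit format with
#' a fixed gain of 1000 ADC units per physical unit. If the record carries
#' `true_r_peaks`, a `<path>.rpeaks` sidecar with 0-based indices is written
#' alongside. Round-tripping through csv reproduces samples to full printed
#' precision (better than 1e-9) and rates exactly.
#'
#' @param record A [paired_record].
#' @param path Output path (CSV file, or WFDB base path without extension).
#' @param format `"csv"` or `"wfdb"`.
#' @return `path`, invisibly.
#' @export
write_record <- function(record, path, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  stopifnot(inherits(record, "paired_record"))
  if (format == "csv") {
    ne <- length(record$ecg$samples); np <- length(record$ppg$samples)
    n <- max(ne, np)
    pad <- function(v) c(format(v, digits = 17), rep("", n - length(v)))
    df <- data.frame(a = pad(record$ecg$samples), b = pad(record$ppg$samples))
    names(df) <- c(sprintf("%s@%gHz", record$ecg$label, record$ecg$fs),
                   sprintf("%s@%gHz", record$ppg$label, record$ppg$fs))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
    base <- sub("\\.csv$", "", path)
  } else {
    if (!isTRUE(all.equal(record$ecg$fs, record$ppg$fs))) {
      abort("WFDB writing requires equal channel rates.", class = "ppg2ecg_error_bad_fs")
    }
    ne <- length(record$ecg$samples); np <- length(record$ppg$samples)
    n <- min(ne, np)
    gain <- 1000
    m <- rbind(round(record$ecg$samples[seq_len(n)] * gain),
               round(record$ppg$samples[seq_len(n)] * gain))
    if (max(abs(m)) > 32767) {
      abort("amplitudes exceed 16-bit WFDB range at gain 1000.",
            class = "ppg2ecg_error_wfdb_range")
    }
    base <- path
    rec_name <- basename(base)
    writeLines(c(
      sprintf("%s 2 %g %d", rec_name, record$ecg$fs, n),
      sprintf("%s.dat 16 %d(0)/mV 16 0 0 0 0 %s", rec_name, gain, record$ecg$label),
      sprintf("%s.dat 16 %d(0)/NU 16 0 0 0 0 %s", rec_name, gain, record$ppg$label)
    ), paste0(base, ".hea"))
    writeBin(as.integer(as.vector(m)), paste0(base, ".dat"), size = 2L,
             endian = "little")
  }
  if (!is.null(record$true_r_peaks)) {
    writeLines(as.character(record$true_r_peaks - 1L), paste0(base, ".rpeaks"))
  }
  invisible(path)
}
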