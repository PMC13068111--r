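#' Training configuration
#'
#' @param epochs Maximum epochs (>= 1).
#' @param batch_size Segments per batch.
#' @param learning_rate Adam step size.
#' @param early_stop_patience Stop after this many epochs without a new best
#'   validation RMSE.
#' @param val_fraction Fraction of *subjects* (never segments) held out for
#'   validation inside [train_model()].
#' @param grad_clip Global gradient-norm clip (deep recurrent stacks are
#'   prone to occasional gradient spikes).
#' @param seed Seed controlling the subject split, shuffling and any other
#'   training randomness.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 150, batch_size = 32, learning_rate = 1e-3,
                         early_stop_patience = 15, val_fraction = 0.2,
                         grad_clip = 5, seed = 1L) {
  if (epochs < 1) abort("`epochs` must be >= 1.", class = "ppg2ecg_error_config")
  if (val_fraction <= 0 || val_fraction >= 1) {
    abort("`val_fraction` must be in (0, 1).", class = "ppg2ecg_error_config")
  }
  if (batch_size < 1) abort("`batch_size` must be >= 1.", class = "ppg2ecg_error_config")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 early_stop_patience = as.integer(early_stop_patience),
                 val_fraction = val_fraction, grad_clip = grad_clip,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Subject-level train/validation/test split
#'
#' Splits are always by subject, never by segment, so no subject's waveforms
#' can appear on both sides of a fit. The partition is a deterministic
#' function of the sorted subject ids and the seed.
#'
#' @param subject_ids Character vector (or list of [paired_record]s).
#' @param val_fraction,test_fraction Fractions of subjects (counts are
#'   rounded, with at least one subject in any non-zero split).
#' @param seed Integer seed.
#' @return List with character vectors `train`, `val`, `test` (disjoint,
#'   covering all subjects).
#' @export
make_splits <- function(subject_ids, val_fraction = 0.2, test_fraction = 0.2,
                        seed = 1L) {
  if (is.list(subject_ids)) {
    subject_ids <- vapply(subject_ids, function(r) r$subject_id, character(1))
  }
  ids <- sort(unique(as.character(subject_ids)))
  n <- length(ids)
  if (n < 3L) abort("need at least 3 subjects to split.", class = "ppg2ecg_error_split")
  n_val <- if (val_fraction > 0) max(1L, round(n * val_fraction)) else 0L
  n_test <- if (test_fraction > 0) max(1L, round(n * test_fraction)) else 0L
  if (n_val + n_test >= n) {
    abort("val + test fractions leave no training subjects.",
          class = "ppg2ecg_error_split")
  }
  set.seed(seed)
  perm <- sample(ids)
  list(train = sort(perm[seq_len(n - n_val - n_test)]),
       val = sort(perm[n - n_val - n_test + seq_len(n_val)]),
       test = sort(perm[n - n_test + seq_len(n_test)]))
}

segments_to_matrices <- function(seg_tbl) {
  list(x = do.call(cbind, seg_tbl$ppg_in),
       y = do.call(cbind, seg_tbl$ecg_target))
}

val_rmse_of <- function(theta, cfg, x, y, batch = 64L) {
  n <- ncol(x)
  tot <- 0
  for (s in seq.int(1L, n, by = batch)) {
    idx <- s:min(n, s + batch - 1L)
    p <- dcblstm_forward_cpp(theta, x[, idx, drop = FALSE], cfg$n_blocks,
                             cfg$hidden_units, conn_code(cfg$connection))$pred
    tot <- tot + sum(sqrt(colMeans((p - y[, idx, drop = FALSE])^2)))
  }
  tot / n
}

#' Train a DC-BiLSTM model
#'
#' Minimises the per-segment RMSE, averaged over each batch, between
#' reconstructed and ground-truth ECG segments with Adam, tracking the
#' per-epoch training and validation RMSE and returning the parameters of
#' the epoch with the lowest validation RMSE. Validation subjects are split
#' off deterministically under the training seed. Records are expected
#' untouched; preprocessing (resample, filter, align, segment) happens here.
#'
#' @param records List of [paired_record]s (>= 2 subjects).
#' @param config A [model_config()].
#' @param train_cfg A [train_config()].
#' @param pipeline A [pipeline_config()].
#' @param quiet Suppress per-epoch messages.
#' @return A trained `dcblstm_model` with a `history` tibble
#'   (`epoch`, `train_rmse`, `val_rmse`) and the best-epoch parameters.
#' @export
train_model <- function(records, config = model_config(),
                        train_cfg = train_config(),
                        pipeline = pipeline_config(), quiet = TRUE) {
  if (!length(records)) abort("empty training set.", class = "ppg2ecg_error_empty")
  ids <- vapply(records, function(r) r$subject_id, character(1))
  set.seed(train_cfg$seed)
  uids <- sort(unique(ids))
  n_val <- max(1L, round(length(uids) * train_cfg$val_fraction))
  if (n_val >= length(uids)) {
    abort("validation split leaves no training subjects.",
          class = "ppg2ecg_error_split")
  }
  val_ids <- sort(sample(uids, n_val))
  seg_of <- function(r) {
    pr <- prepare_record(r, pipeline, align = TRUE)
    segment_record(pr, pipeline$segment_len, pipeline$train_stride,
                   pipeline$norm_method)
  }
  segs <- dplyr::bind_rows(purrr::map(records, seg_of))
  tr <- segments_to_matrices(segs[!(segs$subject_id %in% val_ids), ])
  va <- segments_to_matrices(segs[segs$subject_id %in% val_ids, ])
  if (is.null(tr$x) || is.null(va$x)) {
    abort("empty train or validation segment set.", class = "ppg2ecg_error_empty")
  }

  cfg <- config
  if (cfg$input_len != pipeline$segment_len) {
    cfg$input_len <- pipeline$segment_len
  }
  model <- init_model(cfg)
  theta <- model$theta
  m <- numeric(length(theta)); v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(val = Inf, theta = theta, epoch = 0L)
  hist <- vector("list", train_cfg$epochs)
  n_tr <- ncol(tr$x)
  set.seed(train_cfg$seed + 1L)
  for (ep in seq_len(train_cfg$epochs)) {
    ord <- sample.int(n_tr)
    ep_loss <- 0; n_batch <- 0L
    for (s in seq.int(1L, n_tr, by = train_cfg$batch_size)) {
      idx <- ord[s:min(n_tr, s + train_cfg$batch_size - 1L)]
      g <- dcblstm_grad_cpp(theta, tr$x[, idx, drop = FALSE],
                            tr$y[, idx, drop = FALSE], cfg$n_blocks,
                            cfg$hidden_units, conn_code(cfg$connection))
      grad <- g$grad
      gn <- sqrt(sum(grad^2))
      if (is.finite(gn) && gn > train_cfg$grad_clip) {
        grad <- grad * (train_cfg$grad_clip / gn)
      }
      step <- step + 1L
      m <- b1 * m + (1 - b1) * grad
      v <- b2 * v + (1 - b2) * grad^2
      mh <- m / (1 - b1^step)
      vh <- v / (1 - b2^step)
      theta <- theta - train_cfg$learning_rate * mh / (sqrt(vh) + eps)
      ep_loss <- ep_loss + g$loss; n_batch <- n_batch + 1L
    }
    vr <- val_rmse_of(theta, cfg, va$x, va$y)
    hist[[ep]] <- tibble::tibble(epoch = ep, train_rmse = ep_loss / n_batch,
                                 val_rmse = vr)
    if (vr < best$val) best <- list(val = vr, theta = theta, epoch = ep)
    if (!quiet) {
      message(sprintf("epoch %3d  train %.4f  val %.4f%s", ep,
                      ep_loss / n_batch, vr,
                      if (ep == best$epoch) " *" else ""))
    }
    if (ep - best$epoch >= train_cfg$early_stop_patience) break
  }
  model$theta <- best$theta
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  model$pipeline <- pipeline
  model$train_cfg <- train_cfg
  model$val_subjects <- val_ids
  model
}

#' Broom-style one-row model summary
#'
#' @param x A trained `dcblstm_model`.
#' @param ... Unused.
#' @return One-row tibble: architecture, parameter count, epochs run, best
#'   validation RMSE and its epoch.
#' @export
glance.dcblstm_model <- function(x, ...) {
  tibble::tibble(
    connection = x$config$connection,
    n_blocks = x$config$n_blocks,
    hidden_units = x$config$hidden_units,
    n_params = length(x$theta),
    epochs_run = nrow(x$history),
    best_epoch = if (nrow(x$history)) x$best_epoch else NA_integer_,
    best_val_rmse = if (nrow(x$history)) min(x$history$val_rmse) else NA_real_
  )
}

#' Per-epoch training history
#'
#' @param x A trained `dcblstm_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_rmse`, `val_rmse`.
#' @export
tidy.dcblstm_model <- function(x, ...) x$history

#' @export
glance <- function(x, ...) UseMethod("glance")

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' Save / load a model checkpoint
#'
#' Checkpoints are plain JSON: configs, flat parameter vector, training
#' history and seeds, so a reconstruction is reproducible from the file
#' alone.
#'
#' @param model A `dcblstm_model`.
#' @param path Destination file.
#' @return `path` invisibly (`save_model`); the restored model
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  payload <- list(
    config = unclass(model$config),
    pipeline = if (is.null(model$pipeline)) NULL else unclass(model$pipeline),
    train_cfg = if (is.null(model$train_cfg)) NULL else unclass(model$train_cfg),
    theta = model$theta,
    history = as.data.frame(model$history),
    best_epoch = model$best_epoch,
    val_subjects = model$val_subjects
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(model_config, p$config[c("n_blocks", "hidden_units",
                                          "connection", "input_len", "seed")])
  model <- structure(list(theta = as.numeric(p$theta), config = cfg,
                          history = tibble::as_tibble(p$history),
                          best_epoch = p$best_epoch,
                          val_subjects = p$val_subjects),
                     class = "dcblstm_model")
  if (!is.null(p$pipeline)) {
    pl <- p$pipeline
    model$pipeline <- pipeline_config(pl$working_fs, unlist(pl$ppg_band),
                                      unlist(pl$ecg_band), pl$n_taps,
                                      pl$max_lag_s, pl$segment_len,
                                      pl$train_stride, pl$eval_stride,
                                      pl$norm_method)
  }
  model
}
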