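#' Model configuration for the densely connected BiLSTM
#'
#' The network is a stack of `n_blocks` bidirectional LSTM blocks of equal
#' width followed by a per-time-step affine regression head. Three wirings
#' are available: `"single"` (one block, the single-BiLSTM baseline),
#' `"stacked"` (block j + 1 consumes block j's output verbatim), and
#' `"dense"` (block j + 1 consumes the elementwise sum of the outputs of
#' blocks 1..j, and the head consumes the sum over all blocks — the fusion
#' of every hierarchical feature level). Equal widths across blocks are
#' required for the dense sum to be well defined.
#'
#' @param n_blocks Number of BiLSTM blocks (>= 1; 5 is the reference depth).
#' @param hidden_units Hidden width per direction (block output width is
#'   `2 * hidden_units`).
#' @param connection `"dense"`, `"stacked"` or `"single"`.
#' @param input_len Segment length L the model maps (seq in, seq out).
#' @param seed Seed for parameter initialisation.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_blocks = 5, hidden_units = 128,
                         connection = c("dense", "stacked", "single"),
                         input_len = 512, seed = 1L) {
  connection <- match.arg(connection)
  n_blocks <- as.integer(n_blocks)
  if (n_blocks < 1L) abort("`n_blocks` must be >= 1.", class = "ppg2ecg_error_config")
  if (connection == "single" && n_blocks != 1L) {
    abort("connection = 'single' requires n_blocks == 1.",
          class = "ppg2ecg_error_config")
  }
  structure(list(n_blocks = n_blocks, hidden_units = as.integer(hidden_units),
                 connection = connection, input_len = as.integer(input_len),
                 seed = as.integer(seed)),
            class = "model_config")
}

conn_code <- function(connection) {
  if (connection == "dense") 1L else 0L
}

#' Initialise a DC-BiLSTM model
#'
#' Parameters are drawn from a uniform fan-in scheme,
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))`, under the config seed; forget-gate
#' biases start at 1 (the usual aid to early gradient flow in gated
#' recurrences), all other biases at 0.
#'
#' @param config A [model_config()].
#' @return Object of class `dcblstm_model` with elements `theta` (flat
#'   parameter vector), `config`, and empty `history`.
#' @export
init_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  H <- config$hidden_units
  n_par <- dcblstm_n_params(config$n_blocks, H)
  theta <- numeric(n_par)
  set.seed(config$seed)
  pos <- 1L
  put <- function(n, limit, bias4 = FALSE) {
    v <- if (bias4) {
      b <- numeric(n)
      b[(n / 4 + 1):(n / 2)] <- 1 # forget gate slice of the 4H bias
      b
    } else {
      runif(n, -limit, limit)
    }
    theta[pos:(pos + n - 1L)] <<- v
    pos <<- pos + n
  }
  for (j in seq_len(config$n_blocks)) {
    D <- if (j == 1L) 1L else 2L * H
    for (dir in 1:2) {
      put(4L * H * D, 1 / sqrt(D))      # W
      put(4L * H * H, 1 / sqrt(H))      # U
      put(4L * H, 0, bias4 = TRUE)      # b
    }
  }
  put(2L * H, 1 / sqrt(2 * H))          # head w
  put(1L, 1 / sqrt(2 * H))              # head b
  structure(list(theta = theta, config = config,
                 history = tibble::tibble(), pipeline = NULL),
            class = "dcblstm_model")
}

#' @export
print.dcblstm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<dcblstm_model> %s, %d block(s) x %d units/direction, L = %d (%d parameters)\n",
              cfg$connection, cfg$n_blocks, cfg$hidden_units, cfg$input_len,
              length(x$theta)))
  if (nrow(x$history)) {
    best <- which.min(x$history$val_rmse)
    cat(sprintf("  trained %d epoch(s); best val RMSE %.4f at epoch %d\n",
                nrow(x$history), x$history$val_rmse[best], x$history$epoch[best]))
  }
  invisible(x)
}

#' Forward pass over a batch of PPG segments
#'
#' @param model A `dcblstm_model`.
#' @param x Numeric matrix `L x n_segments` (or a length-L vector).
#' @param return_features Also return the fused feature array
#'   (`2H x n_segments x L`), the head's input.
#' @return Matrix `L x n_segments` of reconstructed ECG values on the
#'   normalized scale (or, with `return_features`, a list).
#' @export
forward_model <- function(model, x, return_features = FALSE) {
  stopifnot(inherits(model, "dcblstm_model"))
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  if (nrow(x) != model$config$input_len) {
    abort(sprintf("input length %d != model input_len %d.", nrow(x),
                  model$config$input_len),
          class = "ppg2ecg_error_shape")
  }
  out <- dcblstm_forward_cpp(model$theta, x, model$config$n_blocks,
                             model$config$hidden_units,
                             conn_code(model$config$connection),
                             return_features)
  if (return_features) out else out$pred
}

#' View the flat parameter vector as per-block matrices
#'
#' Utility for inspection and for oracle-style recomputation of the forward
#' pass block by block.
#'
#' @param model A `dcblstm_model`.
#' @return List with one element per block (`fwd` and `bwd`, each
#'   `list(W, U, b)`) plus `head = list(w, b)`.
#' @export
unflatten_params <- function(model) {
  cfg <- model$config
  H <- cfg$hidden_units
  theta <- model$theta
  pos <- 1L
  take <- function(nr, nc = NULL) {
    n <- nr * max(1L, nc)
    v <- theta[pos:(pos + n - 1L)]
    pos <<- pos + n
    if (is.null(nc)) v else matrix(v, nr, nc)
  }
  blocks <- purrr::map(seq_len(cfg$n_blocks), function(j) {
    D <- if (j == 1L) 1L else 2L * H
    one_dir <- function() list(W = take(4L * H, D), U = take(4L * H, H),
                               b = take(4L * H))
    list(fwd = one_dir(), bwd = one_dir())
  })
  list(blocks = blocks, head = list(w = take(2L * H), b = take(1L, NULL)))
}

#' Run one bidirectional LSTM block
#'
#' @param block A block parameter list as returned in
#'   [unflatten_params()]`$blocks[[j]]`.
#' @param x Input array `D x B x L` (features x segments x time), or an
#'   `L x B` matrix for width-1 input.
#' @return Array `2H x B x L` of per-time-step features.
#' @export
bilstm_block <- function(block, x) {
  if (is.matrix(x)) { # L x B convenience for the width-1 first block
    a <- array(0, dim = c(1L, ncol(x), nrow(x)))
    a[1L, , ] <- t(x)
    x <- a
  }
  if (dim(x)[1] != ncol(block$fwd$W)) {
    abort("input feature width does not match block parameters.",
          class = "ppg2ecg_error_shape")
  }
  bilstm_forward_cpp(block$fwd$W, block$fwd$U, block$fwd$b,
                     block$bwd$W, block$bwd$U, block$bwd$b, x)
}

#' Per-time-step regression head
#'
#' A single affine map `2H -> 1` shared across time steps: each time step's
#' fused feature vector is reduced to one reconstructed ECG sample.
#'
#' @param head `list(w, b)` as in [unflatten_params()]`$head`.
#' @param features Array `2H x B x L`.
#' @return Matrix `L x B`.
#' @export
regression_head <- function(head, features) {
  d <- dim(features)
  if (d[1] != length(head$w)) {
    abort("feature width does not match head.", class = "ppg2ecg_error_shape")
  }
  out <- apply(features, 3L, function(s) drop(crossprod(head$w, s)) + head$b)
  if (is.null(dim(out))) out <- matrix(out, nrow = d[3])
  else out <- t(out)
  out
}

#' Root-mean-square error loss
#'
#' `sqrt(mean((pred - target)^2))`; zero iff the sequences are identical.
#' This single implementation backs both the training loss and the
#' evaluation metric.
#'
#' @param pred,target Equal-length numeric vectors.
#' @return Non-negative scalar.
#' @export
rmse <- function(pred, target) {
  if (length(pred) != length(target)) {
    abort("length mismatch.", class = "ppg2ecg_error_length")
  }
  sqrt(mean((pred - target)^2))
}
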