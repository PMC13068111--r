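test_that("config invariants are enforced", {
  expect_error(model_config(n_blocks = 0), class = "ppg2ecg_error_config")
  expect_error(model_config(n_blocks = 2, connection = "single"),
               class = "ppg2ecg_error_config")
})

test_that("a BiLSTM block is bidirectional: last input step reaches first output", {
  m <- tiny_model(n_blocks = 1, hidden_units = 4, connection = "single")
  p <- unflatten_params(m)
  L <- 16
  set.seed(2)
  x <- matrix(rnorm(L), L, 1)
  x2 <- x
  x2[L, 1] <- x2[L, 1] + 1
  o1 <- bilstm_block(p$blocks[[1]], x)
  o2 <- bilstm_block(p$blocks[[1]], x2)
  expect_gt(max(abs(o1[, 1, 1] - o2[, 1, 1])), 0)
})

test_that("zero parameters give a zero fixed point; fixed seed is deterministic", {
  m <- tiny_model(n_blocks = 2, connection = "dense")
  mz <- m
  mz$theta <- numeric(length(m$theta))
  x <- matrix(0, 16, 2)
  expect_identical(max(abs(forward_model(mz, x))), 0)
  set.seed(7)
  xr <- matrix(rnorm(32), 16, 2)
  expect_identical(forward_model(m, xr), forward_model(m, xr))
})

test_that("compiled recurrence matches an independent pure-R LSTM", {
  m <- tiny_model(n_blocks = 1, hidden_units = 3, connection = "single",
                  input_len = 9)
  p <- unflatten_params(m)$blocks[[1]]
  set.seed(5)
  X <- array(rnorm(1 * 2 * 9), c(1, 2, 9))
  o_cpp <- ppg2ecg:::bilstm_forward_cpp(p$fwd$W, p$fwd$U, p$fwd$b,
                              p$bwd$W, p$bwd$U, p$bwd$b, X)
  o_r <- abind3(r_lstm_dir(p$fwd$W, p$fwd$U, p$fwd$b, X, rev = FALSE),
                r_lstm_dir(p$bwd$W, p$bwd$U, p$bwd$b, X, rev = TRUE))
  expect_lt(max(abs(o_cpp - o_r)), 1e-12)
})

test_that("stacked forward equals manual composition of blocks plus head", {
  m <- tiny_model(n_blocks = 2, hidden_units = 5, connection = "stacked",
                  input_len = 20)
  set.seed(9)
  x <- matrix(rnorm(40), 20, 2)
  p <- unflatten_params(m)
  o1 <- bilstm_block(p$blocks[[1]], x)
  o2 <- bilstm_block(p$blocks[[2]], o1)
  manual <- regression_head(p$head, o2)
  expect_lt(max(abs(forward_model(m, x) - manual)), 1e-6)
})

test_that("dense fusion equals independent accumulation for up to 5 blocks", {
  for (nb in c(1L, 3L, 5L)) {
    m <- tiny_model(n_blocks = nb, hidden_units = 4, connection = "dense",
                    input_len = 12, seed = nb + 20)
    set.seed(nb)
    x <- matrix(rnorm(24), 12, 2)
    p <- unflatten_params(m)
    acc <- NULL
    for (j in seq_len(nb)) {
      o <- bilstm_block(p$blocks[[j]], if (j == 1) x else acc)
      acc <- if (j == 1) o else acc + o
    }
    got <- forward_model(m, x, return_features = TRUE)
    expect_lt(max(abs(got$features - acc)), 1e-6)
    expect_lt(max(abs(got$pred - regression_head(p$head, acc))), 1e-6)
  }
})

test_that("single, stacked and dense coincide bitwise at one block", {
  m <- tiny_model(n_blocks = 1, hidden_units = 4, connection = "single",
                  input_len = 16, seed = 33)
  set.seed(1)
  x <- matrix(rnorm(32), 16, 2)
  preds <- purrr::map(c("single", "stacked", "dense"), function(conn) {
    mm <- m
    mm$config$connection <- conn
    forward_model(mm, x)
  })
  expect_identical(preds[[1]], preds[[2]])
  expect_identical(preds[[1]], preds[[3]])
})

test_that("zeroing blocks 2..n reduces dense output to the 1-block model", {
  m5 <- tiny_model(n_blocks = 3, hidden_units = 4, connection = "dense",
                   input_len = 16, seed = 2)
  # copy block 1 + head into a 1-block model, zero the rest in the big one
  m1 <- tiny_model(n_blocks = 1, hidden_units = 4, connection = "single",
                   input_len = 16, seed = 2)
  n1 <- ppg2ecg:::dcblstm_n_params(1L, 4L)
  nb1 <- n1 - (2L * 4L + 1L) # block-1 parameters
  theta5 <- numeric(length(m5$theta))
  theta5[seq_len(nb1)] <- m5$theta[seq_len(nb1)]
  theta5[(length(theta5) - 2L * 4L):length(theta5)] <-
    m5$theta[(length(m5$theta) - 2L * 4L):length(m5$theta)]
  m1$theta <- c(m5$theta[seq_len(nb1)],
                m5$theta[(length(m5$theta) - 2L * 4L):length(m5$theta)])
  m5z <- m5
  m5z$theta <- theta5
  set.seed(3)
  x <- matrix(rnorm(16), 16, 1)
  expect_lt(max(abs(forward_model(m5z, x) - forward_model(m1, x))), 1e-6)
})

test_that("deeper models add parameters but keep the seq-to-seq shape", {
  n1 <- ppg2ecg:::dcblstm_n_params(1L, 8L)
  n5 <- ppg2ecg:::dcblstm_n_params(5L, 8L)
  expect_gt(n5, n1)
  for (conn in c("dense", "stacked")) {
    m <- tiny_model(n_blocks = 2, hidden_units = 8, connection = conn,
                    input_len = 24)
    x <- matrix(rnorm(24 * 3), 24, 3)
    expect_identical(dim(forward_model(m, x)), c(24L, 3L))
  }
})

test_that("regression head is affine and shared across time steps", {
  head <- list(w = c(0.5, -1), b = 0.25)
  f <- array(2, c(2, 1, 4))
  expect_equal(as.vector(regression_head(head, f)),
               rep(0.5 * 2 - 1 * 2 + 0.25, 4))
  zero_head <- list(w = c(0, 0), b = 0)
  expect_identical(max(abs(regression_head(zero_head, f))), 0)
  # permuting feature time steps permutes outputs identically
  set.seed(8)
  ff <- array(rnorm(2 * 2 * 5), c(2, 2, 5))
  perm <- c(3, 1, 5, 2, 4)
  out <- regression_head(head, ff)
  out_p <- regression_head(head, ff[, , perm, drop = FALSE])
  expect_equal(out_p, out[perm, ])
})

test_that("rmse matches hand arithmetic and the loss shares it", {
  expect_identical(rmse(1:5, 1:5), 0)
  expect_identical(rmse(rep(1, 4), rep(0, 4)), 1)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
  expect_error(rmse(1:3, 1:4), class = "ppg2ecg_error_length")
  # training loss at batch size 1 equals rmse of that segment
  m <- tiny_model(n_blocks = 1, hidden_units = 3, connection = "single",
                  input_len = 10)
  x <- matrix(rnorm(10), 10, 1)
  y <- matrix(rnorm(10), 10, 1)
  g <- ppg2ecg:::dcblstm_grad_cpp(m$theta, x, y, 1L, 3L, 0L)
  expect_equal(g$loss, rmse(forward_model(m, x), y))
})

test_that("analytic gradients match finite differences on a tiny model", {
  for (conn in c("dense", "stacked")) {
    cfg <- model_config(n_blocks = 2, hidden_units = 3, connection = conn,
                        input_len = 6, seed = 4)
    m <- init_model(cfg)
    set.seed(10)
    theta <- m$theta + rnorm(length(m$theta), 0, 0.05)
    X <- matrix(rnorm(12), 6, 2)
    Y <- matrix(rnorm(12), 6, 2)
    code <- ppg2ecg:::conn_code(conn)
    g <- ppg2ecg:::dcblstm_grad_cpp(theta, X, Y, 2L, 3L, code)
    eps <- 1e-6
    idx <- seq(1, length(theta), by = 7) # spot-check a spread of coordinates
    num <- vapply(idx, function(i) {
      tp <- theta; tp[i] <- tp[i] + eps
      tm <- theta; tm[i] <- tm[i] - eps
      (ppg2ecg:::dcblstm_grad_cpp(tp, X, Y, 2L, 3L, code)$loss -
         ppg2ecg:::dcblstm_grad_cpp(tm, X, Y, 2L, 3L, code)$loss) / (2 * eps)
    }, numeric(1))
    expect_lt(max(abs(num - g$grad[idx])), 1e-7)
  }
})
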