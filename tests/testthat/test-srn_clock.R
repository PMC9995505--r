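# Independent R reference of the training loop: per-sample updates in
# temporal order, momentum, Fahlman offset on both sigmoid derivatives,
# mean-over-outputs squared-error loss, context reset at each epoch start.
# Used as the oracle for the compiled implementation.
ref_train <- function(w, states, epochs, lr, mu, offset) {
  sig <- function(a) 1 / (1 + exp(-a))
  H <- nrow(w$A); n_out <- nrow(w$U)
  dA <- w$A * 0; dR <- w$R * 0; dU <- w$U * 0
  dbh <- w$hidden_bias * 0; dbo <- w$output_bias * 0
  for (e in seq_len(epochs)) {
    h_prev <- rep(0.5, H)
    for (t in seq_len(nrow(states) - 1)) {
      x <- states[t, ]; target <- states[t + 1, ]
      h <- sig(drop(w$A %*% x + w$R %*% h_prev) + w$hidden_bias)
      y <- sig(drop(w$U %*% h) + w$output_bias)
      delta_o <- ((y - target) / n_out) * (y * (1 - y) + offset)
      delta_h <- drop(t(w$U) %*% delta_o) * (h * (1 - h) + offset)
      dU <- -lr * tcrossprod(delta_o, h) + mu * dU
      dbo <- -lr * delta_o + mu * dbo
      dA <- -lr * tcrossprod(delta_h, x) + mu * dA
      dR <- -lr * tcrossprod(delta_h, h_prev) + mu * dR
      dbh <- -lr * delta_h + mu * dbh
      w$U <- w$U + dU; w$output_bias <- w$output_bias + dbo
      w$A <- w$A + dA; w$R <- w$R + dR; w$hidden_bias <- w$hidden_bias + dbh
      h_prev <- h
    }
  }
  w
}

toy_weights <- function(H = 2L, n = 2L, seed = 5L) {
  cfg <- srn_config(hidden_size = H, seed = seed)
  w <- init_srn(cfg)
  w$A <- w$A[, seq_len(n), drop = FALSE]
  w$U <- w$U[seq_len(n), , drop = FALSE]
  w$output_bias <- w$output_bias[seq_len(n)]
  w
}

toy_dataset <- function(states) {
  structure(list(horizon_ms = nrow(states) - 1L, states = states),
            class = "trajectory_dataset")
}

test_that("initial weights are seeded, shaped and centred", {
  cfg <- srn_config(hidden_size = 16L)
  w <- init_srn(cfg)
  expect_identical(w, init_srn(cfg))
  expect_equal(dim(w$A), c(16L, 12L))
  expect_equal(dim(w$R), c(16L, 16L))
  expect_equal(dim(w$U), c(12L, 16L))
  # sample mean of ~1e5 uniform [-0.5, 0.5] draws within 3 standard errors
  wb <- init_srn(srn_config(hidden_size = 300L, seed = 2L))
  draws <- c(wb$A, wb$R, wb$U, wb$hidden_bias, wb$output_bias)
  expect_gt(length(draws), 9e4)
  se <- sqrt(1 / 12) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)
  expect_true(all(draws >= -0.5 & draws <= 0.5))
})

test_that("forward step reproduces hand-computed activations", {
  zero <- structure(list(A = matrix(0, 3, 12), R = matrix(0, 3, 3),
                         U = matrix(0, 12, 3), hidden_bias = rep(0, 3),
                         output_bias = rep(0, 12)), class = "srn_weights")
  out <- forward_step(zero, rep(0.7, 12), rep(0.2, 3))
  expect_equal(out$h, rep(0.5, 3))
  expect_equal(out$y, rep(0.5, 12))
  soft <- forward_step(zero, rep(0.7, 12), rep(0.2, 3), "softmax")
  expect_equal(soft$y, rep(1 / 12, 12))

  # 1-hidden-unit toy, frozen from a pencil-and-paper evaluation
  w <- structure(list(A = matrix(c(0.1, -0.2), 1, 2), R = matrix(0.05, 1, 1),
                      U = matrix(c(0.4, -0.3), 2, 1), hidden_bias = 0.1,
                      output_bias = c(0.05, -0.05)), class = "srn_weights")
  out <- forward_step(w, c(0.6, 0.4), 0.5)
  expect_equal(out$h, 0.526225909372, tolerance = 1e-10)
  expect_equal(out$y, c(0.564756830251, 0.448219371808), tolerance = 1e-10)
  expect_error(forward_step(w, c(0.6, 0.4, 0.1), 0.5), "dimensions")
})

test_that("training matches the independent reference loop", {
  w <- toy_weights()
  states <- matrix(c(0.5, 0.5, 0.9, 0.2, 0.4, 0.7, 0.6, 0.3), 4, 2)
  cfg <- srn_config(hidden_size = 2L, epochs = 1L, fahlman_offset = 0.1,
                    attention_horizon_ms = 3L)
  got <- train_srn(w, toy_dataset(states), cfg)$weights
  want <- ref_train(w, states, 1, 0.1, 0.9, 0.1)
  for (f in c("A", "R", "U", "hidden_bias", "output_bias"))
    expect_equal(got[[f]], want[[f]], tolerance = 1e-10)

  # several epochs, context and momentum carried exactly
  cfg5 <- srn_config(hidden_size = 2L, epochs = 5L, fahlman_offset = 0.25,
                     attention_horizon_ms = 3L)
  got5 <- train_srn(w, toy_dataset(states), cfg5)$weights
  want5 <- ref_train(w, states, 5, 0.1, 0.9, 0.25)
  expect_equal(got5$A, want5$A, tolerance = 1e-10)
  expect_equal(got5$R, want5$R, tolerance = 1e-10)

  # zero offset reduces to the textbook sigmoid-derivative rule
  cfg0 <- srn_config(hidden_size = 2L, epochs = 2L, fahlman_offset = 0,
                     attention_horizon_ms = 3L)
  got0 <- train_srn(w, toy_dataset(states), cfg0)$weights
  want0 <- ref_train(w, states, 2, 0.1, 0.9, 0)
  expect_equal(got0$U, want0$U, tolerance = 1e-10)
})

test_that("zero epochs leave the weights untouched", {
  bank <- test_bank()
  cfg <- srn_config(hidden_size = 4L, epochs = 0L, attention_horizon_ms = 8L)
  w <- init_srn(cfg)
  out <- train_srn(w, build_trajectory(bank, 8), cfg)
  expect_identical(out$weights, w)
  expect_equal(nrow(out$log), 0)
})

test_that("training reduces the one-step error on a learnable target", {
  bank <- test_bank()
  cfg <- srn_config(hidden_size = 8L, epochs = 50L,
                    attention_horizon_ms = 64L, seed = 3L)
  out <- train_srn(init_srn(cfg), build_trajectory(bank, 64), cfg)
  expect_lt(out$log$mse[50], out$log$mse[1])
})

test_that("the free run is a closed loop with the right fixed points", {
  bank <- test_bank()
  zero <- structure(list(A = matrix(0, 3, 12), R = matrix(0, 3, 3),
                         U = matrix(0, 12, 3), hidden_bias = rep(0, 3),
                         output_bias = rep(0, 12)), class = "srn_weights")
  one <- free_run(zero, bank, 1)
  expect_equal(dim(one), c(1L, 12L))
  many <- free_run(zero, bank, 50)
  expect_equal(unname(many), matrix(0.5, 50, 12))
  expect_error(free_run(zero, bank, 0), "duration_ms")
})

test_that("trained runs are bit-reproducible from the seed", {
  cfg <- srn_config(hidden_size = 8L, epochs = 20L,
                    attention_horizon_ms = 128L, seed = 11L)
  bank <- test_bank()
  run1 <- simulate_clock(cfg, bank)
  run2 <- simulate_clock(cfg, bank)
  expect_identical(run1$weights, run2$weights)
  expect_identical(run1$trace$per_ms_distance, run2$trace$per_ms_distance)
  expect_identical(free_run(run1$weights, bank, 256),
                   free_run(run2$weights, bank, 256))
})

test_that("driven evaluation feeds the true signal and matches forward steps", {
  bank <- test_bank()
  cfg <- srn_config(hidden_size = 4L, epochs = 5L, attention_horizon_ms = 16L,
                    seed = 9L)
  w <- train_srn(init_srn(cfg), build_trajectory(bank, 16), cfg)$weights
  pred <- driven_run(w, bank, 5)
  # manual two-step recomputation with forward_step
  h <- rep(0.5, 4)
  for (t in 1:5) {
    step <- forward_step(w, oscillator_state(bank, t - 1), h)
    expect_equal(unname(pred[t, ]), unname(step$y), tolerance = 1e-12)
    h <- step$h
  }
})

test_that("error traces follow the Euclidean closed forms", {
  bank <- test_bank()
  truth <- build_trajectory(bank, 20)$states[-1, ]
  tr0 <- error_trace(truth, bank)
  expect_equal(tr0$per_ms_distance, rep(0, 20))
  expect_equal(tr0$cumulative_mean, rep(0, 20))

  # every coordinate off by +0.1: distance 0.1 * sqrt(12) at every ms
  tr1 <- error_trace(pmin(truth + 0.1, Inf), bank)
  expect_equal(tr1$per_ms_distance, rep(0.346410161514, 20), tolerance = 1e-9)
  expect_equal(tr1$cumulative_mean, rep(0.346410161514, 20), tolerance = 1e-9)
  expect_equal(tr1$cumulative_distance, cumsum(tr1$per_ms_distance))
})

test_that("dispersion fits agree with lm and handle degenerate traces", {
  mk <- function(d) structure(list(t_ms = seq_along(d), per_ms_distance = d,
                                   cumulative_distance = cumsum(d),
                                   cumulative_mean = cumsum(d) / seq_along(d)),
                              class = "error_trace")
  # exactly linear cumulative mean: slope recovered, R^2 = 1
  t <- 1:100
  cm <- 0.01 + 0.0002 * t
  d <- diff(c(0, cm * t))  # distances whose running mean is cm
  fit <- dispersion_coefficient(mk(d), statistic = "cumulative_mean")
  expect_equal(fit$slope, 0.0002, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # flat trace: zero slope, R^2 defined as 0
  flat <- dispersion_coefficient(mk(rep(0, 10)))
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)

  # noisy trace: slope and R^2 equal the lm oracle
  set.seed(42)
  d <- abs(0.2 + 0.0001 * (1:500) + rnorm(500, 0, 0.05))
  tr <- mk(d)
  fit <- dispersion_coefficient(tr)
  oracle <- lm(cumsum(d) ~ tr$t_ms)
  expect_equal(fit$slope, unname(coef(oracle)[2]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(coef(oracle)[1]), tolerance = 1e-10)
  expect_equal(fit$r_squared, summary(oracle)$r.squared, tolerance = 1e-10)

  expect_error(dispersion_coefficient(mk(numeric(1))), "length")
})

test_that("cumulative error of a trained default clock accumulates with time", {
  cfg <- srn_config(hidden_size = 16L, epochs = 100L,
                    attention_horizon_ms = 1024L, seed = 1L)
  run <- simulate_clock(cfg, test_bank())
  rho <- cor(run$trace$cumulative_distance, run$trace$t_ms,
             method = "spearman")
  expect_gt(rho, 0.9)
  expect_gt(run$fit$slope, 0)
})
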