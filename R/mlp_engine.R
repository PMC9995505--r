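# Minimal feed-forward network engine used by the meta-model (parameters ->
# dispersion) and the prior network (scores -> parameters). Deliberately
# plain: sigmoid hidden units, sigmoid or linear output, full-batch gradient
# descent with momentum, seeded uniform [-0.5, 0.5] initialisation. The
# composite model needs gradients with respect to a frozen network's inputs,
# which none of the installed single-hidden-layer fitters expose, so the
# engine is written out here.

mlp_new <- function(sizes, output_act = c("linear", "sigmoid"), seed = 1L) {
  output_act <- match.arg(output_act)
  stopifnot(length(sizes) >= 2)
  n_lay <- length(sizes) - 1L
  local_seed(seed, {
    W <- vector("list", n_lay)
    b <- vector("list", n_lay)
    for (l in seq_len(n_lay)) {
      W[[l]] <- matrix(runif(sizes[l + 1] * sizes[l], -0.5, 0.5),
                       sizes[l + 1], sizes[l])
      b[[l]] <- runif(sizes[l + 1], -0.5, 0.5)
    }
    list(sizes = as.integer(sizes), W = W, b = b,
         act = c(rep("sigmoid", n_lay - 1L), output_act))
  })
}

mlp_act <- function(z, act) if (act == "sigmoid") 1 / (1 + exp(-z)) else z

# X: n x d. Returns list of activations, element 1 = X, element l+1 = layer l.
mlp_forward <- function(net, X) {
  A <- vector("list", length(net$W) + 1L)
  A[[1]] <- X
  for (l in seq_along(net$W)) {
    Z <- A[[l]] %*% t(net$W[[l]])
    Z <- sweep(Z, 2, net$b[[l]], "+")
    A[[l + 1]] <- mlp_act(Z, net$act[l])
  }
  A
}

mlp_predict <- function(net, X) mlp_forward(net, X)[[length(net$W) + 1L]]

# Full-batch backprop for loss 0.5 * mean of squared errors. `out_delta`
# overrides the output-layer error (used by the composite model); when given,
# it must already be divided by the sample count. Returns weight/bias
# gradients and the gradient with respect to the input rows.
mlp_backprop <- function(net, A, Y = NULL, out_delta = NULL) {
  n_lay <- length(net$W)
  n <- nrow(A[[1]])
  delta <- if (is.null(out_delta)) (A[[n_lay + 1L]] - Y) / n else out_delta
  if (net$act[n_lay] == "sigmoid") {
    a <- A[[n_lay + 1L]]
    delta <- delta * a * (1 - a)
  }
  gW <- vector("list", n_lay)
  gb <- vector("list", n_lay)
  for (l in n_lay:1) {
    gW[[l]] <- t(delta) %*% A[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% net$W[[l]]
      a <- A[[l]]
      delta <- delta * a * (1 - a)
    }
  }
  list(gW = gW, gb = gb, input_grad = delta %*% net$W[[1]])
}

mlp_mse <- function(net, X, Y) mean((mlp_predict(net, X) - Y)^2)

# Gradient descent with momentum; halves the step and restores the best
# weights if the loss diverges. Returns the trained net plus convergence info.
mlp_train <- function(net, X, Y, lr = 0.5, momentum = 0.9,
                      max_iter = 5000L, tol = 1e-8) {
  vW <- lapply(net$W, function(w) w * 0)
  vb <- lapply(net$b, function(b) b * 0)
  best <- net
  best_mse <- mlp_mse(net, X, Y)
  prev_mse <- best_mse
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- mlp_forward(net, X)
    g <- mlp_backprop(net, A, Y)
    for (l in seq_along(net$W)) {
      vW[[l]] <- -lr * g$gW[[l]] + momentum * vW[[l]]
      vb[[l]] <- -lr * g$gb[[l]] + momentum * vb[[l]]
      net$W[[l]] <- net$W[[l]] + vW[[l]]
      net$b[[l]] <- net$b[[l]] + vb[[l]]
    }
    mse <- mlp_mse(net, X, Y)
    if (!is.finite(mse) || mse > 4 * best_mse + 1e-12) {
      net <- best
      lr <- lr / 2
      vW <- lapply(vW, function(w) w * 0)
      vb <- lapply(vb, function(b) b * 0)
      prev_mse <- best_mse
      next
    }
    if (mse < best_mse) {
      best <- net
      best_mse <- mse
    }
    if (abs(prev_mse - mse) < tol) {
      converged <- TRUE
      break
    }
    prev_mse <- mse
  }
  list(net = best, mse = best_mse, converged = converged, iterations = it)
}
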