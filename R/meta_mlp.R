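#' Normalise the sweep table for the meta-model
#'
#' Min-max scales the four clock parameters to `[0, 1]` (the minimum of each
#' parameter maps to 0, the maximum to 1) and pairs them with the dispersion
#' coefficients. The scaling constants are stored for the inverse mapping
#' and for normalising prediction-time inputs.
#'
#' @param table A [run_sweep()] table (at least 2 distinct values per
#'   parameter, no failed cells among the rows used).
#' @return Object of class `normalized_grid` with `X` (n x 4 matrix, columns
#'   `attention`, `hidden`, `epochs`, `offset`), `y` (dispersion
#'   coefficients) and `ranges` (2 x 4 min/max matrix).
#' @export
normalize_grid <- function(table) {
  cols <- c("attention", "hidden", "epochs", "offset")
  tab <- table[!is.na(table$slope), , drop = FALSE]
  if (nrow(tab) == 0) stop("no completed sweep cells", call. = FALSE)
  X <- as.matrix(tab[cols])
  ranges <- apply(X, 2, range)
  rownames(ranges) <- c("min", "max")
  if (any(ranges["max", ] == ranges["min", ]))
    stop("each parameter needs at least 2 distinct values", call. = FALSE)
  Xn <- sweep(sweep(X, 2, ranges["min", ], "-"), 2,
              ranges["max", ] - ranges["min", ], "/")
  structure(list(X = Xn, y = tab$slope, ranges = ranges),
            class = "normalized_grid")
}

#' Map normalised parameters back to raw values
#'
#' @param grid A [normalize_grid()] object.
#' @param Xn Matrix (or 4-vector) of normalised coordinates.
#' @return Matrix of raw parameter values.
#' @export
denormalize_params <- function(grid, Xn) {
  stopifnot(inherits(grid, "normalized_grid"))
  if (is.null(dim(Xn))) Xn <- matrix(Xn, nrow = 1)
  sweep(sweep(Xn, 2, grid$ranges["max", ] - grid$ranges["min", ], "*"),
        2, grid$ranges["min", ], "+")
}

#' Enumerate candidate hidden architectures
#'
#' All hidden-layer layouts with a total neuron count in
#' `[min_total, max_total]`, each successive layer strictly smaller than the
#' previous one, and every layer holding at least `min_layer` neurons.
#' Candidates are listed in a fixed linear order: by total neurons, then by
#' number of layers, then lexicographically.
#'
#' @param min_total,max_total Bounds on the total hidden neuron count
#'   (defaults 8 and 28, the meta-model search range).
#' @param min_layer Minimum neurons per layer (default 3).
#' @return List of integer vectors, one per architecture.
#' @export
architecture_candidates <- function(min_total = 8L, max_total = 28L,
                                    min_layer = 3L) {
  out <- list()
  grow <- function(prefix, remaining_max) {
    upper <- if (length(prefix)) prefix[length(prefix)] - 1L else remaining_max
    upper <- min(upper, remaining_max)
    for (sz in seq_len(upper)) {
      if (sz < min_layer) next
      cand <- c(prefix, sz)
      if (sum(cand) >= min_total) out[[length(out) + 1L]] <<- cand
      if (remaining_max - sz >= min_layer) grow(cand, remaining_max - sz)
    }
  }
  grow(integer(), max_total)
  ord <- order(vapply(out, sum, integer(1)),
               vapply(out, length, integer(1)),
               vapply(out, function(a) paste(sprintf("%03d", a), collapse = ""),
                      character(1)))
  out[ord]
}

#' Train the meta-model on a normalised grid
#'
#' Fits a feed-forward network (sigmoid hidden layers, linear output, bias
#' units everywhere) mapping the four normalised clock parameters to the
#' dispersion coefficient. Training is full-batch gradient descent with
#' momentum until the MSE change falls below `tol` or `max_iter` is reached;
#' `restarts` seeded restarts are run and the best kept. Targets are
#' standardised internally; the scaling is stored in the model and undone at
#' prediction time.
#'
#' @param grid A [normalize_grid()] object.
#' @param arch Integer vector of hidden-layer sizes (e.g. `c(15, 10, 3)`).
#' @param seed Base seed; restart `r` uses `seed + r - 1`.
#' @param max_iter,tol,restarts,learning_rate,momentum Training control.
#' @return List with `model` (class `meta_model`) and `metrics`
#'   (`r_squared`, `mse`, `mae`, `converged`). MSE and MAE are on the
#'   dispersion-coefficient scale.
#' @export
train_meta <- function(grid, arch, seed = 1L, max_iter = 5000L, tol = 1e-8,
                       restarts = 3L, learning_rate = 0.5, momentum = 0.9) {
  stopifnot(inherits(grid, "normalized_grid"))
  arch <- as.integer(arch)
  y_center <- mean(grid$y)
  y_scale <- sd(grid$y)
  if (y_scale == 0) y_scale <- 1
  Y <- matrix((grid$y - y_center) / y_scale, ncol = 1)
  best <- NULL
  for (r in seq_len(restarts)) {
    net0 <- mlp_new(c(ncol(grid$X), arch, 1L), "linear", seed = seed + r - 1L)
    fit <- mlp_train(net0, grid$X, Y, lr = learning_rate, momentum = momentum,
                     max_iter = max_iter, tol = tol)
    if (is.null(best) || fit$mse < best$mse) best <- fit
  }
  model <- structure(list(net = best$net, arch = arch, ranges = grid$ranges,
                          y_center = y_center, y_scale = y_scale),
                     class = "meta_model")
  pred <- predict_dispersion(model, denormalize_params(grid, grid$X))
  resid <- pred - grid$y
  ss_res <- sum(resid^2)
  ss_tot <- sum((grid$y - mean(grid$y))^2)
  metrics <- list(r_squared = if (ss_tot == 0) NA_real_ else 1 - ss_res / ss_tot,
                  mse = mean(resid^2), mae = mean(abs(resid)),
                  converged = best$converged)
  list(model = model, metrics = metrics)
}

#' @export
print.meta_model <- function(x, ...) {
  cat(sprintf("Meta-model: 4 - [%s] - 1, sigmoid hidden, linear output\n",
              paste(x$arch, collapse = " - ")))
  invisible(x)
}

#' Constrained architecture search for the meta-model
#'
#' Trains every candidate architecture with the same seed policy and keeps
#' the one with the smallest training MSE; ties are broken by fewer total
#' neurons, then enumeration order. To keep the systematic search
#' affordable, candidates are first screened with a shortened training run
#' (`screen_iter` iterations, single start) and the winner is then refitted
#' with the full [train_meta()] settings.
#'
#' @param grid A [normalize_grid()] object.
#' @param candidates List of architectures (default
#'   [architecture_candidates()]).
#' @param seed Seed shared by all candidates.
#' @param screen_iter Iteration cap used during screening.
#' @param ... Passed to the final [train_meta()] refit.
#' @return The [train_meta()] result of the winning architecture, with the
#'   screening table attached as `search`.
#' @export
select_architecture <- function(grid, candidates = architecture_candidates(),
                                seed = 1L, screen_iter = 400L, ...) {
  stopifnot(length(candidates) >= 1)
  mse <- vapply(candidates, function(arch) {
    train_meta(grid, arch, seed = seed, max_iter = screen_iter,
               restarts = 1L)$metrics$mse
  }, numeric(1))
  totals <- vapply(candidates, sum, integer(1))
  best <- order(mse, totals, seq_along(candidates))[1]
  out <- train_meta(grid, candidates[[best]], seed = seed, ...)
  out$search <- data.frame(
    arch = vapply(candidates, function(a) paste(a, collapse = "-"),
                  character(1)),
    total = totals, screen_mse = mse, stringsAsFactors = FALSE)
  out
}

#' Predict a dispersion coefficient from raw parameter values
#'
#' Normalises the inputs with the scaling constants stored in the model and
#' evaluates the network. Inputs outside the training min-max box are
#' flagged (attribute `extrapolated`) with a warning: the meta-model
#' interpolates the simulated grid and is not calibrated beyond it.
#'
#' @param model A `meta_model` from [train_meta()].
#' @param params Matrix (n x 4) or vector (length 4) of raw parameter values
#'   in the column order `attention`, `hidden`, `epochs`, `offset`.
#' @return Numeric vector of predicted dispersion coefficients with a
#'   logical `extrapolated` attribute.
#' @export
predict_dispersion <- function(model, params) {
  stopifnot(inherits(model, "meta_model"))
  if (is.null(dim(params))) params <- matrix(params, nrow = 1)
  if (ncol(params) != 4) stop("`params` must have 4 columns", call. = FALSE)
  rng <- model$ranges
  Xn <- sweep(sweep(params, 2, rng["min", ], "-"), 2,
              rng["max", ] - rng["min", ], "/")
  outside <- apply(Xn < -1e-9 | Xn > 1 + 1e-9, 1, any)
  if (any(outside))
    warning(sum(outside), " input(s) outside the training parameter box",
            call. = FALSE)
  pred <- drop(mlp_predict(model$net, Xn)) * model$y_scale + model$y_center
  attr(pred, "extrapolated") <- unname(outside)
  pred
}

#' Serialize / restore a meta-model as JSON-friendly lists
#'
#' Plain-list form (weights, biases, scaling constants) suitable for
#' `jsonlite::write_json()` or storage in any text format.
#'
#' @param model A `meta_model`.
#' @return `meta_model_to_list()` returns a plain list;
#'   `meta_model_from_list()` rebuilds the `meta_model`.
#' @export
meta_model_to_list <- function(model) {
  stopifnot(inherits(model, "meta_model"))
  # weight matrices are flattened column-major so the layout survives any
  # JSON round trip; sizes determine the reshape
  list(arch = model$arch,
       sizes = model$net$sizes,
       act = model$net$act,
       W = lapply(model$net$W, as.numeric),
       b = model$net$b,
       ranges = as.numeric(model$ranges),
       y_center = model$y_center, y_scale = model$y_scale)
}

#' @rdname meta_model_to_list
#' @param x A list produced by `meta_model_to_list()` (possibly after a JSON
#'   round trip).
#' @export
meta_model_from_list <- function(x) {
  sizes <- as.integer(unlist(x$sizes))
  W <- lapply(seq_along(x$W), function(l)
    matrix(unlist(x$W[[l]]), sizes[l + 1], sizes[l]))
  structure(list(net = list(sizes = sizes, W = W,
                            b = lapply(x$b, as.numeric),
                            act = as.character(unlist(x$act))),
                 arch = as.integer(unlist(x$arch)),
                 ranges = matrix(as.numeric(unlist(x$ranges)), 2, 4,
                                 dimnames = list(c("min", "max"),
                                                 c("attention", "hidden",
                                                   "epochs", "offset"))),
                 y_center = as.numeric(x$y_center),
                 y_scale = as.numeric(x$y_scale)),
            class = "meta_model")
}
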