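#' Relative timing error of a reproduction trial
#'
#' The per-production error is `|reproduced - target| / target`: the
#' magnitude of the reproduction bias relative to the target duration,
#' folded to be sign-free so under- and over-estimations do not cancel.
#' `squared = TRUE` gives the squared relative error instead.
#'
#' @param reproduced_s Reproduced duration(s) in seconds.
#' @param target_s Target duration(s) in seconds (must be positive).
#' @param squared Use the squared relative error (default `FALSE`).
#' @return Numeric vector of dimensionless errors.
#' @export
absolute_error <- function(reproduced_s, target_s, squared = FALSE) {
  if (any(!is.finite(target_s)) || any(target_s <= 0))
    stop("`target_s` must be positive", call. = FALSE)
  rel <- (reproduced_s - target_s) / target_s
  if (squared) rel^2 else abs(rel)
}

#' Tukey 1.5-IQR outlier rejection
#'
#' Computes per-group fences `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR` (quantiles by
#' linear interpolation, R type 7) and rejects values outside either fence.
#' Fences are computed once on the input and applied once; the function is
#' a single-pass filter, not an iterative trimmer.
#'
#' @param values Numeric vector (e.g. per-production absolute errors).
#' @param groups Grouping factor of the same length (e.g. child/adult);
#'   a single group if omitted.
#' @param k Fence multiplier (default 1.5).
#' @return Object of class `cleaned_trials`: logical `retained`, the
#'   `fences` per group, and rejection counts.
#' @export
iqr_filter <- function(values, groups = NULL, k = 1.5) {
  if (is.null(groups)) groups <- rep("all", length(values))
  groups <- as.factor(groups)
  stopifnot(length(groups) == length(values))
  if (any(table(groups) < 4))
    stop("each group needs at least 4 values for quartile fences",
         call. = FALSE)
  retained <- logical(length(values))
  fences <- data.frame(group = levels(groups), q1 = NA_real_, q3 = NA_real_,
                       lower = NA_real_, upper = NA_real_,
                       n = NA_integer_, rejected = NA_integer_)
  for (i in seq_along(levels(groups))) {
    g <- levels(groups)[i]
    sel <- groups == g
    q <- quantile(values[sel], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    lo <- q[1] - k * iqr
    hi <- q[2] + k * iqr
    keep <- values[sel] >= lo & values[sel] <= hi
    retained[sel] <- keep
    fences[i, c("q1", "q3", "lower", "upper")] <- c(q, lo, hi)
    fences$n[i] <- sum(sel)
    fences$rejected[i] <- sum(!keep)
  }
  structure(list(retained = retained, fences = fences,
                 n = length(values), n_rejected = sum(!retained),
                 rejection_rate = mean(!retained)),
            class = "cleaned_trials")
}

#' @export
print.cleaned_trials <- function(x, ...) {
  cat(sprintf("Tukey filter: %d of %d rejected (%.2f%%)\n", x$n_rejected,
              x$n, 100 * x$rejection_rate))
  invisible(x)
}

#' Assemble the serial composite model
#'
#' The composite is two networks in series: a trainable prior network
#' mapping the five individual features (short-term memory, working memory,
#' attention, processing speed, age in months) to the four normalised clock
#' parameters through a sigmoid output layer (so the parameters stay in
#' `[0, 1]`), feeding the fitted meta-model, which is frozen: its weights
#' are never touched by composite training.
#'
#' @param prior_arch Hidden-layer sizes of the prior network (e.g. `10`).
#' @param meta_model A fitted [train_meta()] `meta_model`.
#' @param seed Seed for the prior network initialisation.
#' @return Object of class `composite_model`.
#' @export
build_composite <- function(prior_arch, meta_model, seed = 1L) {
  stopifnot(inherits(meta_model, "meta_model"))
  prior_arch <- as.integer(prior_arch)
  if (any(prior_arch < 1)) stop("invalid prior architecture", call. = FALSE)
  prior <- mlp_new(c(5L, prior_arch, 4L), "sigmoid", seed = seed)
  structure(list(prior = prior, prior_arch = prior_arch, frozen = meta_model,
                 feature_ranges = NULL),
            class = "composite_model")
}

#' @export
print.composite_model <- function(x, ...) {
  cat(sprintf("Composite clock model: [5 - %s - 4] trainable prior -> frozen [4 - %s - 1] meta-model\n",
              paste(x$prior_arch, collapse = " - "),
              paste(x$frozen$arch, collapse = " - ")))
  invisible(x)
}

composite_features <- function(records) {
  need <- c("stm", "wm", "attention", "processing_speed", "age_months")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("participant records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  as.matrix(records[need])
}

scale_features <- function(X, ranges = NULL) {
  if (is.null(ranges)) {
    ranges <- apply(X, 2, range)
    rownames(ranges) <- c("min", "max")
  }
  span <- ranges["max", ] - ranges["min", ]
  span[span == 0] <- 1
  list(X = sweep(sweep(X, 2, ranges["min", ], "-"), 2, span, "/"),
       ranges = ranges)
}

#' Forward pass of the composite model
#'
#' @param model A [build_composite()] model with feature scaling set (after
#'   training) or raw `[0, 1]` features.
#' @param features n x 5 matrix of raw feature values (`stm`, `wm`,
#'   `attention`, `processing_speed`, `age_months`).
#' @return List with `params` (n x 4 normalised clock parameters) and
#'   `prediction` (n predicted errors).
#' @export
predict_composite <- function(model, features) {
  stopifnot(inherits(model, "composite_model"))
  if (is.null(dim(features))) features <- matrix(features, nrow = 1)
  Xs <- scale_features(features, model$feature_ranges)$X
  P <- mlp_predict(model$prior, Xs)
  pred <- drop(mlp_predict(model$frozen$net, P)) * model$frozen$y_scale +
    model$frozen$y_center
  if (!is.null(model$calibration))
    pred <- unname(model$calibration["a"] * pred + model$calibration["b"])
  list(params = P, prediction = pred)
}

#' Train the composite model on cleaned productions
#'
#' One training sample per retained production: the features are the
#' participant's five inputs min-max scaled over the cohort, the target is
#' that production's absolute reproduction error. Gradient descent updates
#' only the prior network; gradients flow through the frozen meta-model but
#' its weights are bit-identical before and after training.
#'
#' The frozen stage emits a temporal dispersion coefficient while the
#' training target is an absolute reproduction error; both are
#' dimensionless with overlapping ranges, so by default they are compared
#' directly. `calibrate = TRUE` adds a trainable affine output layer
#' (`a * prediction + b`, initialised at identity) between the frozen stage
#' and the loss for robustness when the two scales drift apart.
#'
#' @param model A [build_composite()] model.
#' @param records Participant data frame (`id`, `stm`, `wm`, `attention`,
#'   `processing_speed`, `age_months`, ...).
#' @param trials Production data frame (`participant_id`, `target_s`,
#'   `reproduced_s`), already outlier-filtered.
#' @param learning_rate,momentum,max_iter,tol Training control. The default
#'   step size is larger than usual for a plain MLP because gradients reach
#'   the prior only after shrinking through the frozen stage and the
#'   dispersion-scale factor.
#' @param calibrate Train an affine rescaling of the frozen stage's output
#'   (default `FALSE`, reference behaviour).
#' @return List with the trained `model`, `metrics` (`r_squared`, `mse`,
#'   `mae`, `converged`) and `participant_params`: each participant's
#'   inferred normalised and raw clock parameters.
#' @export
train_composite <- function(model, records, trials, learning_rate = 2,
                            momentum = 0.9, max_iter = 4000L, tol = 1e-10,
                            calibrate = FALSE) {
  stopifnot(inherits(model, "composite_model"))
  idx <- match(trials$participant_id, records$id)
  if (anyNA(idx))
    stop("every trial needs a matching participant record", call. = FALSE)
  Xraw <- composite_features(records)[idx, , drop = FALSE]
  sc <- scale_features(Xraw)
  model$feature_ranges <- sc$ranges
  X <- sc$X
  y <- absolute_error(trials$reproduced_s, trials$target_s)
  n <- length(y)

  frozen <- model$frozen
  frozen_before <- frozen$net$W
  prior <- model$prior
  cal <- c(a = 1, b = 0)
  vW <- lapply(prior$W, function(w) w * 0)
  vb <- lapply(prior$b, function(b) b * 0)
  vcal <- c(a = 0, b = 0)
  lr <- learning_rate

  comp_pred <- function(prior, cal) {
    P <- mlp_predict(prior, X)
    raw <- drop(mlp_predict(frozen$net, P)) * frozen$y_scale + frozen$y_center
    cal["a"] * raw + cal["b"]
  }
  best <- list(prior = prior, cal = cal)
  best_mse <- mean((comp_pred(prior, cal) - y)^2)
  prev_mse <- best_mse
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    Ap <- mlp_forward(prior, X)
    P <- Ap[[length(prior$W) + 1L]]
    Af <- mlp_forward(frozen$net, P)
    raw <- drop(Af[[length(frozen$net$W) + 1L]]) * frozen$y_scale +
      frozen$y_center
    pred <- cal["a"] * raw + cal["b"]
    resid <- (pred - y) / n
    out_delta <- matrix(resid * cal["a"] * frozen$y_scale, ncol = 1)
    gfrozen <- mlp_backprop(frozen$net, Af, out_delta = out_delta)
    gprior <- mlp_backprop(prior, Ap, out_delta = gfrozen$input_grad)
    for (l in seq_along(prior$W)) {
      vW[[l]] <- -lr * gprior$gW[[l]] + momentum * vW[[l]]
      vb[[l]] <- -lr * gprior$gb[[l]] + momentum * vb[[l]]
      prior$W[[l]] <- prior$W[[l]] + vW[[l]]
      prior$b[[l]] <- prior$b[[l]] + vb[[l]]
    }
    if (calibrate) {
      g_cal <- c(a = sum(resid * raw), b = sum(resid))
      vcal <- -lr * g_cal + momentum * vcal
      cal <- cal + vcal
    }
    mse <- mean((comp_pred(prior, cal) - y)^2)
    if (!is.finite(mse) || mse > 4 * best_mse + 1e-12) {
      prior <- best$prior
      cal <- best$cal
      lr <- lr / 2
      vW <- lapply(vW, function(w) w * 0)
      vb <- lapply(vb, function(b) b * 0)
      vcal <- c(a = 0, b = 0)
      prev_mse <- best_mse
      next
    }
    if (mse < best_mse) {
      best <- list(prior = prior, cal = cal)
      best_mse <- mse
    }
    if (abs(prev_mse - mse) < tol) {
      converged <- TRUE
      break
    }
    prev_mse <- mse
  }
  model$prior <- best$prior
  model$calibration <- best$cal
  stopifnot(identical(frozen_before, model$frozen$net$W))

  pred <- comp_pred(best$prior, best$cal)
  resid <- pred - y
  ss_tot <- sum((y - mean(y))^2)
  metrics <- list(r_squared = if (ss_tot == 0) NA_real_ else
    1 - sum(resid^2) / ss_tot,
    mse = mean(resid^2), mae = mean(abs(resid)), converged = converged)

  uid <- !duplicated(records$id)
  out <- predict_composite(model, composite_features(records[uid, ]))
  raw <- denormalize_params(structure(list(ranges = frozen$ranges),
                                      class = "normalized_grid"), out$params)
  participant_params <- data.frame(id = records$id[uid], out$params)
  names(participant_params) <- c("id", "attention_norm", "hidden_norm",
                                 "epochs_norm", "offset_norm")
  participant_params$attention <- raw[, 1]
  participant_params$hidden <- raw[, 2]
  participant_params$epochs <- raw[, 3]
  participant_params$offset <- raw[, 4]
  participant_params$predicted_error <- out$prediction

  list(model = model, metrics = metrics,
       participant_params = participant_params)
}

#' Search the prior-network architecture
#'
#' Enumerates prior hidden architectures with 5 to 12 total neurons under
#' the same constraints as the meta-model search (strictly decreasing
#' layers, at least 3 neurons per layer), trains each composite with the
#' same seed, and returns the one with the highest coefficient of
#' determination against the observed errors.
#'
#' @param records,trials As in [train_composite()].
#' @param meta_model The frozen fitted meta-model.
#' @param min_total,max_total Bounds on total prior hidden neurons.
#' @param seed Shared seed.
#' @param ... Passed to [train_composite()].
#' @return The winning [train_composite()] result with a `search` table of
#'   per-architecture fits attached.
#' @export
search_prior_architecture <- function(records, trials, meta_model,
                                      min_total = 5L, max_total = 12L,
                                      seed = 1L, ...) {
  candidates <- architecture_candidates(min_total, max_total, min_layer = 3L)
  fits <- lapply(candidates, function(arch) {
    model <- build_composite(arch, meta_model, seed = seed)
    train_composite(model, records, trials, ...)
  })
  r2 <- vapply(fits, function(f) f$metrics$r_squared, numeric(1))
  best <- which.max(r2)
  out <- fits[[best]]
  out$search <- data.frame(
    arch = vapply(candidates, function(a) paste(a, collapse = "-"),
                  character(1)),
    total = vapply(candidates, sum, integer(1)),
    r_squared = r2, stringsAsFactors = FALSE)
  out
}
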