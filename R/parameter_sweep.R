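#' Define a parameter-sweep grid
#'
#' The sweep crosses the four clock parameters in a full factorial. The
#' reference grid is 5 attention x 5 memory x 5 iterative-learning x
#' 7 plasticity = 875 configurations. Each cell receives a deterministic
#' seed, `base_seed + cell_index - 1`, so a sweep is reproducible from its
#' grid definition alone.
#'
#' @param attention_levels Training-window lengths in ms.
#' @param memory_levels Hidden-layer sizes.
#' @param epoch_levels Training epochs.
#' @param offset_levels Fahlman offsets.
#' @param base_seed Integer base seed for the per-cell seed assignment.
#' @param eval_horizon_ms Evaluation length (ms) shared by all cells; `NULL`
#'   (default) evaluates each cell over its own attention window.
#' @return Object of class `sweep_grid`.
#' @export
sweep_grid <- function(attention_levels = c(1024L, 1792L, 2560L, 3328L, 4096L),
                       memory_levels = c(8L, 16L, 32L, 64L, 128L),
                       epoch_levels = c(100L, 200L, 300L, 400L, 500L),
                       offset_levels = c(0.01, 0.015, 0.03, 0.06, 0.125, 0.25, 0.5),
                       base_seed = 1L,
                       eval_horizon_ms = NULL) {
  stopifnot(length(attention_levels) >= 1, length(memory_levels) >= 1,
            length(epoch_levels) >= 1, length(offset_levels) >= 1)
  structure(list(attention_levels = as.integer(attention_levels),
                 memory_levels = as.integer(memory_levels),
                 epoch_levels = as.integer(epoch_levels),
                 offset_levels = as.numeric(offset_levels),
                 base_seed = as.integer(base_seed),
                 eval_horizon_ms = if (!is.null(eval_horizon_ms))
                   as.integer(eval_horizon_ms)),
            class = "sweep_grid")
}

#' Desk-scale version of the reference sweep grid
#'
#' The full factorial keeps the reference levels for memory and plasticity
#' but divides the attention windows by `attention_scale` (default 16:
#' 64, 112, 160, 208, 256 ms) and the epoch levels by `epoch_scale`
#' (default 2: 50 ... 250). Training cost scales with epochs x window, so
#' this brings the 875-cell sweep from hours to minutes while preserving
#' the factorial structure; the vignette discusses what does and does not
#' survive the rescaling.
#'
#' @param base_seed Base seed for the per-cell seeds.
#' @param attention_scale Integer divisor applied to the attention windows.
#' @param epoch_scale Integer divisor applied to the epoch levels.
#' @return A [sweep_grid()].
#' @export
desk_grid <- function(base_seed = 1L, attention_scale = 16L,
                      epoch_scale = 2L) {
  sweep_grid(attention_levels = c(1024L, 1792L, 2560L, 3328L, 4096L) %/%
               as.integer(attention_scale),
             epoch_levels = c(100L, 200L, 300L, 400L, 500L) %/%
               as.integer(epoch_scale),
             base_seed = base_seed)
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("Sweep grid: %d attention x %d memory x %d epochs x %d offsets = %d cells\n",
              length(x$attention_levels), length(x$memory_levels),
              length(x$epoch_levels), length(x$offset_levels),
              length(x$attention_levels) * length(x$memory_levels) *
                length(x$epoch_levels) * length(x$offset_levels)))
  invisible(x)
}

#' Expand a sweep grid into per-cell configurations
#'
#' Full factorial in a fixed order: attention varies fastest, then memory,
#' then epochs, then offset (the order of [expand.grid()]).
#'
#' @param grid A [sweep_grid()].
#' @return Data frame with one row per cell: `cell`, `attention`, `hidden`,
#'   `epochs`, `offset`, `seed`.
#' @export
build_grid <- function(grid) {
  stopifnot(inherits(grid, "sweep_grid"))
  cells <- expand.grid(attention = grid$attention_levels,
                       hidden = grid$memory_levels,
                       epochs = grid$epoch_levels,
                       offset = grid$offset_levels,
                       KEEP.OUT.ATTRS = FALSE)
  cells$cell <- seq_len(nrow(cells))
  cells$seed <- grid$base_seed + cells$cell - 1L
  cells[c("cell", "attention", "hidden", "epochs", "offset", "seed")]
}

#' Run the parameter sweep
#'
#' Trains and evaluates one clock per grid cell and records its temporal
#' dispersion coefficient. When `out` is given, each completed cell is
#' appended to that CSV and a restarted sweep skips cells already present,
#' so long sweeps are resumable. A cell whose simulation fails is recorded
#' with `NA` slope and the error message; it does not abort the sweep.
#'
#' @param grid A [sweep_grid()].
#' @param bank The [oscillator_bank()] shared by all cells.
#' @param out Optional CSV path for incremental persistence/resume.
#' @param verbose Print a progress line every `verbose` cells (0 = silent).
#' @return Data frame of class `sweep_table`: `cell`, `attention`, `hidden`,
#'   `epochs`, `offset`, `seed`, `slope`, `r2`, `error`.
#' @export
run_sweep <- function(grid, bank = oscillator_bank(), out = NULL, verbose = 0L) {
  stopifnot(inherits(grid, "sweep_grid"))
  cells <- build_grid(grid)
  done <- NULL
  if (!is.null(out) && file.exists(out)) {
    done <- read.csv(out)
    if (!all(c("cell", "slope") %in% names(done)))
      stop("`out` exists but is not a sweep table", call. = FALSE)
  }
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cl <- cells[i, ]
    if (!is.null(done) && cl$cell %in% done$cell) {
      rows[[i]] <- done[done$cell == cl$cell, , drop = FALSE][1, ]
      next
    }
    cfg <- srn_config(hidden_size = cl$hidden, epochs = cl$epochs,
                      fahlman_offset = cl$offset,
                      attention_horizon_ms = cl$attention,
                      eval_horizon_ms = grid$eval_horizon_ms,
                      seed = cl$seed)
    res <- tryCatch({
      run <- simulate_clock(cfg, bank)
      data.frame(cl, slope = run$fit$slope, r2 = run$fit$r_squared,
                 error = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(cl, slope = NA_real_, r2 = NA_real_,
                 error = conditionMessage(e), stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
    if (!is.null(out))
      write.table(res, out, sep = ",", row.names = FALSE,
                  col.names = !file.exists(out), append = file.exists(out))
    if (verbose > 0 && i %% verbose == 0)
      message(sprintf("sweep: %d / %d cells", i, nrow(cells)))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  class(tab) <- c("sweep_table", "data.frame")
  tab
}

sweep_param_col <- function(parameter) {
  cols <- c(attention = "attention", memory = "hidden", hidden = "hidden",
            epochs = "epochs", learning = "epochs",
            offset = "offset", plasticity = "offset")
  col <- cols[parameter]
  if (is.na(col))
    stop(sprintf("unknown sweep parameter '%s'", parameter), call. = FALSE)
  unname(col)
}

#' Marginal mean dispersion per parameter level
#'
#' Mean dispersion coefficient at each level of one parameter, averaged
#' over all combinations of the other three factors.
#'
#' @param table A [run_sweep()] table.
#' @param parameter One of `"attention"`, `"memory"`, `"epochs"`,
#'   `"offset"` (aliases `"hidden"`, `"learning"`, `"plasticity"`).
#' @return Data frame with `level`, `mean`, `n`.
#' @export
marginal_means <- function(table, parameter) {
  col <- sweep_param_col(parameter)
  lv <- sort(unique(table[[col]]))
  data.frame(level = lv,
             mean = vapply(lv, function(l) mean(table$slope[table[[col]] == l]),
                           numeric(1)),
             n = vapply(lv, function(l) sum(table[[col]] == l), integer(1)))
}

# Wide subjects x levels matrix for the within-subject analyses. Subjects are
# the crossed combinations of the three non-analysed factors (forced by the
# reference degrees of freedom: 175 subjects x 5 levels, 125 x 7 for offset).
sweep_wide <- function(table, parameter) {
  col <- sweep_param_col(parameter)
  others <- setdiff(c("attention", "hidden", "epochs", "offset"), col)
  subj <- interaction(table[[others[1]]], table[[others[2]]],
                      table[[others[3]]], drop = TRUE)
  lv <- sort(unique(table[[col]]))
  wide <- matrix(NA_real_, nlevels(subj), length(lv),
                 dimnames = list(levels(subj), as.character(lv)))
  for (j in seq_along(lv)) {
    sel <- table[[col]] == lv[j]
    idx <- match(as.character(subj[sel]), rownames(wide))
    if (anyNA(idx) || any(duplicated(idx)) || sum(sel) != nrow(wide))
      stop("sweep table is not balanced for this parameter", call. = FALSE)
    wide[idx, j] <- table$slope[sel]
  }
  if (anyNA(wide))
    stop("sweep table has missing cells for this parameter", call. = FALSE)
  wide
}

#' One-way repeated-measures ANOVA on the sweep table
#'
#' Within-subject ANOVA of the dispersion coefficient across the levels of
#' one parameter. The "subjects" are the crossed combinations of the other
#' three factors, each measured once at every level of the analysed
#' parameter. Partial eta squared is `SS_effect / (SS_effect + SS_error)`.
#'
#' @inheritParams marginal_means
#' @return List with `F`, `df1`, `df2`, `p`, `partial_eta_squared` and the
#'   underlying sums of squares.
#' @export
rm_anova <- function(table, parameter) {
  wide <- sweep_wide(table, parameter)
  n_s <- nrow(wide); n_l <- ncol(wide)
  long <- data.frame(y = as.vector(wide),
                     level = factor(rep(colnames(wide), each = n_s)),
                     subject = factor(rep(rownames(wide), n_l)))
  fit <- aov(y ~ level + Error(subject), data = long)
  within <- summary(fit)[["Error: Within"]][[1]]
  ss_effect <- within["level", "Sum Sq"]
  ss_error <- within["Residuals", "Sum Sq"]
  df1 <- within["level", "Df"]
  df2 <- within["Residuals", "Df"]
  # no within-subject variance at all (every subject flat across levels):
  # the effect is exactly zero by convention, not 0/0
  degenerate <- sum((wide - rowMeans(wide))^2) <=
    .Machine$double.eps^0.75 * max(1, sum(wide^2))
  f <- if (degenerate) 0 else within["level", "F value"]
  p <- if (degenerate) 1 else within["level", "Pr(>F)"]
  list(F = unname(f), df1 = unname(df1), df2 = unname(df2), p = unname(p),
       partial_eta_squared = if (degenerate) 0 else
         unname(ss_effect / (ss_effect + ss_error)),
       ss_effect = unname(ss_effect), ss_error = unname(ss_error))
}

#' Bonferroni-corrected paired contrasts between parameter levels
#'
#' All pairwise paired t-tests between the levels of one parameter, with
#' subjects defined as in [rm_anova()]. P-values are Bonferroni-corrected
#' within the parameter (capped at 1).
#'
#' @inheritParams marginal_means
#' @param conf_level Confidence level of the interval on the mean difference.
#' @return Data frame with `level_a`, `level_b`, `delta_mean`, `se`,
#'   `ci_low`, `ci_high`, `t`, `p_bonferroni`.
#' @export
paired_contrasts <- function(table, parameter, conf_level = 0.95) {
  wide <- sweep_wide(table, parameter)
  lv <- colnames(wide)
  pairs <- utils::combn(seq_along(lv), 2)
  n_pairs <- ncol(pairs)
  n <- nrow(wide)
  out <- lapply(seq_len(n_pairs), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- wide[, i] - wide[, j]
    m <- mean(d); se <- sd(d) / sqrt(n)
    # zero-variance differences (up to float cancellation): exact tie
    if (se <= 1e-12 * max(1, abs(m))) {
      se <- 0
      tval <- if (abs(m) <= 1e-12) 0 else sign(m) * Inf
    } else tval <- m / se
    p <- if (tval == 0) 1 else 2 * pt(-abs(tval), df = n - 1)
    hw <- qt(1 - (1 - conf_level) / 2, df = n - 1) * se
    data.frame(level_a = lv[i], level_b = lv[j], delta_mean = m, se = se,
               ci_low = m - hw, ci_high = m + hw, t = tval,
               p_bonferroni = min(1, p * n_pairs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write / read a sweep table as CSV
#'
#' @param table A `sweep_table`.
#' @param path File path.
#' @export
write_sweep <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell", "attention", "hidden", "epochs", "offset", "seed",
            "slope", "r2")
  missing <- setdiff(need, names(tab))
  if (length(missing))
    stop("sweep file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(tab$error)) tab$error <- ""
  class(tab) <- c("sweep_table", "data.frame")
  tab
}
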