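#' Default oscillator frequencies (Hz)
#'
#' The twelve gamma-band rates of the clock's oscillator bank. They span
#' 32.9--37.2 Hz, the range of gamma oscillations recorded in awake humans,
#' and are strictly increasing so that the joint 12-dimensional state is a
#' unique signature of elapsed time over many cycles.
#'
#' @return Numeric vector of 12 frequencies in Hz.
#' @export
default_frequencies <- function() {
  c(32.9, 33.2, 33.6, 34, 34.3, 34.7, 35.1, 35.5, 35.9, 36.3, 36.8, 37.2)
}

#' Create an oscillator bank
#'
#' An oscillator bank is the generative signal of the internal clock: twelve
#' formal oscillatory neurons, each fluctuating between a negative and a
#' positive state around 0.5, sampled every millisecond. All oscillators are
#' synchronised at stimulus onset: the state at `t = 0` is 0.5 for every
#' unit.
#'
#' @param frequencies Strictly increasing vector of 12 rates in Hz.
#' @param waveform Function `(f_hz, t_ms) -> state in [0, 1]` evaluated per
#'   oscillator. The default is the sinusoid
#'   `0.5 + 0.5 * sin(2 * pi * f * t / 1000)`, which satisfies the model's
#'   constraints (starts at 0.5, oscillates between negative and positive
#'   states around 0.5, rate in Hz).
#' @return An object of class `oscillator_bank`.
#' @examples
#' bank <- oscillator_bank()
#' oscillator_state(bank, 0)   # all 0.5 at onset
#' @export
oscillator_bank <- function(frequencies = default_frequencies(),
                            waveform = NULL) {
  if (length(frequencies) != 12L)
    stop("an oscillator bank has exactly 12 frequencies", call. = FALSE)
  if (any(diff(frequencies) <= 0))
    stop("frequencies must be strictly increasing", call. = FALSE)
  if (is.null(waveform))
    waveform <- function(f_hz, t_ms) 0.5 + 0.5 * sin(2 * pi * f_hz * t_ms / 1000)
  structure(list(frequencies = as.numeric(frequencies),
                 sampling_period_ms = 1L,
                 initial_value = 0.5,
                 waveform = waveform),
            class = "oscillator_bank")
}

#' @export
print.oscillator_bank <- function(x, ...) {
  cat("Oscillator bank: 12 units,",
      sprintf("%.1f-%.1f Hz, 1 ms sampling, initial state 0.5\n",
              min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' State of the oscillator bank at a given millisecond
#'
#' @param bank An [oscillator_bank()].
#' @param t_ms Non-negative integer time in milliseconds (scalar).
#' @return Numeric vector of 12 states in `[0, 1]`; 0.5 is the zero crossing,
#'   values below/above 0.5 are negative/positive oscillator states.
#' @export
oscillator_state <- function(bank, t_ms) {
  stopifnot(inherits(bank, "oscillator_bank"))
  if (!is.numeric(t_ms) || length(t_ms) != 1L || is.na(t_ms) || t_ms < 0)
    stop("`t_ms` must be a single non-negative number", call. = FALSE)
  vapply(bank$frequencies, function(f) bank$waveform(f, t_ms), numeric(1))
}

# All states for t = 0..horizon as a (horizon + 1) x 12 matrix.
oscillator_states <- function(bank, horizon_ms) {
  t_ms <- 0:horizon_ms
  vapply(bank$frequencies, function(f) bank$waveform(f, t_ms),
         numeric(length(t_ms)))
}

#' Build the supervised trajectory dataset
#'
#' The clock network learns the one-step map of the oscillator bank: each
#' training pair is (state at `t`, state at `t + 1`) for
#' `t = 0 .. horizon - 1`. The horizon is the attention parameter: a smaller
#' window means the system traces the evolution of the oscillations over a
#' shorter stretch of time, i.e. less information enters the training
#' database.
#'
#' @param bank An [oscillator_bank()].
#' @param horizon_ms Positive integer number of training pairs (ms).
#' @return An object of class `trajectory_dataset` with elements `horizon_ms`
#'   and `states`, a `(horizon_ms + 1) x 12` matrix whose row `t + 1` is the
#'   bank state at time `t`.
#' @export
build_trajectory <- function(bank, horizon_ms) {
  stopifnot(inherits(bank, "oscillator_bank"))
  horizon_ms <- stop_if_not_count(horizon_ms, "horizon_ms", min = 1L)
  structure(list(horizon_ms = horizon_ms,
                 states = oscillator_states(bank, horizon_ms)),
            class = "trajectory_dataset")
}

#' Extract the k-th (input, target) pair of a trajectory dataset
#'
#' @param data A [build_trajectory()] result.
#' @param k Pair index, `1 .. horizon_ms`.
#' @return List with `input` (state at `k - 1`) and `target` (state at `k`).
#' @export
trajectory_pair <- function(data, k) {
  stopifnot(inherits(data, "trajectory_dataset"))
  k <- stop_if_not_count(k, "k", min = 1L)
  if (k > data$horizon_ms) stop("`k` exceeds the dataset horizon", call. = FALSE)
  list(input = data$states[k, ], target = data$states[k + 1L, ])
}

#' Write / read a trajectory dataset as CSV
#'
#' Plain-text persistence for inspection and fixtures. Columns are `t` (ms)
#' and `o1`..`o12`.
#'
#' @param data A `trajectory_dataset`.
#' @param path File path.
#' @return `read_trajectory()` returns the `t` column and state matrix as a
#'   list; `write_trajectory()` returns `path` invisibly.
#' @export
write_trajectory <- function(data, path) {
  stopifnot(inherits(data, "trajectory_dataset"))
  df <- data.frame(t = 0:data$horizon_ms, data$states)
  names(df) <- c("t", paste0("o", 1:12))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  need <- c("t", paste0("o", 1:12))
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("trajectory file is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  list(t = df$t, states = as.matrix(df[paste0("o", 1:12)]))
}
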