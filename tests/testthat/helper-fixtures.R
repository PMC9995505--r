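# Shared fixtures, computed lazily and cached for the whole test run so the
# expensive sweeps are trained only once.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

test_bank <- function() fixture("bank", oscillator_bank)

# Small factorial used by the sweep statistics tests: 2 x 2 x 2 x 3 = 24
# cells at toy training sizes (seconds to run).
tiny_sweep <- function() {
  fixture("tiny_sweep", function() {
    grid <- sweep_grid(attention_levels = c(64L, 128L),
                      memory_levels = c(4L, 8L),
                      epoch_levels = c(5L, 10L),
                      offset_levels = c(0.01, 0.125, 0.5),
                      base_seed = 42L,
                      eval_horizon_ms = 256L)
    run_sweep(grid, test_bank())
  })
}

# Desk-scale version of the reference factorial shared by the acceptance
# tests: all 875 parameter combinations with the training window shortened
# eightfold. One sweep, reused by every check.
desk_sweep <- function() {
  fixture("desk_sweep", function() {
    run_sweep(desk_grid(base_seed = 1L), test_bank())
  })
}

# A synthetic cohort at study scale, shared across participant tests.
study_cohort <- function() {
  fixture("study_cohort", function() {
    spec <- cohort_spec(seed = 7L)
    records <- suppressWarnings(sample_cohort(spec))
    trials <- sample_reproductions(records, spec)
    list(spec = spec, records = records, trials = trials)
  })
}
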