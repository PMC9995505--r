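---
title: "An oscillator-bank recurrent-network clock: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An oscillator-bank recurrent-network clock: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpclock)
```

## The model

`cpclock` simulates an internal clock for human interval timing built from
two ingredients.

**The oscillator bank.** Twelve formal oscillatory neurons with strictly
increasing gamma-band rates (32.9--37.2 Hz) are sampled every millisecond.
Each unit's state is `0.5 + 0.5 sin(2 pi f t / 1000)`: 0.5 is the zero
crossing, values below and above it are negative and positive states, and
all units are synchronised at 0.5 when a stimulus starts. Because the rates
are incommensurate over the durations of interest, the joint 12-dimensional
state is a unique signature of elapsed time: reading the bank's state *is*
reading the clock.

**The readout network.** An Elman simple recurrent network (SRN) learns the
one-step map of the bank. The hidden layer is updated as
`h_t = sigma(A x_t + R h_{t-1})` and the output as `y_t = f(U h_t)`, where
`x_t` is the 12-dimensional oscillator state, `h_{t-1}` a context copy of
the previous hidden state, and `f` a per-unit logistic function by default
(a softmax output is available behind `output_activation = "softmax"`; it
turns the prediction into a probability distribution, which cannot be
compared coordinate-wise against oscillator states, so it is not the
default). Training is stochastic backpropagation in temporal order: one
update per (state at `t`, state at `t + 1`) pair, learning rate 0.1,
momentum 0.9, gradients truncated at the context copy (no backpropagation
through time). The loss is the squared error averaged over the 12 output
units; with a summed loss the same printed learning rate and momentum
drive training into saturation at large Fahlman offsets, so the averaged
convention is used throughout.

## The four cognitive dials

| dial | mechanism | levels swept |
|---|---|---|
| attention | length of the training window (ms of oscillation traced) | 1024, 1792, 2560, 3328, 4096 |
| memory | hidden-layer size | 8, 16, 32, 64, 128 |
| iterative learning | training epochs | 100 ... 500 |
| clock plasticity | Fahlman offset on the sigmoid derivative | 0.01 ... 0.5 |

The Fahlman offset adds a constant to `y(1 - y)` wherever that derivative
scales an error term (both layers here; the choice of "both" rather than
one layer is a documented reading of an ambiguous description). It removes
the flat spots of the sigmoid, which speeds learning but destabilises it:
a highly "plastic" clock learns aggressively and forgets. Hidden state
resets to the 0.5 resting state (the sigmoid fixed point) at each epoch
start; momentum buffers persist across epochs.

## Evaluating a trained clock

Two evaluation modes are implemented.

* **Driven** (`eval_mode = "driven"`, the default): the true oscillator
  state is the input at every millisecond — the input layer acts as a
  buffer for the oscillation signal — while the context layer carries the
  network's own hidden history. Prediction error then reflects how well
  the readout tracks a signal whose joint phase pattern becomes
  progressively harder (the oscillators desynchronise over seconds), and
  it accumulates smoothly across the whole window.
* **Free-running** (`eval_mode = "free"`): the fully closed loop, each
  prediction fed back as the next input. Empirically this loop amplifies
  its own prediction error and decoheres to the distance plateau within
  tens of milliseconds at *every* training quality reachable under the
  fixed hyperparameters; no factor structure survives. It is retained as
  an explicit mode because it is the literal reading of "adding t + 1
  until reaching the duration", but it cannot express gradual,
  seconds-long error accumulation, which is the phenomenon of interest.

By default each run is evaluated over its own attention window
(`eval_horizon_ms = NULL`). Evaluating every cell on a fixed long horizon
instead lets the beyond-window extrapolation error (mean distances near
the decorrelation plateau) swamp every other factor; in-window evaluation
keeps the coefficient on the scale of the network's actual tracking error
and preserves the factor structure. The horizon remains an explicit
configuration field for any other protocol.

## The temporal dispersion coefficient

`error_trace()` records the per-millisecond Euclidean distance between
predicted and true states, its running sum and its running mean.
`dispersion_coefficient()` fits ordinary least squares of the cumulative
*summed* distance on time in milliseconds; the slope — asymptotically the
mean per-millisecond prediction error, a dimensionless quantity on a
0.1--0.3 scale — is the temporal dispersion coefficient, and the fit is
near-perfectly linear (R² above 0.98) for every configuration. A running
*mean* regression is available via `statistic = "cumulative_mean"`; it was
not chosen as the default because its slope is bounded by
`sqrt(12) / horizon` per millisecond, three orders of magnitude below the
scale on which dispersion coefficients are conventionally reported, and
because it penalises uniformly bad runs (a flat, high error trace) with a
*small* slope. A flat trace has zero slope and, by convention, `r_squared
= 0`.

The cumulative trace is the model's analogue of the scalar property of
timing: error accumulates with the length of the estimated interval.

## The parameter sweep and its statistics

`run_sweep()` crosses the four dials in a full factorial (the reference
grid is 5 x 5 x 5 x 7 = 875 cells), each cell seeded deterministically as
`base_seed + cell_index - 1`, and records each cell's coefficient and fit
R². The sweep is resumable: with `out =` a CSV path, completed cells are
appended as they finish and skipped on restart.

For the within-subject analyses the "subjects" are the crossed
combinations of the three non-analysed factors — for memory, the 175
(attention, epochs, offset) combinations each measured at 5 hidden sizes,
giving the degrees of freedom (4, 696); for plasticity, 125 subjects at 7
levels, giving (6, 744). `rm_anova()` fits the one-way repeated-measures
ANOVA through `stats::aov` with an `Error(subject)` stratum and reports
partial eta squared as `SS_effect / (SS_effect + SS_error)`;
`paired_contrasts()` runs all pairwise paired t-tests with Bonferroni
correction within the parameter.

### Desk-scale protocol

Training cost scales with epochs x window length. The full reference
factorial takes hours on one core, so the package defines a desk-scale
protocol, `desk_grid()`: the same 875-cell factorial with the attention
windows divided by 16 (64--256 ms, still 2--9 full oscillation cycles)
and the epoch levels halved (50--250). This is the problem size used by
the test suite and the acceptance script. What survives the rescaling:
the factorial structure, the sign and dominance order of the factor
effects, the linearity of the cumulative traces, and the rough scale of
the coefficients. What does not: absolute coefficient values shift with
the window (shorter windows are easier to memorise), and the attention
marginal reflects 64--256 ms windows, not seconds-long ones.

## The meta-model (parameters to dispersion)

`normalize_grid()` min-max scales the four parameters to [0, 1];
`train_meta()` fits a feed-forward network — sigmoid hidden layers, linear
output, bias units everywhere — by full-batch gradient descent with
momentum (tolerance 1e-8 on the MSE change, cap 5000 iterations, 3 seeded
restarts, best kept). Targets are standardised internally and the scaling
stored in the model. `architecture_candidates()` enumerates every hidden
layout with 8--28 total neurons, strictly decreasing layer sizes and at
least 3 neurons per layer, in a fixed linear order;
`select_architecture()` trains each candidate (screened at a reduced
iteration cap, single start, then the winner refitted in full — the
two-stage screen keeps the several-hundred-candidate search affordable)
and keeps the minimum-MSE model, ties broken by fewer neurons then
enumeration order. The meta-model is fitted and reported on the same grid
it was trained on — it is a compression of the simulation, not a
generalisation claim.

## The participant pipeline (scores to errors)

Reproduction trials (3/6/9/12-s targets) are summarised by the relative
error magnitude `|reproduced - target| / target`; the sign-free form stops
under- and over-estimations cancelling (a squared variant is available).
The superscript in the source description of this formula is read as a
citation marker, not an exponent, because its stated purpose is avoiding
sign cancellation. Cleaning uses Tukey fences `Q1 -/+ 1.5 IQR` per age
group, quantiles by linear interpolation (R type 7), computed once on the
input and applied once.

The composite model chains a trainable **prior network** (five inputs —
short-term memory, working memory, attention, processing speed, age in
months — min-max scaled over the cohort; sigmoid output layer, so the four
predicted clock parameters live in the meta-model's [0, 1] input space)
into the **frozen** fitted meta-model. Training updates only the prior;
gradients flow through the frozen stage whose weights are bit-identical
before and after (asserted at run time). One training sample per retained
production. The frozen stage emits a dispersion coefficient while the
target is a reproduction error; both are dimensionless with overlapping
ranges and are compared directly by default, with an optional trainable
affine output calibration (`calibrate = TRUE`) for robustness. The default
learning rate (2) is larger than usual because gradients shrink through
the frozen stage and the dispersion-scale factor.
`search_prior_architecture()` repeats the constrained enumeration for the
prior (5--12 total neurons) and keeps the highest coefficient of
determination against the observed errors.

## The synthetic cohort generator

`cohort_spec()` reproduces the reference study's structure: 192 children
(60--107 months) and 116 adults (truncated-normal ages, mean 21 y), four
neuropsychological scores per group drawn from truncated normals matching
the published means, SDs and ranges, and 7 (children) / 6 (adults)
reproductions per participant cycling through the 3/6/9/12-s targets
(2040 productions; the study's 2055 are unevenly distributed per subject
in a way that is not described, so an even design is used). The published
children's processing-speed parameters (mean 44.28, SD 26.28, maximum 51)
are mutually inconsistent; the generator takes the bounds as hard
truncation and warns.

Reproductions follow an invented scalar-noise model, clearly labelled as
such: with `c` the participant's min-max-scaled cognitive composite,
`bias = k_bias (1 - c)`, `cv = cv0 + k_cv (1 - c)` and
`R = T (1 + bias + eps)`, `eps ~ N(0, cv^2)`, occasionally inflated by an
outlier mixture. The reproduction SD is proportional to the target by
construction — the scalar property. Defaults `cv0 = 0.10`, `k_cv = 0.20`,
`k_bias = 0.15` are chosen as psychophysically plausible weber-fraction
scales; the outlier defaults (rate 0.12, SD multiplier 6) were calibrated
once so the default cohort loses 7--8% of its productions to the Tukey
filter, matching the study's reported rejection fraction. What the
generator emulates: marginal score distributions, group sizes, scalar
variability, a score-dependent error level, an outlier tail. What it does
not: correlations between scores within a participant, age-score
coupling beyond group membership, sequential effects across trials, and
any claim about the study's latent parameters. Passing tests on this
cohort therefore demonstrate machinery (recovery, filtering, freezing),
not fidelity to individual human data.

## Numerical choices and degenerate inputs

* Weight initialisation: uniform [-0.5, 0.5], seeded per configuration;
  all randomness flows from explicit seeds and runs are bit-reproducible.
* Softmax outputs receive no Fahlman offset (there is no sigmoid
  derivative on that path); the softmax Jacobian is applied exactly.
* Zero-variance traces: slope 0, R² defined as 0. A repeated-measures
  design in which every subject is flat across levels returns F = 0,
  p = 1, partial eta squared 0 rather than 0/0.
* Paired contrasts with zero-variance differences report t = 0 and
  p = 1 on exact ties (and an infinite t on exact constant differences).
* The architecture search breaks MSE ties by fewer total neurons, then
  enumeration order.
* MLP training halves its step and restores the best weights whenever the
  loss diverges; convergence is a 1e-8 tolerance on the MSE change.

## Known limitations

* The direction of temporal bias (under- versus over-estimation) is out
  of scope; the model speaks to error magnitude only.
* The closed-loop mode is faithful to its definition but numerically
  degenerate (see above); conclusions about the four dials rest on the
  driven mode.
* Absolute dispersion levels are sensitive to initialisation scale, loss
  convention and window length; orderings and effect dominance are the
  robust quantities.
* The meta-model and composite are fitted, not cross-validated, mirroring
  the reference analysis; `train_meta()` reports fit metrics on the
  training grid.
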