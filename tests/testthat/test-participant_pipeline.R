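# A small fitted meta-model over a smooth synthetic dispersion surface,
# reused as the frozen stage of the composite tests.
frozen_meta <- function() {
  fixture("frozen_meta", function() {
    tab <- expand.grid(attention = c(1024, 2560, 4096), hidden = c(8, 32, 128),
                       epochs = c(100, 300, 500), offset = c(0.01, 0.125, 0.5))
    tab$slope <- 0.12 + 0.25 * tab$offset / 0.5 - 0.08 * log2(tab$hidden) / 7 +
      0.02 * tab$epochs / 500 + 0.01 * tab$attention / 4096
    tab$r2 <- 1
    train_meta(normalize_grid(tab), arch = c(8L), seed = 6L,
               max_iter = 3000L)$model
  })
}

test_that("absolute reproduction error follows its closed form", {
  expect_equal(absolute_error(3, 3), 0)
  expect_equal(absolute_error(6, 3), 1.0)
  expect_equal(absolute_error(2, 4), 0.5)
  expect_equal(absolute_error(c(2, 6), c(4, 3)), c(0.5, 1))
  expect_equal(absolute_error(2, 4, squared = TRUE), 0.25)
  expect_error(absolute_error(3, 0), "positive")
})

test_that("the Tukey filter reproduces hand-computed fences", {
  # toy list: Q1 = 2, Q3 = 4 under linear interpolation, fences [-1, 7]
  out <- iqr_filter(c(1, 2, 3, 4, 100))
  expect_equal(out$retained, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$fences$q1, 2)
  expect_equal(out$fences$q3, 4)
  expect_equal(out$fences$lower, -1)
  expect_equal(out$fences$upper, 7)
  expect_equal(out$n_rejected, 1L)

  # all-equal values: IQR 0, fences collapse onto the data, nothing rejected
  same <- iqr_filter(rep(0.3, 10))
  expect_true(all(same$retained))

  # per-group fences: the outlier is only an outlier within its own group
  vals <- c(1, 2, 3, 4, 100, 90, 100, 110, 120, 3)
  grp <- rep(c("a", "b"), each = 5)
  out <- iqr_filter(vals, grp)
  expect_equal(out$retained[grp == "a"], c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$retained[grp == "b"], c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_error(iqr_filter(1:3), "at least 4")
})

test_that("fences are computed once and applied once", {
  vals <- c(1, 2, 3, 4, 100)
  once <- iqr_filter(vals)
  again <- iqr_filter(vals[once$retained])
  # the second pass recomputes fences on the cleaned data; the contract is
  # only that the first pass's fences came from the full input
  expect_equal(once$fences$q1, 2)
  expect_true(all(again$retained))
})

test_that("the composite wires the frozen stage verbatim", {
  meta <- frozen_meta()
  comp <- build_composite(c(10L), meta, seed = 2L)
  expect_identical(comp$frozen$net$W, meta$net$W)
  X <- matrix(runif(50, 0, 1), 10, 5)
  comp$feature_ranges <- rbind(min = rep(0, 5), max = rep(1, 5))
  out <- predict_composite(comp, X)
  expect_true(all(is.finite(out$prediction)))
  expect_true(all(out$params >= 0 & out$params <= 1))
  # equals the manual two-stage evaluation
  P <- cpclock:::mlp_predict(comp$prior, X)
  manual <- drop(cpclock:::mlp_predict(meta$net, P)) * meta$y_scale +
    meta$y_center
  expect_equal(out$prediction, manual, tolerance = 1e-12)
  expect_error(build_composite(0L, meta), "architecture")
})

recovery_setup <- function(n = 320L, noise_sd = 0.002, seed = 31L) {
  meta <- frozen_meta()
  truth <- build_composite(c(10L), meta, seed = 99L)
  # a freshly initialised sigmoid prior is nearly constant; scale its weights
  # so the ground-truth map has real structure to recover
  truth$prior$W <- lapply(truth$prior$W, function(w) 5 * w)
  truth$prior$b <- lapply(truth$prior$b, function(b) 5 * b)
  spec <- cohort_spec(n_children = ceiling(n * 0.6), n_adults = floor(n * 0.4),
                      seed = seed)
  records <- suppressWarnings(sample_cohort(spec))
  feats <- cpclock:::composite_features(records)
  truth$feature_ranges <- apply(feats, 2, range)
  rownames(truth$feature_ranges) <- c("min", "max")
  y <- predict_composite(truth, feats)$prediction
  targets <- rep_len(c(3, 6, 9, 12), nrow(records))
  y_obs <- pmax(0, y + local({set.seed(seed + 1); rnorm(length(y), 0, noise_sd)}))
  trials <- data.frame(participant_id = records$id, target_s = targets,
                       reproduced_s = targets * (1 + y_obs))
  list(records = records, trials = trials, meta = meta, y_true = y)
}

test_that("composite training leaves the frozen weights bit-identical", {
  s <- recovery_setup(n = 60L)
  comp <- build_composite(c(5L), s$meta, seed = 1L)
  before <- comp$frozen$net
  fit <- train_composite(comp, s$records, s$trials, max_iter = 200L)
  expect_identical(fit$model$frozen$net, before)
})

test_that("composite training recovers errors generated by its own map", {
  s <- recovery_setup()
  comp <- build_composite(c(10L), s$meta, seed = 12L)
  fit <- train_composite(comp, s$records, s$trials, max_iter = 8000L)
  expect_gt(fit$metrics$r_squared, 0.9)
  pred <- predict_composite(fit$model,
                            cpclock:::composite_features(s$records))$prediction
  expect_gt(cor(pred, s$y_true)^2, 0.9)
  # per-participant parameter estimates cover every participant once
  expect_equal(nrow(fit$participant_params), nrow(s$records))
  expect_true(all(fit$participant_params$offset >=
                    s$meta$ranges["min", "offset"] - 1e-9))
})

test_that("the prior search spans 5-12 neurons and keeps the best fit", {
  cand <- architecture_candidates(5L, 12L, 3L)
  key <- vapply(cand, paste, character(1), collapse = "-")
  expect_true("10" %in% key)
  expect_true(all(vapply(cand, sum, integer(1)) <= 12))
  s <- recovery_setup(n = 40L)
  # two-candidate search: the winner must carry the higher R^2
  sel <- search_prior_architecture(s$records, s$trials, s$meta,
                                   min_total = 5L, max_total = 6L,
                                   seed = 2L, max_iter = 150L)
  expect_equal(nrow(sel$search), 2)
  expect_equal(max(sel$search$r_squared), sel$metrics$r_squared)
})

test_that("the affine calibration layer absorbs a scale mismatch", {
  s <- recovery_setup(n = 60L)
  # shift the observed errors so the frozen output scale no longer matches
  shifted <- s$trials
  shifted$reproduced_s <- shifted$target_s *
    (1 + 2 * absolute_error(s$trials$reproduced_s, s$trials$target_s) + 0.1)
  base <- train_composite(build_composite(c(5L), s$meta, seed = 3L),
                          s$records, shifted, max_iter = 1500L)
  cal <- train_composite(build_composite(c(5L), s$meta, seed = 3L),
                         s$records, shifted, max_iter = 1500L,
                         calibrate = TRUE)
  expect_lte(cal$metrics$mse, base$metrics$mse + 1e-8)
  expect_false(is.null(cal$model$calibration))
})

test_that("external column names map onto the cohort schema", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subj,grp,age_months,corsi_f,corsi_b,sky,ivt,target_s,reproduced_s",
               "c1,child,72,5,4,20,40,3,3.5",
               "c2,child,80,6,5,22,41,6,5.1",
               "c3,adult,250,9,8,4,60,9,8.8"), path)
  got <- read_cohort(path, column_map = c(participant_id = "subj",
                                          group = "grp", stm = "corsi_f",
                                          wm = "corsi_b", attention = "sky",
                                          processing_speed = "ivt"))
  expect_equal(got$records$id, c("c1", "c2", "c3"))
  expect_equal(got$trials$target_s, c(3, 6, 9))
})

test_that("trials without records are rejected", {
  s <- recovery_setup(n = 40L)
  comp <- build_composite(c(5L), s$meta, seed = 1L)
  bad <- s$trials
  bad$participant_id[1] <- "nobody"
  expect_error(train_composite(comp, s$records, bad), "matching participant")
})
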