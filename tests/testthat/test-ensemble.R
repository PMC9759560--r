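test_that("a single perfectly predictive reference yields intercept 0, coefficient 1", {
  # query subject's noiseless signal equals 1.0 x reference signal
  cfg <- tiny_config(n_subjects = 2L, n_stimuli = 100L, noise_sd = 0,
                     idiosyncratic_signal_sd = 0.2, seed = 6L,
                     query_mixing = list(intercept = 0, beta = 1))
  gen <- generate_cohort(cfg)
  sp <- build_split(gen$cohort, n_val = 10L, n_test = 20L, seed = 6L)
  ors <- oracle_readouts(gen$ground_truth, "V1v")
  m <- fit_linear_ensemble(ors["sub01"], sp, "sub02", "V1v", n_train = 30L,
                           seed = 1L, loo = TRUE)
  expect_equal(unname(m$coefficients), 1, tolerance = 1e-10)
  expect_equal(m$intercept, 0, tolerance = 1e-10)
})

test_that("OLS coefficients match the normal-equations oracle", {
  gen <- generate_cohort(tiny_config(n_subjects = 4L, n_stimuli = 120L,
                                     feature_dim = 8L, noise_sd = 0.6,
                                     seed = 13L))
  sp <- build_split(gen$cohort, n_val = 10L, n_test = 20L, seed = 13L)
  ors <- oracle_readouts(gen$ground_truth, "V1v")
  m <- fit_linear_ensemble(ors, sp, "sub04", "V1v", n_train = 50L, seed = 3L)
  rows <- attr(m, "training_rows")
  x <- sapply(ors[m$reference_subjects], function(r) {
    predict(r, gen$cohort$stimuli$features[rows$stimulus_id, , drop = FALSE])
  })
  resp <- gen$cohort$responses
  y <- resp$response[match(paste(rows$subject_id, "V1v", rows$stimulus_id,
                                 rows$repeat_index),
                           paste(resp$subject_id, resp$region_id,
                                 resp$stimulus_id, resp$repeat_index))]
  beta <- ols_oracle(x, y)
  expect_equal(m$intercept, unname(beta[1]), tolerance = 1e-8)
  expect_equal(unname(m$coefficients), unname(beta[-1]), tolerance = 1e-8)
  expect_equal(m$n_train_used, 50L)
})

test_that("rank-deficient designs get a minimum-norm solution with a warning", {
  gen <- generate_cohort(tiny_config(n_subjects = 2L, n_stimuli = 80L,
                                     seed = 21L))
  sp <- build_split(gen$cohort, n_val = 10L, n_test = 10L, seed = 21L)
  d <- feature_dim(gen$cohort)
  const_ref <- readout_model("flat", "V1v", rep(0, d), 1.7)
  expect_warning(
    m <- fit_linear_ensemble(list(const_ref), sp, "sub01", "V1v",
                             n_train = 20L, seed = 2L),
    "minimum-norm")
  # fitted mean is preserved: intercept + coef * 1.7 equals the OLS mean fit
  rows <- attr(m, "training_rows")
  resp <- gen$cohort$responses
  y <- resp$response[match(paste(rows$subject_id, "V1v", rows$stimulus_id,
                                 rows$repeat_index),
                           paste(resp$subject_id, resp$region_id,
                                 resp$stimulus_id, resp$repeat_index))]
  expect_equal(m$intercept + m$coefficients[["flat"]] * 1.7, mean(y),
               tolerance = 1e-10)
})

test_that("ensemble predictions evaluate the linear combination per stimulus", {
  d <- 5L
  refs <- lapply(1:3, function(i) random_readout(sprintf("r%d", i), "R", d, i))
  set.seed(99)
  x <- matrix(rnorm(20 * d), 20, d, dimnames = list(sprintf("s%02d", 1:20), NULL))
  m <- linear_ensemble_model("q", "R", sprintf("r%d", 1:3),
                             intercept = 0.3, coefficients = c(0.5, -1, 2))
  got <- predict(m, refs, x)
  want <- vapply(seq_len(20), function(i) {
    0.3 + sum(c(0.5, -1, 2) * vapply(refs, function(r) {
      sum(r$weights * x[i, ]) + r$bias
    }, numeric(1L)))
  }, numeric(1L))
  expect_equal(unname(got), want, tolerance = 1e-12)

  # equal-weight linear ensemble with zero intercept = average ensemble
  meq <- linear_ensemble_model("q", "R", sprintf("r%d", 1:3),
                               intercept = 0, coefficients = rep(1 / 3, 3))
  ma <- average_ensemble_model("q", "R", sprintf("r%d", 1:3))
  expect_equal(predict(meq, refs, x), predict(ma, refs, x), tolerance = 1e-12)

  # identical readouts: average equals any single readout
  same <- list(refs[[1]], readout_model("r2", "R", refs[[1]]$weights,
                                        refs[[1]]$bias))
  ma2 <- average_ensemble_model("q", "R", c("r1", "r2"))
  expect_equal(unname(predict(ma2, same, x)), unname(predict(refs[[1]], x)),
               tolerance = 1e-12)

  expect_error(predict(m, refs[1:2], x), class = "visens_missing_reference")
})

test_that("leave-one-out construction excludes each query and is deterministic", {
  gen <- generate_cohort(synthetic_config(n_subjects = 8L, n_regions = 1L,
                                          n_stimuli = 400L,
                                          n_shared_stimuli = 400L, seed = 17L))
  sp <- build_split(gen$cohort, n_val = 20L, n_test = 40L, seed = 17L)
  ors <- oracle_readouts(gen$ground_truth, "V1v")
  ens <- build_loo_ensembles(ors, sp, "V1v", n_train = 60L, seed = 4L)
  expect_length(ens, 8L)
  for (s in names(ens)) {
    expect_length(ens[[s]]$reference_subjects, 7L)
    expect_false(s %in% ens[[s]]$reference_subjects)
  }
  ens2 <- build_loo_ensembles(ors, sp, "V1v", n_train = 60L, seed = 4L)
  for (s in names(ens)) {
    expect_identical(ens[[s]]$coefficients, ens2[[s]]$coefficients)
    expect_identical(ens[[s]]$intercept, ens2[[s]]$intercept)
  }
  expect_error(build_loo_ensembles(ors[1], sp, "V1v", 60L, 1L),
               class = "visens_sizing_error")

  # two subjects: one reference each
  gen2 <- generate_cohort(tiny_config(n_subjects = 2L, n_stimuli = 80L, seed = 2L))
  sp2 <- build_split(gen2$cohort, n_val = 10L, n_test = 10L, seed = 2L)
  ors2 <- oracle_readouts(gen2$ground_truth, "V1v")
  ens2s <- build_loo_ensembles(ors2, sp2, "V1v", n_train = 20L, seed = 1L)
  expect_identical(ens2s$sub01$reference_subjects, "sub02")
  expect_identical(ens2s$sub02$reference_subjects, "sub01")
})

test_that("the linear ensemble's training fit is at least as good as the average ensemble's", {
  gen <- generate_cohort(tiny_config(n_subjects = 5L, n_stimuli = 150L,
                                     noise_sd = 0.8, seed = 23L))
  sp <- build_split(gen$cohort, n_val = 10L, n_test = 20L, seed = 23L)
  ors <- oracle_readouts(gen$ground_truth, "V1v")
  for (s in c("sub01", "sub03")) {
    m <- fit_linear_ensemble(ors, sp, s, "V1v", n_train = 40L, seed = 7L)
    rows <- attr(m, "training_rows")
    fx <- gen$cohort$stimuli$features[rows$stimulus_id, , drop = FALSE]
    resp <- gen$cohort$responses
    y <- resp$response[match(paste(rows$subject_id, "V1v", rows$stimulus_id,
                                   rows$repeat_index),
                             paste(resp$subject_id, resp$region_id,
                                   resp$stimulus_id, resp$repeat_index))]
    refs <- ors[m$reference_subjects]
    p_lin <- m$intercept +
      drop(sapply(refs, function(r) predict(r, fx)) %*% m$coefficients)
    p_avg <- rowMeans(sapply(refs, function(r) predict(r, fx)))
    expect_lte(mean((p_lin - y)^2), mean((p_avg - y)^2) + 1e-12)
  }
})

test_that("sizing preconditions are enforced", {
  gen <- generate_cohort(tiny_config(n_subjects = 3L, n_stimuli = 60L, seed = 3L))
  sp <- build_split(gen$cohort, n_val = 10L, n_test = 10L, seed = 3L)
  ors <- oracle_readouts(gen$ground_truth, "V1v")
  expect_error(fit_linear_ensemble(ors, sp, "sub01", "V1v", n_train = 2L,
                                   seed = 1L),
               class = "visens_sizing_error")
  expect_error(linear_ensemble_model("q", "R", c("a", "b"), 0, c(1, 2, 3)),
               class = "visens_shape_error")
  expect_error(linear_ensemble_model("a", "R", c("a", "b"), 0, c(1, 2),
                                     loo = TRUE),
               class = "visens_invalid_model")
})
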