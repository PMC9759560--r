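test_that("prediction accuracy equals the covariance formula and flags degenerate input", {
  expect_equal(prediction_accuracy(1:10, 1:10), 1)
  expect_equal(prediction_accuracy(1:10, -(1:10)), -1)
  set.seed(1)
  p <- rnorm(10); m <- rnorm(10)
  want <- sum((p - mean(p)) * (m - mean(m))) /
    sqrt(sum((p - mean(p))^2) * sum((m - mean(m))^2))
  expect_equal(prediction_accuracy(p, m), want, tolerance = 1e-12)
  expect_true(is.na(prediction_accuracy(rep(1, 5), rnorm(5))))
  expect_error(prediction_accuracy(1:4, 1:5), class = "visens_shape_error")
  expect_error(prediction_accuracy(1:2, 1:2), class = "visens_sizing_error")
})

test_that("accuracy and ISC are invariant to affine rescaling", {
  set.seed(7)
  for (i in 1:10) {
    p <- rnorm(30); m <- rnorm(30)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(prediction_accuracy(a * p + b, m),
                 prediction_accuracy(p, m), tolerance = 1e-12)
  }
  resp <- list(s1 = rnorm(25), s2 = rnorm(25), s3 = rnorm(25))
  i1 <- isc_matrix(resp, "measurement", "R")
  resp2 <- lapply(resp, function(v) 3 * v - 1)
  i2 <- isc_matrix(resp2, "measurement", "R")
  expect_equal(i1$values, i2$values, tolerance = 1e-12)
})

test_that("ISC matrices are symmetric, definitionally consistent, and handle degenerate subjects", {
  set.seed(3)
  resp <- list(s1 = rnorm(20), s2 = rnorm(20), s3 = rnorm(20))
  im <- isc_matrix(resp, "prediction", "FFA1")
  expect_equal(im$values, t(im$values))
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    expect_equal(im$values[pair[1], pair[2]],
                 prediction_accuracy(resp[[pair[1]]], resp[[pair[2]]]),
                 tolerance = 1e-12)
  }
  expect_length(isc_pairs(im), 3L)
  # identical subjects: all off-diagonals 1
  same <- isc_matrix(list(a = 1:10 + 0, b = 1:10 + 0, c = 1:10 + 0),
                     "prediction")
  expect_true(all(abs(isc_pairs(same) - 1) < 1e-12))
  # a flat subject yields flagged-undefined entries, not zeros
  flat <- isc_matrix(list(a = rnorm(10), b = rep(2, 10)), "measurement")
  expect_true(all(is.na(isc_pairs(flat))))
  expect_error(isc_matrix(list(a = rnorm(5)), "measurement"),
               class = "visens_sizing_error")
  # two independent long vectors decorrelate at the 3/sqrt(n) scale
  set.seed(11)
  n <- 2000L
  iz <- isc_matrix(list(a = rnorm(n), b = rnorm(n)), "measurement")
  expect_lt(abs(isc_pairs(iz)), 3 / sqrt(n))
})

test_that("prediction consistency pools k(k-1)/2 pairs per region with a valid permutation p", {
  set.seed(5)
  resp <- lapply(1:6, function(i) rnorm(30))
  names(resp) <- paste0("s", 1:6)
  im <- isc_matrix(resp, "measurement", "R1")
  # identical ISC vectors: r = 1 and minimal attainable p
  res <- prediction_consistency(im, im, n_permutations = 500L, seed = 1L)
  expect_equal(res$r, 1)
  expect_equal(res$n_pairs, 15L)  # 6 subjects -> (6 x 5)/2 pairs
  expect_equal(res$p_one_tailed, 1 / 501)
  expect_false(res$undefined)
  # Bonferroni multiplies and caps at 1
  res2 <- prediction_consistency(im, im, n_permutations = 500L, seed = 1L,
                                 n_comparisons = 4L)
  expect_equal(res2$corrected_p, 4 / 501)
  res3 <- prediction_consistency(im, im, n_permutations = 1L, seed = 1L,
                                 n_comparisons = 10L)
  expect_equal(res3$corrected_p, 1)
  # two regions pool 30 points
  im2 <- isc_matrix(lapply(resp, function(v) v + rnorm(30)), "measurement", "R2")
  res4 <- prediction_consistency(list(im, im2), list(im2, im),
                                 n_permutations = 0L)
  expect_equal(res4$n_pairs, 30L)
  # zero-variance ISC vector flags undefined, never silently 0
  ones <- isc_matrix(stats::setNames(rep(list(1:30 + 0), 6), paste0("s", 1:6)),
                     "prediction")
  res5 <- prediction_consistency(ones, im, n_permutations = 100L, seed = 1L)
  expect_true(res5$undefined)
  expect_true(is.na(res5$r))
  # per-region mode returns one result per region
  res6 <- prediction_consistency(list(im, im2), list(im, im2),
                                 n_permutations = 0L, pool = "per_region")
  expect_length(res6, 2L)
  expect_equal(res6[[1]]$n_pairs, 15L)
})

test_that("noise ceilings behave on degenerate and independent cohorts", {
  # all subjects identical and noiseless: across-subject NC = 1
  gen <- generate_cohort(tiny_config(n_subjects = 4L, n_stimuli = 40L,
                                     idiosyncratic_signal_sd = 0,
                                     noise_sd = 0, seed = 2L))
  sp <- build_split(gen$cohort, n_val = 5L, n_test = 10L, seed = 2L)
  nc <- across_subject_nc(sp, "sub01", "V1v")
  expect_equal(nc$value, 1, tolerance = 1e-12)
  expect_identical(nc$kind, "across_subject")
  # within-subject NC on noiseless repeats = 1 for both styles
  wn <- within_subject_nc(gen$cohort, "sub01", "V1v", sp$test_ids, "neurogen")
  expect_equal(wn$value, 1, tolerance = 1e-12)
  gen3 <- generate_cohort(tiny_config(n_stimuli = 30L, repeats = 3L,
                                      noise_sd = 0, seed = 3L))
  w3 <- within_subject_nc(gen3$cohort, "sub01", "V1v",
                          gen3$cohort$stimuli$info$stimulus_id, "nsd")
  expect_equal(w3$value, 1, tolerance = 1e-12)
  # nsd style demands 3 repeats and lists deficient stimuli
  expect_error(within_subject_nc(gen$cohort, "sub01", "V1v", sp$test_ids, "nsd"),
               class = "visens_sizing_error")
  # an idiosyncratic-only subject decorrelates from the others' average;
  # with fixed linear readouts the null ISC concentrates at the cosine of
  # independent d-dimensional readouts, so the bound combines readout
  # (1/sqrt(d)) and stimulus-sampling (1/sqrt(n)) scales
  genz <- generate_cohort(synthetic_config(n_subjects = 6L, n_regions = 1L,
                                           n_stimuli = 1500L,
                                           n_shared_stimuli = 1500L,
                                           feature_dim = 2000L,
                                           shared_signal_sd = 0,
                                           idiosyncratic_signal_sd = 1,
                                           noise_sd = 0, repeats = 2L,
                                           seed = 19L))
  spz <- build_split(genz$cohort, n_val = 10L, n_test = 1000L, seed = 19L)
  ncz <- across_subject_nc(spz, "sub01", "V1v")
  expect_lt(abs(ncz$value), 4 * sqrt(1 / 2000 + 1 / 1000))
})

test_that("Wilcoxon signed-rank matches exhaustive sign-flip enumeration for n = 8", {
  # brute-force oracle: enumerate all 2^8 sign assignments of the ranked
  # absolute differences
  exact_signed_rank <- function(d) {
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    v_all <- signs %*% r
    p_ge <- mean(v_all >= v_obs)
    p_le <- mean(v_all <= v_obs)
    min(1, 2 * min(p_ge, p_le))
  }
  set.seed(12)
  for (k in 1:5) {
    a <- rnorm(8)
    b <- rnorm(8)
    got <- compare_to_reference_wilcoxon(a, b)
    expect_true(got$exact)
    expect_equal(got$p, exact_signed_rank(a - b), tolerance = 1e-12)
  }
  # all-positive shifts: the minimal attainable two-tailed exact p = 2/2^8
  a <- 1:8 + 0
  b <- a - seq(0.1, 0.8, by = 0.1)
  got <- compare_to_reference_wilcoxon(a, b)
  expect_equal(got$p, 2 / 256, tolerance = 1e-12)
  # identical vectors are degenerate
  expect_true(compare_to_reference_wilcoxon(a, a)$degenerate)
  expect_error(compare_to_reference_wilcoxon(1:3, 1:3),
               class = "visens_sizing_error")
})

test_that("Friedman statistic matches the rank formula and BH matches the step-up procedure", {
  # dominant-model toy: statistic from 12n/(k(k+1)) * sum (Rbar_j - (k+1)/2)^2
  set.seed(8)
  n <- 8L; k <- 3L
  acc <- matrix(rnorm(n * k, sd = 0.05), n, k)
  acc[, 1] <- acc[, 1] + 1  # model 1 uniformly dominant
  colnames(acc) <- c("winner", "m2", "m3")
  res <- compare_models_friedman_fdr(acc)
  ranks <- t(apply(acc, 1L, rank))
  rbar <- colMeans(ranks)
  want <- 12 * n / (k * (k + 1)) * sum((rbar - (k + 1) / 2)^2)
  expect_equal(res$statistic, want, tolerance = 1e-12)
  expect_true(is.matrix(res$pairwise) && isSymmetric(res$pairwise))
  # identical models: statistic 0 under midranks
  same <- matrix(rep(rnorm(n), k), n, k)
  expect_equal(compare_models_friedman_fdr(same)$statistic, 0)
  # BH step-up on a hand-worked vector
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), method = "BH"),
               rep(0.04, 4))
  p <- c(0.005, 0.009, 0.05, 0.2, 0.9)
  m <- length(p)
  manual <- rev(cummin(rev(pmin(1, p * m / seq_len(m)))))
  expect_equal(p.adjust(p, method = "BH"), manual, tolerance = 1e-12)
  expect_error(compare_models_friedman_fdr(acc[, 1:2]),
               class = "visens_sizing_error")
})

test_that("Welch's t reports two-tailed p with unequal variances", {
  set.seed(4)
  x <- rnorm(10); y <- rnorm(12, sd = 3)
  got <- welch_t(x, y)
  s2x <- var(x) / 10; s2y <- var(y) / 12
  t_manual <- (mean(x) - mean(y)) / sqrt(s2x + s2y)
  expect_equal(got$statistic, t_manual, tolerance = 1e-12)
  df_manual <- (s2x + s2y)^2 / (s2x^2 / 9 + s2y^2 / 11)
  expect_equal(got$df, df_manual, tolerance = 1e-12)
  expect_equal(got$p, 2 * pt(-abs(t_manual), df_manual), tolerance = 1e-12)
})
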