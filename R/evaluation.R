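# Model evaluation: prediction accuracy, inter-subject correlation (ISC),
# prediction consistency with permutation inference, noise ceilings, and
# classical model-comparison statistics.
#
# Accuracy is the Pearson correlation between predicted and measured
# responses over the shared test stimuli. Consistency asks whether a
# model's predictions preserve the *pattern* of inter-individual
# differences: the pairwise ISC of predictions is correlated against the
# pairwise ISC of measurements, pooling the upper triangles across
# regions, with a one-tailed permutation p-value (Bonferroni corrected
# across the model panel by the caller-supplied comparison count).
# Undefined correlations (zero-variance inputs) are flagged, never
# silently reported as 0.

#' Prediction accuracy: Pearson r between predicted and measured responses
#'
#' @param predicted,measured numeric vectors of equal length >= 3 over the
#'   test stimuli.
#' @return Pearson correlation, or `NA` (flagged undefined) when either
#'   vector has zero variance; `NA` values are excluded from aggregates by
#'   the reporting helpers.
#' @export
prediction_accuracy <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    visens_stop("visens_shape_error", "predicted (%d) and measured (%d) differ in length",
                length(predicted), length(measured))
  }
  if (length(predicted) < 3L) {
    visens_stop("visens_sizing_error", "need >= 3 paired values, got %d",
                length(predicted))
  }
  if (!all(is.finite(predicted)) || !all(is.finite(measured))) {
    visens_stop("visens_invalid_responses", "non-finite values in accuracy input")
  }
  if (stats::sd(predicted) == 0 || stats::sd(measured) == 0) return(NA_real_)
  stats::cor(predicted, measured)
}

#' Pairwise inter-subject correlation matrix
#'
#' @param responses named list `subject_id -> numeric vector`, all aligned
#'   to the same shared test stimuli, or a stimuli x subjects matrix.
#' @param source `"measurement"` or `"prediction"`.
#' @param region_id region identifier carried along for pooling.
#' @return object of class `isc_matrix`: symmetric `values` matrix of
#'   pairwise Pearson correlations (diagonal `NA`, unused), `subject_ids`,
#'   `source`, `region_id`.
#' @export
isc_matrix <- function(responses, source = c("measurement", "prediction"),
                       region_id = NA_character_) {
  source <- match.arg(source)
  m <- if (is.matrix(responses)) responses else do.call(cbind, responses)
  if (ncol(m) < 2L) {
    visens_stop("visens_sizing_error", "ISC needs >= 2 subjects, got %d", ncol(m))
  }
  sds <- apply(m, 2L, stats::sd)
  values <- suppressWarnings(stats::cor(m))
  values[, sds == 0] <- NA_real_
  values[sds == 0, ] <- NA_real_
  diag(values) <- NA_real_
  structure(list(values = values, subject_ids = colnames(m),
                 source = source, region_id = region_id),
            class = "isc_matrix")
}

#' @export
print.isc_matrix <- function(x, ...) {
  off <- isc_pairs(x)
  cat(sprintf("<isc_matrix> %s, region %s, %d subjects, %d pairs, mean ISC %.3f\n",
              x$source, x$region_id, length(x$subject_ids), length(off),
              mean(off, na.rm = TRUE)))
  invisible(x)
}

#' Upper-triangle ISC values of an ISC matrix
#'
#' For k subjects this is the k(k-1)/2 unordered pairs.
#'
#' @param isc an [isc_matrix()].
#' @return numeric vector of pairwise ISC values.
#' @export
isc_pairs <- function(isc) {
  stopifnot(inherits(isc, "isc_matrix"))
  isc$values[upper.tri(isc$values)]
}

#' Prediction consistency with permutation inference
#'
#' Correlates the pooled upper triangles of per-region ISC-prediction
#' matrices against the matching ISC-measurement values (the number of
#' points is regions x k(k-1)/2 subject pairs). The one-tailed p-value
#' permutes the ISC-measurement vector against the fixed ISC-prediction
#' vector, with the add-one estimator
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_permutations)`, and is then
#' Bonferroni multiplied by `n_comparisons` (capped at 1).
#'
#' A nearly constant ISC vector cannot encode inter-individual
#' differences, so if either pooled ISC vector has spread below
#' `degenerate_tol` — as for the average ensemble, whose leave-one-out
#' ISC-predictions are all 1 or near 1 — the correlation is reported as
#' undefined (flagged), never silently as a number.
#'
#' @param isc_pred,isc_meas an [isc_matrix()] or list of them (one per
#'   region), with matching subject sets and region order.
#' @param n_permutations number of permutations (default 10,000);
#'   0 skips inference and returns only `r`.
#' @param seed permutation seed.
#' @param n_comparisons Bonferroni multiplier supplied by the caller (the
#'   size of the model panel being tested).
#' @param pool `"regions"` pools all regions into one correlation
#'   (default); `"per_region"` returns one result per region.
#' @param degenerate_tol standard-deviation threshold (on the correlation
#'   scale) below which a pooled ISC vector is treated as constant and the
#'   consistency flagged undefined. The default 0.002 sits an order of
#'   magnitude above the spread produced by leave-one-out average
#'   ensembles and an order of magnitude below that of models that retain
#'   subject-specific structure.
#' @return object of class `consistency_result`: `r`, `p_one_tailed`,
#'   `corrected_p`, `n_pairs`, `n_permutations`, `undefined` flag; or a
#'   list of such objects for `pool = "per_region"`.
#' @export
prediction_consistency <- function(isc_pred, isc_meas, n_permutations = 10000L,
                                   seed = 1L, n_comparisons = 1L,
                                   pool = c("regions", "per_region"),
                                   degenerate_tol = 0.002) {
  pool <- match.arg(pool)
  if (inherits(isc_pred, "isc_matrix")) isc_pred <- list(isc_pred)
  if (inherits(isc_meas, "isc_matrix")) isc_meas <- list(isc_meas)
  if (length(isc_pred) != length(isc_meas)) {
    visens_stop("visens_shape_error",
                "mismatched number of regions: %d prediction vs %d measurement",
                length(isc_pred), length(isc_meas))
  }
  for (i in seq_along(isc_pred)) {
    if (!identical(isc_pred[[i]]$subject_ids, isc_meas[[i]]$subject_ids)) {
      visens_stop("visens_shape_error", "mismatched subject sets in region %d", i)
    }
  }
  if (pool == "per_region") {
    return(lapply(seq_along(isc_pred), function(i) {
      prediction_consistency(isc_pred[[i]], isc_meas[[i]],
                             n_permutations = n_permutations, seed = seed,
                             n_comparisons = n_comparisons,
                             degenerate_tol = degenerate_tol)
    }))
  }
  x <- unlist(lapply(isc_pred, isc_pairs))
  y <- unlist(lapply(isc_meas, isc_pairs))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n_pairs <- length(x)
  undefined <- n_pairs < 3L || stats::sd(x) < degenerate_tol ||
    stats::sd(y) < degenerate_tol
  if (undefined) {
    return(structure(list(r = NA_real_, p_one_tailed = NA_real_,
                          corrected_p = NA_real_, n_pairs = n_pairs,
                          n_permutations = as.integer(n_permutations),
                          undefined = TRUE),
                     class = "consistency_result"))
  }
  r_obs <- stats::cor(x, y)
  p <- NA_real_
  if (n_permutations > 0L) {
    perms <- with_stream(seed, "consistency_perm", {
      vapply(seq_len(n_permutations), function(i) y[sample.int(n_pairs)],
             numeric(n_pairs))
    })
    r_perm <- drop(stats::cor(x, perms))
    p <- (1 + sum(r_perm >= r_obs)) / (1 + n_permutations)
  }
  structure(list(r = r_obs, p_one_tailed = p,
                 corrected_p = if (is.na(p)) NA_real_ else min(1, p * n_comparisons),
                 n_pairs = n_pairs,
                 n_permutations = as.integer(n_permutations),
                 undefined = FALSE),
            class = "consistency_result")
}

#' @export
print.consistency_result <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("<consistency_result> undefined (zero-variance ISC), %d pairs\n",
                x$n_pairs))
  } else {
    cat(sprintf("<consistency_result> r = %.4f, one-tailed p = %.4g (corrected %.4g), %d pairs, %d permutations\n",
                x$r, x$p_one_tailed, x$corrected_p, x$n_pairs, x$n_permutations))
  }
  invisible(x)
}

# ---- noise ceilings -------------------------------------------------------

noise_ceiling <- function(subject_id, region_id, kind, value) {
  structure(list(subject_id = subject_id, region_id = region_id,
                 kind = kind, value = value),
            class = "noise_ceiling")
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat(sprintf("<noise_ceiling> %s, subject %s, region %s: %.4f\n",
              x$kind, x$subject_id, x$region_id, x$value))
  invisible(x)
}

#' Across-subject noise ceiling
#'
#' Pearson correlation between a subject's repeat-averaged test responses
#' and the average of the other subjects' test responses over the shared
#' test stimuli.
#'
#' @param split a [build_split()] result.
#' @param subject_id,region_id the cell.
#' @return a `noise_ceiling` with `kind = "across_subject"`.
#' @export
across_subject_nc <- function(split, subject_id, region_id) {
  te <- test_data(split, region_id)
  subjects <- colnames(te$y)
  if (length(subjects) < 2L) {
    visens_stop("visens_sizing_error", "across-subject NC needs >= 2 subjects")
  }
  if (!subject_id %in% subjects) {
    visens_stop("visens_sizing_error", "subject %s has no test responses", subject_id)
  }
  own <- te$y[, subject_id]
  others <- rowMeans(te$y[, setdiff(subjects, subject_id), drop = FALSE])
  noise_ceiling(subject_id, region_id, "across_subject", stats::cor(own, others))
}

#' Within-subject noise ceiling
#'
#' For `style = "nsd"` (3 repeats available): the Pearson correlation
#' between the average of two measured responses and the third, per test
#' stimulus; the two lowest repeat indices are averaged and correlated
#' with the highest. For `style = "neurogen"` (2 repeats): the correlation
#' between the two measured responses.
#'
#' @param cohort a [cohort()]; raw single-trial records are used.
#' @param subject_id,region_id the cell.
#' @param test_ids stimulus ids of the test set.
#' @param style `"nsd"` or `"neurogen"`.
#' @return a `noise_ceiling` with `kind = "within_subject_<style>"`.
#' @export
within_subject_nc <- function(cohort, subject_id, region_id, test_ids,
                              style = c("nsd", "neurogen")) {
  style <- match.arg(style)
  need <- if (style == "nsd") 3L else 2L
  r <- cohort$responses
  r <- r[r$subject_id == subject_id & r$region_id == region_id &
           r$stimulus_id %in% test_ids, , drop = FALSE]
  r <- r[order(r$stimulus_id, r$repeat_index), , drop = FALSE]
  counts <- table(r$stimulus_id)
  deficient <- setdiff(test_ids, names(counts)[counts >= need])
  if (length(deficient)) {
    visens_stop("visens_sizing_error",
                "within-subject NC (%s) needs %d repeats; deficient stimuli: %s",
                style, need, paste(utils::head(deficient, 10L), collapse = ", "))
  }
  by_stim <- split(r$response, r$stimulus_id)
  a <- vapply(by_stim, function(v) if (style == "nsd") mean(v[1:2]) else v[1L],
              numeric(1L))
  b <- vapply(by_stim, function(v) if (style == "nsd") v[3L] else v[2L],
              numeric(1L))
  noise_ceiling(subject_id, region_id, paste0("within_subject_", style),
                stats::cor(a, b))
}

# ---- classical model-comparison statistics --------------------------------

#' Wilcoxon matched-pairs signed-rank test against a reference model
#'
#' Two-tailed; the exact signed-rank distribution is used for n <= 25 when
#' there are no zero or tied differences (at the small subject counts of
#' densely-sampled cohorts the exact distribution is the appropriate one).
#'
#' @param accuracies_model,accuracies_reference paired per-subject accuracy
#'   vectors, length >= 5.
#' @return list with `statistic` (V), `p`, `degenerate` (all differences
#'   zero) and `exact` (whether the exact distribution was used).
#' @export
compare_to_reference_wilcoxon <- function(accuracies_model, accuracies_reference) {
  if (length(accuracies_model) != length(accuracies_reference)) {
    visens_stop("visens_shape_error", "paired vectors differ in length")
  }
  if (length(accuracies_model) < 5L) {
    visens_stop("visens_sizing_error", "need >= 5 pairs, got %d",
                length(accuracies_model))
  }
  d <- accuracies_model - accuracies_reference
  if (all(d == 0)) {
    return(list(statistic = NA_real_, p = NA_real_, degenerate = TRUE,
                exact = NA))
  }
  dn <- d[d != 0]
  exact_ok <- length(dn) <= 25L && !any(duplicated(abs(dn))) && all(d != 0)
  res <- suppressWarnings(stats::wilcox.test(
    accuracies_model, accuracies_reference, paired = TRUE,
    exact = exact_ok, correct = !exact_ok))
  list(statistic = unname(res$statistic), p = res$p.value,
       degenerate = FALSE, exact = exact_ok)
}

#' Friedman test across models with Benjamini-Hochberg post hoc
#'
#' Friedman chi-square on within-subject ranks of the accuracy matrix,
#' followed by pairwise Wilcoxon signed-rank tests between all model
#' columns, Benjamini-Hochberg adjusted.
#'
#' @param accuracies numeric matrix, subjects x models (>= 5 subjects,
#'   >= 3 models), column names = model names.
#' @return list with `statistic`, `df`, `p` and `pairwise` (symmetric
#'   matrix of BH-adjusted two-tailed signed-rank p-values).
#' @export
compare_models_friedman_fdr <- function(accuracies) {
  accuracies <- as.matrix(accuracies)
  if (ncol(accuracies) < 3L) {
    visens_stop("visens_sizing_error", "need >= 3 models, got %d", ncol(accuracies))
  }
  if (nrow(accuracies) < 5L) {
    visens_stop("visens_sizing_error", "need >= 5 subjects, got %d", nrow(accuracies))
  }
  if (is.null(colnames(accuracies))) {
    colnames(accuracies) <- paste0("model", seq_len(ncol(accuracies)))
  }
  fr <- stats::friedman.test(accuracies)
  statistic <- unname(fr$statistic)
  p_global <- fr$p.value
  if (is.nan(statistic)) {
    # fully tied ranks: the tie-corrected statistic is 0/0; report the
    # uncorrected value 0 (no evidence of any difference)
    statistic <- 0
    p_global <- 1
  }
  k <- ncol(accuracies)
  pair_idx <- utils::combn(k, 2L)
  raw <- apply(pair_idx, 2L, function(ij) {
    d <- accuracies[, ij[1L]] - accuracies[, ij[2L]]
    if (all(d == 0)) return(1)
    suppressWarnings(stats::wilcox.test(accuracies[, ij[1L]], accuracies[, ij[2L]],
                                        paired = TRUE, exact = FALSE,
                                        correct = TRUE)$p.value)
  })
  adj <- stats::p.adjust(raw, method = "BH")
  pairwise <- matrix(NA_real_, k, k,
                     dimnames = list(colnames(accuracies), colnames(accuracies)))
  for (c2 in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1L, c2]; j <- pair_idx[2L, c2]
    pairwise[i, j] <- pairwise[j, i] <- adj[c2]
  }
  list(statistic = statistic, df = unname(fr$parameter),
       p = p_global, pairwise = pairwise)
}

#' Welch's unequal-variance two-sample t test
#'
#' Generic utility used, e.g., to compare responses to animal-face vs
#' human-face stimuli, or accuracies on natural vs synthetic stimuli.
#'
#' @param x,y numeric samples (length >= 2 each).
#' @return list with `statistic` (t), `df` and `p` (two-tailed).
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    visens_stop("visens_sizing_error", "Welch t needs >= 2 values per group")
  }
  res <- stats::t.test(x, y, var.equal = FALSE)
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}
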