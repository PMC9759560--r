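# Linear and average ensembles over reference subjects' encoding models.
#
# The linear ensemble predicts a query subject i's response to stimulus S
# as
#
#   LE_i(S) = beta_{i,0} + sum_{j in N_-i} beta_{i,j} * r_hat_j(S)
#
# where r_hat_j(S) is reference subject j's readout prediction and the
# coefficients are fitted by ordinary least squares against the query's
# single-trial measured responses on a seeded random sample of training
# entries (number equal to the train size). In-cohort, ensembles are
# built leave-one-out: subject i's own readout is never among its
# references. Out-of-cohort (a query subject absent from the reference
# cohort) simply passes all reference readouts. The average ensemble is
# the unweighted mean of the reference predictions and needs no data from
# the query subject.

# Minimum-norm least squares via SVD. Returns coefficients, rank, and
# whether the design was rank deficient (singular values below
# tol * largest dropped).
lstsq_min_norm <- function(x, y, tol = 1e-10) {
  s <- svd(x)
  keep <- s$d > tol * s$d[1L]
  beta <- s$v[, keep, drop = FALSE] %*%
    (crossprod(s$u[, keep, drop = FALSE], y) / s$d[keep])
  list(beta = drop(beta), rank = sum(keep),
       deficient = sum(keep) < min(dim(x)))
}

#' Construct a linear ensemble model
#'
#' @param query_subject,region_id identifiers.
#' @param reference_subjects ordered character vector of reference subject
#'   ids (the index set excluding the query in leave-one-out use).
#' @param intercept numeric scalar.
#' @param coefficients numeric vector, one per reference subject.
#' @param n_train_used number of single-trial samples the OLS fit used.
#' @param loo logical: was the model built leave-one-out (query excluded
#'   from references)?
#' @return object of class `linear_ensemble_model`.
#' @export
linear_ensemble_model <- function(query_subject, region_id, reference_subjects,
                                  intercept, coefficients, n_train_used = 0L,
                                  loo = TRUE) {
  reference_subjects <- as.character(reference_subjects)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != length(reference_subjects)) {
    visens_stop("visens_shape_error",
                "got %d coefficients for %d reference subjects",
                length(coefficients), length(reference_subjects))
  }
  if (loo && query_subject %in% reference_subjects) {
    visens_stop("visens_invalid_model",
                "leave-one-out ensemble for %s contains itself as reference",
                query_subject)
  }
  structure(list(query_subject = as.character(query_subject),
                 region_id = as.character(region_id),
                 reference_subjects = reference_subjects,
                 intercept = as.numeric(intercept),
                 coefficients = stats::setNames(coefficients, reference_subjects),
                 n_train_used = as.integer(n_train_used),
                 loo = isTRUE(loo)),
            class = "linear_ensemble_model")
}

#' @export
print.linear_ensemble_model <- function(x, ...) {
  cat(sprintf("<linear_ensemble_model> query %s, region %s, %d references, n_train = %d\n",
              x$query_subject, x$region_id, length(x$reference_subjects),
              x$n_train_used))
  invisible(x)
}

#' Construct an average ensemble model
#'
#' Predicts the unweighted mean of the reference readouts' predictions;
#' requires no data from the query subject (train size 0 semantics).
#'
#' @inheritParams linear_ensemble_model
#' @return object of class `average_ensemble_model`.
#' @export
average_ensemble_model <- function(query_subject, region_id, reference_subjects) {
  reference_subjects <- as.character(reference_subjects)
  if (!length(reference_subjects)) {
    visens_stop("visens_invalid_model", "average ensemble needs >= 1 reference subject")
  }
  structure(list(query_subject = as.character(query_subject),
                 region_id = as.character(region_id),
                 reference_subjects = reference_subjects),
            class = "average_ensemble_model")
}

# Reference predictions as a stimuli x references matrix; errors name any
# reference subject without a readout for the region.
reference_prediction_matrix <- function(reference_subjects, region_id,
                                        reference_readouts, stimuli) {
  by_subject <- stats::setNames(reference_readouts, vapply(
    reference_readouts, `[[`, character(1L), "subject_id"))
  missing_refs <- setdiff(reference_subjects, names(by_subject))
  if (length(missing_refs)) {
    visens_stop("visens_missing_reference",
                "no readout supplied for reference subject(s): %s",
                paste(missing_refs, collapse = ", "))
  }
  x <- if (inherits(stimuli, "stimulus_set")) stimuli$features else as.matrix(stimuli)
  preds <- vapply(reference_subjects,
                  function(s) predict(by_subject[[s]], x),
                  numeric(nrow(x)))
  matrix(preds, nrow = nrow(x),
         dimnames = list(rownames(x), reference_subjects))
}

#' Fit a linear ensemble by ordinary least squares
#'
#' Builds the design matrix of reference readout predictions on a seeded
#' random sample of the query subject's single-trial training entries and
#' solves for intercept plus per-reference coefficients by OLS. A
#' rank-deficient design (e.g. duplicated or constant reference
#' predictors) is solved by the minimum-norm solution with a warning
#' rather than an error.
#'
#' @param reference_readouts list of [readout_model()] covering the
#'   reference subjects for this region.
#' @param split a [build_split()] result.
#' @param query_subject,region_id the query cell.
#' @param n_train number of single-trial training samples for the OLS fit;
#'   must be at least the number of references + 1.
#' @param seed seed for the training-sample draw.
#' @param loo logical: leave-one-out mode (default `TRUE`); when `TRUE` a
#'   readout belonging to the query subject is dropped from the reference
#'   list; when `FALSE` (out-of-cohort query) all readouts are used.
#' @return a [linear_ensemble_model()]; attribute `"training_rows"` holds
#'   the sampled (subject, stimulus, repeat) keys so the fit can be
#'   reproduced externally.
#' @export
fit_linear_ensemble <- function(reference_readouts, split, query_subject,
                                region_id, n_train, seed = 1L, loo = TRUE) {
  refs <- vapply(reference_readouts, `[[`, character(1L), "subject_id")
  if (loo) {
    keep <- refs != query_subject
    reference_readouts <- reference_readouts[keep]
    refs <- refs[keep]
  }
  if (!length(refs)) {
    visens_stop("visens_invalid_model", "no reference readouts for query %s",
                query_subject)
  }
  if (n_train < length(refs) + 1L) {
    visens_stop("visens_sizing_error",
                "n_train = %d is below the %d references + 1 needed for OLS",
                n_train, length(refs))
  }
  tr <- train_data(split, query_subject, region_id, n_train = n_train,
                   seed = seed)
  design <- reference_prediction_matrix(refs, region_id, reference_readouts,
                                        tr$x)
  fit <- lstsq_min_norm(cbind(`(Intercept)` = 1, design), tr$y)
  if (fit$deficient) {
    warning(sprintf(
      "rank-deficient ensemble design for %s/%s (rank %d of %d); minimum-norm solution used",
      query_subject, region_id, fit$rank, length(refs) + 1L))
  }
  model <- linear_ensemble_model(query_subject, region_id, refs,
                                 intercept = fit$beta[1L],
                                 coefficients = fit$beta[-1L],
                                 n_train_used = nrow(tr$x), loo = loo)
  attr(model, "training_rows") <- tr$rows
  model
}

#' Predict from a linear ensemble model
#'
#' @param object a [linear_ensemble_model()].
#' @param reference_readouts list of [readout_model()] covering all
#'   reference subjects for the region.
#' @param stimuli a [stimulus_set()] or feature matrix.
#' @param ... unused.
#' @return numeric vector of ensemble predictions, in stimulus order.
#' @export
predict.linear_ensemble_model <- function(object, reference_readouts, stimuli, ...) {
  p <- reference_prediction_matrix(object$reference_subjects, object$region_id,
                                   reference_readouts, stimuli)
  drop(object$intercept + p %*% object$coefficients)
}

#' Predict from an average ensemble model
#'
#' @inheritParams predict.linear_ensemble_model
#' @param object an [average_ensemble_model()].
#' @return numeric vector: unweighted mean of reference predictions.
#' @export
predict.average_ensemble_model <- function(object, reference_readouts, stimuli, ...) {
  p <- reference_prediction_matrix(object$reference_subjects, object$region_id,
                                   reference_readouts, stimuli)
  rowMeans(p)
}

#' Predict from a linear or average ensemble model
#'
#' Thin dispatcher over the ensemble `predict` methods.
#'
#' @param model a [linear_ensemble_model()] or [average_ensemble_model()].
#' @inheritParams predict.linear_ensemble_model
#' @return numeric vector of predictions.
#' @export
predict_ensemble <- function(model, reference_readouts, stimuli) {
  predict(model, reference_readouts, stimuli)
}

#' Build leave-one-out linear ensembles for every subject
#'
#' For each subject with a readout, fits a linear ensemble whose references
#' are all the other subjects' readouts.
#'
#' @param cohort_readouts named list `subject_id -> readout_model` for one
#'   region (the desk-scale analogue of densely-trained per-subject
#'   models).
#' @param split a [build_split()] result.
#' @param region_id region.
#' @param n_train OLS training-sample size per query subject.
#' @param seed base seed; each query uses its own derived stream.
#' @return named list `subject_id -> linear_ensemble_model`.
#' @export
build_loo_ensembles <- function(cohort_readouts, split, region_id, n_train,
                                seed = 1L) {
  subjects <- vapply(cohort_readouts, `[[`, character(1L), "subject_id")
  if (length(subjects) < 2L) {
    visens_stop("visens_sizing_error",
                "leave-one-out ensembles need >= 2 subjects, got %d",
                length(subjects))
  }
  out <- lapply(subjects, function(s) {
    fit_linear_ensemble(cohort_readouts, split, s, region_id, n_train,
                        seed = stream_seed(seed, paste0("loo_", s)), loo = TRUE)
  })
  stats::setNames(out, subjects)
}

#' Save ensemble coefficients to a delimited table
#'
#' One row per model: query_subject, region_id, n_train_used, intercept,
#' then one `b_<reference subject>` column per reference in order.
#'
#' @param models list of [linear_ensemble_model()] sharing one reference
#'   ordering (within rows, missing references are `NA`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
save_ensembles <- function(models, path) {
  all_refs <- unique(unlist(lapply(models, `[[`, "reference_subjects")))
  rows <- lapply(models, function(m) {
    co <- stats::setNames(rep(NA_real_, length(all_refs)), all_refs)
    co[m$reference_subjects] <- m$coefficients
    c(list(query_subject = m$query_subject, region_id = m$region_id,
           n_train_used = m$n_train_used, intercept = m$intercept),
      as.list(co))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  names(df)[-(1:4)] <- paste0("b_", all_refs)
  df <- df[order(df$query_subject, df$region_id), , drop = FALSE]
  write_table_precise(df, path)
  invisible(path)
}
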