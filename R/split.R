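# Train / validation / test construction.
#
# Training points are always single trials: no responses to the same
# stimulus are averaged. Validation and test responses are the mean of
# exactly two repeats; when a stimulus was seen three times, two of the
# three trials are chosen at random (seeded), which keeps the
# signal-to-noise properties of the averaged responses consistent across
# stimuli and subjects. Test stimuli are drawn from the shared set and are
# identical across subjects.

#' Build a train/validation/test split of a cohort
#'
#' @param cohort a [cohort()].
#' @param n_train per-subject number of single-trial training entries to
#'   retain, or `NULL` to keep the whole training pool (model-fitting
#'   functions can subsample further).
#' @param n_val per-subject number of validation stimuli (repeat-averaged).
#' @param n_test number of test stimuli, shared across subjects
#'   (repeat-averaged).
#' @param seed integer seed; selection of stimuli, of training entries and
#'   of repeat pairs each use their own named RNG stream derived from it.
#' @return an object of class `dataset_split` with elements `train`
#'   (data.frame subject_id, stimulus_id, repeat_index), `validation` and
#'   `test` (data.frames subject_id, region_id, stimulus_id, response),
#'   `test_ids`, the originating `cohort` and the `seed`.
#' @export
build_split <- function(cohort, n_train = NULL, n_val = 50L, n_test = 100L,
                        seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  r <- data.table::as.data.table(cohort$responses)
  # presentations are region-independent: collapse regions first
  pres <- unique(r[, c("subject_id", "stimulus_id", "repeat_index")])
  counts <- pres[, list(n_rep = .N), by = c("subject_id", "stimulus_id")]
  shared_ids <- cohort$stimuli$info$stimulus_id[cohort$stimuli$info$shared]
  n_subj <- length(cohort$subject_ids)

  # test: shared stimuli with >= 2 repeats for every subject
  cnt_shared <- counts[counts$stimulus_id %in% shared_ids & counts$n_rep >= 2L, ]
  per_stim <- cnt_shared[, list(n_ok = .N), by = "stimulus_id"]
  eligible_test <- sort(per_stim$stimulus_id[per_stim$n_ok == n_subj])
  if (length(eligible_test) < n_test) {
    visens_stop("visens_sizing_error",
                "n_test = %d but only %d shared stimuli have >= 2 repeats for all subjects",
                n_test, length(eligible_test))
  }
  test_ids <- with_stream(seed, "split_test",
                          sort(sample(eligible_test, n_test)))

  # validation: per subject, stimuli with >= 2 repeats, disjoint from test
  val_list <- vector("list", n_subj)
  names(val_list) <- cohort$subject_ids
  with_stream(seed, "split_val", {
    for (s in cohort$subject_ids) {
      elig <- sort(setdiff(
        counts$stimulus_id[counts$subject_id == s & counts$n_rep >= 2L],
        test_ids))
      if (length(elig) < n_val) {
        visens_stop("visens_sizing_error",
                    "n_val = %d but subject %s has only %d eligible stimuli (>= 2 repeats, outside test)",
                    n_val, s, length(elig))
      }
      val_list[[s]] <- sort(sample(elig, n_val))
    }
  })

  # choose the averaged repeat pair per (subject, stimulus); 2 repeats ->
  # both, 3 repeats -> a seeded random 2 of the 3
  avg_keys <- data.table::rbindlist(c(
    lapply(cohort$subject_ids, function(s) {
      data.table::data.table(subject_id = s, stimulus_id = test_ids, role = "test")
    }),
    lapply(cohort$subject_ids, function(s) {
      data.table::data.table(subject_id = s, stimulus_id = val_list[[s]], role = "validation")
    })
  ))
  cand <- merge(pres, avg_keys, by = c("subject_id", "stimulus_id"))
  data.table::setorderv(cand, c("role", "subject_id", "stimulus_id", "repeat_index"))
  chosen <- with_stream(seed, "split_pairs", {
    cand[, list(repeat_index = {
      n <- length(repeat_index)
      if (n < 2L) {
        visens_stop("visens_sizing_error",
                    "stimulus selected for averaging has fewer than 2 repeats")
      }
      if (n == 2L) repeat_index else sort(sample(repeat_index, 2L))
    }), by = c("role", "subject_id", "stimulus_id")]
  })
  merged <- merge(r, chosen, by = c("subject_id", "stimulus_id", "repeat_index"))
  avg <- merged[, list(response = mean(response), n_used = .N),
                by = c("role", "subject_id", "region_id", "stimulus_id")]
  if (any(avg$n_used != 2L)) {
    visens_stop("visens_sizing_error",
                "internal averaging error: expected exactly 2 repeats per averaged stimulus")
  }
  avg$n_used <- NULL
  data.table::setorderv(avg, c("role", "subject_id", "region_id", "stimulus_id"))
  validation <- as.data.frame(avg[avg$role == "validation", -"role"])
  test <- as.data.frame(avg[avg$role == "test", -"role"])

  # training pool: single trials of stimuli outside this subject's val and
  # the shared test set
  held <- data.table::rbindlist(lapply(cohort$subject_ids, function(s) {
    data.table::data.table(subject_id = s,
                           stimulus_id = c(test_ids, val_list[[s]]))
  }))
  train_pool <- pres[!held, on = c("subject_id", "stimulus_id")]
  data.table::setorderv(train_pool, c("subject_id", "stimulus_id", "repeat_index"))
  if (!is.null(n_train)) {
    with_stream(seed, "split_train", {
      train_pool <- data.table::rbindlist(lapply(cohort$subject_ids, function(s) {
        rows <- train_pool[train_pool$subject_id == s, ]
        if (nrow(rows) < n_train) {
          visens_stop("visens_sizing_error",
                      "n_train = %d but subject %s has only %d single-trial entries",
                      n_train, s, nrow(rows))
        }
        rows[sort(sample(nrow(rows), n_train)), ]
      }))
    })
  }

  structure(list(
    cohort = cohort,
    train = as.data.frame(train_pool),
    validation = validation,
    test = test,
    test_ids = test_ids,
    seed = as.integer(seed),
    n_val = as.integer(n_val),
    n_test = as.integer(n_test)
  ), class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d train entries, %d validation stimuli/subject, %d shared test stimuli (seed %d)\n",
              nrow(x$train), x$n_val, x$n_test, x$seed))
  invisible(x)
}

#' Single-trial training data for one subject and region
#'
#' @param split a [build_split()] result.
#' @param subject_id,region_id which cell to extract.
#' @param n_train optional subsample size ("randomly selected samples,
#'   number equals to train size"); drawn without replacement.
#' @param seed seed for the subsample (required when `n_train` is given).
#' @return list with `x` (feature matrix, one row per single trial), `y`
#'   (measured responses) and `rows` (subject/stimulus/repeat keys used).
#' @export
train_data <- function(split, subject_id, region_id, n_train = NULL, seed = NULL) {
  stopifnot(inherits(split, "dataset_split"))
  tr <- split$train[split$train$subject_id == subject_id, , drop = FALSE]
  if (!is.null(n_train)) {
    if (nrow(tr) < n_train) {
      visens_stop("visens_sizing_error",
                  "n_train = %d but subject %s has only %d training entries",
                  n_train, subject_id, nrow(tr))
    }
    if (is.null(seed)) {
      visens_stop("visens_sizing_error", "seed required when subsampling training entries")
    }
    tr <- with_stream(seed, paste0("train_sample_", subject_id, "_", region_id),
                      tr[sort(sample(nrow(tr), n_train)), , drop = FALSE])
  }
  r <- split$cohort$responses
  idx <- match(paste(tr$subject_id, region_id, tr$stimulus_id, tr$repeat_index),
               paste(r$subject_id, r$region_id, r$stimulus_id, r$repeat_index))
  if (anyNA(idx)) {
    visens_stop("visens_sizing_error",
                "subject %s lacks responses in region %s for some training entries",
                subject_id, region_id)
  }
  list(x = split$cohort$stimuli$features[tr$stimulus_id, , drop = FALSE],
       y = r$response[idx],
       rows = tr)
}

#' Repeat-averaged validation data for one subject and region
#' @inheritParams train_data
#' @return list with `x` (features) and `y` (averaged responses).
#' @export
validation_data <- function(split, subject_id, region_id) {
  v <- split$validation
  v <- v[v$subject_id == subject_id & v$region_id == region_id, , drop = FALSE]
  list(x = split$cohort$stimuli$features[v$stimulus_id, , drop = FALSE],
       y = v$response)
}

#' Repeat-averaged shared test responses as a stimuli x subjects matrix
#'
#' @param split a [build_split()] result.
#' @param region_id region.
#' @return list with `x` (test feature matrix), `y` (matrix, rows = test
#'   stimuli in `split$test_ids` order, columns = subjects).
#' @export
test_data <- function(split, region_id) {
  te <- split$test[split$test$region_id == region_id, , drop = FALSE]
  subjects <- split$cohort$subject_ids
  y <- matrix(NA_real_, length(split$test_ids), length(subjects),
              dimnames = list(split$test_ids, subjects))
  idx <- cbind(match(te$stimulus_id, split$test_ids),
               match(te$subject_id, subjects))
  y[idx] <- te$response
  list(x = split$cohort$stimuli$features[split$test_ids, , drop = FALSE], y = y)
}
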