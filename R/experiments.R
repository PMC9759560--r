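# Experiment orchestration at desk scale: training-size sweeps, ensemble-
# size sweeps, subsampling reliability, top-k stimulus rankings and the
# animal-vs-human preference analysis. Every experiment is a pure function
# of (cohort, config, seeds): re-running reproduces all tables.

sweep_result <- function(axis, grid, accuracy, consistency = NULL,
                         comparisons = NULL, skipped = NULL, seeds = NULL) {
  structure(list(axis = axis, grid = grid, accuracy = accuracy,
                 consistency = consistency, comparisons = comparisons,
                 skipped = skipped, seeds = seeds),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> axis = %s, grid = {%s}, %d accuracy rows, %d seeds\n",
              x$axis, paste(x$grid, collapse = ", "), nrow(x$accuracy),
              length(x$seeds)))
  invisible(x)
}

# accuracy of a map subject -> predicted test vector against measured test
cell_accuracies <- function(pred_by_subject, measured) {
  vapply(names(pred_by_subject), function(s) {
    prediction_accuracy(pred_by_subject[[s]], measured[, s])
  }, numeric(1L))
}

#' Training-size sweep across model families
#'
#' For every seed and every grid point, fits the requested model families
#' for every subject and region and records test accuracy. `scratch`
#' trains a randomly initialized readout on the sampled single trials;
#' `finetuned` is identical but initialized at the group average of the
#' other subjects' reference readouts; `linear_ensemble` fits the OLS
#' ensemble on the same number of single trials; `average_ensemble`
#' (train size 0 semantics) and `oracle` (the reference readout of the
#' subject itself) are computed once per seed, independent of the grid.
#' Per cell, a Wilcoxon matched-pairs signed-rank test compares the model's
#' per-subject accuracies with the oracle reference accuracies.
#'
#' @param cohort a [cohort()].
#' @param reference_readouts named list `region_id -> (subject_id ->
#'   readout_model)`, e.g. [oracle_readouts()] per region: the
#'   densely-trained per-subject reference models.
#' @param grid strictly increasing integer training sizes.
#' @param seeds integer vector; one split + model fit per seed.
#' @param models subset of
#'   `c("scratch", "finetuned", "linear_ensemble", "average_ensemble", "oracle")`.
#' @param region_ids regions to include; default all in `cohort`.
#' @param n_val,n_test split sizes.
#' @param hyper a [readout_hyper()] for the trained readouts.
#' @return a `sweep_result` with `accuracy` (seed, region, subject, model,
#'   train_size, accuracy), `consistency` (pooled across regions, per
#'   seed x model x train_size), `comparisons` (Wilcoxon vs oracle per
#'   cell, when oracle is included) and `skipped` (infeasible cells).
#' @export
run_train_size_sweep <- function(cohort, reference_readouts, grid, seeds,
                                 models = c("scratch", "finetuned",
                                            "linear_ensemble",
                                            "average_ensemble", "oracle"),
                                 region_ids = NULL, n_val = 50L, n_test = 100L,
                                 hyper = readout_hyper()) {
  models <- match.arg(models, several.ok = TRUE)
  if (is.unsorted(grid, strictly = TRUE)) {
    visens_stop("visens_invalid_config", "grid must be strictly increasing")
  }
  if (is.null(region_ids)) region_ids <- cohort$region_ids
  subjects <- cohort$subject_ids
  acc_rows <- list(); skip_rows <- list()
  pred_store <- list()  # predictions for consistency, keyed by cell
  meas_store <- list()

  for (seed in seeds) {
    sp <- build_split(cohort, NULL, n_val = n_val, n_test = n_test, seed = seed)
    pool_sizes <- table(sp$train$subject_id)
    for (region in region_ids) {
      refs <- reference_readouts[[region]]
      te <- test_data(sp, region)
      meas_store[[paste(seed, region)]] <- te$y
      add_cell <- function(model, train_size, preds) {
        acc <- cell_accuracies(preds, te$y)
        acc_rows[[length(acc_rows) + 1L]] <<- data.frame(
          seed = seed, region = region, subject = names(acc), model = model,
          train_size = train_size, accuracy = unname(acc),
          stringsAsFactors = FALSE, row.names = NULL)
        pred_store[[paste(seed, region, model, train_size)]] <<- preds
      }
      if ("oracle" %in% models) {
        preds <- lapply(refs, predict, stimuli = te$x)
        add_cell("oracle", NA_integer_, preds[subjects])
      }
      if ("average_ensemble" %in% models) {
        preds <- lapply(subjects, function(s) {
          m <- average_ensemble_model(s, region, setdiff(subjects, s))
          predict(m, refs, te$x)
        })
        add_cell("average_ensemble", 0L, stats::setNames(preds, subjects))
      }
      for (n in grid) {
        if (any(pool_sizes[subjects] < n)) {
          skip_rows[[length(skip_rows) + 1L]] <- data.frame(
            seed = seed, region = region, train_size = n,
            reason = sprintf("training pool (min %d) below n", min(pool_sizes)),
            stringsAsFactors = FALSE)
          next
        }
        cell_seed <- stream_seed(seed, sprintf("cell_%s_%d", region, n))
        if ("scratch" %in% models) {
          preds <- lapply(subjects, function(s) {
            fit <- train_readout(sp, s, region, init = "random", hyper = hyper,
                                 n_train = n, seed = cell_seed)
            predict(fit$model, te$x)
          })
          add_cell("scratch", n, stats::setNames(preds, subjects))
        }
        if ("finetuned" %in% models) {
          preds <- lapply(subjects, function(s) {
            fit <- train_readout(sp, s, region, init = "group_average",
                                 reference_readouts = refs[setdiff(subjects, s)],
                                 hyper = hyper, n_train = n, seed = cell_seed)
            predict(fit$model, te$x)
          })
          add_cell("finetuned", n, stats::setNames(preds, subjects))
        }
        if ("linear_ensemble" %in% models) {
          preds <- lapply(subjects, function(s) {
            m <- fit_linear_ensemble(refs, sp, s, region, n_train = n,
                                     seed = cell_seed, loo = TRUE)
            predict(m, refs, te$x)
          })
          add_cell("linear_ensemble", n, stats::setNames(preds, subjects))
        }
      }
    }
  }
  accuracy <- do.call(rbind, acc_rows)

  # pooled-region consistency per seed x model x train_size
  cons_rows <- list()
  cells <- unique(accuracy[c("seed", "model", "train_size")])
  for (i in seq_len(nrow(cells))) {
    sd_i <- cells$seed[i]; mo <- cells$model[i]; n <- cells$train_size[i]
    isc_p <- list(); isc_m <- list()
    for (region in region_ids) {
      key <- paste(sd_i, region, mo, n)
      if (is.null(pred_store[[key]])) next
      isc_p[[region]] <- isc_matrix(do.call(cbind, pred_store[[key]]),
                                    "prediction", region)
      isc_m[[region]] <- isc_matrix(meas_store[[paste(sd_i, region)]],
                                    "measurement", region)
    }
    if (!length(isc_p)) next
    cr <- prediction_consistency(isc_p, isc_m, n_permutations = 0L)
    cons_rows[[i]] <- data.frame(seed = sd_i, model = mo, train_size = n,
                                 consistency = cr$r, undefined = cr$undefined,
                                 stringsAsFactors = FALSE)
  }
  consistency <- do.call(rbind, cons_rows)

  comparisons <- NULL
  if ("oracle" %in% models) {
    cmp_rows <- list()
    key_or <- accuracy[accuracy$model == "oracle", ]
    for (i in seq_len(nrow(cells))) {
      if (cells$model[i] == "oracle") next
      sub <- accuracy[accuracy$seed == cells$seed[i] &
                        accuracy$model == cells$model[i] &
                        (is.na(cells$train_size[i]) |
                           accuracy$train_size %in% cells$train_size[i]), ]
      for (region in unique(sub$region)) {
        a <- sub$accuracy[sub$region == region][match(subjects, sub$subject[sub$region == region])]
        b <- key_or$accuracy[key_or$seed == cells$seed[i] & key_or$region == region]
        b <- b[match(subjects, key_or$subject[key_or$seed == cells$seed[i] &
                                                key_or$region == region])]
        if (anyNA(a) || anyNA(b)) next
        w <- compare_to_reference_wilcoxon(a, b)
        cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
          seed = cells$seed[i], region = region, model = cells$model[i],
          train_size = cells$train_size[i], p = w$p,
          significant = !is.na(w$p) && w$p < 0.05,
          stringsAsFactors = FALSE)
      }
    }
    comparisons <- do.call(rbind, cmp_rows)
  }

  sweep_result("train_size", grid, accuracy, consistency, comparisons,
               if (length(skip_rows)) do.call(rbind, skip_rows) else NULL,
               seeds)
}

#' Ensemble-size sweep
#'
#' For each size m, fits linear ensembles on m randomly chosen reference
#' subjects per query (seeded) and records test accuracy and pooled
#' prediction consistency. At the maximal size (all other subjects) the
#' construction delegates to [build_loo_ensembles()].
#'
#' @param cohort a [cohort()].
#' @param reference_readouts named list `region_id -> (subject_id ->
#'   readout_model)`.
#' @param sizes strictly increasing ensemble sizes, each in
#'   1..(n_subjects - 1).
#' @param seeds integer vector.
#' @param n_train OLS training-sample size.
#' @param region_ids,n_val,n_test as in [run_train_size_sweep()].
#' @return a `sweep_result` with axis `"ensemble_size"`; `accuracy` has a
#'   `size` column, `consistency` one row per seed x size.
#' @export
run_ensemble_size_sweep <- function(cohort, reference_readouts, sizes, seeds,
                                    n_train = 300L, region_ids = NULL,
                                    n_val = 50L, n_test = 100L) {
  if (any(sizes < 1L)) {
    visens_stop("visens_invalid_config", "ensemble sizes must be >= 1")
  }
  if (any(sizes > length(cohort$subject_ids) - 1L)) {
    visens_stop("visens_invalid_config",
                "ensemble sizes must be <= n_subjects - 1 = %d",
                length(cohort$subject_ids) - 1L)
  }
  if (is.null(region_ids)) region_ids <- cohort$region_ids
  subjects <- cohort$subject_ids
  max_size <- length(subjects) - 1L
  acc_rows <- list(); cons_rows <- list()

  for (seed in seeds) {
    sp <- build_split(cohort, NULL, n_val = n_val, n_test = n_test, seed = seed)
    for (m in sizes) {
      isc_p <- list(); isc_m <- list()
      for (region in region_ids) {
        refs <- reference_readouts[[region]]
        te <- test_data(sp, region)
        if (m == max_size) {
          ens <- build_loo_ensembles(refs, sp, region, n_train, seed = seed)
        } else {
          ens <- stats::setNames(lapply(subjects, function(s) {
            chosen <- with_stream(seed, sprintf("esweep_%s_%d_%s", region, m, s),
                                  sample(setdiff(subjects, s), m))
            fit_linear_ensemble(refs[chosen], sp, s, region, n_train,
                                seed = stream_seed(seed, paste0("loo_", s)),
                                loo = TRUE)
          }), subjects)
        }
        preds <- lapply(ens, function(e) predict(e, refs, te$x))
        acc <- cell_accuracies(preds, te$y)
        acc_rows[[length(acc_rows) + 1L]] <- data.frame(
          seed = seed, region = region, subject = names(acc),
          model = "linear_ensemble", size = m, accuracy = unname(acc),
          stringsAsFactors = FALSE, row.names = NULL)
        isc_p[[region]] <- isc_matrix(do.call(cbind, preds), "prediction", region)
        isc_m[[region]] <- isc_matrix(te$y, "measurement", region)
      }
      cr <- prediction_consistency(isc_p, isc_m, n_permutations = 0L)
      cons_rows[[length(cons_rows) + 1L]] <- data.frame(
        seed = seed, size = m, consistency = cr$r, undefined = cr$undefined,
        stringsAsFactors = FALSE)
    }
  }
  sweep_result("ensemble_size", sizes, do.call(rbind, acc_rows),
               do.call(rbind, cons_rows), seeds = seeds)
}

#' Subsampling reliability of ISC-measurement or prediction consistency
#'
#' Repeatedly subsamples a fraction of the test stimuli and recomputes the
#' metric, reporting its distribution and relative error against the
#' full-data value.
#'
#' @param split a [build_split()] result.
#' @param metric `"isc_measurement"` (mean pooled pairwise ISC of measured
#'   test responses) or `"consistency"` (pooled prediction-consistency r;
#'   requires `predictions`).
#' @param predictions for `"consistency"`: named list `region_id ->
#'   (subject_id -> predicted test vector)` aligned to `split$test_ids`.
#' @param n_draws number of subsampling draws (default 1000).
#' @param fraction fraction of test stimuli per draw, in (0, 1].
#' @param seed integer seed.
#' @param region_ids regions to pool; default all.
#' @return list with `full` (full-data value), `draws` (data.frame draw /
#'   value / rel_error), `cv` (coefficient of variation of the draws) and
#'   `n_degenerate` (draws with undefined metric, flagged and excluded).
#' @export
subsample_reliability <- function(split, metric = c("isc_measurement",
                                                    "consistency"),
                                  predictions = NULL, n_draws = 1000L,
                                  fraction = 0.9, seed = 1L,
                                  region_ids = NULL) {
  metric <- match.arg(metric)
  if (fraction <= 0 || fraction > 1) {
    visens_stop("visens_invalid_config", "fraction must be in (0, 1], got %g",
                fraction)
  }
  if (metric == "consistency" && is.null(predictions)) {
    visens_stop("visens_invalid_config",
                "metric = 'consistency' requires predictions")
  }
  if (is.null(region_ids)) region_ids <- split$cohort$region_ids
  te <- lapply(region_ids, function(g) test_data(split, g))
  names(te) <- region_ids
  n_stim <- length(split$test_ids)
  take <- max(3L, round(fraction * n_stim))

  value_of <- function(idx) {
    isc_m <- lapply(region_ids, function(g) {
      isc_matrix(te[[g]]$y[idx, , drop = FALSE], "measurement", g)
    })
    if (metric == "isc_measurement") {
      v <- unlist(lapply(isc_m, isc_pairs))
      if (!any(is.finite(v))) return(NA_real_)
      return(mean(v, na.rm = TRUE))
    }
    isc_p <- lapply(region_ids, function(g) {
      p <- do.call(cbind, lapply(predictions[[g]], function(v) v[idx]))
      isc_matrix(p, "prediction", g)
    })
    cr <- prediction_consistency(isc_p, isc_m, n_permutations = 0L)
    if (cr$undefined) NA_real_ else cr$r
  }

  full <- value_of(seq_len(n_stim))
  draws <- with_stream(seed, "reliability", {
    vapply(seq_len(n_draws), function(i) {
      value_of(sort(sample.int(n_stim, take)))
    }, numeric(1L))
  })
  ok <- is.finite(draws)
  rel <- (draws - full) / abs(full)
  list(full = full,
       draws = data.frame(draw = seq_len(n_draws), value = draws,
                          rel_error = rel),
       cv = stats::sd(draws[ok]) / abs(mean(draws[ok])),
       n_degenerate = sum(!ok))
}

#' Top-k stimuli by predicted response
#'
#' @param predicted named numeric vector of predicted responses (names =
#'   stimulus ids), e.g. from [predict.readout_model()] on a
#'   [stimulus_set()]; or a model accepted by [predict()] together with
#'   `stimuli`.
#' @param k how many stimuli; 1 <= k <= number of stimuli.
#' @param stimuli optional [stimulus_set()] when `predicted` is a model.
#' @param reference_readouts optional, for ensemble models.
#' @return character vector of k stimulus ids, by descending predicted
#'   response; ties broken by lexicographic stimulus id.
#' @export
top_k_stimuli <- function(predicted, k, stimuli = NULL,
                          reference_readouts = NULL) {
  if (!is.numeric(predicted)) {
    if (is.null(stimuli)) {
      visens_stop("visens_invalid_config",
                  "supply stimuli when predicted is a model")
    }
    predicted <- if (inherits(predicted, "readout_model")) {
      stats::setNames(predict(predicted, stimuli), stimuli$info$stimulus_id)
    } else {
      stats::setNames(predict(predicted, reference_readouts, stimuli),
                      stimuli$info$stimulus_id)
    }
  }
  if (k <= 0L || k > length(predicted)) {
    visens_stop("visens_sizing_error", "k must be in 1..%d, got %d",
                length(predicted), k)
  }
  if (is.null(names(predicted))) {
    visens_stop("visens_invalid_config", "predicted vector must be named by stimulus id")
  }
  ord <- order(-predicted, names(predicted), method = "radix")
  names(predicted)[ord][seq_len(k)]
}

#' Animal-face vs human-face preference analysis
#'
#' For every (subject, face region): a Welch two-sample t statistic of the
#' subject's measured (repeat-averaged) test responses to animal-face vs
#' human-face stimuli, and the preference ratio
#' `(n_animal - n_human) / (n_animal + n_human)` within the model's top-k
#' predicted stimuli. The two quantities are then correlated across all
#' subject x region points (Pearson, two-tailed p).
#'
#' @param split a [build_split()] result on a labeled cohort.
#' @param ensembles named list `region_id -> (subject_id -> ensemble or
#'   readout model)`.
#' @param reference_readouts named list `region_id -> (subject_id ->
#'   readout_model)` used by ensemble predictions.
#' @param face_regions regions to analyse.
#' @param k top-k size (default 10).
#' @return list with `results` (data.frame subject / region / t_stat /
#'   ratio / n_animal / n_human), `r`, `p` and `n_dropped` (points with an
#'   undefined ratio or too few labeled stimuli, dropped with a warning).
#' @export
preference_analysis <- function(split, ensembles, reference_readouts,
                                face_regions, k = 10L) {
  st <- split$cohort$stimuli
  if (is.null(st$info$label)) {
    visens_stop("visens_invalid_config", "cohort stimuli carry no labels")
  }
  lab <- stats::setNames(st$info$label, st$info$stimulus_id)
  test_lab <- lab[split$test_ids]
  rows <- list(); dropped <- 0L
  for (region in face_regions) {
    te <- test_data(split, region)
    for (s in split$cohort$subject_ids) {
      meas <- te$y[, s]
      a <- meas[test_lab == "animal_face"]
      h <- meas[test_lab == "human_face"]
      model <- ensembles[[region]][[s]]
      pred <- if (inherits(model, "readout_model")) {
        predict(model, te$x)
      } else {
        predict(model, reference_readouts[[region]], te$x)
      }
      top <- top_k_stimuli(stats::setNames(pred, split$test_ids), k)
      n_animal <- sum(lab[top] == "animal_face", na.rm = TRUE)
      n_human <- sum(lab[top] == "human_face", na.rm = TRUE)
      if (length(a) < 2L || length(h) < 2L || n_animal + n_human == 0L) {
        warning(sprintf("dropping %s/%s: undefined preference point", s, region))
        dropped <- dropped + 1L
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, region = region,
        t_stat = welch_t(a, h)$statistic,
        ratio = (n_animal - n_human) / (n_animal + n_human),
        n_animal = n_animal, n_human = n_human,
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  if (is.null(results) || nrow(results) < 3L) {
    visens_stop("visens_sizing_error",
                "fewer than 3 usable subject x region points")
  }
  ct <- stats::cor.test(results$t_stat, results$ratio)
  list(results = results, r = unname(ct$estimate), p = ct$p.value,
       n_dropped = dropped)
}
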