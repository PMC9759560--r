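# Synthetic multi-subject cohort generator.
#
# A Gaussian linear generative model with the two axes the real analyses
# rest on: a stimulus-driven signal shared across subjects and a
# subject-idiosyncratic component, plus additive measurement noise on
# every repeat. Per region, a shared readout w_g with |w_g| = sigma_g
# (direction uniform on the sphere, so every region carries exactly the
# same shared-signal variance) and per-subject offsets
# u_j ~ N(0, sigma_u^2/d I) define noiseless signals
# r_j(S) = (w_g + u_j) . f(S); each repeat measures r_j(S) + eps with
# eps ~ N(0, sigma_eps^2). Features are i.i.d. standard normal, so the
# noiseless response variance is sigma_g^2 + sigma_u^2 in expectation
# regardless of d.
# Optionally the last subject's signal is a known linear mixture
# intercept* + sum_j beta*_j r_j(S) of the other subjects' signals, giving
# ground-truth ensemble coefficients for parameter-recovery checks.
#
# Each concern (features, labels, readouts, noise) draws from its own
# named RNG stream, so changing e.g. the number of repeats does not
# perturb the features.

#' Configuration for a synthetic cohort
#'
#' Defaults emulate a densely-sampled visual-fMRI cohort at desk scale:
#' 8 subjects, 4 regions, 1000 stimuli of which 250 are shared by all
#' subjects (the rest split round-robin as subject-exclusive stimuli),
#' 3 repeats, a dominant shared signal (sd 1) with a smaller but reliable
#' subject-idiosyncratic component (sd 0.2) and measurement noise
#' (sd 0.6). The feature dimension (12) is deliberately small relative to
#' the number of reference subjects, so that the span of the reference
#' readouts can represent a substantial fraction of a new subject's
#' idiosyncratic component — the regime in which densely-trained reference
#' models transfer well across subjects while inter-individual differences
#' remain detectable.
#'
#' @param n_subjects,n_regions,n_stimuli,n_shared_stimuli cohort shape.
#' @param feature_dim feature dimension d (abstract feature units).
#' @param shared_signal_sd sd of the shared stimulus-driven signal
#'   (response units).
#' @param idiosyncratic_signal_sd sd of the per-subject signal component.
#' @param noise_sd sd of additive measurement noise per repeat.
#' @param repeats repeats per (subject, stimulus), in 1..3.
#' @param query_mixing optional `list(intercept =, beta =)` with `beta` of
#'   length `n_subjects - 1`: the last subject's noiseless signal becomes
#'   this linear mixture of the other subjects' signals.
#' @param label_probs optional named probabilities over
#'   `c("animal_face", "human_face", "other")`; stimuli are then labeled
#'   and labeled categories shift dedicated feature axes by
#'   `label_effect`, planting category-selective response differences.
#' @param label_effect feature shift for labeled stimuli.
#' @param noise_df optional degrees of freedom for Student-t (heavier
#'   tailed) measurement noise, scaled to sd `noise_sd`; default Gaussian.
#' @param seed integer seed.
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_subjects = 8L, n_regions = 4L,
                             n_stimuli = 1000L, n_shared_stimuli = 250L,
                             feature_dim = 12L, shared_signal_sd = 1,
                             idiosyncratic_signal_sd = 0.2, noise_sd = 0.6,
                             repeats = 3L, query_mixing = NULL,
                             label_probs = NULL, label_effect = 1,
                             noise_df = NULL, seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_regions = as.integer(n_regions),
              n_stimuli = as.integer(n_stimuli),
              n_shared_stimuli = as.integer(n_shared_stimuli),
              feature_dim = as.integer(feature_dim),
              shared_signal_sd = shared_signal_sd,
              idiosyncratic_signal_sd = idiosyncratic_signal_sd,
              noise_sd = noise_sd, repeats = as.integer(repeats),
              query_mixing = query_mixing, label_probs = label_probs,
              label_effect = label_effect, noise_df = noise_df,
              seed = as.integer(seed))
  if (cfg$n_subjects < 1L || cfg$n_regions < 1L || cfg$feature_dim < 1L) {
    visens_stop("visens_invalid_config", "cohort shape parameters must be >= 1")
  }
  if (cfg$n_shared_stimuli > cfg$n_stimuli) {
    visens_stop("visens_invalid_config",
                "n_shared_stimuli (%d) exceeds n_stimuli (%d)",
                cfg$n_shared_stimuli, cfg$n_stimuli)
  }
  if (min(cfg$shared_signal_sd, cfg$idiosyncratic_signal_sd, cfg$noise_sd) < 0) {
    visens_stop("visens_invalid_config", "signal/noise sds must be >= 0")
  }
  if (!cfg$repeats %in% 1:3) {
    visens_stop("visens_invalid_config", "repeats must be 1, 2 or 3")
  }
  if (!is.null(query_mixing)) {
    if (is.null(query_mixing$beta) ||
        length(query_mixing$beta) != cfg$n_subjects - 1L) {
      visens_stop("visens_invalid_config",
                  "query_mixing$beta must have length n_subjects - 1 = %d",
                  cfg$n_subjects - 1L)
    }
    if (is.null(query_mixing$intercept)) cfg$query_mixing$intercept <- 0
  }
  structure(cfg, class = "synthetic_config")
}

#' Load a synthetic-cohort configuration from JSON
#' @param path JSON file with fields named as in [synthetic_config()].
#' @return a `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(synthetic_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    visens_stop("visens_invalid_config", "unknown config fields: %s",
                paste(unknown, collapse = ", "))
  }
  if (!is.null(raw$query_mixing)) raw$query_mixing <- as.list(raw$query_mixing)
  do.call(synthetic_config, raw)
}

default_region_ids <- function(n) {
  base <- c("V1v", "FFA1", "EBA", "PPA", "OFA", "FFA2")
  if (n <= length(base)) base[seq_len(n)] else paste0("ROI", seq_len(n))
}

#' Generate a synthetic cohort with ground truth
#'
#' @param config a [synthetic_config()].
#' @return list with `cohort` (a [cohort()]) and `ground_truth` (class
#'   `ground_truth`: per-region latent readouts, per-subject biases, the
#'   config and any planted mixing coefficients).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  seed <- cfg$seed
  d <- cfg$feature_dim
  stim_ids <- sprintf("s%05d", seq_len(cfg$n_stimuli))
  subj_ids <- sprintf("sub%02d", seq_len(cfg$n_subjects))
  region_ids <- default_region_ids(cfg$n_regions)

  feats <- with_stream(seed, "features",
                       matrix(stats::rnorm(cfg$n_stimuli * d), cfg$n_stimuli, d))
  labels <- NULL
  if (!is.null(cfg$label_probs)) {
    p <- cfg$label_probs[LABEL_VOCABULARY]
    p[is.na(p)] <- 0
    labels <- with_stream(seed, "labels",
                          sample(LABEL_VOCABULARY, cfg$n_stimuli, replace = TRUE,
                                 prob = p))
    # category-selective axes: animal faces load on f0, human faces on f1
    feats[labels == "animal_face", 1L] <-
      feats[labels == "animal_face", 1L] + cfg$label_effect
    feats[labels == "human_face", 2L] <-
      feats[labels == "human_face", 2L] + cfg$label_effect
  }
  shared <- seq_len(cfg$n_stimuli) <= cfg$n_shared_stimuli
  stimuli <- stimulus_set(stim_ids, feats, label = labels, shared = shared)

  # subject-exclusive stimuli partitioned round-robin
  owner <- rep(NA_integer_, cfg$n_stimuli)
  excl <- which(!shared)
  if (length(excl)) {
    owner[excl] <- rep_len(seq_len(cfg$n_subjects), length(excl))
  }
  stim_of_subject <- lapply(seq_len(cfg$n_subjects), function(j) {
    stim_ids[shared | (!is.na(owner) & owner == j)]
  })

  regions <- with_stream(seed, "readouts", {
    out <- vector("list", cfg$n_regions)
    names(out) <- region_ids
    for (g in seq_len(cfg$n_regions)) {
      # fixed norm |w_g| = sigma_g, uniform direction: all regions carry
      # identical shared-signal variance
      z <- stats::rnorm(d)
      w_g <- if (cfg$shared_signal_sd > 0) {
        cfg$shared_signal_sd * z / sqrt(sum(z^2))
      } else {
        numeric(d)
      }
      u <- matrix(stats::rnorm(cfg$n_subjects * d, 0,
                               cfg$idiosyncratic_signal_sd / sqrt(d)),
                  cfg$n_subjects, d)
      w <- sweep(u, 2L, w_g, `+`)
      bias <- numeric(cfg$n_subjects)
      if (!is.null(cfg$query_mixing)) {
        q <- cfg$n_subjects
        w[q, ] <- drop(crossprod(w[-q, , drop = FALSE], cfg$query_mixing$beta))
        bias[q] <- cfg$query_mixing$intercept
      }
      rownames(w) <- subj_ids
      out[[g]] <- list(shared_weights = w_g, weights = w, bias = bias)
    }
    out
  })

  # response table: subject's stimuli x regions x repeats, single trials
  blocks <- vector("list", cfg$n_subjects)
  for (j in seq_len(cfg$n_subjects)) {
    ids <- stim_of_subject[[j]]
    n_s <- length(ids)
    fx <- feats[match(ids, stim_ids), , drop = FALSE]
    per_region <- lapply(region_ids, function(g) {
      signal <- drop(fx %*% regions[[g]]$weights[j, ]) + regions[[g]]$bias[j]
      data.frame(subject_id = subj_ids[j], region_id = g,
                 stimulus_id = rep(ids, each = cfg$repeats),
                 repeat_index = rep(seq_len(cfg$repeats) - 1L, n_s),
                 signal = rep(signal, each = cfg$repeats),
                 stringsAsFactors = FALSE)
    })
    blocks[[j]] <- do.call(rbind, per_region)
  }
  resp <- do.call(rbind, blocks)
  noise <- with_stream(seed, "noise", {
    if (is.null(cfg$noise_df)) {
      stats::rnorm(nrow(resp), 0, cfg$noise_sd)
    } else {
      scale <- cfg$noise_sd / sqrt(cfg$noise_df / (cfg$noise_df - 2))
      stats::rt(nrow(resp), df = cfg$noise_df) * scale
    }
  })
  resp$response <- resp$signal + noise
  resp$signal <- NULL

  co <- cohort(stimuli, resp, subject_ids = subj_ids, region_ids = region_ids)
  gt <- structure(list(config = cfg, subject_ids = subj_ids,
                       region_ids = region_ids, regions = regions,
                       query_mixing = cfg$query_mixing),
                  class = "ground_truth")
  list(cohort = co, ground_truth = gt)
}

#' Export latent generative readouts as readout models
#'
#' The noiseless per-subject readouts of the generator stand in for
#' densely-trained per-subject encoding models: they are the best linear
#' predictor of each subject's responses and serve as the reference
#' ("gold standard") models for ensembles and sweeps.
#'
#' @param ground_truth a `ground_truth` from [generate_cohort()].
#' @param region_id which region; default the first.
#' @return named list `subject_id -> readout_model` with
#'   `init_mode = "oracle"`.
#' @export
oracle_readouts <- function(ground_truth, region_id = NULL) {
  stopifnot(inherits(ground_truth, "ground_truth"))
  if (is.null(region_id)) region_id <- ground_truth$region_ids[1L]
  reg <- ground_truth$regions[[region_id]]
  if (is.null(reg)) {
    visens_stop("visens_sizing_error", "unknown region: %s", region_id)
  }
  out <- lapply(seq_along(ground_truth$subject_ids), function(j) {
    readout_model(ground_truth$subject_ids[j], region_id,
                  reg$weights[j, ], reg$bias[j],
                  init_mode = "oracle", n_train_used = 0L)
  })
  stats::setNames(out, ground_truth$subject_ids)
}

#' Save simulator ground truth as JSON
#' @param ground_truth a `ground_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_ground_truth <- function(ground_truth, path) {
  gt <- ground_truth
  obj <- list(
    config = unclass(gt$config),
    subject_ids = gt$subject_ids,
    region_ids = gt$region_ids,
    regions = lapply(gt$regions, function(r) {
      list(shared_weights = r$shared_weights,
           weights = apply(r$weights, 1L, identity, simplify = FALSE),
           bias = r$bias)
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
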