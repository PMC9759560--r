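# Per-subject, per-region linear readout encoding models.
#
# A readout maps precomputed stimulus features to one region's scalar
# response: r_hat(S) = w . f(S) + b. The feature extractor is outside the
# trainable path here; features are fixed inputs. Readouts are trained by
# mini-batch gradient descent on mean squared error (default batch size
# 32) and stop early when the Pearson correlation between predicted and
# measured responses on the validation set stops improving; the weights at
# the best validation correlation (including the initial ones, epoch 0)
# are returned. Initialization is either random or the element-wise
# average of previously trained reference readouts ("group average"),
# which emulates warm-starting a new subject's model from densely-trained
# subjects.

#' Construct a readout model
#'
#' @param subject_id,region_id identifiers.
#' @param weights numeric vector, length = feature dimension.
#' @param bias numeric scalar.
#' @param init_mode `"random"` or `"group_average"` (or `"oracle"` for
#'   simulator ground-truth readouts).
#' @param n_train_used number of single-trial training points used.
#' @return object of class `readout_model`.
#' @export
readout_model <- function(subject_id, region_id, weights, bias = 0,
                          init_mode = "random", n_train_used = 0L) {
  weights <- as.numeric(weights)
  if (!all(is.finite(weights)) || !is.finite(bias)) {
    visens_stop("visens_invalid_model", "readout weights/bias must be finite")
  }
  structure(list(subject_id = as.character(subject_id),
                 region_id = as.character(region_id),
                 weights = weights, bias = as.numeric(bias),
                 init_mode = init_mode,
                 n_train_used = as.integer(n_train_used)),
            class = "readout_model")
}

#' @export
print.readout_model <- function(x, ...) {
  cat(sprintf("<readout_model> subject %s, region %s, d = %d, init = %s, n_train = %d\n",
              x$subject_id, x$region_id, length(x$weights), x$init_mode,
              x$n_train_used))
  invisible(x)
}

#' Training hyperparameters for readout models
#'
#' @param lr learning-rate (step size).
#' @param batch_size mini-batch size; default 32.
#' @param max_epochs hard epoch budget.
#' @param patience stop after this many validation evaluations without
#'   improvement in validation correlation; validation is evaluated once
#'   per epoch (and at epoch 0, before any update).
#' @param optimizer `"sgd"` (plain mini-batch gradient descent, default)
#'   or `"adam"` (AdamW-style adaptive steps with decoupled weight decay).
#' @param weight_decay decoupled weight decay, only used by `"adam"`.
#' @return a list of class `readout_hyper`.
#' @export
readout_hyper <- function(lr = 0.05, batch_size = 32L, max_epochs = 300L,
                          patience = 10L, optimizer = c("sgd", "adam"),
                          weight_decay = 0) {
  optimizer <- match.arg(optimizer)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), optimizer = optimizer,
                 weight_decay = weight_decay),
            class = "readout_hyper")
}

#' Train a linear readout for one subject and region
#'
#' Minimizes mean squared error between predicted and measured single-trial
#' responses by mini-batch gradient descent, monitoring the Pearson
#' correlation between predictions and repeat-averaged responses on the
#' validation set. Training stops once the validation correlation has not
#' improved for `hyper$patience` consecutive evaluations and the weights
#' from the best evaluation are returned.
#'
#' If the validation responses have zero variance the correlation is
#' undefined: training then falls back to the fixed `max_epochs` budget and
#' returns the final weights, with `val_correlation` recorded as `NA`.
#'
#' @param split a [build_split()] result.
#' @param subject_id,region_id which cell to train.
#' @param init `"random"` (weights ~ Normal(0, 1/d), bias 0) or
#'   `"group_average"` (mean of `reference_readouts`).
#' @param reference_readouts list of [readout_model()] used when
#'   `init = "group_average"`.
#' @param hyper a [readout_hyper()].
#' @param n_train optional number of single-trial training entries to
#'   subsample (seeded); default uses the split's whole training pool.
#' @param seed integer seed (initialization, batch shuffling, subsampling).
#' @return list with `model` (a [readout_model()]) and `trace`
#'   (data.frame epoch / train_mse / val_correlation, epoch 0 = initial).
#' @export
train_readout <- function(split, subject_id, region_id,
                          init = c("random", "group_average"),
                          reference_readouts = NULL,
                          hyper = readout_hyper(), n_train = NULL, seed = 1L) {
  init <- match.arg(init)
  stopifnot(inherits(split, "dataset_split"))
  tr <- train_data(split, subject_id, region_id, n_train = n_train, seed = seed)
  if (nrow(tr$x) == 0L) {
    visens_stop("visens_sizing_error", "empty training set for %s/%s",
                subject_id, region_id)
  }
  va <- validation_data(split, subject_id, region_id)
  d <- ncol(tr$x)
  if (init == "group_average") {
    if (is.null(reference_readouts) || !length(reference_readouts)) {
      visens_stop("visens_invalid_model",
                  "group_average initialization requires reference readouts")
    }
    avg <- group_average_readout(reference_readouts)
    if (length(avg$weights) != d) {
      visens_stop("visens_shape_error",
                  "reference readout dimension %d != feature dimension %d",
                  length(avg$weights), d)
    }
    w <- avg$weights
    b <- avg$bias
  } else {
    w <- with_stream(seed, paste0("init_", subject_id, "_", region_id),
                     stats::rnorm(d, 0, sqrt(1 / d)))
    b <- 0
  }

  val_defined <- length(va$y) >= 3L && stats::sd(va$y) > 0
  val_cor <- function(w, b) {
    if (!val_defined) return(NA_real_)
    p <- drop(va$x %*% w) + b
    if (stats::sd(p) == 0) return(NA_real_)
    stats::cor(p, va$y)
  }
  mse <- function(w, b) mean((drop(tr$x %*% w) + b - tr$y)^2)

  n <- nrow(tr$x)
  bs <- min(hyper$batch_size, n)
  trace <- data.frame(epoch = 0L, train_mse = mse(w, b),
                      val_correlation = val_cor(w, b))
  best <- list(w = w, b = b, cor = trace$val_correlation[1L], epoch = 0L)
  stale <- 0L
  if (hyper$optimizer == "adam") {
    m_w <- v_w <- numeric(d); m_b <- v_b <- 0; t_step <- 0L
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  }

  with_stream(seed, paste0("batches_", subject_id, "_", region_id), {
    for (epoch in seq_len(hyper$max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1L, n)]
        xb <- tr$x[idx, , drop = FALSE]
        resid <- drop(xb %*% w) + b - tr$y[idx]
        g_w <- 2 * drop(crossprod(xb, resid)) / length(idx)
        g_b <- 2 * mean(resid)
        if (hyper$optimizer == "adam") {
          t_step <- t_step + 1L
          m_w <- beta1 * m_w + (1 - beta1) * g_w
          v_w <- beta2 * v_w + (1 - beta2) * g_w^2
          m_b <- beta1 * m_b + (1 - beta1) * g_b
          v_b <- beta2 * v_b + (1 - beta2) * g_b^2
          mh_w <- m_w / (1 - beta1^t_step); vh_w <- v_w / (1 - beta2^t_step)
          mh_b <- m_b / (1 - beta1^t_step); vh_b <- v_b / (1 - beta2^t_step)
          w <- w - hyper$lr * (mh_w / (sqrt(vh_w) + eps) + hyper$weight_decay * w)
          b <- b - hyper$lr * mh_b / (sqrt(vh_b) + eps)
        } else {
          w <- w - hyper$lr * g_w
          b <- b - hyper$lr * g_b
        }
      }
      vc <- val_cor(w, b)
      trace <- rbind(trace, data.frame(epoch = epoch, train_mse = mse(w, b),
                                       val_correlation = vc))
      if (val_defined && !is.na(vc)) {
        if (is.na(best$cor) || vc > best$cor + 1e-12) {
          best <- list(w = w, b = b, cor = vc, epoch = epoch)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= hyper$patience) break
        }
      }
    }
  })
  if (!val_defined) best <- list(w = w, b = b, cor = NA_real_,
                                 epoch = hyper$max_epochs)
  model <- readout_model(subject_id, region_id, best$w, best$b,
                         init_mode = init, n_train_used = n)
  list(model = model, trace = trace, best_epoch = best$epoch)
}

#' Element-wise average of readout models
#'
#' Used to initialize a new subject's readout at the group mean of
#' densely-trained reference subjects' readouts.
#'
#' @param readouts non-empty list of [readout_model()] with equal feature
#'   dimension and region.
#' @return a [readout_model()] with `init_mode = "group_average"`.
#' @export
group_average_readout <- function(readouts) {
  if (!length(readouts)) {
    visens_stop("visens_invalid_model", "need at least one readout to average")
  }
  d <- length(readouts[[1L]]$weights)
  region <- readouts[[1L]]$region_id
  for (m in readouts) {
    if (length(m$weights) != d) {
      visens_stop("visens_shape_error", "readouts have mixed feature dimensions")
    }
    if (!identical(m$region_id, region)) {
      visens_stop("visens_shape_error", "readouts come from mixed regions")
    }
  }
  w <- rowMeans(vapply(readouts, `[[`, numeric(d), "weights"))
  b <- mean(vapply(readouts, `[[`, numeric(1L), "bias"))
  readout_model("group_average", region, w, b, init_mode = "group_average",
                n_train_used = 0L)
}

#' Predict region responses for a set of stimuli
#'
#' @param object a [readout_model()].
#' @param stimuli a [stimulus_set()], or a feature matrix with stimulus ids
#'   as row names.
#' @param ... unused.
#' @return named numeric vector of predicted responses, in stimulus order.
#' @export
predict.readout_model <- function(object, stimuli, ...) {
  x <- if (inherits(stimuli, "stimulus_set")) stimuli$features else as.matrix(stimuli)
  if (ncol(x) != length(object$weights)) {
    visens_stop("visens_shape_error",
                "feature dimension %d != readout dimension %d",
                ncol(x), length(object$weights))
  }
  drop(x %*% object$weights) + object$bias
}

# ---- serialization --------------------------------------------------------

#' Save readout models to a delimited table
#'
#' Columns: subject_id, region_id, init_mode, n_train_used, bias,
#' w0..w{d-1}. Full double precision; [load_readouts()] is the exact
#' inverse.
#'
#' @param readouts list of [readout_model()].
#' @param path output file (.csv or .tsv).
#' @return `path`, invisibly.
#' @export
save_readouts <- function(readouts, path) {
  stopifnot(length(readouts) > 0L)
  d <- length(readouts[[1L]]$weights)
  w <- t(vapply(readouts, `[[`, numeric(d), "weights"))
  colnames(w) <- paste0("w", seq_len(d) - 1L)
  df <- data.frame(
    subject_id = vapply(readouts, `[[`, character(1L), "subject_id"),
    region_id = vapply(readouts, `[[`, character(1L), "region_id"),
    init_mode = vapply(readouts, `[[`, character(1L), "init_mode"),
    n_train_used = vapply(readouts, `[[`, integer(1L), "n_train_used"),
    bias = vapply(readouts, `[[`, numeric(1L), "bias"),
    stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(w))
  df <- df[order(df$subject_id, df$region_id), , drop = FALSE]
  write_table_precise(df, path)
  invisible(path)
}

#' Load readout models written by [save_readouts()]
#'
#' @param path delimited table path.
#' @return named list of [readout_model()], names `subject_id/region_id`.
#' @export
load_readouts <- function(path) {
  df <- read_table_auto(path)
  wcols <- grep("^w[0-9]+$", names(df), value = TRUE)
  wcols <- wcols[order(as.integer(sub("^w", "", wcols)))]
  out <- lapply(seq_len(nrow(df)), function(i) {
    readout_model(df$subject_id[i], df$region_id[i],
                  as.numeric(df[i, wcols]), df$bias[i],
                  init_mode = df$init_mode[i],
                  n_train_used = df$n_train_used[i])
  })
  names(out) <- paste(df$subject_id, df$region_id, sep = "/")
  out
}
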