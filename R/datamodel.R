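# Cohort data structures and on-disk formats.
#
# A cohort couples a stimulus set (feature vectors, optional category
# labels, shared flag) with a long-format table of single-trial responses:
# one GLM-beta-like scalar per (subject, region, stimulus, repeat). This is
# the desk-scale analogue of densely-sampled fMRI datasets in which each
# subject views thousands of natural scenes with 1-3 repeats, a subset of
# stimuli being shared across all subjects.

#' Closed label vocabulary for stimulus categories
#' @keywords internal
LABEL_VOCABULARY <- c("animal_face", "human_face", "other")

#' Construct a stimulus set
#'
#' @param stimulus_id character vector of unique stimulus identifiers.
#' @param features numeric matrix, one row per stimulus, `d` feature
#'   columns (abstract feature units standing in for image feature maps).
#' @param label optional character vector of category labels drawn from
#'   `"animal_face"`, `"human_face"`, `"other"`; `NA` allowed.
#' @param shared logical vector: is the stimulus available to all subjects?
#' @return an object of class `stimulus_set` with elements `info`
#'   (data.frame: stimulus_id, shared, and label when present) and
#'   `features` (matrix with stimulus ids as row names).
#' @export
stimulus_set <- function(stimulus_id, features, label = NULL, shared = TRUE) {
  stimulus_id <- as.character(stimulus_id)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyDuplicated(stimulus_id)) {
    visens_stop("visens_invalid_stimuli", "duplicate stimulus_id: %s",
                paste(unique(stimulus_id[duplicated(stimulus_id)]), collapse = ", "))
  }
  if (nrow(features) != length(stimulus_id) || ncol(features) < 1L) {
    visens_stop("visens_invalid_stimuli",
                "features must be a matrix with one row per stimulus and d > 0 columns")
  }
  if (!all(is.finite(features))) {
    visens_stop("visens_invalid_stimuli", "non-finite feature values")
  }
  if (!is.null(label)) {
    bad <- !is.na(label) & !(label %in% LABEL_VOCABULARY)
    if (any(bad)) {
      visens_stop("visens_invalid_stimuli", "labels outside vocabulary: %s",
                  paste(unique(label[bad]), collapse = ", "))
    }
  }
  shared <- rep_len(as.logical(shared), length(stimulus_id))
  rownames(features) <- stimulus_id
  colnames(features) <- paste0("f", seq_len(ncol(features)) - 1L)
  info <- data.frame(stimulus_id = stimulus_id, shared = shared,
                     stringsAsFactors = FALSE)
  if (!is.null(label)) info$label <- as.character(label)
  structure(list(info = info, features = features),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %d stimuli, %d features, %d shared%s\n",
              nrow(x$info), ncol(x$features), sum(x$info$shared),
              if (!is.null(x$info$label)) ", labeled" else ""))
  invisible(x)
}

#' Feature dimension of a stimulus set or cohort
#' @param x a `stimulus_set` or `cohort`.
#' @return integer `d`.
#' @export
feature_dim <- function(x) {
  if (inherits(x, "cohort")) x <- x$stimuli
  ncol(x$features)
}

#' Construct a cohort of stimulus-response records
#'
#' @param stimuli a [stimulus_set()].
#' @param responses data.frame with columns `subject_id`, `region_id`,
#'   `stimulus_id`, `repeat_index` (integer >= 0) and `response`
#'   (finite numeric, GLM-beta-like units).
#' @param subject_ids,region_ids optional orderings; default sorted unique.
#' @return an object of class `cohort`.
#' @export
cohort <- function(stimuli, responses, subject_ids = NULL, region_ids = NULL) {
  stopifnot(inherits(stimuli, "stimulus_set"))
  need <- c("subject_id", "region_id", "stimulus_id", "repeat_index", "response")
  missing_cols <- setdiff(need, names(responses))
  if (length(missing_cols)) {
    visens_stop("visens_invalid_responses", "response table missing columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  responses <- as.data.frame(responses)[need]
  responses$subject_id <- as.character(responses$subject_id)
  responses$region_id <- as.character(responses$region_id)
  responses$stimulus_id <- as.character(responses$stimulus_id)
  responses$repeat_index <- as.integer(responses$repeat_index)
  responses$response <- as.numeric(responses$response)
  obj <- structure(list(
    stimuli = stimuli,
    responses = responses,
    subject_ids = if (is.null(subject_ids)) sort(unique(responses$subject_id))
                  else as.character(subject_ids),
    region_ids = if (is.null(region_ids)) sort(unique(responses$region_id))
                 else as.character(region_ids)
  ), class = "cohort")
  validate_cohort(obj)
  obj
}

#' Validate cohort invariants
#'
#' Checks referential integrity (every record points at an existing
#' stimulus), key uniqueness of (subject, region, stimulus, repeat),
#' finiteness of responses, that every subject has at least one record in
#' every region, and that no (subject, stimulus) has more than 3 repeats.
#' Failures enumerate the offending rows.
#'
#' @param x a `cohort`.
#' @return `x`, invisibly.
#' @export
validate_cohort <- function(x) {
  r <- x$responses
  bad <- which(!is.finite(r$response))
  if (length(bad)) {
    visens_stop("visens_invalid_responses", "non-finite responses at rows: %s",
                paste(utils::head(bad, 10L), collapse = ", "))
  }
  bad <- which(is.na(r$repeat_index) | r$repeat_index < 0L)
  if (length(bad)) {
    visens_stop("visens_invalid_responses", "invalid repeat_index at rows: %s",
                paste(utils::head(bad, 10L), collapse = ", "))
  }
  key <- paste(r$subject_id, r$region_id, r$stimulus_id, r$repeat_index, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    visens_stop("visens_duplicate_key",
                "duplicate (subject, region, stimulus, repeat) keys: %s",
                paste(utils::head(gsub("\r", "/", key[dup]), 5L), collapse = "; "))
  }
  unknown <- setdiff(unique(r$stimulus_id), x$stimuli$info$stimulus_id)
  if (length(unknown)) {
    visens_stop("visens_unknown_stimulus", "records reference unknown stimuli: %s",
                paste(utils::head(unknown, 10L), collapse = ", "))
  }
  have <- unique(r[c("subject_id", "region_id")])
  want <- expand.grid(subject_id = x$subject_ids, region_id = x$region_ids,
                      stringsAsFactors = FALSE)
  miss <- !paste(want$subject_id, want$region_id) %in% paste(have$subject_id, have$region_id)
  if (any(miss)) {
    visens_stop("visens_invalid_responses",
                "subjects missing records for regions: %s",
                paste(paste(want$subject_id[miss], want$region_id[miss], sep = "/"),
                      collapse = ", "))
  }
  nrep <- table(paste(r$subject_id[r$region_id == x$region_ids[1L]],
                      r$stimulus_id[r$region_id == x$region_ids[1L]]))
  if (any(nrep > 3L)) {
    visens_stop("visens_invalid_responses",
                "more than 3 repeats for (subject, stimulus): %s",
                paste(utils::head(names(nrep)[nrep > 3L], 5L), collapse = ", "))
  }
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects x %d regions, %d stimuli (%d shared), %d records\n",
              length(x$subject_ids), length(x$region_ids),
              nrow(x$stimuli$info), sum(x$stimuli$info$shared),
              nrow(x$responses)))
  invisible(x)
}

# ---- on-disk format -------------------------------------------------------

# Numbers are serialized with %.17g so that save -> load is the identity on
# doubles; delimiter chosen from the file extension (.csv comma, .tsv tab).

table_sep <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

write_table_precise <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = table_sep(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

read_table_auto <- function(path) {
  if (!file.exists(path)) {
    visens_stop("visens_io_error", "file not found: %s", path)
  }
  utils::read.table(path, sep = table_sep(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Save a cohort to delimited tables plus a JSON manifest
#'
#' Writes `stimuli.csv` (stimulus_id, shared, optional label, f0..f{d-1}),
#' `responses.csv` (long format) and `manifest.json` with keys
#' `stimuli_file`, `responses_file`, `feature_dim`, `label_vocabulary`.
#' Rows are sorted by (subject, region, stimulus, repeat) so two saves of
#' the same cohort are byte-identical.
#'
#' @param cohort a [cohort()].
#' @param out_dir output directory, created if needed.
#' @return the manifest path, invisibly usable with [load_cohort()].
#' @export
save_cohort <- function(cohort, out_dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    visens_stop("visens_io_error", "cannot create directory: %s", out_dir)
  }
  st <- cohort$stimuli
  stim_df <- st$info
  stim_df <- stim_df[order(stim_df$stimulus_id), , drop = FALSE]
  feats <- as.data.frame(st$features[stim_df$stimulus_id, , drop = FALSE])
  stim_out <- cbind(stim_df, feats)
  rownames(stim_out) <- NULL
  r <- cohort$responses
  r <- r[order(r$subject_id, r$region_id, r$stimulus_id, r$repeat_index), ,
         drop = FALSE]
  stim_path <- file.path(out_dir, "stimuli.csv")
  resp_path <- file.path(out_dir, "responses.csv")
  write_table_precise(stim_out, stim_path)
  write_table_precise(r, resp_path)
  manifest <- list(
    stimuli_file = "stimuli.csv",
    responses_file = "responses.csv",
    feature_dim = ncol(st$features),
    label_vocabulary = if (!is.null(st$info$label)) LABEL_VOCABULARY else character(0),
    subject_ids = cohort$subject_ids,
    region_ids = cohort$region_ids
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  manifest_path
}

#' Load a cohort from a JSON manifest
#'
#' Inverse of [save_cohort()]: `load_cohort(save_cohort(c))` reproduces `c`
#' field by field. All cohort invariants are re-validated on load and
#' violations raise structured errors naming the offending rows.
#'
#' @param manifest_path path to a `manifest.json` written by [save_cohort()]
#'   (or hand-authored with the same keys).
#' @return a [cohort()].
#' @export
load_cohort <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    visens_stop("visens_io_error", "manifest not found: %s", manifest_path)
  }
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  for (key in c("stimuli_file", "responses_file", "feature_dim")) {
    if (is.null(m[[key]])) {
      visens_stop("visens_invalid_manifest", "manifest missing key: %s", key)
    }
  }
  base <- dirname(manifest_path)
  stim_df <- read_table_auto(file.path(base, m$stimuli_file))
  d <- as.integer(m$feature_dim)
  fcols <- paste0("f", seq_len(d) - 1L)
  missing_cols <- setdiff(c("stimulus_id", "shared", fcols), names(stim_df))
  if (length(missing_cols)) {
    visens_stop("visens_invalid_manifest", "stimulus table missing columns: %s",
                paste(missing_cols, collapse = ", "))
  }
  st <- stimulus_set(
    stimulus_id = stim_df$stimulus_id,
    features = as.matrix(stim_df[fcols]),
    label = if ("label" %in% names(stim_df)) stim_df$label else NULL,
    shared = stim_df$shared
  )
  resp_df <- read_table_auto(file.path(base, m$responses_file))
  cohort(st, resp_df,
         subject_ids = if (!is.null(m$subject_ids)) m$subject_ids else NULL,
         region_ids = if (!is.null(m$region_ids)) m$region_ids else NULL)
}
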