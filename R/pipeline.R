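# Per-seizure orchestration: band-pass -> windowed features -> interictal
# model -> Mahalanobis distance over the 6 h search span -> interval
# detection -> channel selection -> feature importance -> report row.

#' Default pipeline configuration
#'
#' All tunables in one nested list, with the study defaults: 0.5--75 Hz
#' band-pass, 6 s / 3 s windows, a 2 h interictal interval ending 6 h
#' before onset, the 99th-percentile threshold, a 15 min minimum interval,
#' a 20% test split, the 75th selection quantile and top-3 features.
#'
#' @return Nested named list; override entries or use [load_config()].
#' @export
default_config <- function() {
  list(
    filter = list(low_hz = 0.5, high_hz = 75, transition_hz = 0.25),
    window_s = 6, hop_s = 3,
    hfd = list(k_max = 8L),
    dfa = list(min_scale = 16L, n_scales = 12L),
    bands = list(delta = c(0.4, 4), theta = c(4, 8), alpha = c(8, 13),
                 beta = c(13, 30), gamma = c(30, 48)),
    interictal = list(duration_h = 2, gap_h = 6),
    detect = list(min_duration_min = 15, percentile = 0.99, ridge = 1e-6),
    select = list(test_fraction = 0.2, quantile = 0.75, seed = 1L),
    logreg = list(C = 1),
    report = list(top_k = 3L)
  )
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]]))
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Load a YAML configuration
#'
#' Reads a YAML file and merges it recursively onto [default_config()],
#' so partial configurations are valid.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  .merge_config(cfg, yaml::read_yaml(path))
}

.empty_row <- function(patient_id = NA_character_,
                       seizure_id = NA_character_) {
  data.frame(
    patient_id = patient_id, seizure_id = seizure_id,
    detected = FALSE,
    preictal_start_min_before_onset = NA_real_,
    preictal_duration_min = NA_real_,
    channel = NA_character_,
    channels_selected = NA_character_,
    top3_features = NA_character_,
    d50 = NA_real_, L99 = NA_real_,
    error = NA_character_, stage = NA_character_,
    stringsAsFactors = FALSE
  )
}

#' Run the full analysis for one seizure
#'
#' Executes the whole per-seizure pipeline on a recording and returns one
#' report row plus diagnostics. The recording is trimmed to the
#' `interictal + gap` hours preceding onset before filtering. A seizure
#' whose preictal interval is not detected yields a `detected = FALSE`
#' row; stage errors are caught and recorded in the row (`error`,
#' `stage`) so batch runs continue.
#'
#' @param rec an [eeg_recording()] (raw; filtering happens here).
#' @param event one-row [seizure_events()] data frame (or a list with
#'   `onset_s`, `seizure_id`).
#' @param config configuration list (see [default_config()]).
#' @return A list with `row` (one-row data frame), `detection`,
#'   `scores`, `ranking` and `distances` (diagnostics; `NULL` where not
#'   reached).
#' @export
run_seizure <- function(rec, event, config = default_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  onset_s <- event$onset_s[1]
  patient_id <- if (!is.null(rec$meta$patient_id)) rec$meta$patient_id else NA_character_
  seizure_id <- if (!is.null(event$seizure_id)) event$seizure_id[1] else "s1"
  row <- .empty_row(patient_id, seizure_id)
  diag <- list(row = row, detection = NULL, scores = NULL,
               ranking = NULL, distances = NULL)
  stage <- "setup"
  out <- tryCatch({
    span_h <- config$interictal$duration_h + config$interictal$gap_h
    t_lo <- onset_s - span_h * 3600
    if (t_lo < -1e-9)
      stop("recording does not cover ", span_h, " h before onset")
    i_lo <- max(1L, as.integer(floor(t_lo * rec$fs)) + 1L)
    i_hi <- min(nrow(rec$signal), as.integer(round(onset_s * rec$fs)))
    sub <- rec  # already validated; just narrow the sample range
    sub$signal <- rec$signal[i_lo:i_hi, , drop = FALSE]
    sub$duration_s <- nrow(sub$signal) / rec$fs
    t_offset <- (i_lo - 1L) / rec$fs

    stage <- "bandpass"
    sub <- bandpass(sub, config$filter$low_hz, config$filter$high_hz,
                    config$filter$transition_hz)

    stage <- "extract_features"
    feat <- extract_features(
      sub, window_s = config$window_s, hop_s = config$hop_s,
      k_max = config$hfd$k_max,
      dfa_min_scale = config$dfa$min_scale,
      dfa_n_scales = config$dfa$n_scales,
      bands = do.call(rbind, config$bands),
      band_lo = config$filter$low_hz, band_hi = config$filter$high_hz,
      t_offset_s = t_offset
    )

    stage <- "fit_interictal_model"
    model <- fit_interictal_model(
      feat, onset_s,
      interictal_duration_h = config$interictal$duration_h,
      gap_h = config$interictal$gap_h,
      percentile = config$detect$percentile,
      ridge_lambda = config$detect$ridge
    )

    stage <- "mahalanobis_series"
    ds <- mahalanobis_series(feat, model)
    diag$distances <- ds

    stage <- "detect_preictal"
    det <- detect_preictal(ds, model,
                           min_duration_min = config$detect$min_duration_min)
    diag$detection <- det
    if (is.null(det$interval)) {
      diag$row <- row
      return(diag)
    }
    iv <- det$interval
    row$detected <- TRUE
    row$preictal_start_min_before_onset <- (onset_s - iv$t1_s) / 60
    row$preictal_duration_min <- (iv$tL_s - iv$t1_s) / 60
    row$channel <- iv$channel
    row$d50 <- iv$d50
    row$L99 <- iv$L99

    stage <- "score_channels"
    ispan <- c(model$interictal_start_s, model$interictal_end_s)
    scores <- score_all_channels(
      feat, iv, ispan, seed = config$select$seed,
      test_fraction = config$select$test_fraction, C = config$logreg$C
    )
    diag$scores <- scores

    stage <- "select_channels"
    # the quantile rule needs >= 4 channels; smaller montages report the
    # single best channel
    selected <- if (nrow(scores) >= 4L)
      select_channels(scores, quantile = config$select$quantile)
    else character(0)
    best <- scores$channel[which.max(scores$f1)]
    if (length(selected) == 0L) selected <- best
    row$channels_selected <- paste(selected, collapse = ";")

    stage <- "rank_features"
    ranking <- rank_features(
      feat, best, iv, ispan, seed = config$select$seed,
      test_fraction = config$select$test_fraction, C = config$logreg$C
    )
    diag$ranking <- ranking
    row$top3_features <- paste(top_features(ranking, config$report$top_k),
                               collapse = ";")
    diag$row <- row
    diag
  }, error = function(e) {
    row$error <- conditionMessage(e)
    row$stage <- stage
    diag$row <- row
    diag
  })
  out
}

#' Run a batch of records
#'
#' Applies the record-quality screen and the seizure inclusion/cluster
#' rules to every manifest entry, runs each retained seizure, and
#' aggregates the per-seizure rows into a report with summary statistics
#' (mean and SD of start times and durations, detected counts). Failures
#' are isolated per record.
#'
#' @param manifest data frame (or list of lists) with columns/fields
#'   `edf` and `annotations` (file paths).
#' @param config configuration list.
#' @return An object of class `analysis_report`: `rows` (one per analyzed
#'   seizure) and `summary`.
#' @export
run_batch <- function(manifest, config = default_config()) {
  if (is.data.frame(manifest)) {
    entries <- lapply(seq_len(nrow(manifest)),
                      function(i) as.list(manifest[i, , drop = FALSE]))
  } else entries <- manifest
  rows <- list()
  for (entry in entries) {
    res <- tryCatch({
      rec <- read_recording(entry$edf)
      ann <- read_annotations(entry$annotations)
      if (flag_noisy(rec)) {
        r <- .empty_row(rec$meta$patient_id, NA_character_)
        r$error <- "record excluded: noisy (over-range time > 10%)"
        r$stage <- "flag_noisy"
        list(r)
      } else {
        events <- select_seizures(ann$events, rec$duration_s)
        lapply(seq_len(nrow(events)), function(i)
          run_seizure(rec, events[i, , drop = FALSE], config)$row)
      }
    }, error = function(e) {
      r <- .empty_row(NA_character_, NA_character_)
      r$error <- conditionMessage(e)
      r$stage <- "read"
      list(r)
    })
    rows <- c(rows, res)
  }
  rows <- if (length(rows)) do.call(rbind, rows) else .empty_row()[0, ]
  structure(list(rows = rows, summary = summarize_report(rows)),
            class = "analysis_report")
}

#' Summary statistics of a report
#'
#' Mean and SD of preictal start times (minutes before onset) and
#' durations over the detected seizures, plus detected/total counts.
#'
#' @param rows report row data frame.
#' @return Named list.
#' @export
summarize_report <- function(rows) {
  det <- rows[which(rows$detected), , drop = FALSE]
  list(
    n_seizures = sum(!is.na(rows$seizure_id)),
    n_detected = nrow(det),
    start_min_mean = if (nrow(det)) mean(det$preictal_start_min_before_onset) else NA_real_,
    start_min_sd = if (nrow(det) > 1) stats::sd(det$preictal_start_min_before_onset) else NA_real_,
    duration_min_mean = if (nrow(det)) mean(det$preictal_duration_min) else NA_real_,
    duration_min_sd = if (nrow(det) > 1) stats::sd(det$preictal_duration_min) else NA_real_
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<analysis_report> %d seizures, %d detected\n",
              s$n_seizures, s$n_detected))
  if (s$n_detected > 0)
    cat(sprintf("  start %.0f +/- %.0f min before onset; duration %.0f +/- %.0f min\n",
                s$start_min_mean, if (is.na(s$start_min_sd)) 0 else s$start_min_sd,
                s$duration_min_mean, if (is.na(s$duration_min_sd)) 0 else s$duration_min_sd))
  invisible(x)
}

#' Write a report to JSON and CSV
#'
#' `<prefix>.csv` holds one row per analyzed seizure (header-only when the
#' report is empty); `<prefix>.json` holds the rows plus the summary.
#'
#' @param report an [run_batch()] result (or a list with `rows`).
#' @param prefix output path prefix.
#' @return Named vector of the two paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  rows <- report$rows
  csv <- paste0(prefix, ".csv")
  js <- paste0(prefix, ".json")
  utils::write.csv(rows, csv, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(rows = rows,
         summary = if (!is.null(report$summary)) report$summary
                   else summarize_report(rows)),
    js, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(c(csv = csv, json = js))
}
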