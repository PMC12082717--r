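#' Construct a multi-channel EEG recording
#'
#' The in-memory container for a scalp EEG record: a samples-by-channels
#' signal matrix in microvolts, the sampling rate, 10--20-system channel
#' labels and the per-channel transducer maximum used by the noisy-record
#' screen.
#'
#' @param signal numeric matrix, samples x channels, in microvolts.
#' @param fs sampling rate in Hz (positive scalar).
#' @param channel_labels character vector of unique channel names, one per
#'   column of `signal`.
#' @param transducer_max physical maximum per channel in microvolts
#'   (recycled if scalar). Defaults to `Inf` (unknown).
#' @param meta named list of identifiers (e.g. `record_id`, `patient_id`).
#' @return An object of class `eeg_recording` with elements `signal`, `fs`,
#'   `channel_labels`, `transducer_max`, `meta` and `duration_s`.
#' @export
eeg_recording <- function(signal, fs, channel_labels,
                          transducer_max = Inf, meta = list()) {
  signal <- as.matrix(signal)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive scalar")
  if (length(channel_labels) != ncol(signal))
    stop("`channel_labels` must have one entry per signal column")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (!all(is.finite(signal)))
    stop("signal must be finite")
  transducer_max <- rep_len(as.numeric(transducer_max), ncol(signal))
  structure(
    list(
      signal = signal,
      fs = fs,
      channel_labels = as.character(channel_labels),
      transducer_max = transducer_max,
      meta = meta,
      duration_s = nrow(signal) / fs
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.2f h)\n",
    ncol(x$signal), nrow(x$signal), x$fs, x$duration_s / 3600
  ))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (length(x$meta)) {
    ids <- x$meta[intersect(names(x$meta), c("record_id", "patient_id"))]
    if (length(ids))
      cat(" ", paste(names(ids), unlist(ids), sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Seizure annotation table
#'
#' @param onset_s,offset_s numeric vectors of seizure start/end times in
#'   seconds from record start.
#' @param seizure_id optional identifiers; defaults to `"s1"`, `"s2"`, ...
#' @param record_duration_s optional record duration used to validate that
#'   `offset_s` does not exceed the record.
#' @return A data frame with columns `seizure_id`, `onset_s`, `offset_s`,
#'   sorted by onset.
#' @export
seizure_events <- function(onset_s, offset_s,
                           seizure_id = NULL, record_duration_s = NULL) {
  if (length(onset_s) != length(offset_s))
    stop("onset and offset must have equal length")
  if (is.null(seizure_id))
    seizure_id <- paste0("s", seq_along(onset_s))
  ok <- onset_s >= 0 & onset_s < offset_s
  if (!all(ok))
    stop("need 0 <= onset_s < offset_s for every event")
  if (!is.null(record_duration_s) && any(offset_s > record_duration_s))
    stop("seizure offset beyond record duration")
  ev <- data.frame(
    seizure_id = as.character(seizure_id),
    onset_s = as.numeric(onset_s),
    offset_s = as.numeric(offset_s),
    stringsAsFactors = FALSE
  )
  ev[order(ev$onset_s), , drop = FALSE]
}
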