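#' Flag a recording as too noisy to analyze
#'
#' A record is considered noisy when more than 10% of its time has values
#' exceeding the transducer's maximum. The fraction is pooled over the
#' whole samples-by-channels array: the proportion of samples whose
#' absolute value strictly exceeds the per-channel transducer maximum.
#'
#' @param rec an [eeg_recording()] with finite `transducer_max`.
#' @param max_fraction flag threshold (default 0.10; strictly greater).
#' @return `TRUE` if the recording should be excluded.
#' @export
flag_noisy <- function(rec, max_fraction = 0.10) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(is.finite(rec$transducer_max)))
    stop("transducer maximum unknown; cannot screen recording")
  over <- sweep(abs(rec$signal), 2L, rec$transducer_max, ">")
  mean(over) > max_fraction
}

#' Apply the seizure inclusion and cluster rules
#'
#' Retains seizures that (a) have at least `min_preonset_h` hours of signal
#' before onset and (b) are either the first retained event or occur at
#' least `cluster_gap_h` hours after the previously retained one. Seizures
#' closer than the gap belong to the same cluster and only the first is
#' analyzed. The scan is greedy left-to-right over onset-sorted events, so
#' the operation is idempotent.
#'
#' @param events a [seizure_events()] data frame.
#' @param record_duration_s record duration in seconds (events ending after
#'   it are rejected).
#' @param min_preonset_h required pre-onset signal, hours (default 8).
#' @param cluster_gap_h minimum onset-to-onset separation, hours
#'   (default 12).
#' @return The retained subset of `events`, onset-sorted.
#' @export
select_seizures <- function(events, record_duration_s,
                            min_preonset_h = 8, cluster_gap_h = 12) {
  if (NROW(events) == 0L) return(events)
  if (any(events$offset_s > record_duration_s))
    stop("seizure offset beyond record duration")
  events <- events[order(events$onset_s), , drop = FALSE]
  keep <- logical(nrow(events))
  last_onset <- -Inf
  for (i in seq_len(nrow(events))) {
    if (events$onset_s[i] < min_preonset_h * 3600) next
    if (events$onset_s[i] - last_onset < cluster_gap_h * 3600) next
    keep[i] <- TRUE
    last_onset <- events$onset_s[i]
  }
  events[keep, , drop = FALSE]
}
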