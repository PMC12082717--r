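# Synthetic multi-channel EEG with a known injected preictal anomaly.
# Baseline channels are stationary colored noise: a weighted sum of five
# resonator-filtered white-noise components (one per classical EEG band)
# whose weights follow a 1/f-like decay. An anomaly crossfades a modified
# resonator bank in on a subset of channels over a contiguous interval,
# so ground truth (interval, channels, mechanism) is known exactly.

.ten_twenty <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                 "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

.band_centers <- c(2, 6, 10.5, 21, 39)
.band_widths <- c(3.5, 4, 5, 17, 18)

# Mechanism intensity scales: chosen once so that `effect_size` is roughly
# the displacement, in interictal standard deviations, of the features the
# mechanism targets (see the methods vignette for the calibration).
.mech_constants <- list(
  tilt_bw = 0.45,      # fractional resonator broadening per effect unit
  tilt_exp = 0.015,    # high-frequency weight tilt exponent per unit
  shift_frac = 0.25,   # band-power fraction moved per unit (band_shift)
  shift_mig = 0.15,    # fractional alpha-peak migration per unit
  drop_narrow = 0.45,  # fractional resonator narrowing per unit
  drop_conc = 0.10     # power concentration per unit (entropy_drop)
)

# RBJ constant-peak-gain band-pass biquad; returns c(b0, b1, b2, a1, a2).
.resonator <- function(fc, bw, fs) {
  w0 <- 2 * pi * fc / fs
  Q <- fc / bw
  alpha <- sin(w0) / (2 * Q)
  a0 <- 1 + alpha
  c(alpha / a0, 0, -alpha / a0, -2 * cos(w0) / a0, (1 - alpha) / a0)
}

.resonator_bank <- function(centers, widths, fs) {
  t(vapply(seq_along(centers),
           function(b) .resonator(centers[b], widths[b], fs),
           numeric(5)))
}

# White-noise gain of each resonator (RMS of the impulse response), used to
# normalize band weights to a target per-band RMS amplitude.
.bank_gains <- function(coefs, widths, fs) {
  vapply(seq_len(nrow(coefs)), function(b) {
    n <- max(4096L, as.integer(32 * fs / widths[b]))
    h <- biquad_filter_cpp(c(1, numeric(n - 1L)), coefs[b, , drop = FALSE])
    sqrt(sum(h^2))
  }, numeric(1))
}

# Baseline and anomaly generator parameters (centers, widths, per-band RMS)
# for a mechanism at a given effect size.
.anomaly_params <- function(mechanism, effect_size, band_rms) {
  k <- .mech_constants
  centers <- .band_centers
  widths <- .band_widths * 0.4   # baseline resonators: peaked band spectra
  rms <- band_rms
  pw <- rms^2
  if (mechanism == "spectral_tilt") {
    widths <- widths * (1 + k$tilt_bw * effect_size)
    w <- rms * (centers / 10)^(k$tilt_exp * effect_size)
    rms <- w * sqrt(sum(pw) / sum(w^2))   # preserve total power
  } else if (mechanism == "band_shift") {
    phi <- min(0.9, k$shift_frac * effect_size)
    moved <- phi * pw[3]                  # alpha -> theta power transfer
    pw[3] <- pw[3] - moved
    pw[2] <- pw[2] + moved
    rms <- sqrt(pw)
    # the residual alpha peak also migrates toward the theta band
    centers[3] <- centers[3] - min(0.85, k$shift_mig * effect_size) *
      (centers[3] - centers[2])
  } else if (mechanism == "entropy_drop") {
    widths <- widths / (1 + k$drop_narrow * effect_size)
    phi <- min(0.9, k$drop_conc * effect_size)
    pw2 <- (1 - phi) * pw
    pw2[3] <- pw2[3] + phi * sum(pw)      # concentrate into alpha
    rms <- sqrt(pw2)
  } else stop("unknown mechanism: ", mechanism)
  list(centers = centers, widths = widths, rms = rms)
}

.expected_features <- function(mechanism) {
  switch(mechanism,
         spectral_tilt = c("spectral_entropy", "hjorth_mobility"),
         band_shift = c("alpha_power", "theta_power"),
         entropy_drop = c("spectral_entropy"))
}

#' Specify a synthetic EEG recording
#'
#' Defines the study conditions for one synthetic record: channel count and
#' rate, total duration, seizure onset time (at least 8 h in, so the
#' inclusion rule is satisfiable), the baseline noise model, and optionally
#' an injected preictal anomaly. The anomaly interval must lie inside the
#' 6 h search span before onset.
#'
#' @param n_channels number of channels (default 19; labeled by the 10--20
#'   system).
#' @param fs sampling rate in Hz (default 256).
#' @param duration_h record duration in hours (default 8.2).
#' @param seizure_onset_h seizure onset in hours from record start
#'   (default 8.1; must be at least 8 and within the record).
#' @param anomaly `NULL` for a null record, or a list with
#'   `start_min_before_onset`, `duration_min`, `channels` (labels),
#'   `mechanism` (one of `"spectral_tilt"`, `"band_shift"`,
#'   `"entropy_drop"`) and `effect_size` (calibrated so that one unit is
#'   roughly one interictal SD of displacement for the targeted features).
#' @param band_rms per-band RMS amplitudes in microvolts
#'   (delta..gamma; the default decays roughly as 1/f).
#' @param transducer_max amplifier physical maximum in microvolts.
#' @param seed RNG seed; generation is bit-reproducible given the spec.
#' @return A validated object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_channels = 19L, fs = 256, duration_h = 8.2,
                           seizure_onset_h = 8.1,
                           anomaly = list(start_min_before_onset = 60,
                                          duration_min = 40,
                                          channels = c("O1", "O2", "Pz"),
                                          mechanism = "spectral_tilt",
                                          effect_size = 4),
                           band_rms = c(10, 6, 5, 3, 1.5),
                           transducer_max = 3276.7, seed = 1L) {
  if (seizure_onset_h < 8)
    stop("seizure_onset_h must be >= 8 (inclusion rule)")
  if (duration_h < seizure_onset_h)
    stop("duration_h must be >= seizure_onset_h")
  labels <- if (n_channels <= length(.ten_twenty)) .ten_twenty[seq_len(n_channels)]
            else c(.ten_twenty, paste0("X", seq_len(n_channels - length(.ten_twenty))))
  if (!is.null(anomaly)) {
    need <- c("start_min_before_onset", "duration_min", "channels",
              "mechanism", "effect_size")
    if (!all(need %in% names(anomaly)))
      stop("anomaly needs fields: ", paste(need, collapse = ", "))
    if (anomaly$effect_size < 0) stop("effect_size must be >= 0")
    if (anomaly$start_min_before_onset > 360)
      stop("anomaly must start within 6 h of onset")
    if (anomaly$duration_min > anomaly$start_min_before_onset)
      stop("anomaly must end at or before seizure onset")
    if (anomaly$duration_min <= 0) stop("anomaly duration must be positive")
    if (!all(anomaly$channels %in% labels))
      stop("anomaly channels must be a subset of the channel labels")
    if (!anomaly$mechanism %in% c("spectral_tilt", "band_shift", "entropy_drop"))
      stop("unknown mechanism: ", anomaly$mechanism)
  }
  if (length(band_rms) != 5L || any(band_rms <= 0))
    stop("band_rms must be 5 positive amplitudes")
  structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         duration_h = duration_h, seizure_onset_h = seizure_onset_h,
         anomaly = anomaly, band_rms = band_rms,
         transducer_max = transducer_max,
         channel_labels = labels, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

#' Generate a synthetic recording with ground truth
#'
#' Baseline channels are strictly stationary outside the anomaly;
#' generation is deterministic given the spec (including its seed). Inside
#' the anomaly interval, only the listed channels crossfade (1 s
#' raised-cosine ramps) to a modified resonator bank: `spectral_tilt`
#' broadens the band resonances and tilts power toward high frequencies
#' (raising spectral entropy and Hjorth mobility), `band_shift` moves
#' power from the alpha into the theta band, and `entropy_drop` narrows
#' the resonances and concentrates power (lowering spectral entropy).
#'
#' @param spec a [synthetic_spec()].
#' @return A list with `recording` (an [eeg_recording()]), `events`
#'   (a [seizure_events()] row for the synthetic seizure) and `truth`
#'   (a list with `t1_s`, `tL_s`, `channels`, `mechanism`, `effect_size`,
#'   `expected_top_features`; `NULL`-interval fields for null records).
#' @export
generate_recording <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  fs <- spec$fs
  n <- as.integer(round(spec$duration_h * 3600 * fs))
  onset_s <- spec$seizure_onset_h * 3600
  base_widths <- .band_widths * 0.4
  base_coefs <- .resonator_bank(.band_centers, base_widths, fs)
  base_w <- spec$band_rms / .bank_gains(base_coefs, base_widths, fs)

  has_anom <- !is.null(spec$anomaly)
  anom_coefs <- base_coefs
  anom_w <- base_w
  t1_s <- tL_s <- NULL
  lo <- hi <- 0
  if (has_anom) {
    a <- spec$anomaly
    t1_s <- onset_s - a$start_min_before_onset * 60
    tL_s <- t1_s + a$duration_min * 60
    lo <- round(t1_s * fs)
    hi <- round(tL_s * fs)
    ap <- .anomaly_params(a$mechanism, a$effect_size, spec$band_rms)
    anom_coefs <- .resonator_bank(ap$centers, ap$widths, fs)
    anom_w <- ap$rms / .bank_gains(anom_coefs, ap$widths, fs)
  }

  set.seed(spec$seed)
  sig <- matrix(0, n, spec$n_channels)
  for (ch in seq_len(spec$n_channels)) {
    white <- stats::rnorm(n)
    affected <- has_anom && spec$channel_labels[ch] %in% spec$anomaly$channels
    sig[, ch] <- synth_channel_cpp(
      white, base_coefs, base_w, anom_coefs, anom_w,
      lo, hi, ramp_n = as.integer(fs), warmup_n = as.integer(10 * fs),
      has_anom = affected
    )
  }
  rec <- eeg_recording(
    sig, fs, spec$channel_labels,
    transducer_max = spec$transducer_max,
    meta = list(record_id = sprintf("synthetic-seed%d", spec$seed),
                patient_id = sprintf("sim%d", spec$seed),
                synthetic = TRUE)
  )
  events <- seizure_events(onset_s, min(onset_s + 60, rec$duration_s))
  truth <- list(
    t1_s = t1_s, tL_s = tL_s,
    channels = if (has_anom) spec$anomaly$channels else character(0),
    mechanism = if (has_anom) spec$anomaly$mechanism else NULL,
    effect_size = if (has_anom) spec$anomaly$effect_size else 0,
    expected_top_features =
      if (has_anom) .expected_features(spec$anomaly$mechanism) else character(0),
    onset_s = onset_s
  )
  list(recording = rec, events = events, truth = truth)
}

#' Generate a null (anomaly-free) synthetic recording
#'
#' @param spec a [synthetic_spec()]; its anomaly, if any, is ignored.
#' @return As [generate_recording()], with an empty ground-truth interval.
#' @export
generate_null_recording <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  spec$anomaly <- NULL
  generate_recording(spec)
}

#' Export a synthetic recording to disk
#'
#' Writes the EDF signal file, the sidecar annotation JSON and the
#' ground-truth JSON (`<name>.edf`, `<name>.json`, `<name>-truth.json`).
#'
#' @param gen a [generate_recording()] result.
#' @param dir output directory (created if needed).
#' @param name file stem (default the record id).
#' @return Named character vector of the three paths, invisibly.
#' @export
export_synthetic <- function(gen, dir, name = NULL) {
  if (is.null(name)) name <- gen$recording$meta$record_id
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edf <- file.path(dir, paste0(name, ".edf"))
  ann <- file.path(dir, paste0(name, ".json"))
  tru <- file.path(dir, paste0(name, "-truth.json"))
  write_edf(gen$recording, edf)
  write_annotations(gen$recording$meta$record_id, gen$events, ann)
  jsonlite::write_json(gen$truth, tru, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(c(edf = edf, annotations = ann, truth = tru))
}
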