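# Small fixtures built in code: stationary colored-noise recordings for
# unit tests, and hand-built windowed_features objects with controlled
# statistics for the model/selection tests.

# AR(1) colored noise, independent of the package's generator.
make_noise_rec <- function(duration_s, n_ch = 2, fs = 256, seed = 1,
                           labels = NULL) {
  set.seed(seed)
  n <- round(duration_s * fs)
  sig <- vapply(seq_len(n_ch), function(ch)
    as.numeric(stats::filter(rnorm(n, sd = 5), 0.9, "recursive")),
    numeric(n))
  if (is.null(labels)) labels <- paste0("CH", seq_len(n_ch))
  eeg_recording(sig, fs, labels, transducer_max = 3000)
}

# A windowed_features object with values drawn from per-channel Gaussians;
# `shift` (features x channels) is added inside [shift_from, shift_to).
make_fake_features <- function(n_win, n_ch, hop_s = 3, window_s = 6,
                               seed = 1, shift = NULL,
                               shift_from = Inf, shift_to = Inf,
                               t0 = 0) {
  set.seed(seed)
  vals <- array(rnorm(n_win * n_ch * 10), dim = c(n_win, n_ch, 10))
  labels <- paste0("CH", seq_len(n_ch))
  times <- t0 + (seq_len(n_win) - 1) * hop_s
  if (!is.null(shift)) {
    rows <- which(times >= shift_from & times + window_s <= shift_to)
    for (ch in seq_len(n_ch))
      vals[rows, ch, ] <- vals[rows, ch, ] +
        matrix(shift[, ch], length(rows), 10, byrow = TRUE)
  }
  dimnames(vals) <- list(NULL, labels, eeg_feature_names)
  structure(
    list(values = vals, window_start_s = times,
         window_s = window_s, hop_s = hop_s, fs = 256,
         channel_labels = labels, feature_names = eeg_feature_names,
         k_max = 8L, dfa_scales = dfa_scales(1536),
         bands = eeg_default_bands, band_lo = 0.5, band_hi = 75,
         mask = matrix(FALSE, n_win, n_ch)),
    class = "windowed_features"
  )
}

# Shared full-scale pipeline runs for the acceptance suite (computed once,
# reused across test blocks).
.accept_cache <- new.env(parent = emptyenv())

accept_recovery_runs <- function() {
  if (!is.null(.accept_cache$recovery)) return(.accept_cache$recovery)
  runs <- list()
  idx <- 0L
  for (dur in c(30, 60, 120)) {
    for (s in 1:20) {
      idx <- idx + 1L
      seed <- 1000L + idx
      ch <- preictalr:::.ten_twenty[(seed %% 4L) + 1L]
      spec <- synthetic_spec(
        n_channels = 4L,
        anomaly = list(start_min_before_onset = dur + 30,
                       duration_min = dur, channels = ch,
                       mechanism = "spectral_tilt", effect_size = 4),
        seed = seed
      )
      gen <- generate_recording(spec)
      res <- run_seizure(gen$recording, gen$events)
      runs[[idx]] <- list(row = res$row, truth = gen$truth,
                          duration_min = dur)
    }
  }
  .accept_cache$recovery <- runs
  runs
}
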