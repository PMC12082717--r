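#' Design the band-pass FIR filter
#'
#' Windowed-sinc (Hamming) linear-phase FIR band-pass, designed with
#' [signal::fir1()]. The number of taps is chosen from the Hamming-window
#' transition-width rule `3.3 * fs / transition_hz`, rounded up to odd, so
#' the low edge at 0.5 Hz is resolved; this makes the filter long
#' (thousands of taps) but it is applied by FFT convolution so the cost is
#' unaffected.
#'
#' @param fs sampling rate in Hz.
#' @param low_hz,high_hz passband edges in Hz (defaults 0.5 and 75).
#' @param transition_hz transition width at the band edges in Hz
#'   (default 0.25).
#' @return Numeric vector of FIR coefficients (odd length, symmetric).
#' @export
design_bandpass_fir <- function(fs, low_hz = 0.5, high_hz = 75,
                                transition_hz = 0.25) {
  if (high_hz >= fs / 2)
    stop("high_hz must be below the Nyquist frequency")
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("need 0 < low_hz < high_hz")
  taps <- ceiling(3.3 * fs / transition_hz)
  if (taps %% 2 == 0) taps <- taps + 1
  as.numeric(signal::fir1(taps - 1L, c(low_hz, high_hz) / (fs / 2),
                          type = "pass"))
}

#' Band-pass filter a recording
#'
#' Removes the constant trend and slow drift below `low_hz` and
#' high-frequency noise above `high_hz` with a linear-phase FIR filter
#' applied zero-phase: the group delay is compensated exactly and edges are
#' handled by signal reflection, so the output has the same length as the
#' input and no phase distortion.
#'
#' @inheritParams design_bandpass_fir
#' @param rec an [eeg_recording()].
#' @return A filtered [eeg_recording()] of identical shape.
#' @export
bandpass <- function(rec, low_hz = 0.5, high_hz = 75, transition_hz = 0.25) {
  stopifnot(inherits(rec, "eeg_recording"))
  h <- design_bandpass_fir(rec$fs, low_hz, high_hz, transition_hz)
  out <- fir_filter_mat_cpp(rec$signal, h)
  dimnames(out) <- dimnames(rec$signal)
  filtered <- rec
  filtered$signal <- out
  filtered$meta$filtered <- c(low_hz = low_hz, high_hz = high_hz)
  filtered
}
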