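# Single-window feature operations (reference implementations) and the
# batch extractor. The batch path runs in compiled code; the functions here
# define the conventions and are cross-checked against it in the tests.

.check_window <- function(window, min_len = 2L) {
  if (!is.numeric(window) || length(window) < min_len)
    stop("window must be a numeric vector of length >= ", min_len)
  if (!all(is.finite(window))) stop("window contains non-finite values")
}

.onesided_power <- function(window) {
  M <- length(window)
  nb <- M %/% 2
  X <- stats::fft(window)
  Mod(X[2:(nb + 1)])^2    # DC bin excluded
}

#' Spectral entropy of a window (bits)
#'
#' Shannon entropy of the one-sided power spectrum normalized to a
#' probability distribution. The DC bin is excluded so the entropy of a
#' window is well defined regardless of its mean.
#'
#' @param window numeric vector of samples.
#' @param fs sampling rate in Hz (kept for interface symmetry; the entropy
#'   itself does not depend on it).
#' @return Entropy in bits, `>= 0`. A single pure tone on an FFT bin gives
#'   0 bits; an equal-power pair of tones gives 1 bit.
#' @export
spectral_entropy <- function(window, fs = NULL) {
  .check_window(window)
  S <- .onesided_power(window)
  tot <- sum(S)
  if (!(tot > 0)) stop("degenerate window: zero spectral power")
  p <- S / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Hjorth mobility
#'
#' Square root of the ratio between the variance of the first difference of
#' the signal and the variance of the signal; a per-sample analogue of the
#' mean frequency. The derivative is the plain first difference (no
#' sampling-rate scaling), so mobility of a sinusoid at digital angular
#' frequency `w` is `2*sin(w/2)`.
#'
#' @param window numeric vector with positive variance.
#' @return Nonnegative scalar.
#' @export
hjorth_mobility <- function(window) {
  .check_window(window)
  v0 <- stats::var(window)
  if (!(v0 > 0)) stop("degenerate window: zero variance")
  sqrt(stats::var(diff(window)) / v0)
}

#' Hjorth complexity
#'
#' Ratio between the mobility of the first difference of the signal and the
#' mobility of the signal itself. A pure sinusoid has minimal complexity
#' (1); broadband signals exceed 1.
#'
#' @param window numeric vector whose first difference has positive
#'   variance.
#' @return Scalar `>= ~1` for non-degenerate signals.
#' @export
hjorth_complexity <- function(window) {
  .check_window(window, min_len = 3L)
  d1 <- diff(window)
  if (!(stats::var(window) > 0) || !(stats::var(d1) > 0))
    stop("degenerate window: zero variance")
  hjorth_mobility(d1) / hjorth_mobility(window)
}

#' Higuchi fractal dimension
#'
#' Curve-length complexity estimate in roughly \[1, 2\]: average normalized
#' curve lengths `L(k)` are computed for lags `k = 1..k_max` and the HFD is
#' the least-squares slope of `log L(k)` against `log(1/k)`. A straight
#' ramp gives 1; white noise approaches 2.
#'
#' @param window numeric vector, longer than `k_max`.
#' @param k_max maximum lag (integer `>= 2`, default 8).
#' @return The fitted slope.
#' @export
higuchi_fd <- function(window, k_max = 8L) {
  .check_window(window, min_len = 3L)
  if (length(k_max) != 1L || !is.finite(k_max) || k_max < 2)
    stop("k_max must be an integer >= 2")
  k_max <- as.integer(k_max)
  if (length(window) <= k_max) stop("window must be longer than k_max")
  N <- length(window)
  Lk <- numeric(k_max)
  for (k in seq_len(k_max)) {
    lm_sum <- 0
    for (m in seq_len(k)) {
      nm <- (N - m) %/% k
      if (nm < 1L) next
      i <- seq_len(nm)
      s <- sum(abs(window[m + i * k] - window[m + (i - 1L) * k]))
      lm_sum <- lm_sum + s * (N - 1) / (nm * k^2)
    }
    Lk[k] <- lm_sum / k
  }
  t <- log(1 / seq_len(k_max))
  y <- log(Lk)
  sum((t - mean(t)) * (y - mean(y))) / sum((t - mean(t))^2)
}

#' Relative band power
#'
#' Fraction of one-sided spectral energy in `[f1, f2)` relative to the
#' total energy in the analysis band (by default the 0.5--75 Hz filter
#' passband), so "fraction of spectral energy" stays well defined after
#' band-pass filtering. Frequency-bin membership uses half-open band edges
#' so adjacent bands never double-count a bin.
#'
#' @param window numeric vector of samples.
#' @param fs sampling rate in Hz.
#' @param f1,f2 band edges in Hz, `0 <= f1 < f2 <= fs/2`.
#' @param band_lo,band_hi analysis-band edges (defaults 0.5 and 75 Hz).
#' @return Fraction in \[0, 1\].
#' @export
band_power <- function(window, fs, f1, f2, band_lo = 0.5, band_hi = 75) {
  .check_window(window)
  if (!(f1 >= 0 && f1 < f2)) stop("need 0 <= f1 < f2")
  if (f2 > fs / 2) stop("f2 must not exceed the Nyquist frequency")
  S <- .onesided_power(window)
  M <- length(window)
  f <- seq_along(S) * fs / M
  eps <- 1e-6
  in_analysis <- f >= band_lo - eps & f <= band_hi + eps
  den <- sum(S[in_analysis])
  if (!(den > 0)) stop("degenerate window: zero power in analysis band")
  num <- sum(S[in_analysis & f >= f1 - eps & f < f2 - eps])
  num / den
}

#' Log-spaced scales for detrended fluctuation analysis
#'
#' @param n window length in samples.
#' @param min_scale smallest scale (default 16 samples).
#' @param n_scales number of candidate log-spaced scales (default 12;
#'   duplicates after rounding are removed).
#' @return Integer vector of distinct scales up to `floor(n/4)`.
#' @export
dfa_scales <- function(n, min_scale = 16L, n_scales = 12L) {
  max_scale <- n %/% 4L
  if (max_scale < min_scale)
    stop("window too short for DFA (need length >= 4 * min_scale)")
  unique(round(exp(seq(log(min_scale), log(max_scale),
                       length.out = n_scales))))
}

#' Detrended fluctuation analysis exponent
#'
#' The signal is converted to a mean-centered cumulative sum, divided into
#' consecutive segments of each scale `n`, and the root-mean-square
#' deviation from the per-segment linear trend is aggregated into `F(n)`.
#' The exponent is the least-squares slope of `log F(n)` on `log n`
#' (about 0.5 for white noise, about 1.5 for Brownian motion).
#'
#' @param window numeric vector of samples.
#' @param scales integer vector of at least 4 distinct scales, each
#'   `<= length(window)/4`; defaults to [dfa_scales()].
#' @return The scaling exponent.
#' @export
dfa <- function(window, scales = NULL) {
  .check_window(window, min_len = 64L)
  n <- length(window)
  if (is.null(scales)) scales <- dfa_scales(n)
  scales <- sort(unique(as.integer(scales)))
  if (length(scales) < 4L) stop("need at least 4 distinct scales")
  if (any(scales < 4L) || max(scales) > n %/% 4L)
    stop("scales must lie in [4, length(window)/4]")
  z <- cumsum(window - mean(window))
  logF <- vapply(scales, function(s) {
    m <- n %/% s
    t <- seq_len(s)
    tc <- t - mean(t)
    sxx <- sum(tc^2)
    sse <- 0
    for (seg in seq_len(m)) {
      zs <- z[((seg - 1L) * s + 1L):(seg * s)]
      zc <- zs - mean(zs)
      ssres <- sum(zc^2) - sum(tc * zc)^2 / sxx
      sse <- sse + ssres / s
    }
    log(sqrt(sse / m))
  }, numeric(1))
  lt <- log(scales)
  sum((lt - mean(lt)) * (logF - mean(logF))) / sum((lt - mean(lt))^2)
}

#' Extract the windowed feature tensor from a recording
#'
#' Computes all ten features (see [eeg_feature_names]) for every channel
#' over sliding windows (6 s length, 3 s hop by default). Windows with zero
#' variance on a channel are degenerate: their feature row is set to `NA`
#' and flagged in the `mask`, and downstream model fitting skips them.
#'
#' @param rec a band-passed [eeg_recording()].
#' @param window_s,hop_s window length and hop in seconds (defaults 6
#'   and 3).
#' @param k_max Higuchi lag parameter (default 8).
#' @param dfa_min_scale,dfa_n_scales DFA scale-grid parameters passed to
#'   [dfa_scales()].
#' @param bands 5 x 2 matrix of band edges (default [eeg_default_bands]).
#' @param band_lo,band_hi analysis band for the band-power denominator.
#' @param t_offset_s time of the first sample relative to the epoch the
#'   window timestamps should use (default 0).
#' @return An object of class `windowed_features`: list with `values`
#'   (windows x channels x 10 array), `window_start_s`, `window_s`,
#'   `hop_s`, `fs`, `channel_labels`, `feature_names` and a logical `mask`
#'   (windows x channels, `TRUE` for degenerate windows).
#' @export
extract_features <- function(rec, window_s = 6, hop_s = 3, k_max = 8L,
                             dfa_min_scale = 16L, dfa_n_scales = 12L,
                             bands = eeg_default_bands,
                             band_lo = 0.5, band_hi = 75,
                             t_offset_s = 0) {
  stopifnot(inherits(rec, "eeg_recording"))
  win_n <- as.integer(round(window_s * rec$fs))
  hop_n <- as.integer(round(hop_s * rec$fs))
  if (nrow(rec$signal) < win_n)
    stop("recording shorter than one analysis window")
  scales <- dfa_scales(win_n, dfa_min_scale, dfa_n_scales)
  vals <- window_features_cpp(rec$signal, rec$fs, win_n, hop_n,
                              as.integer(k_max), as.integer(scales),
                              unname(as.matrix(bands)), band_lo, band_hi)
  n_win <- dim(vals)[1]
  dimnames(vals) <- list(NULL, rec$channel_labels, eeg_feature_names)
  mask <- apply(is.na(vals), c(1, 2), any)
  structure(
    list(
      values = vals,
      window_start_s = t_offset_s + (seq_len(n_win) - 1) * hop_s,
      window_s = window_s, hop_s = hop_s, fs = rec$fs,
      channel_labels = rec$channel_labels,
      feature_names = eeg_feature_names,
      k_max = as.integer(k_max), dfa_scales = scales,
      bands = bands, band_lo = band_lo, band_hi = band_hi,
      mask = mask
    ),
    class = "windowed_features"
  )
}

#' @export
print.windowed_features <- function(x, ...) {
  cat(sprintf(
    "<windowed_features> %d windows x %d channels x %d features (%gs/%gs)\n",
    dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
    x$window_s, x$hop_s
  ))
  if (any(x$mask))
    cat(sprintf("  %d degenerate (masked) window-channel cells\n",
                sum(x$mask)))
  invisible(x)
}

#' Flatten a feature tensor to a data frame
#'
#' One row per window; columns named `channel:feature`.
#'
#' @param x a `windowed_features` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @export
as.data.frame.windowed_features <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  d <- dim(x$values)
  flat <- matrix(aperm(x$values, c(1, 3, 2)), nrow = d[1])
  colnames(flat) <- as.vector(outer(x$feature_names, x$channel_labels,
                                    function(f, ch) paste0(ch, ":", f)))
  out <- data.frame(window_start_s = x$window_start_s, flat,
                    check.names = FALSE)
  out
}

#' Write the feature matrix as CSV
#'
#' @param x a `windowed_features` object.
#' @param path output path.
#' @export
write_features_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
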