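fs <- 256
win_n <- 6 * fs
tt <- (0:(win_n - 1)) / fs

test_that("spectral entropy hits pure-tone limits", {
  # bin-aligned 10 Hz tone: a single nonzero spectral bin
  tone <- sin(2 * pi * 10 * tt)
  expect_equal(spectral_entropy(tone, fs), 0, tolerance = 1e-8)
  # equal-power pair of bin-aligned tones: exactly 1 bit
  pair <- sin(2 * pi * 10 * tt) + cos(2 * pi * 20 * tt)
  expect_equal(spectral_entropy(pair, fs), 1, tolerance = 1e-8)
  # white noise approaches log2(#one-sided bins) from below
  set.seed(11)
  H <- vapply(1:100, function(i) spectral_entropy(rnorm(win_n), fs),
              numeric(1))
  expect_lt(abs(mean(H) - log2(win_n / 2)), 1)
  expect_error(spectral_entropy(rep(2, win_n), fs), "degenerate")
})

test_that("Hjorth parameters match closed forms", {
  for (f0 in c(5, 10, 25)) {
    w0 <- 2 * pi * f0 / fs
    tone <- sin(w0 * (0:(win_n - 1)))
    expect_equal(hjorth_mobility(tone), 2 * sin(w0 / 2), tolerance = 1e-3)
    expect_equal(hjorth_complexity(tone), 1, tolerance = 1e-2)
  }
  set.seed(12)
  mob <- vapply(1:50, function(i) hjorth_mobility(rnorm(win_n)), numeric(1))
  expect_equal(mean(mob), sqrt(2), tolerance = 0.02)
  set.seed(13)
  w <- rnorm(win_n)
  expect_gt(hjorth_complexity(w), 1)
  expect_equal(hjorth_complexity(w), oracle_complexity(w), tolerance = 1e-10)
  expect_error(hjorth_mobility(rep(1, 100)), "degenerate")
  expect_error(hjorth_complexity(rep(0, 100)), "degenerate")
})

test_that("Higuchi fractal dimension spans the ramp-to-noise range", {
  expect_error(higuchi_fd(rnorm(100), k_max = 1), "k_max")
  ramp <- as.numeric(1:win_n)
  expect_equal(higuchi_fd(ramp), 1, tolerance = 0.05)
  set.seed(14)
  fd <- vapply(1:20, function(i) higuchi_fd(rnorm(win_n)), numeric(1))
  expect_equal(mean(fd), 2, tolerance = 0.1)
})

test_that("band powers are fractions of analysis-band energy", {
  tone <- sin(2 * pi * 10 * tt)
  expect_equal(band_power(tone, fs, 8, 13), 1, tolerance = 1e-8)
  for (b in c("delta", "theta", "beta", "gamma")) {
    e <- eeg_default_bands[b, ]
    expect_lt(band_power(tone, fs, e[1], e[2]), 1e-8)
  }
  # white noise: each fraction ~ bandwidth / analysis bandwidth
  set.seed(15)
  fr <- rowMeans(vapply(1:40, function(i) {
    w <- rnorm(win_n)
    vapply(rownames(eeg_default_bands), function(b)
      band_power(w, fs, eeg_default_bands[b, 1], eeg_default_bands[b, 2]),
      numeric(1))
  }, numeric(5)))
  bw <- c(3.5, 4, 5, 17, 18) / 74.5  # effective delta support is 0.5-4 Hz
  expect_equal(unname(fr), unname(bw), tolerance = 0.02)
  # the five fractions never sum above 1
  set.seed(16)
  for (i in 1:10) {
    w <- rnorm(512)
    s <- sum(vapply(rownames(eeg_default_bands), function(b)
      band_power(w, fs, eeg_default_bands[b, 1], eeg_default_bands[b, 2]),
      numeric(1)))
    expect_lte(s, 1 + 1e-12)
  }
  expect_error(band_power(tone, fs, 13, 8), "f1 < f2")
})

test_that("band fractions are monotone under band widening", {
  set.seed(17)
  w <- rnorm(win_n)
  f_grid <- seq(2, 40, by = 2)
  fr <- vapply(f_grid, function(f2) band_power(w, fs, 1, f2), numeric(1))
  expect_true(all(diff(fr) >= -1e-12))
})

test_that("DFA recovers white and Brownian scaling exponents", {
  set.seed(18)
  a_white <- vapply(1:20, function(i) dfa(rnorm(win_n)), numeric(1))
  expect_equal(mean(a_white), 0.5, tolerance = 0.1)
  a_brown <- vapply(1:20, function(i) dfa(cumsum(rnorm(win_n))), numeric(1))
  expect_equal(mean(a_brown), 1.5, tolerance = 0.15)
  expect_error(dfa(rnorm(win_n), scales = 100), "4 distinct")
  expect_error(dfa(rnorm(200), scales = c(10, 20, 40, 80)), "length")
})

test_that("features are invariant to positive amplitude rescaling", {
  set.seed(19)
  w <- rnorm(win_n)
  ops <- list(
    function(x) spectral_entropy(x, fs),
    hjorth_mobility, hjorth_complexity,
    function(x) higuchi_fd(x, 8),
    function(x) band_power(x, fs, 8, 13),
    dfa
  )
  for (a in c(1e-3, 0.5, 7, 1e4)) {
    for (op in ops) {
      expect_equal(op(a * w), op(w), tolerance = 1e-8)
    }
  }
})

test_that("the batch extractor reproduces single-window operations", {
  rec <- make_noise_rec(60, n_ch = 2, seed = 20)
  wf <- extract_features(rec)
  expect_equal(dim(wf$values), c(19, 2, 10))  # floor((60-6)/3)+1 windows
  expect_equal(dimnames(wf$values)[[3]], eeg_feature_names)
  expect_equal(wf$window_start_s, seq(0, by = 3, length.out = 19))
  for (wi in c(1, 7, 19)) {
    for (ch in 1:2) {
      w <- rec$signal[((wi - 1) * 768 + 1):((wi - 1) * 768 + 1536), ch]
      direct <- c(
        spectral_entropy(w, 256), hjorth_mobility(w), hjorth_complexity(w),
        higuchi_fd(w, 8),
        vapply(rownames(eeg_default_bands), function(b)
          band_power(w, 256, eeg_default_bands[b, 1],
                     eeg_default_bands[b, 2]), numeric(1)),
        dfa(w)
      )
      expect_equal(unname(wf$values[wi, ch, ]), unname(direct),
                   tolerance = 1e-10)
    }
  }
})

test_that("degenerate windows are masked, not fatal", {
  rec <- make_noise_rec(30, n_ch = 2, seed = 21)
  rec$signal[2305:4608, 2] <- 0  # flat stretch covering whole windows
  wf <- extract_features(rec)
  expect_true(any(wf$mask[, 2]))
  expect_false(any(wf$mask[, 1]))
  expect_true(all(is.na(wf$values[which(wf$mask[, 2]), 2, ])))
  expect_true(all(is.finite(wf$values[which(!wf$mask[, 2]), 2, ])))
})

test_that("feature frames export with channel:feature headers", {
  rec <- make_noise_rec(30, n_ch = 2, seed = 22)
  wf <- extract_features(rec)
  df <- as.data.frame(wf)
  expect_equal(ncol(df), 1 + 2 * 10)
  expect_true("CH1:spectral_entropy" %in% names(df))
  expect_equal(df[["CH2:dfa"]], unname(wf$values[, 2, "dfa"]))
})
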