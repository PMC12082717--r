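# Independent brute-force oracles for the windowed features and the
# interval search. These deliberately avoid the package's code paths:
# spectra come from an explicit DFT matrix, slopes from lm()/lm.fit(),
# and the interval oracle enumerates every subinterval.

.dft_cache <- new.env(parent = emptyenv())

oracle_periodogram <- function(w) {
  M <- length(w)
  key <- as.character(M)
  if (is.null(.dft_cache[[key]])) {
    m <- 0:(M - 1)
    .dft_cache[[key]] <- exp(-2i * pi * outer(m, m) / M)
  }
  X <- as.vector(.dft_cache[[key]] %*% w)
  Mod(X[2:(M %/% 2 + 1)])^2    # one-sided, DC excluded
}

oracle_spectral_entropy <- function(w) {
  S <- oracle_periodogram(w)
  p <- S / sum(S)
  p <- p[p > 0]
  -sum(p * log2(p))
}

oracle_band_power <- function(w, fs, f1, f2, lo = 0.5, hi = 75) {
  S <- oracle_periodogram(w)
  f <- seq_along(S) * fs / length(w)
  eps <- 1e-6
  keep <- f >= lo - eps & f <= hi + eps
  sum(S[keep & f >= f1 - eps & f < f2 - eps]) / sum(S[keep])
}

oracle_mobility <- function(w) {
  d <- w[-1] - w[-length(w)]
  sqrt(var(d) / var(w))
}

oracle_complexity <- function(w) {
  d <- w[-1] - w[-length(w)]
  oracle_mobility(d) / oracle_mobility(w)
}

oracle_hfd <- function(w, k_max) {
  N <- length(w)
  L <- numeric(k_max)
  for (k in 1:k_max) {
    Lm <- numeric(k)
    for (m in 1:k) {
      nm <- floor((N - m) / k)
      tot <- 0
      for (i in 1:nm)
        tot <- tot + abs(w[m + i * k] - w[m + (i - 1) * k])
      Lm[m] <- tot * (N - 1) / (nm * k^2)
    }
    L[k] <- mean(Lm)
  }
  unname(coef(lm(log(L) ~ log(1 / (1:k_max))))[2])
}

oracle_dfa <- function(w, scales) {
  z <- cumsum(w - mean(w))
  Fn <- vapply(scales, function(s) {
    m <- floor(length(z) / s)
    e2 <- numeric(m)
    for (i in 1:m) {
      seg <- z[((i - 1) * s + 1):(i * s)]
      t <- 1:s
      fit <- lm(seg ~ t)
      e2[i] <- mean(residuals(fit)^2)
    }
    sqrt(mean(e2))
  }, numeric(1))
  unname(coef(lm(log(Fn) ~ log(scales)))[2])
}

# Exhaustive subinterval search over a distance series: among all
# [i, j] with at least min_w windows and both endpoint windows above the
# threshold, maximize the net exceedance count (#d > L99 minus #d <= L99,
# NAs ignored); ties prefer longer, then later. Returns NULL if the best
# net count is not positive or the median criterion fails.
oracle_detect <- function(d, L99, min_w) {
  n <- length(d)
  v <- ifelse(is.na(d), 0, ifelse(d > L99, 1, -1))
  best <- NULL
  for (i in 1:(n - min_w + 1)) {
    if (v[i] != 1) next
    cs <- cumsum(v[i:n])
    for (j in (i + min_w - 1):n) {
      if (v[j] != 1) next
      s <- cs[j - i + 1]
      len <- j - i + 1
      if (is.null(best) || s > best$s ||
          (s == best$s && (len > best$len ||
                           (len == best$len && j > best$j)))) {
        best <- list(s = s, len = len, i = i, j = j)
      }
    }
  }
  if (is.null(best) || best$s <= 0) return(NULL)
  if (!(median(d[best$i:best$j], na.rm = TRUE) > L99)) return(NULL)
  best[c("i", "j")]
}
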