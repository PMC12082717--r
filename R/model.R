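# Patient-specific interictal baseline model and preictal interval
# detection. Each channel gets its own 10-feature Gaussian summary
# (mean + regularized covariance); distances of later windows from that
# baseline are Mahalanobis distances, and the preictal interval is a
# prolonged excursion beyond the baseline's own 99th percentile.

.regularize_cov <- function(S, lambda = 1e-6, max_cond = 1e10) {
  p <- ncol(S)
  base <- sum(diag(S)) / p
  if (!(base > 0)) base <- 1
  repeat {
    Sr <- S + diag(lambda * base, p)
    ev <- eigen(Sr, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) > 0 && max(ev) / min(ev) < max_cond)
      return(list(cov = Sr, lambda = lambda))
    lambda <- lambda * 10
    if (lambda > 1e6) stop("covariance could not be regularized")
  }
}

#' Fit the per-channel interictal feature distribution
#'
#' The interictal interval is the `interictal_duration_h`-hour stretch
#' ending `gap_h` hours before seizure onset. For every channel the
#' windowed feature vectors inside that interval estimate a mean and a
#' covariance; the covariance is ridge-regularized (band powers are
#' linearly constrained so the raw covariance is near singular) by adding
#' `lambda * trace(S)/10` to the diagonal, escalating `lambda` tenfold
#' until the condition number is below 1e10. The detection threshold `L99`
#' is the chosen percentile (linear-interpolation convention) of the
#' training windows' own Mahalanobis distances.
#'
#' @param feat a [extract_features()] result covering the interictal
#'   interval.
#' @param onset_s seizure onset in the same time base as
#'   `feat$window_start_s`.
#' @param interictal_duration_h interictal duration in hours (default 2;
#'   the definition admits 2--4).
#' @param gap_h gap between the interictal interval and onset, hours
#'   (default 6).
#' @param percentile threshold percentile (default 0.99).
#' @param ridge_lambda initial ridge factor (default 1e-6).
#' @param min_train minimum usable training windows per channel
#'   (default 100).
#' @return An object of class `interictal_model`: per-channel list of
#'   `mu`, `cov`, `cov_inv`, `L99`, `n_train`, plus the interval bounds.
#' @export
fit_interictal_model <- function(feat, onset_s, interictal_duration_h = 2,
                                 gap_h = 6, percentile = 0.99,
                                 ridge_lambda = 1e-6, min_train = 100L) {
  stopifnot(inherits(feat, "windowed_features"))
  t1 <- onset_s - gap_h * 3600
  t0 <- t1 - interictal_duration_h * 3600
  ts <- feat$window_start_s
  if (min(ts) > t0 + 1e-9 || max(ts) + feat$window_s < t1 - 1e-9)
    stop("features do not cover the interictal interval [",
         t0, ", ", t1, "] s")
  in_train <- ts >= t0 - 1e-9 & ts + feat$window_s <= t1 + 1e-9
  channels <- feat$channel_labels
  per_channel <- vector("list", length(channels))
  names(per_channel) <- channels
  for (ch in seq_along(channels)) {
    use <- in_train & !feat$mask[, ch]
    X <- feat$values[use, ch, , drop = FALSE]
    X <- matrix(X, ncol = dim(feat$values)[3],
                dimnames = list(NULL, feat$feature_names))
    if (nrow(X) < min_train)
      stop("channel ", channels[ch], ": only ", nrow(X),
           " usable interictal windows (need >= ", min_train, ")")
    mu <- colMeans(X)
    reg <- .regularize_cov(stats::cov(X), ridge_lambda)
    cov_inv <- chol2inv(chol(reg$cov))
    d_train <- sqrt(stats::mahalanobis(X, mu, cov_inv, inverted = TRUE))
    per_channel[[ch]] <- list(
      mu = mu, cov = reg$cov, cov_inv = cov_inv,
      ridge_lambda = reg$lambda,
      L99 = as.numeric(stats::quantile(d_train, percentile, type = 7)),
      n_train = nrow(X)
    )
  }
  structure(
    list(channels = per_channel, channel_labels = channels,
         interictal_start_s = t0, interictal_end_s = t1,
         onset_s = onset_s, percentile = percentile,
         feature_names = feat$feature_names),
    class = "interictal_model"
  )
}

#' @export
print.interictal_model <- function(x, ...) {
  l99 <- vapply(x$channels, `[[`, numeric(1), "L99")
  cat(sprintf(
    "<interictal_model> %d channels, %d training windows, L99 in [%.2f, %.2f]\n",
    length(x$channels), x$channels[[1]]$n_train, min(l99), max(l99)
  ))
  invisible(x)
}

#' Mahalanobis distance series against the interictal baseline
#'
#' For every window in `[t_start_s, t_end_s]` and every channel, the
#' distance `d = sqrt((p - mu)' S^-1 (p - mu))` of the 10-feature point
#' from that channel's interictal distribution. Masked (degenerate)
#' windows propagate as `NA`.
#'
#' @param feat a [extract_features()] result.
#' @param model an [fit_interictal_model()] result.
#' @param t_start_s,t_end_s span to evaluate; defaults to the search span
#'   from the end of the interictal interval to seizure onset.
#' @return An object of class `distance_series`: `times` (window starts),
#'   `d` (windows x channels matrix), `channel_labels`, and the per-channel
#'   thresholds `L99`.
#' @export
mahalanobis_series <- function(feat, model,
                               t_start_s = model$interictal_end_s,
                               t_end_s = model$onset_s) {
  stopifnot(inherits(feat, "windowed_features"),
            inherits(model, "interictal_model"))
  if (!identical(feat$channel_labels, model$channel_labels))
    stop("feature and model channels differ")
  ts <- feat$window_start_s
  use <- ts >= t_start_s - 1e-9 & ts + feat$window_s <= t_end_s + 1e-9
  if (!any(use)) stop("no windows inside the requested span")
  nch <- length(model$channel_labels)
  d <- matrix(NA_real_, sum(use), nch,
              dimnames = list(NULL, model$channel_labels))
  for (ch in seq_len(nch)) {
    m <- model$channels[[ch]]
    X <- matrix(feat$values[use, ch, ], ncol = length(model$feature_names))
    ok <- !feat$mask[use, ch]
    if (any(ok))
      d[ok, ch] <- sqrt(stats::mahalanobis(X[ok, , drop = FALSE],
                                           m$mu, m$cov_inv, inverted = TRUE))
  }
  structure(
    list(times = ts[use], d = d,
         channel_labels = model$channel_labels,
         window_s = feat$window_s, hop_s = feat$hop_s,
         L99 = vapply(model$channels, `[[`, numeric(1), "L99")),
    class = "distance_series"
  )
}

# Core interval scan on one binary/NA exceedance vector. Finds the
# contiguous window index range [i, j] (at least min_windows windows,
# both endpoint windows above threshold) maximizing the net exceedance
# count (#above - #below, NA windows count 0); ties prefer the longer
# interval, then the later one. Requiring above-threshold endpoints keeps
# a short elevated block from being padded with sub-threshold windows
# merely to reach the duration floor. Returns NULL when no qualifying
# interval with positive net exceedance exists.
.scan_exceedance <- function(above, min_windows) {
  v <- ifelse(is.na(above), 0, ifelse(above, 1, -1))
  n <- length(v)
  if (n < min_windows) return(NULL)
  P <- c(0, cumsum(v))
  best <- NULL  # c(sum, len, i, j)
  min_p <- Inf; min_idx <- 0L
  for (j in min_windows:n) {
    k <- j - min_windows + 1L      # new start index available: prefix P[k]
    # strictly smaller prefix wins; an equal prefix keeps the earliest
    # index, which yields the longer interval
    if (v[k] == 1 && P[k] < min_p) { min_p <- P[k]; min_idx <- k }
    if (v[j] != 1 || min_idx == 0L) next
    s <- P[j + 1L] - min_p
    len <- j - min_idx + 1L        # interval is [min_idx, j] in window indices
    if (is.null(best) ||
        s > best[1] ||
        (s == best[1] && (len > best[2] ||
                          (len == best[2] && j > best[4])))) {
      best <- c(s, len, min_idx, j)
    }
  }
  if (is.null(best) || best[1] <= 0) return(NULL)
  list(i = best[3], j = best[4], net = best[1])
}

#' Detect the preictal interval
#'
#' Per channel, finds the contiguous window interval whose Mahalanobis
#' distances most exceed the channel threshold `L99`: the scan maximizes
#' the net exceedance count (#windows above `L99` minus #below; ties go to
#' the longer, then the later interval) among intervals of at least
#' `min_duration_min` minutes, then verifies the defining criteria
#' directly -- the median distance over the interval must exceed `L99`
#' (equivalent to a strict majority of windows above it) and the duration
#' `tL - t1` (first window start to last window end) must reach the
#' minimum. The record-level interval is the detection on the channel with
#' the largest `d50 / L99` ratio; all per-channel detections are retained.
#'
#' @param ds a [mahalanobis_series()] result covering the search span.
#' @param model the matching [fit_interictal_model()].
#' @param min_duration_min minimum interval duration in minutes
#'   (default 15).
#' @return An object of class `preictal_detection`: `interval` (`NULL` or
#'   a list with `t1_s`, `tL_s`, `d50`, `channel`, `L99`), and
#'   `per_channel`, a named list of per-channel detections (or `NULL`s).
#' @export
detect_preictal <- function(ds, model, min_duration_min = 15) {
  stopifnot(inherits(ds, "distance_series"))
  n <- length(ds$times)
  if (n == 0L) stop("empty distance series")
  hop <- ds$hop_s
  win <- ds$window_s
  min_w <- ceiling((min_duration_min * 60 - win) / hop) + 1L
  if (min_w > n)
    stop("distance series shorter than the minimum interval duration")
  per_channel <- vector("list", length(ds$channel_labels))
  names(per_channel) <- ds$channel_labels
  for (ch in seq_along(ds$channel_labels)) {
    L99 <- ds$L99[ch]
    d <- ds$d[, ch]
    hit <- .scan_exceedance(d > L99, min_w)
    if (is.null(hit)) next
    dd <- d[hit$i:hit$j]
    d50 <- stats::median(dd, na.rm = TRUE)
    t1 <- ds$times[hit$i]
    tL <- ds$times[hit$j] + win
    # defining criteria, asserted on every output
    if (!(is.finite(d50) && d50 > L99)) next
    if (!(tL - t1 >= min_duration_min * 60)) next
    per_channel[[ch]] <- list(
      t1_s = t1, tL_s = tL, d50 = d50, L99 = L99,
      ratio = d50 / L99, channel = ds$channel_labels[ch],
      n_windows = hit$j - hit$i + 1L, net_exceedance = hit$net
    )
  }
  detected <- !vapply(per_channel, is.null, logical(1))
  interval <- NULL
  if (any(detected)) {
    ratios <- vapply(per_channel[detected], `[[`, numeric(1), "ratio")
    interval <- per_channel[detected][[which.max(ratios)]]
  }
  structure(list(interval = interval, per_channel = per_channel,
                 min_duration_min = min_duration_min),
            class = "preictal_detection")
}

#' @export
print.preictal_detection <- function(x, ...) {
  if (is.null(x$interval)) {
    cat("<preictal_detection> no interval detected\n")
  } else {
    iv <- x$interval
    cat(sprintf(
      "<preictal_detection> [%.1f, %.1f] min (%.1f min) on %s; d50/L99 = %.2f\n",
      iv$t1_s / 60, iv$tL_s / 60, (iv$tL_s - iv$t1_s) / 60,
      iv$channel, iv$ratio
    ))
    nd <- sum(!vapply(x$per_channel, is.null, logical(1)))
    cat(sprintf("  detections on %d of %d channels\n",
                nd, length(x$per_channel)))
  }
  invisible(x)
}

#' Export the per-channel distance series as CSV
#'
#' Long format (`time_s`, `channel`, `d`) for plotting distance traces.
#'
#' @param ds a [mahalanobis_series()] result.
#' @param path output path.
#' @export
write_distances_csv <- function(ds, path) {
  out <- data.frame(
    time_s = rep(ds$times, times = ncol(ds$d)),
    channel = rep(ds$channel_labels, each = nrow(ds$d)),
    d = as.vector(ds$d)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
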