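# Interictal model fitting, Mahalanobis distances, and interval detection
# are exercised on hand-built feature objects with known statistics.

test_that("interictal model recovers known Gaussian statistics", {
  nf <- 10
  errs <- vapply(1:10, function(s) {
    wf <- make_fake_features(2500, 1, seed = s)
    model <- fit_interictal_model(wf, onset_s = 2500 * 3 + 6 * 3600,
                                  interictal_duration_h = 2)
    max(abs(model$channels[[1]]$mu) / (1 / sqrt(model$channels[[1]]$n_train)))
  }, numeric(1))
  # true mean is 0, unit variance: each coordinate within 3 SE most runs
  expect_lt(mean(errs > 3), 0.35)
  wf <- make_fake_features(2500, 1, seed = 99)
  model <- fit_interictal_model(wf, onset_s = 2500 * 3 + 6 * 3600)
  m <- model$channels[[1]]
  expect_equal(m$cov %*% m$cov_inv, diag(10), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_gt(m$L99, 0)
  expect_gte(m$n_train, 100)
})

test_that("identical training vectors are regularized to a valid model", {
  wf <- make_fake_features(150, 1, seed = 1)
  wf$values[] <- 1  # all feature vectors identical
  model <- fit_interictal_model(wf, onset_s = 150 * 3 + 6 * 3600,
                                interictal_duration_h = 150 * 3 / 3600)
  m <- model$channels[[1]]
  expect_true(all(is.finite(m$cov_inv)))
  d <- sqrt(stats::mahalanobis(matrix(1, 1, 10), m$mu, m$cov_inv,
                               inverted = TRUE))
  expect_equal(d, 0, tolerance = 1e-8)
  expect_equal(m$L99, 0, tolerance = 1e-8)
})

test_that("insufficient interictal coverage raises errors", {
  wf <- make_fake_features(500, 1, seed = 2)
  expect_error(fit_interictal_model(wf, onset_s = 500 * 3 + 6 * 3600,
                                    interictal_duration_h = 4),
               "cover")
  wf2 <- make_fake_features(60, 1, seed = 3)
  expect_error(fit_interictal_model(wf2, onset_s = 60 * 3 + 6 * 3600,
                                    interictal_duration_h = 60 * 3 / 3600),
               "usable interictal windows")
})

test_that("Mahalanobis series matches direct quadratic forms", {
  wf <- make_fake_features(3000, 2, seed = 4)
  onset <- 3000 * 3
  model <- fit_interictal_model(wf, onset, interictal_duration_h = 2,
                                gap_h = 0.4)
  ds <- mahalanobis_series(wf, model)
  expect_true(all(ds$d >= 0, na.rm = TRUE))
  # independent check: solve() on the regularized covariance
  m <- model$channels[[2]]
  idx <- which(wf$window_start_s >= model$interictal_end_s &
                 wf$window_start_s + 6 <= onset)
  p <- wf$values[idx[7], 2, ]
  d_direct <- sqrt(drop(t(p - m$mu) %*% solve(m$cov) %*% (p - m$mu)))
  expect_equal(unname(ds$d[7, 2]), d_direct, tolerance = 1e-10)
  # a point at the mean has zero distance
  expect_equal(
    sqrt(stats::mahalanobis(matrix(m$mu, 1), m$mu, m$cov_inv,
                            inverted = TRUE)), 0)
  # identity covariance reduces to Euclidean distance
  mu <- rep(0, 10)
  p2 <- rnorm(10)
  expect_equal(sqrt(stats::mahalanobis(matrix(p2, 1), mu, diag(10),
                                       inverted = TRUE)),
               sqrt(sum(p2^2)))
})

.mk_series <- function(d, L99, hop_s = 3, window_s = 6) {
  structure(
    list(times = (seq_along(d) - 1) * hop_s, d = matrix(d, ncol = 1,
         dimnames = list(NULL, "CH1")),
         channel_labels = "CH1", window_s = window_s, hop_s = hop_s,
         L99 = c(CH1 = L99)),
    class = "distance_series"
  )
}

.mk_model <- function(L99) {
  structure(list(channels = list(CH1 = list(L99 = L99)),
                 channel_labels = "CH1"),
            class = "interictal_model")
}

test_that("interval detection honors both defining criteria", {
  set.seed(5)
  base <- abs(rnorm(2400, 1, 0.3))  # 2 h of sub-threshold distances
  L99 <- 3

  expect_null(detect_preictal(.mk_series(base, L99), .mk_model(L99))$interval)

  # clean 20-min elevated block: recovered within one hop at each edge
  d <- base
  blk <- 801:1200  # 400 windows = 20 min
  d[blk] <- 5
  det <- detect_preictal(.mk_series(d, L99), .mk_model(L99))
  expect_lte(abs(det$interval$t1_s - 800 * 3), 3 + 1e-9)
  expect_lte(abs(det$interval$tL_s - (1199 * 3 + 6)), 3 + 1e-9)
  expect_gt(det$interval$d50, L99)

  # 10-min block fails the duration floor
  d2 <- base
  d2[801:1000] <- 5
  expect_null(detect_preictal(.mk_series(d2, L99), .mk_model(L99))$interval)

  expect_error(detect_preictal(.mk_series(numeric(0), L99), .mk_model(L99)),
               "empty")
})

test_that("detection equals the exhaustive subinterval oracle", {
  min_w <- 20  # coarse series: 20-window floor (1 min at 3 s hop)
  for (s in 1:25) {
    set.seed(300 + s)
    n <- 160
    d <- abs(rnorm(n, 1, 0.4))
    # embed a noisy elevated stretch in most runs
    if (s %% 5 != 0) {
      len <- sample(25:60, 1)
      i0 <- sample(1:(n - len), 1)
      hot <- runif(len) < 0.65
      d[i0:(i0 + len - 1)][hot] <- 4 + rnorm(sum(hot), 0, 0.3)
    }
    L99 <- 2.5
    det <- detect_preictal(.mk_series(d, L99), .mk_model(L99),
                           min_duration_min = (min_w - 1) * 3 / 60 + 0.1)
    orc <- oracle_detect(d, L99, min_w)
    if (is.null(orc)) {
      expect_null(det$interval)
    } else {
      expect_equal(det$interval$t1_s, (orc$i - 1) * 3)
      expect_equal(det$interval$tL_s, (orc$j - 1) * 3 + 6)
    }
  }
})

test_that("detection is invariant to monotone transforms of distance", {
  set.seed(6)
  d <- abs(rnorm(1000, 1, 0.4))
  d[301:650] <- 4 + rnorm(350, 0, 0.5)
  L99 <- 2.5
  a <- detect_preictal(.mk_series(d, L99), .mk_model(L99))
  b <- detect_preictal(.mk_series(d^2, L99^2), .mk_model(L99^2))
  expect_equal(a$interval$t1_s, b$interval$t1_s)
  expect_equal(a$interval$tL_s, b$interval$tL_s)
})

test_that("median exceedance equals strict majority on an interval", {
  set.seed(7)
  for (i in 1:50) {
    d <- rnorm(101)
    L <- rnorm(1)
    expect_equal(median(d) > L, sum(d > L) > length(d) / 2)
  }
})

test_that("every emitted interval satisfies the defining constraints", {
  set.seed(8)
  for (i in 1:30) {
    d <- abs(rnorm(600, 1, 0.5))
    if (i %% 2 == 0) {
      len <- sample(250:400, 1)
      i0 <- sample(1:(600 - len), 1)
      d[i0:(i0 + len - 1)] <- d[i0:(i0 + len - 1)] + runif(1, 1, 3)
    }
    L99 <- 2
    det <- detect_preictal(.mk_series(d, L99), .mk_model(L99))
    if (!is.null(det$interval)) {
      expect_gte(det$interval$tL_s - det$interval$t1_s, 15 * 60)
      expect_gt(det$interval$d50, L99)
    }
  }
})
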