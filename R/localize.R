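# Channel selection by preictal/interictal separability and feature
# importance from logistic-regression coefficients. Features are z-scored
# with interictal statistics before any fit so coefficient magnitudes are
# comparable across features.

#' F1 score from a confusion count
#'
#' Harmonic mean of precision and recall; 0 when the denominator vanishes.
#'
#' @param tp,fp,fn true-positive, false-positive and false-negative counts.
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(tp, fp, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
}

# Assemble the labeled, z-scored design matrix for one channel:
# preictal windows (positive class) vs interictal windows (negative class),
# masked windows dropped, z-scoring by interictal mean/sd per feature.
.channel_design <- function(feat, ch_idx, preictal, interictal_span) {
  ts <- feat$window_start_s
  win <- feat$window_s
  in_pre <- ts >= preictal$t1_s - 1e-9 & ts + win <= preictal$tL_s + 1e-9
  in_int <- ts >= interictal_span[1] - 1e-9 &
    ts + win <= interictal_span[2] + 1e-9
  ok <- !feat$mask[, ch_idx]
  in_pre <- in_pre & ok
  in_int <- in_int & ok
  if (!any(in_pre) || !any(in_int))
    stop("both classes must be non-empty for channel scoring")
  nf <- dim(feat$values)[3]
  Xp <- matrix(feat$values[in_pre, ch_idx, ], ncol = nf)
  Xi <- matrix(feat$values[in_int, ch_idx, ], ncol = nf)
  mu <- colMeans(Xi)
  s <- apply(Xi, 2, stats::sd)
  s[!(s > 0)] <- 1  # constant features carry no information; leave centered
  X <- rbind(Xi, Xp)
  X <- sweep(sweep(X, 2, mu), 2, s, "/")
  colnames(X) <- feat$feature_names
  list(X = X, y = c(rep(0L, nrow(Xi)), rep(1L, nrow(Xp))))
}

# Deterministic stratified 80/20 split and ridge-logistic fit.
.fit_channel_model <- function(X, y, seed, test_fraction, C) {
  set.seed(seed)
  test <- logical(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_test <- max(1L, floor(length(idx) * test_fraction))
    test[sample(idx, n_test)] <- TRUE
  }
  if (all(test) || !any(test))
    stop("degenerate train/test split")
  n_train <- sum(!test)
  fit <- glmnet::glmnet(X[!test, , drop = FALSE], y[!test],
                        family = "binomial", alpha = 0,
                        lambda = 1 / (C * n_train), standardize = FALSE)
  pred <- as.numeric(stats::predict(fit, X[test, , drop = FALSE],
                                    type = "response") > 0.5)
  truth <- y[test]
  list(
    fit = fit,
    tp = sum(pred == 1 & truth == 1),
    fp = sum(pred == 1 & truth == 0),
    fn = sum(pred == 0 & truth == 1)
  )
}

#' Score one channel's preictal separability
#'
#' Labels that channel's feature windows as preictal (inside the detected
#' record-level interval; positive class) or interictal (inside the
#' baseline interval), z-scores them with interictal statistics, splits
#' them into a stratified 80% train / 20% test partition, fits an
#' L2-penalized logistic regression on the train part and reports the
#' held-out F1 score.
#'
#' @param feat a [extract_features()] result.
#' @param channel channel label.
#' @param preictal detected interval (list with `t1_s`, `tL_s`).
#' @param interictal_span numeric `c(start_s, end_s)` of the interictal
#'   interval.
#' @param seed RNG seed for the split (recorded in the result).
#' @param test_fraction held-out fraction (default 0.2).
#' @param C inverse L2 penalty strength (default 1).
#' @return A list with `channel`, `f1`, `precision`, `recall`, `seed` and
#'   the confusion counts.
#' @export
score_channel <- function(feat, channel, preictal, interictal_span,
                          seed = 1L, test_fraction = 0.2, C = 1) {
  stopifnot(inherits(feat, "windowed_features"))
  ch_idx <- match(channel, feat$channel_labels)
  if (is.na(ch_idx)) stop("unknown channel: ", channel)
  des <- .channel_design(feat, ch_idx, preictal, interictal_span)
  m <- .fit_channel_model(des$X, des$y, seed, test_fraction, C)
  precision <- if (m$tp + m$fp > 0) m$tp / (m$tp + m$fp) else 0
  recall <- if (m$tp + m$fn > 0) m$tp / (m$tp + m$fn) else 0
  list(
    channel = channel,
    f1 = f1_score(m$tp, m$fp, m$fn),
    precision = precision, recall = recall,
    tp = m$tp, fp = m$fp, fn = m$fn, seed = seed
  )
}

#' Score every channel
#'
#' @inheritParams score_channel
#' @return A data frame with one row per channel (`channel`, `f1`,
#'   `precision`, `recall`), in recording channel order.
#' @export
score_all_channels <- function(feat, preictal, interictal_span,
                               seed = 1L, test_fraction = 0.2, C = 1) {
  rows <- lapply(feat$channel_labels, function(ch)
    score_channel(feat, ch, preictal, interictal_span,
                  seed = seed, test_fraction = test_fraction, C = C))
  data.frame(
    channel = vapply(rows, `[[`, "", "channel"),
    f1 = vapply(rows, `[[`, numeric(1), "f1"),
    precision = vapply(rows, `[[`, numeric(1), "precision"),
    recall = vapply(rows, `[[`, numeric(1), "recall"),
    stringsAsFactors = FALSE
  )
}

#' Select the channels most indicative of preictal activity
#'
#' Channels whose F1 score strictly exceeds the 75th percentile
#' (linear-interpolation convention) of the F1 distribution, returned in
#' descending F1 order. Ties at the threshold are excluded; when no
#' channel clears it (e.g. all scores equal) the selection is empty and
#' callers fall back to the single best channel.
#'
#' @param scores data frame from [score_all_channels()] (needs `channel`
#'   and `f1`; at least 4 rows).
#' @param quantile selection quantile (default 0.75).
#' @return Character vector of selected channel labels (possibly empty).
#' @export
select_channels <- function(scores, quantile = 0.75) {
  if (NROW(scores) < 4L)
    stop("channel selection needs at least 4 scored channels")
  q <- as.numeric(stats::quantile(scores$f1, quantile, type = 7))
  sel <- scores[scores$f1 > q, , drop = FALSE]
  sel$channel[order(sel$f1, decreasing = TRUE)]
}

#' Rank features by logistic coefficient magnitude
#'
#' Refits the ridge-logistic model on the best channel (the F1 argmax)
#' using the same stratified split and standardization as
#' [score_channel()], and orders all ten features by the absolute value of
#' their weight coefficients. Ties keep the canonical feature order.
#'
#' @inheritParams score_channel
#' @param channel the best (argmax-F1) channel label.
#' @return An object of class `feature_ranking`: data frame with columns
#'   `feature`, `coefficient`, `abs_coefficient`, ordered nonincreasing by
#'   `abs_coefficient`; the source channel is in `attr(, "channel")`.
#' @export
rank_features <- function(feat, channel, preictal, interictal_span,
                          seed = 1L, test_fraction = 0.2, C = 1) {
  stopifnot(inherits(feat, "windowed_features"))
  ch_idx <- match(channel, feat$channel_labels)
  if (is.na(ch_idx)) stop("unknown channel: ", channel)
  des <- .channel_design(feat, ch_idx, preictal, interictal_span)
  m <- .fit_channel_model(des$X, des$y, seed, test_fraction, C)
  beta <- as.numeric(stats::coef(m$fit))[-1]  # drop intercept
  if (length(beta) != length(feat$feature_names) || anyNA(beta))
    stop("logistic fit did not produce a full coefficient vector")
  ord <- order(-abs(beta), seq_along(beta))
  out <- data.frame(
    feature = feat$feature_names[ord],
    coefficient = beta[ord],
    abs_coefficient = abs(beta[ord]),
    stringsAsFactors = FALSE
  )
  attr(out, "channel") <- channel
  class(out) <- c("feature_ranking", "data.frame")
  out
}

#' Top features of a ranking
#'
#' @param ranking a [rank_features()] result.
#' @param k how many (default 3).
#' @return Character vector of the first `k` feature names.
#' @export
top_features <- function(ranking, k = 3L) {
  utils::head(ranking$feature, k)
}
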