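#' Coefficient of determination against the identity line y = x
#'
#' Measures absolute agreement between measured and estimated weights:
#' `1 - SSE / SST` where the error sum of squares is taken against the
#' 1:1 line (`SSE = sum((y - yhat)^2)` with `yhat` the estimate) and
#' `SST = sum((y - mean(y))^2)` uses the mean of the measured values.
#' Unlike the regression R^2 it can be negative: predictions worse than
#' the plain mean of the measured data give R^2 < 0.
#'
#' @param measured numeric vector of field-measured weights (g); the y.
#' @param estimated numeric vector of LWR-estimated weights (g); the yhat.
#' @return scalar in (-Inf, 1].
#' @export
#' @examples
#' yx_r2(c(1, 2, 3), c(1, 2, 3))  # 1
#' yx_r2(c(1, 2, 3), c(3, 2, 1))  # -3
yx_r2 <- function(measured, estimated) {
  stopifnot(length(measured) == length(estimated), length(measured) > 0)
  sst <- sum((measured - mean(measured))^2)
  if (sst == 0) stop("measured values are all identical (SST = 0)")
  1 - sum((measured - estimated)^2) / sst
}

#' Ordinary least squares fit of measured on estimated weights
#'
#' Fits the first-order regression line of y (measured) on x (estimated),
#' the orientation used throughout the concordance plots, via
#' [stats::lm()].
#'
#' @param x estimated weights (g).
#' @param y measured weights (g).
#' @return list with `slope`, `intercept`, `r2` (regression R^2),
#'   `fitted`, `residuals`, and the underlying `lm` object (`fit`).
#' @export
ols_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (length(unique(x)) < 2) stop("constant x: regression undefined")
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  list(slope = unname(co[2]), intercept = unname(co[1]), r2 = r2,
       fitted = unname(stats::fitted(fit)),
       residuals = unname(stats::residuals(fit)), fit = fit)
}

#' Q outlier scores from MedAD-normalized residuals
#'
#' The residual of each point is the absolute difference between the
#' measured and estimated weight on the raw gram scale; MedAD is the
#' median of these absolute residuals, and `Q_i = residual_i / MedAD`.
#' Scores are invariant under a common positive rescaling of the
#' residuals. Degenerate MedAD = 0: if every residual is zero all scores
#' are 0; otherwise the nonzero residuals score `Inf` (always filtered).
#'
#' @inheritParams yx_r2
#' @param threshold outlier threshold used for `keep` (strict `>`).
#' @return list with `q` (per-point scores), `med_ad`, `residuals`, and
#'   `keep` (logical, `q <= threshold`).
#' @export
#' @examples
#' q_scores(c(1, 2, 3, 100), c(0, 0, 0, 0))$q  # 0.4 0.8 1.2 40
q_scores <- function(measured, estimated, threshold = 6) {
  stopifnot(length(measured) == length(estimated), length(measured) > 0)
  res <- abs(measured - estimated)
  med_ad <- stats::median(res)
  q <- if (med_ad == 0) {
    ifelse(res == 0, 0, Inf)
  } else {
    res / med_ad
  }
  list(q = q, med_ad = med_ad, residuals = res, keep = q <= threshold)
}

#' Remove Q-score outliers from a paired-point table
#'
#' Single pass: Q scores are computed once on the full set and points
#' with `Q > threshold` removed; MedAD is not recomputed after removal.
#'
#' @param points data.frame with `measured_g` and `estimated_g` columns.
#' @param threshold Q threshold (default 6, strict `>`).
#' @return list with `kept` and `removed` data.frames; `removed` carries a
#'   `q` column, and both retain all input columns.
#' @export
filter_q <- function(points, threshold = 6) {
  stopifnot(all(c("measured_g", "estimated_g") %in% names(points)))
  qs <- q_scores(points$measured_g, points$estimated_g, threshold)
  kept <- points[qs$keep, , drop = FALSE]
  removed <- points[!qs$keep, , drop = FALSE]
  removed$q <- qs$q[!qs$keep]
  kept$q <- qs$q[qs$keep]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed, med_ad = qs$med_ad, q = qs$q)
}

#' Cook's distances for the simple concordance regression
#'
#' Deletion influence of each point on the OLS fit of measured (y) on
#' estimated (x): `D_i = sum_j (yhat_j - yhat_j(i))^2 / (p * MSE)` with
#' p = 2 predictors (slope + intercept) and MSE from the full fit.
#' Computed through the leverage closed form of [stats::cooks.distance()],
#' which is algebraically identical to the deletion definition. A fit
#' with all residuals zero (points exactly on a line) has no deletion
#' influence and returns all zeros rather than 0/0.
#'
#' @param x estimated weights (g).
#' @param y measured weights (g).
#' @param cutoff influence threshold for `influential`; default `4/n`.
#' @return list with `d` (per-point distances), `p` (= 2), `mse` (full-fit
#'   mean squared error, SSE / (n - p)), `cutoff`, `influential` (logical,
#'   `d > cutoff`).
#' @export
cooks_distance <- function(x, y, cutoff = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4)
  if (length(unique(x)) < 2) stop("constant x: regression undefined")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  p <- 2L
  mse <- sum(res^2) / (n - p)
  scale_y <- max(abs(y), 1)
  d <- if (mse <= (.Machine$double.eps * scale_y)^2) {
    rep(0, n)
  } else {
    unname(stats::cooks.distance(fit))
  }
  d[!is.finite(d)] <- 0
  if (is.null(cutoff)) cutoff <- 4 / n
  list(d = d, p = p, mse = mse, cutoff = cutoff, influential = d > cutoff)
}

#' Remove influential points by Cook's distance
#'
#' Single pass: distances are computed once on the input set and points
#' above the cutoff removed. The rule is configurable because no single
#' convention is universal: `list(rule = "4n")` (default) uses the
#' conventional `D_i > 4/n` cutoff; `list(rule = "fixed", cutoff = c)` a
#' fixed cutoff; `list(rule = "top_k", k = k)` removes the k largest
#' distances (ties broken by first occurrence).
#'
#' @param points data.frame with `measured_g` (y) and `estimated_g` (x).
#' @param rule list describing the cutoff rule (see Details).
#' @return list with `kept`, `removed` (both with a `cooks_d` column),
#'   `d`, `cutoff` (NA for top_k).
#' @export
filter_influential <- function(points, rule = list(rule = "4n")) {
  stopifnot(all(c("measured_g", "estimated_g") %in% names(points)))
  n <- nrow(points)
  cd <- cooks_distance(points$estimated_g, points$measured_g)
  kind <- rule$rule %||% "4n"
  if (kind == "4n") {
    cutoff <- 4 / n
    drop <- cd$d > cutoff
  } else if (kind == "fixed") {
    cutoff <- rule$cutoff
    stopifnot(is.numeric(cutoff), length(cutoff) == 1)
    drop <- cd$d > cutoff
  } else if (kind == "top_k") {
    k <- as.integer(rule$k)
    stopifnot(k >= 0, k < n)
    cutoff <- NA_real_
    drop <- rep(FALSE, n)
    if (k > 0) drop[order(cd$d, decreasing = TRUE)[seq_len(k)]] <- TRUE
  } else {
    stop("unknown Cook's-distance rule: ", kind)
  }
  points$cooks_d <- cd$d
  kept <- points[!drop, , drop = FALSE]
  removed <- points[drop, , drop = FALSE]
  rownames(kept) <- rownames(removed) <- NULL
  list(kept = kept, removed = removed, d = cd$d, cutoff = cutoff)
}

#' Root-mean-square error between measured and estimated weights
#' @inheritParams yx_r2
#' @return RMSE in g.
#' @export
rmse <- function(measured, estimated) {
  stopifnot(length(measured) == length(estimated), length(measured) > 0)
  sqrt(mean((measured - estimated)^2))
}

#' Mean absolute error between measured and estimated weights
#' @inheritParams yx_r2
#' @return MAE in g.
#' @export
mae <- function(measured, estimated) {
  stopifnot(length(measured) == length(estimated), length(measured) > 0)
  mean(abs(measured - estimated))
}

#' Log-scale IQR outlier screen
#'
#' Descriptive screen on the weight distribution: weights are
#' log-transformed (natural log) and values outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` flagged, the usual boxplot whisker
#' rule. Quartiles use [stats::quantile()] type 7 (linear interpolation),
#' so the screen is reproducible bit-for-bit. The screen only reports;
#' it removes nothing from the pipeline.
#'
#' @param weights positive weights (g).
#' @param k whisker multiplier (default 1.5).
#' @return list with `outlier` (logical), `lower`/`upper` fence on the
#'   log scale, `q1`, `q3`.
#' @export
iqr_outlier_screen <- function(weights, k = 1.5) {
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("weights must be finite and > 0")
  }
  lw <- log(weights)
  qs <- stats::quantile(lw, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- qs[2] - qs[1]
  lower <- qs[1] - k * iqr
  upper <- qs[2] + k * iqr
  list(outlier = lw < lower | lw > upper, lower = lower, upper = upper,
       q1 = qs[1], q3 = qs[2])
}
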