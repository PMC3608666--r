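# First-order decay fits to native-contact fraction series.
#
# The fit is linear least squares of ln q versus t (matching the log-scale
# presentation of unbinding kinetics), so rate and half-time come with
# closed-form standard errors from the slope covariance.

#' Fit first-order decay kinetics to a Q series
#'
#' Fits `ln q = a - k t` by ordinary least squares over the fit window and
#' reports the rate `k` (ps^-1), the half-time `ln 2 / k` (ps) and its
#' standard error propagated from the slope standard error
#' (`se_half = ln2 * se_k / k^2`). Fits with `k <= 0` are flagged
#' non-decaying (`half_time = NA`).
#'
#' @param series a [q_series()] (or any list with `times` and the channel
#'   vector).
#' @param channel `"qf"` or `"qb"`.
#' @param window numeric `c(t_start, t_end)` in ps; default the first 80%
#'   of frames (mirroring equilibration-trimmed trajectory analysis).
#' @return object of class `kinetics_fit`.
#' @export
fit_first_order <- function(series, channel = c("qb", "qf"), window = NULL) {
  channel <- match.arg(channel)
  t <- series$times
  q <- series[[channel]]
  if (is.null(q) || all(is.na(q)))
    stop("channel ", channel, " is undefined for this series")
  if (is.null(window)) {
    n80 <- max(2L, floor(0.8 * length(t)))
    window <- c(t[1L], t[n80])
  }
  in_win <- t >= window[1L] & t <= window[2L]
  t <- t[in_win]; q <- q[in_win]
  if (length(t) < 5L) stop("need at least 5 frames in the fit window")
  if (any(q <= 0, na.rm = TRUE) || anyNA(q))
    stop("q <= 0 (or NA) inside the fit window: truncate the window to the ",
         "region where the series stays positive before the log-linear fit")
  fit <- stats::lm(log(q) ~ t)
  sm <- suppressWarnings(summary(fit))   # noiseless fits are legitimate here
  k <- -unname(stats::coef(fit)[2L])
  se_k <- unname(sm$coefficients[2L, 2L])
  non_decaying <- k <= 1e-12
  half <- if (non_decaying) NA_real_ else log(2) / k
  se_half <- if (non_decaying) NA_real_ else log(2) * se_k / k^2
  structure(list(rate = k, se_rate = se_k,
                 half_time = half, se_half_time = se_half,
                 r_squared = sm$r.squared,
                 fit_window = window, n = length(t),
                 channel = channel, non_decaying = non_decaying,
                 intercept = unname(stats::coef(fit)[1L])),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("first-order kinetics fit (channel ", x$channel, ", ", x$n,
      " frames, t in [", x$fit_window[1L], ", ", x$fit_window[2L],
      "] ps)\n", sep = "")
  if (x$non_decaying) {
    cat(sprintf("  non-decaying: k = %.3g ps^-1 (flagged)\n", x$rate))
  } else {
    cat(sprintf("  k = %.5g +/- %.2g ps^-1\n", x$rate, x$se_rate))
    cat(sprintf("  half-time = %.4g +/- %.2g ps   (R^2 = %.4f)\n",
                x$half_time, x$se_half_time, x$r_squared))
  }
  invisible(x)
}

#' @export
coef.kinetics_fit <- function(object, ...) {
  c(rate = object$rate, half_time = object$half_time,
    intercept = object$intercept)
}

#' @export
predict.kinetics_fit <- function(object, times, ...) {
  exp(object$intercept - object$rate * times)
}

#' Average replicate Q series and fit the mean curve
#'
#' Replicate series must share an identical time grid; their channel
#' values are averaged per timestamp and [fit_first_order()] is applied to
#' the mean curve. Per-replica fits are also computed, and the
#' across-replica standard deviation of the half-time is reported
#' alongside the fit standard error (the two need not agree).
#'
#' @param series_list list of [q_series()] objects on a common time grid.
#' @inheritParams fit_first_order
#' @return a `kinetics_fit` with extra fields `n_replicas`,
#'   `half_time_sd_across` and `replica_fits`.
#' @export
averaged_fit <- function(series_list, channel = c("qb", "qf"),
                         window = NULL) {
  channel <- match.arg(channel)
  stopifnot(length(series_list) >= 1L)
  t0 <- series_list[[1L]]$times
  for (s in series_list)
    if (length(s$times) != length(t0) || any(abs(s$times - t0) > 1e-9))
      stop("replicate series must share an identical time grid")
  qmat <- vapply(series_list, function(s) s[[channel]], numeric(length(t0)))
  mean_series <- structure(list(times = t0), class = "q_series")
  mean_series[[channel]] <- rowMeans(qmat)
  fit <- fit_first_order(mean_series, channel, window)
  reps <- lapply(series_list, function(s)
    tryCatch(fit_first_order(s, channel, window), error = function(e) NULL))
  halfs <- vapply(reps, function(f)
    if (is.null(f)) NA_real_ else f$half_time, 0)
  fit$n_replicas <- length(series_list)
  fit$half_time_sd_across <- stats::sd(halfs, na.rm = TRUE)
  fit$replica_fits <- reps
  fit
}

#' @export
plot.kinetics_fit <- function(x, series = NULL, ...) {
  if (!is.null(series)) {
    graphics::plot(series$times, series[[x$channel]], log = "y",
                   xlab = "time (ps)", ylab = x$channel, pch = 16,
                   cex = 0.6, ...)
  } else {
    tt <- seq(x$fit_window[1L], x$fit_window[2L], length.out = 100L)
    graphics::plot(tt, predict(x, tt), type = "n", log = "y",
                   xlab = "time (ps)", ylab = x$channel, ...)
  }
  tt <- seq(x$fit_window[1L], x$fit_window[2L], length.out = 100L)
  graphics::lines(tt, predict(x, tt), col = "red3", lwd = 2)
  invisible(x)
}
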