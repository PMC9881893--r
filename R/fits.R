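# The four kinematic parameter fits. Each fitting function returns a classed
# S3 model object with print, summary, coef and predict methods; fits are
# always on raw per-bout / per-IBI points (binned averages are display-only).

# ---- vertex-form parabola: bout timing ------------------------------------

#' Fit the bout-timing parabola
#'
#' Least-squares fit of bout frequency on IBI pitch with the vertex-form
#' model \eqn{y = a(x-b)^2 + c}: `a` is the sensitivity to posture changes
#' (reported in mHz/deg^2), `b` the pitch at which movement rate is minimal,
#' and `c` the baseline bout rate. The fit is an ordinary quadratic
#' regression; vertex-form coefficients and their standard errors follow by
#' the delta method from the polynomial coefficients' covariance.
#'
#' @param ibis an [extract_ibis()] data.frame (`mean_pitch`,
#'   `bout_frequency`), or any data.frame with columns `x` and `y`.
#' @return object of class `parabola_fit`: `a` (Hz/deg^2), `sensitivity_mhz`
#'   (= 1000 a), `b`, `c`, `se` (named, for a, b, c), `r_squared`, `n`.
#' @export
fit_bout_timing <- function(ibis) {
  xy <- .xy_of(ibis, xcol = "mean_pitch", ycol = "bout_frequency")
  x <- xy$x; y <- xy$y
  if (length(unique(x)) < 3)
    stop("need at least 3 distinct pitch values for a parabola fit")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  if (!is.finite(cf[3]) || cf[3] == 0)
    stop("degenerate pitch spread: quadratic coefficient is zero")
  a <- unname(cf[3]); b <- unname(-cf[2] / (2 * cf[3]))
  cc <- unname(cf[1] - cf[2]^2 / (4 * cf[3]))
  V <- suppressWarnings(stats::vcov(fit))   # noise-free data is legitimate
  g_a <- c(0, 0, 1)
  g_b <- c(0, -1 / (2 * cf[3]), cf[2] / (2 * cf[3]^2))
  g_c <- c(1, -cf[2] / (2 * cf[3]), cf[2]^2 / (4 * cf[3]^2))
  se <- c(a = sqrt(drop(g_a %*% V %*% g_a)),
          b = sqrt(drop(g_b %*% V %*% g_b)),
          c = sqrt(drop(g_c %*% V %*% g_c)))
  if (cc < 0) warning("fitted baseline rate c is negative")
  r2 <- suppressWarnings(summary(fit)$r.squared)   # noise-free data is fine
  structure(list(a = a, b = b, c = cc, sensitivity_mhz = 1000 * a,
                 se = se, r_squared = r2, n = length(x),
                 data = data.frame(x = x, y = y)),
            class = "parabola_fit")
}

#' @export
print.parabola_fit <- function(x, ...) {
  cat(sprintf("Bout-timing parabola: y = a(x - b)^2 + c  (n = %d, R^2 = %.3f)\n",
              x$n, x$r_squared))
  cat(sprintf("  sensitivity a = %.3f mHz/deg^2 (SE %.3f)\n",
              x$sensitivity_mhz, 1000 * x$se["a"]))
  cat(sprintf("  vertex b      = %.2f deg (SE %.2f)\n", x$b, x$se["b"]))
  cat(sprintf("  baseline c    = %.3f Hz (SE %.3f)\n", x$c, x$se["c"]))
  invisible(x)
}

#' @export
coef.parabola_fit <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @export
predict.parabola_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) (newdata$x %||% newdata$mean_pitch) else newdata
  object$a * (x - object$b)^2 + object$c
}

#' @export
summary.parabola_fit <- function(object, ...) {
  out <- data.frame(
    term = c("a (Hz/deg^2)", "b (deg)", "c (Hz)"),
    estimate = c(object$a, object$b, object$c),
    se = unname(object$se))
  attr(out, "r_squared") <- object$r_squared
  attr(out, "n") <- object$n
  out
}

# ---- straight lines: steering and righting --------------------------------

.xy_of <- function(data, xcol, ycol) {
  if (all(c("x", "y") %in% names(data))) return(list(x = data$x, y = data$y))
  if (all(c(xcol, ycol) %in% names(data)))
    return(list(x = data[[xcol]], y = data[[ycol]]))
  stop("data must have columns (x, y) or (", xcol, ", ", ycol, ")")
}

.ols_line <- function(x, y, kind, n_min = 2) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < n_min) stop("need at least ", n_min, " points")
  if (stats::var(x) == 0) stop("zero variance in x; line is undefined")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  sm <- suppressWarnings(summary(fit))   # noise-free data is legitimate here
  r <- suppressWarnings(stats::cor(x, y))
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 slope_se = sm$coefficients[2, 2],
                 intercept_se = sm$coefficients[1, 2],
                 pearson_r = r, r_squared = sm$r.squared,
                 n = length(x), kind = kind,
                 data = data.frame(x = x, y = y)),
            class = "line_fit")
}

#' Fit the steering line
#'
#' Ordinary least squares of pitch at the time of peak speed (y) on bout
#' trajectory (x). The slope is the steering gain: a gain of 1 means the
#' trajectory is fully explained by the posture at peak speed.
#'
#' @param features a [bout_features()] data.frame (`trajectory`,
#'   `pitch_at_peak`), or any data.frame with columns `x` and `y`.
#' @return object of class `line_fit` with `slope` (= steering gain),
#'   `intercept`, `slope_se`, `pearson_r`, `r_squared`, `n`.
#' @export
fit_steering <- function(features) {
  xy <- .xy_of(features, "trajectory", "pitch_at_peak")
  .ols_line(xy$x, xy$y, kind = "steering")
}

#' Fit the righting line
#'
#' Ordinary least squares of righting rotation (y) on initial pitch (x). As
#' righting is corrective the slope is negative; the righting gain is the
#' negated slope and the set point is the x-intercept (the initial posture
#' that elicits no righting rotation). A non-negative slope is reported with
#' a warning (non-corrective behavior).
#'
#' @param features a [bout_features()] data.frame (`initial_pitch`,
#'   `righting_rotation`), or any data.frame with columns `x` and `y`.
#' @return `line_fit` object additionally carrying `righting_gain`
#'   (= -slope) and `set_point` (= -intercept/slope).
#' @export
fit_righting <- function(features) {
  xy <- .xy_of(features, "initial_pitch", "righting_rotation")
  fit <- .ols_line(xy$x, xy$y, kind = "righting")
  if (fit$slope >= 0)
    warning("righting slope is non-negative: behavior is not corrective")
  fit$righting_gain <- -fit$slope
  fit$set_point <- -fit$intercept / fit$slope
  fit
}

#' @export
print.line_fit <- function(x, ...) {
  cat(sprintf("%s line fit (n = %d): y = %.4f x + %.4f\n",
              switch(x$kind, steering = "Steering", righting = "Righting",
                     "Linear"),
              x$n, x$slope, x$intercept))
  cat(sprintf("  slope SE %.4f, Pearson r %.3f, R^2 %.3f\n",
              x$slope_se, x$pearson_r, x$r_squared))
  if (!is.null(x$righting_gain))
    cat(sprintf("  righting gain %.3f, set point %.2f deg\n",
                x$righting_gain, x$set_point))
  invisible(x)
}

#' @export
coef.line_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.line_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  object$intercept + object$slope * x
}

#' @export
summary.line_fit <- function(object, ...) {
  out <- data.frame(term = c("intercept", "slope"),
                    estimate = c(object$intercept, object$slope),
                    se = c(object$intercept_se, object$slope_se))
  attr(out, "r_squared") <- object$r_squared
  attr(out, "n") <- object$n
  out
}

# ---- logistic: fin-body coordination --------------------------------------

#' Fit the fin-body sigmoid
#'
#' Least-squares fit of attack angle (y) on steering-related rotation (x)
#' with the four-parameter logistic \eqn{y = a + h / (1 + e^{-k(x+b)})},
#' under the constraints \eqn{h \ge 0}, \eqn{k \ge 0}. The fin-body ratio is
#' the sigmoid's maximal slope, \eqn{kh/4}. Fitting is multi-start
#' Levenberg-Marquardt (sigmoid least squares is multimodal); the best
#' converged start by residual sum of squares wins.
#'
#' When called on [bout_features()] data, bouts slower than `min_speed` are
#' dropped first, and bouts whose steering rotation exceeds the median of the
#' kept set *while* having a negative attack angle are excluded (`n_excluded`
#' reports how many). A plain (x, y) data.frame is fitted as-is.
#'
#' @param features a [bout_features()] data.frame (`steering_related_rotation`,
#'   `attack_angle`, `peak_speed`, `steering_rotation`) or a data.frame with
#'   columns `x` and `y`.
#' @param min_speed mm/s; peak-speed floor for inclusion.
#' @param n_min minimum number of points after filtering.
#' @return object of class `logistic_fit`: `a`, `b`, `k`, `h`, `se` (named),
#'   `vcov` (4x4), `fin_body_ratio` (= k h / 4), `ratio_se` (from
#'   [finbody_slope_variance()]), `r_squared`, `n_used`, `n_excluded`.
#' @export
fit_fin_body <- function(features, min_speed = 7, n_min = 10) {
  if (all(c("x", "y") %in% names(features))) {
    x <- features$x; y <- features$y
    n_excluded <- 0L
  } else {
    stopifnot(all(c("steering_related_rotation", "attack_angle") %in%
                    names(features)))
    keep <- if ("peak_speed" %in% names(features))
      features$peak_speed >= min_speed else rep(TRUE, nrow(features))
    f <- features[keep, , drop = FALSE]
    sr <- if ("steering_rotation" %in% names(f)) f$steering_rotation else
      f$steering_related_rotation
    med <- stats::quantile(sr, 0.5, names = FALSE)
    excl <- sr > med & f$attack_angle < 0
    n_excluded <- sum(excl)
    f <- f[!excl, , drop = FALSE]
    x <- f$steering_related_rotation; y <- f$attack_angle
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < n_min)
    stop("too few bouts after filtering (", length(x), " < ", n_min, ")")

  rng_y <- range(y); h0 <- max(diff(rng_y), 1e-3)
  starts <- list(
    c(a = rng_y[1], b = -stats::median(x), k = 0.5, h = h0),
    c(a = rng_y[1], b = -stats::median(x), k = 2, h = h0),
    c(a = stats::quantile(y, 0.05, names = FALSE), b = 0, k = 1,
      h = max(stats::quantile(y, 0.95, names = FALSE) -
                stats::quantile(y, 0.05, names = FALSE), 1e-3)),
    c(a = rng_y[1], b = -mean(x), k = 0.2, h = h0),
    c(a = mean(y) - h0 / 4, b = 0, k = 5, h = h0 / 2)
  )
  dat <- data.frame(x = x, y = y)
  best <- NULL; best_sse <- Inf
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a + h / (1 + exp(-k * (x + b))), data = dat,
                        start = as.list(st),
                        lower = c(a = -90, b = -45, k = 0, h = 0),
                        upper = c(a = 90, b = 45, k = 10, h = 90),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (sse < best_sse) { best <- fit; best_sse <- sse }
  }
  if (is.null(best))
    stop("logistic fit failed to converge from all starts (n = ", length(x),
         ", x range ", paste(signif(range(x), 3), collapse = " to "), ")")
  cf <- stats::coef(best)
  V <- tryCatch(stats::vcov(best), error = function(e)
    matrix(NA_real_, 4, 4, dimnames = list(names(cf), names(cf))))
  ratio <- unname(cf["k"] * cf["h"]) / 4
  ratio_var <- finbody_slope_variance(E_k = unname(cf["k"]),
                                      E_h = unname(cf["h"]),
                                      V_k = V["k", "k"], V_h = V["h", "h"])
  sst <- sum((y - mean(y))^2)
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]),
                 k = unname(cf["k"]), h = unname(cf["h"]),
                 se = sqrt(diag(V)), vcov = V,
                 fin_body_ratio = ratio, ratio_se = sqrt(ratio_var),
                 r_squared = 1 - best_sse / sst,
                 n_used = length(x), n_excluded = as.integer(n_excluded),
                 data = dat),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("Fin-body logistic fit: y = a + h/(1 + exp(-k(x + b)))  (n = %d, %d excluded)\n",
              x$n_used, x$n_excluded))
  cat(sprintf("  a = %.3f deg, b = %.3f deg, k = %.3f /deg, h = %.3f deg\n",
              x$a, x$b, x$k, x$h))
  cat(sprintf("  fin-body ratio kh/4 = %.3f (SE %.3f), R^2 = %.3f\n",
              x$fin_body_ratio, x$ratio_se, x$r_squared))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) {
  c(a = object$a, b = object$b, k = object$k, h = object$h)
}

#' @export
predict.logistic_fit <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  logistic4(x, object$a, object$b, object$k, object$h)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  out <- data.frame(term = c("a", "b", "k", "h", "fin_body_ratio"),
                    estimate = c(object$a, object$b, object$k, object$h,
                                 object$fin_body_ratio),
                    se = c(unname(object$se), object$ratio_se))
  attr(out, "r_squared") <- object$r_squared
  out
}

# ---- shared methods over the fitted data ----------------------------------

#' @export
residuals.parabola_fit <- function(object, ...) {
  object$data$y - predict(object, object$data)
}

#' @export
residuals.line_fit <- function(object, ...) {
  object$data$y - predict(object, object$data)
}

#' @export
residuals.logistic_fit <- function(object, ...) {
  object$data$y - predict(object, object$data)
}

# scatter of the fitted data, binned averages for display, and the fitted
# curve; the standard way this family of relationships is drawn
.plot_fit <- function(object, bin_width, xlab, ylab, main, ...) {
  d <- object$data
  graphics::plot(d$x, d$y, pch = 16, cex = 0.3,
                 col = grDevices::adjustcolor("grey40", 0.4),
                 xlab = xlab, ylab = ylab, main = main, ...)
  if (nrow(d) > 20) {
    b <- binned_average(d$x, d$y, bin_width)
    graphics::points(b$x_mean, b$y_mean, pch = 15, col = "brown")
  }
  xs <- seq(min(d$x), max(d$x), length.out = 300)
  graphics::lines(xs, predict(object, xs), lwd = 2)
  invisible(object)
}

#' @export
plot.parabola_fit <- function(x, bin_width = 3, ...) {
  .plot_fit(x, bin_width, xlab = "IBI pitch (deg)",
            ylab = "bout frequency (Hz)", main = "Bout timing", ...)
}

#' @export
plot.line_fit <- function(x, bin_width = 3, ...) {
  lab <- switch(x$kind,
                steering = c("trajectory (deg)", "pitch at peak speed (deg)",
                             "Steering"),
                righting = c("initial pitch (deg)", "righting rotation (deg)",
                             "Righting"),
                c("x", "y", "Line fit"))
  .plot_fit(x, bin_width, xlab = lab[1], ylab = lab[2], main = lab[3], ...)
}

#' @export
plot.logistic_fit <- function(x, bin_width = 0.8, ...) {
  .plot_fit(x, bin_width, xlab = "steering-related rotation (deg)",
            ylab = "attack angle (deg)", main = "Fin-body coordination", ...)
}
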