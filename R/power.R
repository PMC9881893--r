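# Resampling-based resolution analysis: confidence-interval width versus
# sample size, logistic-slope variance propagation, and effect-size (Cohen's
# d) simulation under imposed fractional changes.

#' Resampling configuration
#'
#' @param n_resamples resamples per sample size (default 20).
#' @param confidence confidence level for CI widths (default 0.95).
#' @return list of class `resample_config`.
#' @export
resample_config <- function(n_resamples = 20, confidence = 0.95) {
  stopifnot(n_resamples >= 2, confidence > 0, confidence < 1)
  structure(list(n_resamples = n_resamples, confidence = confidence),
            class = "resample_config")
}

#' Effect-size simulation configuration
#'
#' @param inner_reps resamples per distribution (default 200).
#' @param outer_reps repetitions of the whole procedure (default 20).
#' @param fixed_angvel_lead ms; the fixed time of peak angular velocity used
#'   for steering-related rotation in fin-body fits during simulation.
#' @return list of class `effect_size_config`.
#' @export
effect_size_config <- function(inner_reps = 200, outer_reps = 20,
                               fixed_angvel_lead = 40) {
  stopifnot(inner_reps >= 2, outer_reps >= 1)
  structure(list(inner_reps = inner_reps, outer_reps = outer_reps,
                 fixed_angvel_lead = fixed_angvel_lead),
            class = "effect_size_config")
}

#' Variance of the fin-body ratio k h / 4
#'
#' Propagates the variances of the logistic coefficients k and h to the
#' variance of the sigmoid's maximal slope:
#' \deqn{V = (E_k^2 V_h + E_h^2 V_k + V_k V_h) / 16.}
#'
#' @param E_k,E_h means of k and h.
#' @param V_k,V_h their variances (>= 0).
#' @return variance of k h / 4.
#' @examples
#' finbody_slope_variance(2, 10, 0.01, 0.25)  # 0.12515625
#' @export
finbody_slope_variance <- function(E_k, E_h, V_k, V_h) {
  if (any(c(V_k, V_h) < 0)) stop("variances must be non-negative")
  (E_k^2 * V_h + E_h^2 * V_k + V_k * V_h) * (1 / 4)^2
}

# Fast estimate + SE of one relationship's headline parameter on (x, y).
# Closed forms for the linear and quadratic fits; Levenberg-Marquardt for
# the logistic (whose SE comes from finbody_slope_variance).
.fit_param_fast <- function(relationship, x, y) {
  n <- length(x)
  if (relationship %in% c("steering", "righting")) {
    mx <- mean(x); my <- mean(y)
    sxx <- sum((x - mx)^2)
    if (sxx == 0) stop("zero variance in x")
    slope <- sum((x - mx) * (y - my)) / sxx
    resid <- y - my - slope * (x - mx)
    se <- sqrt(sum(resid^2) / (n - 2) / sxx)
    list(estimate = slope, se = se)
  } else if (relationship == "timing") {
    X <- cbind(1, x, x * x)
    XtX <- crossprod(X)
    cf <- tryCatch(drop(solve(XtX, crossprod(X, y))),
                   error = function(e) stop("singular quadratic design"))
    resid <- y - drop(X %*% cf)
    s2 <- sum(resid^2) / (n - 3)
    V <- s2 * chol2inv(chol(XtX))
    # sensitivity in mHz/deg^2
    list(estimate = 1000 * cf[3], se = 1000 * sqrt(V[3, 3]))
  } else if (relationship == "finbody") {
    fit <- fit_fin_body(data.frame(x = x, y = y))
    list(estimate = fit$fin_body_ratio, se = fit$ratio_se)
  } else stop("unknown relationship: ", relationship)
}

.xy_for_relationship <- function(data, relationship) {
  if (all(c("x", "y") %in% names(data)))
    return(data.frame(x = data$x, y = data$y))
  cols <- switch(relationship,
    timing = c("mean_pitch", "bout_frequency"),
    steering = c("trajectory", "pitch_at_peak"),
    finbody = c("steering_related_rotation", "attack_angle"),
    righting = c("initial_pitch", "righting_rotation"))
  if (!all(cols %in% names(data)))
    stop("data must have columns (x, y) or (", paste(cols, collapse = ", "), ")")
  data.frame(x = data[[cols[1]]], y = data[[cols[2]]])
}

#' Confidence-interval width versus sample size
#'
#' For each sample size N, draws N points with replacement from the dataset,
#' fits the relationship, and converts the parameter's standard error to a
#' normal-approximation CI width, \eqn{2 z_{1-\alpha/2} \cdot SE}; repeated
#' `n_resamples` times per N. For the fin-body ratio the SE comes from
#' [finbody_slope_variance()]. A resample whose fit fails is redrawn and
#' counted, so silent bias is visible.
#'
#' @param data a data.frame with columns `x`, `y` (or the relationship's
#'   feature columns: IBIs for `timing`, bout features otherwise).
#' @param relationship `"timing"`, `"steering"`, `"finbody"` or `"righting"`.
#' @param sample_sizes vector of N.
#' @param cfg a [resample_config()].
#' @param seed integer seed.
#' @return data.frame of class `ci_width_table`: `parameter`, `n`,
#'   `mean_width`, `sd_width`, `n_redrawn`.
#' @export
ci_width_vs_n <- function(data, relationship, sample_sizes,
                          cfg = resample_config(), seed = 1L) {
  relationship <- match.arg(relationship,
                            c("timing", "steering", "finbody", "righting"))
  xy <- .xy_for_relationship(data, relationship)
  z <- stats::qnorm(1 - (1 - cfg$confidence) / 2)
  set.seed(as.integer(seed))
  rows <- lapply(sample_sizes, function(N) {
    widths <- numeric(cfg$n_resamples)
    redrawn <- 0L
    for (r in seq_len(cfg$n_resamples)) {
      for (try in 1:20) {
        idx <- sample.int(nrow(xy), N, replace = TRUE)
        est <- tryCatch(.fit_param_fast(relationship, xy$x[idx], xy$y[idx]),
                        error = function(e) NULL)
        if (!is.null(est) && is.finite(est$se)) break
        redrawn <- redrawn + 1L
        est <- NULL
      }
      if (is.null(est)) stop("fit failed repeatedly at N = ", N)
      widths[r] <- 2 * z * est$se
    }
    data.frame(parameter = relationship, n = N,
               mean_width = mean(widths), sd_width = stats::sd(widths),
               n_redrawn = redrawn)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ci_width_table", "data.frame")
  out
}

#' Impose a fractional effect on a dataset
#'
#' Builds an altered dataset in which the relationship's target coefficient
#' (timing sensitivity a; steering slope; righting slope; fin-body maximal
#' slope, via k) is scaled by `1 + fraction` while every other coefficient
#' and the y residuals at the given x values are preserved:
#' \eqn{y_{new}(x) = f_{altered}(x) + (y(x) - f_{orig}(x))}.
#'
#' @param data data.frame with `x`, `y` (or feature columns).
#' @param relationship the relationship name.
#' @param fraction signed fractional change (not -1).
#' @param fitted_model optional pre-computed fit of `data` (a
#'   `parabola_fit`, `line_fit` or `logistic_fit`); fitted when omitted.
#' @return data.frame with `x` and altered `y`; attributes `fraction` and
#'   `relationship`.
#' @export
impose_effect <- function(data, relationship, fraction, fitted_model = NULL) {
  relationship <- match.arg(relationship,
                            c("timing", "steering", "finbody", "righting"))
  if (fraction == -1) stop("fraction -1 removes the coefficient entirely")
  xy <- .xy_for_relationship(data, relationship)
  if (is.null(fitted_model)) {
    fitted_model <- switch(relationship,
      timing = fit_bout_timing(data.frame(x = xy$x, y = xy$y)),
      steering = fit_steering(xy),
      righting = fit_righting(xy),
      finbody = fit_fin_body(xy))
  }
  f_orig <- predict(fitted_model, xy)
  f_alt <- switch(relationship,
    timing = (fitted_model$a * (1 + fraction)) * (xy$x - fitted_model$b)^2 +
      fitted_model$c,
    steering = ,
    righting = fitted_model$intercept +
      fitted_model$slope * (1 + fraction) * xy$x,
    finbody = logistic4(xy$x, fitted_model$a, fitted_model$b,
                        fitted_model$k * (1 + fraction), fitted_model$h))
  out <- data.frame(x = xy$x, y = f_alt + (xy$y - f_orig))
  attr(out, "fraction") <- fraction
  attr(out, "relationship") <- relationship
  out
}

#' Effect-size (Cohen's d) curves over sample size and imposed change
#'
#' For each (fraction, N) pair: N points are drawn with replacement from the
#' original dataset and, independently, from the dataset with the imposed
#' effect; the relationship is fit to each draw; repeating `inner_reps` times
#' yields two distributions of parameter values, and the effect size is
#' Cohen's d, \eqn{d = (\mu_{sim} - \mu_{ori}) / \sigma}, with \eqn{\sigma}
#' the SD of all `2 * inner_reps` pooled values. The whole procedure is
#' repeated `outer_reps` times and the mean d (and its SD) reported.
#' Non-convergent fits are redrawn and counted.
#'
#' @param data data.frame with `x`, `y` (or feature columns; for `finbody`
#'   the steering-related rotation is expected to use the fixed
#'   `cfg$fixed_angvel_lead` convention upstream).
#' @param relationship the relationship name.
#' @param fractions signed fractional changes to impose.
#' @param sample_sizes vector of N.
#' @param cfg an [effect_size_config()].
#' @param seed integer seed.
#' @return data.frame of class `effect_size_table`: `parameter`, `fraction`,
#'   `n`, `d_mean`, `d_sd`, `n_redrawn`.
#' @export
effect_size_curve <- function(data, relationship, fractions, sample_sizes,
                              cfg = effect_size_config(), seed = 1L) {
  relationship <- match.arg(relationship,
                            c("timing", "steering", "finbody", "righting"))
  xy <- .xy_for_relationship(data, relationship)
  set.seed(as.integer(seed))
  one_estimate <- function(d, N, redraw_counter) {
    for (try in 1:20) {
      idx <- sample.int(nrow(d), N, replace = TRUE)
      est <- tryCatch(.fit_param_fast(relationship, d$x[idx], d$y[idx])$estimate,
                      error = function(e) NULL)
      if (!is.null(est) && is.finite(est)) return(est)
      redraw_counter$n <- redraw_counter$n + 1L
    }
    stop("fit failed repeatedly at N = ", N)
  }
  rows <- list()
  for (fr in fractions) {
    altered <- impose_effect(xy, relationship, fr)
    for (N in sample_sizes) {
      cnt <- new.env(); cnt$n <- 0L
      d_vals <- numeric(cfg$outer_reps)
      for (o in seq_len(cfg$outer_reps)) {
        ori <- vapply(seq_len(cfg$inner_reps), function(i)
          one_estimate(xy, N, cnt), 0)
        sim <- vapply(seq_len(cfg$inner_reps), function(i)
          one_estimate(altered, N, cnt), 0)
        d_vals[o] <- (mean(sim) - mean(ori)) / stats::sd(c(sim, ori))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = relationship, fraction = fr, n = N,
        d_mean = mean(d_vals),
        d_sd = if (cfg$outer_reps > 1) stats::sd(d_vals) else NA_real_,
        n_redrawn = cnt$n)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("effect_size_table", "data.frame")
  out
}
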