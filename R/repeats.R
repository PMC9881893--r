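# Per-repeat aggregation and cross-condition comparison.

.repeat_params <- function(feat, ibis, min_bouts = 10) {
  timing <- fit_bout_timing(ibis)
  steering <- fit_steering(feat)
  righting <- fit_righting(feat)
  finbody <- fit_fin_body(feat)
  c(sensitivity = timing$sensitivity_mhz,
    baseline_rate = timing$c,
    timing_vertex = timing$b,
    steering_gain = steering$slope,
    fin_body_ratio = finbody$fin_body_ratio,
    sigmoid_height = finbody$h,
    righting_gain = righting$righting_gain,
    set_point = righting$set_point,
    ibi_pitch_sd = stats::sd(ibis$mean_pitch))
}

#' Per-repeat kinematic parameters and their across-repeat summary
#'
#' Computes every kinematic parameter (bout-timing sensitivity and baseline
#' rate, steering gain, fin-body ratio and sigmoid height, righting gain and
#' set point, IBI-pitch SD) separately for each experimental repeat, then
#' reports the mean and SD across repeats — the convention used for
#' reference tables — alongside fits pooled over all repeats. Repeats with
#' too few bouts or IBIs are skipped with a warning.
#'
#' @param features a [bout_features()] data.frame with a `repeat_id` column.
#' @param ibis an [extract_ibis()] data.frame with a `repeat_id` column.
#' @param min_bouts minimum bouts (and IBIs) for a repeat to be fit.
#' @param condition optional condition label carried into the report.
#' @return list of class `kinematics_report`: `per_repeat` (one row per
#'   repeat, one column per parameter), `summary` (parameter, mean, sd,
#'   n_repeats), `pooled` (list of the four pooled fit objects), `condition`.
#' @export
analyze_repeats <- function(features, ibis, min_bouts = 10,
                            condition = "all") {
  stopifnot("repeat_id" %in% names(features), "repeat_id" %in% names(ibis))
  reps <- intersect(unique(features$repeat_id), unique(ibis$repeat_id))
  if (!length(reps)) stop("no repeat present in both bouts and IBIs")
  rows <- list()
  for (r in reps) {
    f <- features[features$repeat_id == r, , drop = FALSE]
    ib <- ibis[ibis$repeat_id == r, , drop = FALSE]
    if (nrow(f) < min_bouts || nrow(ib) < min_bouts) {
      warning("repeat ", r, " skipped: too few bouts/IBIs")
      next
    }
    pars <- tryCatch(.repeat_params(f, ib, min_bouts),
                     error = function(e) {
                       warning("repeat ", r, " skipped: ", conditionMessage(e))
                       NULL
                     })
    if (is.null(pars)) next
    rows[[r]] <- data.frame(repeat_id = r, t(pars))
  }
  if (!length(rows)) stop("no repeat could be fit")
  per_repeat <- do.call(rbind, rows)
  rownames(per_repeat) <- NULL
  par_cols <- setdiff(names(per_repeat), "repeat_id")
  summ <- data.frame(
    parameter = par_cols,
    mean = vapply(par_cols, function(p) mean(per_repeat[[p]]), 0),
    sd = vapply(par_cols, function(p)
      if (nrow(per_repeat) > 1) stats::sd(per_repeat[[p]]) else 0, 0),
    n_repeats = nrow(per_repeat))
  rownames(summ) <- NULL
  pooled <- list(timing = fit_bout_timing(ibis),
                 steering = fit_steering(features),
                 righting = fit_righting(features),
                 finbody = fit_fin_body(features))
  structure(list(per_repeat = per_repeat, summary = summ, pooled = pooled,
                 condition = condition),
            class = "kinematics_report")
}

#' @export
print.kinematics_report <- function(x, ...) {
  cat("Kinematics report (", x$condition, "), ",
      nrow(x$per_repeat), " repeat(s): mean (SD) across repeats\n", sep = "")
  with(x$summary, for (i in seq_along(parameter))
    cat(sprintf("  %-15s %8.3f (%.3f)\n", parameter[i], mean[i], sd[i])))
  invisible(x)
}

#' Percent differences between two parameter sets
#'
#' Signed percent change of each shared parameter, `100 * (other/ref - 1)`.
#' Accepts [analyze_repeats()] reports (their across-repeat means are
#' compared) or plain named numeric vectors. Parameters whose reference value
#' is zero are flagged with `NA`.
#'
#' @param report_ref,report_other `kinematics_report` objects or named
#'   numeric vectors.
#' @return data.frame with `parameter`, `ref`, `other`, `percent`.
#' @export
compare_profiles <- function(report_ref, report_other) {
  as_vec <- function(r) {
    if (inherits(r, "kinematics_report"))
      stats::setNames(r$summary$mean, r$summary$parameter)
    else if (is.numeric(r) && !is.null(names(r))) r
    else stop("expected a kinematics_report or a named numeric vector")
  }
  a <- as_vec(report_ref); b <- as_vec(report_other)
  shared <- intersect(names(a), names(b))
  if (!length(shared)) stop("no shared parameters to compare")
  pct <- ifelse(a[shared] == 0, NA_real_, 100 * (b[shared] / a[shared] - 1))
  if (anyNA(pct)) warning("reference value 0: percent change undefined")
  data.frame(parameter = shared, ref = unname(a[shared]),
             other = unname(b[shared]), percent = unname(pct))
}
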