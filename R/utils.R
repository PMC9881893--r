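# Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Centered moving average
#'
#' Smooths a numeric series with a centered window; near the edges the window
#' shrinks symmetrically so the output has the same length as the input and no
#' NA padding. A window of 1 returns the input unchanged.
#'
#' @param x numeric vector.
#' @param k odd integer window width in samples.
#' @return numeric vector, same length as `x`.
#' @keywords internal
moving_average <- function(x, k) {
  stopifnot(is.numeric(x), k >= 1)
  k <- as.integer(k)
  if (k %% 2L == 0L) stop("smoothing window must be odd")
  if (k == 1L || length(x) <= 1L) return(x)
  h <- (k - 1L) %/% 2L
  n <- length(x)
  cs <- cumsum(c(0, x))
  out <- numeric(n)
  for (i in seq_len(n)) {
    hh <- min(h, i - 1L, n - i)
    out[i] <- (cs[i + hh + 1L] - cs[i - hh]) / (2L * hh + 1L)
  }
  out
}

# Moments of a normal truncated below at `lower`.
trunc_norm_moments <- function(mu, sigma, lower) {
  mu <- unname(mu); sigma <- unname(sigma)
  a <- (lower - mu) / sigma
  lam <- stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  m <- mu + sigma * lam
  v <- sigma^2 * (1 + a * lam - lam^2)
  c(mean = m, sd = sqrt(v))
}

# Solve for the parent normal's (mu, sigma) such that truncation below at
# `lower` yields the observed mean/sd. Used so that detected (super-threshold)
# speed distributions reproduce printed summary statistics exactly.
match_truncated_normal <- function(mean_obs, sd_obs, lower) {
  stopifnot(mean_obs > lower, sd_obs > 0)
  obj <- function(p) {
    m <- trunc_norm_moments(p[1], exp(p[2]), lower)
    (m["mean"] - mean_obs)^2 + (m["sd"] - sd_obs)^2
  }
  fit <- stats::optim(c(mean_obs, log(sd_obs)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
  out <- c(mu = fit$par[1], sigma = exp(fit$par[2]))
  chk <- trunc_norm_moments(out["mu"], out["sigma"], lower)
  if (abs(chk["mean"] - mean_obs) > 1e-6 * max(1, abs(mean_obs)) ||
      abs(chk["sd"] - sd_obs) > 1e-6 * max(1, sd_obs))
    stop("truncated-normal moment matching failed to converge")
  out
}

# Draw from a normal truncated below at `lower` by inverse-CDF sampling.
rtrunc_norm <- function(n, mu, sigma, lower) {
  p0 <- stats::pnorm((lower - mu) / sigma)
  u <- stats::runif(n, p0, 1)
  mu + sigma * stats::qnorm(u)
}

# Elevation angle (deg) of a displacement vector, nose-up positive and
# invariant to left/right heading; range (-90, 90].
elevation_angle <- function(dx, dz) {
  ang <- atan2(dz, abs(dx)) * 180 / pi
  ang[dx == 0 & dz == 0] <- 0
  ang
}

logistic4 <- function(x, a, b, k, h) a + h / (1 + exp(-k * (x + b)))
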