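steer_data <- function(n = 4000, gain = 0.67, resid = 6, seed = 51) {
  generate_relationship_samples(
    "steering", list(gain = gain, intercept = 0.86, x_mean = 8.92,
                     x_sd = 20.19, resid_sd = resid), n = n, seed = seed)
}

test_that("variance propagation matches the closed form and Monte Carlo", {
  # direct evaluation of the propagation formula
  expect_equal(finbody_slope_variance(2, 10, 0.01, 0.25), 0.12515625)
  expect_equal(finbody_slope_variance(2, 10, 0, 0), 0)
  expect_error(finbody_slope_variance(2, 10, -0.1, 0.2), "non-negative")
  # Monte-Carlo oracle at small coefficients of variation (<= 0.1)
  set.seed(61)
  k <- rnorm(1e6, 2, 0.1); h <- rnorm(1e6, 10, 0.5)
  expect_equal(finbody_slope_variance(2, 10, 0.1^2, 0.5^2),
               var(k * h / 4), tolerance = 0.01)
})

test_that("CI width follows 2 z SE and shrinks like 1/sqrt(N)", {
  # the width rule itself: SE 0.1 at 95% gives 0.392
  expect_equal(2 * qnorm(0.975) * 0.1, 0.392, tolerance = 1e-3)
  d <- steer_data()
  tab <- ci_width_vs_n(d, "steering", c(250, 500, 1000, 2000),
                       cfg = resample_config(n_resamples = 10), seed = 2)
  expect_true(all(diff(tab$mean_width) < 0))
  sl <- coef(lm(log(mean_width) ~ log(n), data = tab))[2]
  expect_lt(abs(sl + 0.5), 0.1)
  # zero-noise data: width collapses toward zero at large N
  d0 <- steer_data(resid = 1e-8)
  tab0 <- ci_width_vs_n(d0, "steering", nrow(d0),
                        cfg = resample_config(n_resamples = 5), seed = 3)
  expect_lt(tab0$mean_width, 1e-9)
})

test_that("imposed effects scale the target coefficient and keep residuals", {
  d <- steer_data(n = 500)
  same <- impose_effect(d, "steering", 0)
  expect_equal(same$y, d$y, tolerance = 1e-12)
  fit0 <- fit_steering(d)
  alt <- impose_effect(d, "steering", 0.10, fit0)
  # residuals preserved exactly
  expect_equal(alt$y - predict(fit0, alt) - 0.1 * fit0$slope * alt$x,
               d$y - predict(fit0, d), tolerance = 1e-12)
  # noise-free line: refit slope is exactly 1.1x the original
  line <- data.frame(x = 1:50, y = 2 * (1:50) + 1)
  lfit <- suppressWarnings(fit_steering(line))
  alt2 <- impose_effect(line, "steering", 0.1, lfit)
  expect_equal(suppressWarnings(fit_steering(alt2))$slope, 2.2,
               tolerance = 1e-9)
  expect_error(impose_effect(d, "steering", -1), "fraction")
  # fin-body alteration scales the max slope by exactly (1 + fraction)
  xb <- seq(-6, 6, length.out = 200)
  db <- data.frame(x = xb, y = -5 + 10 / (1 + exp(-2 * xb)))
  bfit <- fit_fin_body(db)
  alt3 <- impose_effect(db, "finbody", 0.2, bfit)
  expect_equal(fit_fin_body(alt3)$fin_body_ratio,
               1.2 * bfit$fin_body_ratio, tolerance = 1e-3)
})

test_that("Cohen's d matches the closed form on known distributions", {
  # two samples with means 0 and 1, common SD 0.5 -> d about 2
  set.seed(71)
  ori <- rnorm(200, 0, 0.5); sim <- rnorm(200, 1, 0.5)
  d <- (mean(sim) - mean(ori)) / sd(c(sim, ori))
  # pooling the two groups inflates sigma by sqrt(1 + delta^2/4) relative to
  # the within-group SD; the resampling procedure shares this convention
  expect_equal(d, 2 / sqrt(1 + 1 / (4 * 0.25)), tolerance = 0.2)
})

test_that("effect sizes are null at fraction 0 and grow with N and fraction", {
  d <- steer_data(n = 6000)
  cfg <- effect_size_config(inner_reps = 30, outer_reps = 5)
  tab <- effect_size_curve(d, "steering", fractions = c(0, 0.02, 0.05),
                          sample_sizes = c(500, 2000), cfg = cfg, seed = 4)
  null_d <- tab$d_mean[tab$fraction == 0]
  expect_true(all(abs(null_d) < 0.1))
  for (N in c(500, 2000)) {
    row <- tab[tab$n == N, ]
    expect_true(all(diff(row$d_mean[order(row$fraction)]) > 0))
  }
  for (fr in c(0.02, 0.05)) {
    row <- tab[tab$fraction == fr, ]
    expect_gt(row$d_mean[row$n == 2000], row$d_mean[row$n == 500])
  }
  # sign of d follows the sign of the fraction
  neg <- effect_size_curve(d, "steering", fractions = -0.05,
                           sample_sizes = 2000,
                           cfg = effect_size_config(inner_reps = 20,
                                                    outer_reps = 3),
                           seed = 5)
  expect_lt(neg$d_mean, 0)
})

test_that("resampling procedures are reproducible under a fixed seed", {
  d <- steer_data(n = 1000)
  a <- ci_width_vs_n(d, "steering", 300,
                     cfg = resample_config(n_resamples = 5), seed = 9)
  b <- ci_width_vs_n(d, "steering", 300,
                     cfg = resample_config(n_resamples = 5), seed = 9)
  expect_identical(a, b)
  cfg <- effect_size_config(inner_reps = 10, outer_reps = 2)
  e1 <- effect_size_curve(d, "steering", 0.1, 300, cfg = cfg, seed = 8)
  e2 <- effect_size_curve(d, "steering", 0.1, 300, cfg = cfg, seed = 8)
  expect_identical(e1, e2)
})
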