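test_that("parabola fit recovers exact vertex-form coefficients", {
  x <- seq(-30, 40, length.out = 25)
  y <- 0.001 * (x - 10)^2 + 0.5
  fit <- fit_bout_timing(data.frame(x = x, y = y))
  expect_equal(fit$a, 0.001, tolerance = 1e-10)
  expect_equal(fit$b, 10, tolerance = 1e-8)
  expect_equal(fit$c, 0.5, tolerance = 1e-10)
  expect_equal(fit$sensitivity_mhz, 1, tolerance = 1e-7)
  expect_equal(predict(fit, c(10, 20)), c(0.5, 0.6), tolerance = 1e-9)
  expect_error(fit_bout_timing(data.frame(x = rep(1, 10), y = 1:10)),
               "distinct")
})

test_that("parabola fit matches a brute-force SSE grid search", {
  set.seed(21)
  x <- runif(20, -25, 35)
  y <- 0.0012 * (x - 6)^2 + 0.45 + rnorm(20, 0, 0.2)
  fit <- fit_bout_timing(data.frame(x = x, y = y))
  sse <- function(a, b, c) sum((y - (a * (x - b)^2 + c))^2)
  # oracle: grid around truth, then assert the analytic fit is no worse
  grid <- expand.grid(a = seq(0.0002, 0.003, length.out = 41),
                      b = seq(-5, 20, length.out = 41),
                      c = seq(0.2, 0.8, length.out = 41))
  g_sse <- mapply(sse, grid$a, grid$b, grid$c)
  best <- grid[which.min(g_sse), ]
  expect_lte(sse(fit$a, fit$b, fit$c), min(g_sse) + 1e-12)
  expect_equal(fit$a, best$a, tolerance = 0.15)
  expect_equal(fit$b, best$b, tolerance = 0.35)
})

test_that("line fits match the closed-form normal equations", {
  x <- c(1.5, 2, 4, 7, 11)
  y <- c(0.9, 2.4, 3.1, 7.2, 10.1)
  # closed-form OLS oracle
  sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  ic <- mean(y) - sl * mean(x)
  fit <- fit_steering(data.frame(x = x, y = y))
  expect_equal(fit$slope, sl, tolerance = 1e-12)
  expect_equal(fit$intercept, ic, tolerance = 1e-12)
  expect_equal(fit$r_squared, fit$pearson_r^2, tolerance = 1e-12)
  # identity data has gain 1 and r = 1
  d <- data.frame(x = 1:20, y = 1:20)
  idfit <- fit_steering(d)
  expect_equal(idfit$slope, 1, tolerance = 1e-12)
  expect_equal(idfit$pearson_r, 1, tolerance = 1e-12)
  expect_error(fit_steering(data.frame(x = rep(2, 5), y = 1:5)), "variance")
})

test_that("righting fit derives gain and set point from the line", {
  x <- seq(-20, 40, by = 4)
  y <- -0.2 * (x - 10)
  fit <- fit_righting(data.frame(x = x, y = y))
  expect_equal(fit$righting_gain, 0.2, tolerance = 1e-12)
  expect_equal(fit$set_point, 10, tolerance = 1e-10)
  # the set point is the root of the fitted line, exactly
  expect_equal(fit$slope * fit$set_point + fit$intercept, 0, tolerance = 1e-12)
  # 4-point hand-computed OLS
  hx <- c(-10, 0, 10, 30); hy <- c(2.5, 1.3, -0.4, -4.1)
  sl <- sum((hx - mean(hx)) * (hy - mean(hy))) / sum((hx - mean(hx))^2)
  hfit <- fit_righting(data.frame(x = hx, y = hy))
  expect_equal(hfit$slope, sl, tolerance = 1e-12)
  expect_warning(fit_righting(data.frame(x = 1:10, y = 1:10)),
                 "not corrective")
})

test_that("logistic fit: ratio equals kh/4 and the curve's max derivative", {
  set.seed(31)
  x <- seq(-6, 6, length.out = 60)
  y <- -5 + 10 / (1 + exp(-2 * (x + 0)))
  fit <- fit_fin_body(data.frame(x = x, y = y))
  expect_equal(fit$fin_body_ratio, 5, tolerance = 1e-6)
  expect_equal(fit$k * fit$h / 4, fit$fin_body_ratio, tolerance = 1e-12)
  # oracle: numerical max derivative of the *fitted* curve
  xs <- seq(-10, 10, by = 1e-4)
  dmax <- max(diff(predict(fit, xs)) / 1e-4)
  expect_equal(dmax, fit$fin_body_ratio, tolerance = 1e-7)
  expect_gte(fit$h, 0)
})

test_that("fin-body filtering applies the speed floor and exclusion rule", {
  set.seed(32)
  n <- 60
  f <- data.frame(
    steering_related_rotation = seq(-6, 6, length.out = n),
    steering_rotation = seq(-6, 6, length.out = n),
    peak_speed = rep(10, n))
  f$attack_angle <- -2 + 8 / (1 + exp(-1.2 * f$steering_related_rotation)) +
    rnorm(n, 0, 0.1)
  # three high-rotation bouts with negative attack angles -> excluded
  f$attack_angle[f$steering_rotation > 4][1:3] <- -1
  f$peak_speed[1:5] <- 6    # below the 7 mm/s floor
  fit <- fit_fin_body(f)
  expect_equal(fit$n_excluded, 3L)
  expect_equal(fit$n_used, n - 5 - 3)
  expect_error(fit_fin_body(f[1:8, ]), "too few")
})

test_that("binned averages align to multiples of the bin width", {
  x <- c(0.2, 0.4, 3.1, 3.4, 6.9)
  y <- c(1, 3, 10, 14, 7)
  b <- binned_average(x, y, 3)
  expect_equal(b$bin_center, c(1.5, 4.5, 7.5))
  expect_equal(b$y_mean, c(2, 12, 7))
  expect_equal(binned_average(x, rep(5, 5), 1)$y_mean,
               rep(5, length(unique(floor(x)))))
})

test_that("bout features obey their defining identities", {
  tr <- simulate_session(make_profile("7dpf"), 200, seed = 6)
  cfg <- extraction_config()
  eps <- select_epochs(compute_speed(trace_to_records(tr), cfg), cfg)
  f <- bout_features(extract_bouts(eps, cfg))
  expect_equal(f$attack_angle, f$trajectory - f$pitch_at_peak,
               tolerance = 1e-12)
  expect_equal(f$steering_rotation, f$pitch_at_peak - f$initial_pitch,
               tolerance = 1e-12)
  expect_true(all(f$trajectory > -90 & f$trajectory <= 90))
})

test_that("constant-pitch horizontal motion gives the textbook geometry", {
  rec <- bump_records(duration = 3, center = 1.5, pitch = 10)
  cfg <- extraction_config(speed_smoothing = 1)
  eps <- select_epochs(compute_speed(rec, cfg), cfg)
  f <- bout_features(extract_bouts(eps, cfg))
  expect_equal(f$steering_rotation, 0)
  expect_equal(f$trajectory, 0)
  expect_equal(f$attack_angle, -10)
})
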