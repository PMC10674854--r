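test_that("amplitude statistics use the population variance", {
  expect_equal(amplitude_stats(make_peaks(c(1, 2, 3))),
               c(amp_avg = 2, amp_var = 2 / 3))
  expect_equal(amplitude_stats(peak_set(5L, 5, 60)),
               c(amp_avg = 5, amp_var = 0))
  set.seed(21)
  a <- rnorm(100, 1.5, 0.2)
  st <- amplitude_stats(make_peaks(a))
  expect_lt(abs(st[["amp_avg"]] - 1.5), 3 * 0.2 / sqrt(100))
  ref <- oracle_mean_var(a)
  expect_equal(st[["amp_avg"]], ref[["mean"]], tolerance = 1e-12)
  expect_equal(st[["amp_var"]], ref[["var"]], tolerance = 1e-12)
})

test_that("piecewise fit recovers exact two-segment parameters", {
  x <- 1:12
  y <- 2 - 0.05 * x - 0.20 * pmax(0, x - 6)
  fit <- fit_piecewise(x, y)
  expect_equal(fit$breakpoint, 6)
  expect_equal(fit$slope1, -0.05, tolerance = 1e-6)
  expect_equal(fit$slope2, -0.20, tolerance = 1e-6)
  expect_equal(fit$intercept, 2, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-16)
  expect_false(fit$degenerate)
})

test_that("piecewise fit degrades gracefully on collinear and tiny inputs", {
  x <- 1:10
  y <- 3 + 0.4 * x
  fit <- fit_piecewise(x, y)
  expect_lte(abs(fit$slope2), 1e-8 * abs(fit$slope1) + 1e-12)
  expect_lt(fit$rss, 1e-16)
  small <- fit_piecewise(1:3, c(1, 2, 3))
  expect_true(small$degenerate)
  expect_equal(small$slope2, 0)
  expect_equal(small$breakpoint, 2)
  expect_error(fit_piecewise(1:4, 1:3), "length")
})

test_that("piecewise fit mirrors under x reversal", {
  set.seed(31)
  for (rep in 1:10) {
    N <- sample(8:16, 1)
    bp <- sample(3:(N - 2), 1)
    y <- runif(1, 1, 2) + runif(1, -0.1, 0.1) * (1:N) +
      runif(1, -0.3, -0.05) * pmax(0, (1:N) - bp) + rnorm(N, 0, 0.02)
    f1 <- fit_piecewise(1:N, y)
    f2 <- fit_piecewise(1:N, rev(y))
    expect_equal(f2$rss, f1$rss, tolerance = 1e-8)
    expect_equal(f2$slope1, -(f1$slope1 + f1$slope2), tolerance = 1e-6)
    expect_equal(f2$slope2, f1$slope2, tolerance = 1e-6)
    expect_equal(f2$breakpoint, N + 1 - f1$breakpoint)
  }
})

test_that("velocity series implements the paired-amplitude rate", {
  pk <- peak_set(c(1L, 31L), c(1, 1), fps = 60)   # 0.5 s apart
  expect_equal(velocity_series(pk)$values, 4)
  pk2 <- peak_set(c(1L, 61L), c(2, 0), fps = 60)  # 1 s apart
  expect_equal(velocity_series(pk2)$values, 2)
  # constant amplitude and spacing give constant velocity
  pk3 <- make_peaks(rep(1.2, 6), gap = 20)
  expect_equal(diff(range(velocity_series(pk3)$values)), 0)
  expect_error(velocity_series(peak_set(1L, 1, 60)), "too few")
})

test_that("velocity statistics match an independent two-pass oracle", {
  expect_equal(velocity_stats(structure(list(values = c(4, 4, 4)),
                                        class = "velocity_series")),
               c(vel_avg = 4, vel_var = 0))
  expect_equal(velocity_stats(structure(list(values = c(2, 4)),
                                        class = "velocity_series")),
               c(vel_avg = 3, vel_var = 1))
  set.seed(22)
  v <- runif(50, 1, 8)
  st <- velocity_stats(structure(list(values = v), class = "velocity_series"))
  ref <- oracle_mean_var(v)
  expect_equal(st[["vel_avg"]], ref[["mean"]], tolerance = 1e-12)
  expect_equal(st[["vel_var"]], ref[["var"]], tolerance = 1e-12)
})

test_that("decrement features expose the trend against tap ordinal", {
  a <- c(rep(1, 5), 1 - 0.1 * (1:5))
  d <- decrement_features(a)
  expect_equal(d[["bp"]], 5)
  expect_lt(abs(d[["alpha1"]]), 1e-8)
  expect_lt(d[["alpha2"]], 0)
  flat <- decrement_features(rep(2, 8))
  expect_lt(abs(flat[["alpha1"]]), 1e-10)
  expect_lt(abs(flat[["alpha2"]]), 1e-10)
  up <- decrement_features(seq(1, 2, length.out = 8))
  expect_gt(up[["alpha1"]], 0)
})

test_that("halt detection thresholds residuals at 20% of neighbour mean", {
  a <- rep(1, 11)
  a[6] <- 0.5
  expect_identical(halt_hesitation_count(make_peaks(a)), 1L)
  a[6] <- 0.9
  expect_identical(halt_hesitation_count(make_peaks(a)), 0L)
  expect_identical(halt_hesitation_count(make_peaks(rep(1, 11))), 0L)
  # upward outliers are not halts
  a[6] <- 1.5
  expect_identical(halt_hesitation_count(make_peaks(a)), 0L)
  expect_warning(n <- halt_hesitation_count(make_peaks(c(1, 1))), "fewer")
  expect_identical(n, 0L)
})

test_that("halt count is invariant to uniform amplitude scaling", {
  set.seed(23)
  a <- 1 + 0.02 * (1:12)
  a[c(4, 9)] <- a[c(4, 9)] * 0.45
  n1 <- halt_hesitation_count(make_peaks(a))
  expect_identical(n1, 2L)
  for (c_scale in c(0.1, 7)) {
    expect_identical(halt_hesitation_count(make_peaks(a * c_scale)), n1)
  }
})

test_that("frequency and count follow the inter-peak definition", {
  pk <- peak_set(seq(1, by = 30, length.out = 11), rep(1, 11), fps = 60)
  expect_equal(frequency_and_count(pk), c(freq = 2, n_peaks = 11))
  pk2 <- peak_set(c(1L, 25L), c(1, 1), fps = 60)   # 0.4 s apart
  expect_equal(frequency_and_count(pk2)[["freq"]], 2.5)
  expect_warning(fc <- frequency_and_count(peak_set(1L, 1, 60)), "single")
  expect_equal(fc[["freq"]], 0)
})

test_that("feature vector is assembled in canonical order and isolates age", {
  pk <- make_peaks(c(1, 1.1, 0.9, 1, 1.05))
  f1 <- build_feature_vector(pk, demographics(60, "female"))
  f2 <- build_feature_vector(pk, demographics(80, "female"))
  expect_identical(names(f1), tap_feature_names())
  expect_length(f1, 15)
  diffs <- names(f1)[f1 != f2]
  expect_identical(diffs, "age")
  expect_equal(f1[["sex"]], 0)
  expect_equal(build_feature_vector(pk, demographics(60, "male"))[["sex"]], 1)
})

test_that("feature vector matches element-wise recomputation by oracle", {
  set.seed(24)
  a <- 1.3 - 0.03 * (1:10) + rnorm(10, 0, 0.05)
  idx <- cumsum(c(1, sample(25:35, 9, replace = TRUE)))
  pk <- peak_set(idx, a, fps = 60)
  fv <- build_feature_vector(pk, demographics(71, "male"))
  times <- (idx - 1) / 60
  mv <- oracle_mean_var(a)
  expect_equal(fv[["amp_avg"]], mv[["mean"]], tolerance = 1e-12)
  expect_equal(fv[["amp_var"]], mv[["var"]], tolerance = 1e-12)
  v <- numeric(9)
  for (n in 2:10) v[n - 1] <- (a[n] + a[n - 1]) / (times[n] - times[n - 1])
  vv <- oracle_mean_var(v)
  expect_equal(fv[["vel_avg"]], vv[["mean"]], tolerance = 1e-12)
  expect_equal(fv[["vel_var"]], vv[["var"]], tolerance = 1e-12)
  expect_equal(fv[["freq"]], 9 / (times[10] - times[1]), tolerance = 1e-12)
  expect_equal(fv[["n_peaks"]], 10)
  amp_fit <- fit_piecewise(1:10, a)
  expect_equal(fv[["amp_bp"]], amp_fit$breakpoint)
  expect_equal(fv[["amp_alpha1"]], amp_fit$slope1)
  expect_equal(fv[["amp_alpha2"]], amp_fit$slope2)
})

test_that("features are invariant to the frame-rate representation", {
  # the same physical motion sampled at 60 and 120 fps
  a <- c(1.2, 1.1, 1.15, 1.0, 0.95, 1.05, 0.9, 0.85)
  idx60 <- seq(1, by = 30, length.out = 8)
  idx120 <- 2L * idx60 - 1L
  f60 <- build_feature_vector(peak_set(idx60, a, 60), demographics(70, "male"))
  f120 <- build_feature_vector(peak_set(idx120, a, 120), demographics(70, "male"))
  expect_equal(f120, f60, tolerance = 1e-6)
})

test_that("feature-label correlations behave at the extremes", {
  set.seed(25)
  n <- 1000
  labels <- sample(0:4, n, replace = TRUE)
  X <- matrix(rnorm(n * 3), n, 3,
              dimnames = list(NULL, c("amp_avg", "vel_avg", "freq")))
  X[, "amp_avg"] <- labels
  X[, "vel_avg"] <- -labels
  r <- feature_label_correlations(X, labels)
  expect_equal(r[["amp_avg"]], 1)
  expect_equal(r[["vel_avg"]], -1)
  expect_lt(abs(r[["freq"]]), 0.1)
  X[, "freq"] <- 7
  r2 <- feature_label_correlations(X, labels)
  expect_equal(r2[["freq"]], 0)
  expect_identical(attr(r2, "constant"), "freq")
  expect_error(feature_label_correlations(X[1:2, ], labels[1:2]), "3 samples")
})
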