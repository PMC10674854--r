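#' Amplitude statistics
#'
#' Mean and population variance (denominator `N`) of the peak amplitudes,
#' the per-tap full-opening distances in palm-size units.
#'
#' @param peaks a [peak_set()].
#' @return Named numeric vector `c(amp_avg, amp_var)`.
#' @export
amplitude_stats <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  a <- peaks$amplitudes
  m <- sum(a) / length(a)
  c(amp_avg = m, amp_var = sum((a - m)^2) / length(a))
}

#' Continuous two-segment piecewise linear fit
#'
#' Fits `y = a0 + s1 * x + s2 * (x - bp) * [x > bp]` - a line whose slope
#' changes by `s2` at the breakpoint `bp` while remaining continuous - by
#' exhaustive search: every interior data position `x[2..n-1]` is tried as
#' the breakpoint, ordinary least squares is solved for each candidate, and
#' the fit with the smallest residual sum of squares wins (ties broken by the
#' earliest breakpoint, for determinism). This brute-force definition is the
#' implementation: with at most a few dozen taps per recording the grid is
#' tiny.
#'
#' With fewer than 4 points the model is unidentifiable and a single-line
#' OLS fit is returned with `slope2 = 0`, breakpoint at the x-range midpoint,
#' and `degenerate = TRUE`.
#'
#' @param x ordered numeric positions (typically peak ordinals `1..N`).
#' @param y values at those positions.
#' @return An object of class `piecewise_fit`: list with `intercept`,
#'   `slope1`, `slope2`, `breakpoint`, `rss`, `fitted`, `degenerate`.
#' @export
fit_piecewise <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("x and y differ in length", call. = FALSE)
  if (n < 4L) {
    fit <- stats::lm.fit(cbind(1, x), y)
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    return(structure(list(
      intercept = unname(cf[1]), slope1 = unname(cf[2]), slope2 = 0,
      breakpoint = mean(range(x)), rss = sum(fit$residuals^2),
      fitted = unname(fit$fitted.values), degenerate = TRUE),
      class = "piecewise_fit"))
  }
  best <- NULL
  for (bp in x[2:(n - 1L)]) {
    hinge <- pmax(x - bp, 0)
    X <- cbind(1, x, hinge)
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss - 1e-12) {
      cf <- fit$coefficients
      cf[is.na(cf)] <- 0
      best <- list(intercept = unname(cf[1]), slope1 = unname(cf[2]),
                   slope2 = unname(cf[3]), breakpoint = bp, rss = rss,
                   fitted = unname(fit$fitted.values), degenerate = FALSE)
    }
  }
  structure(best, class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf(
    "<piecewise_fit> y = %.4g + %.4g x %+.4g (x - %.4g)+  (rss %.4g%s)\n",
    x$intercept, x$slope1, x$slope2, x$breakpoint, x$rss,
    if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Per-tap velocity series
#'
#' Average opening-plus-closing speed between consecutive peaks:
#' `V_n = (A_n + A_{n-1}) / dt_n` where `dt_n` is the inter-peak interval.
#' Units are palm sizes per second.
#'
#' @param peaks a [peak_set()] with at least 2 peaks.
#' @return An object of class `velocity_series`: list with `values` (length
#'   `N - 1`) and `intervals` (the `dt_n`, seconds).
#' @export
velocity_series <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  n <- length(peaks$indices)
  if (n < 2L) stop("too few taps: velocity needs at least 2 peaks",
                   call. = FALSE)
  dt <- diff(peaks$times)
  v <- (peaks$amplitudes[-1L] + peaks$amplitudes[-n]) / dt
  structure(list(values = v, intervals = dt), class = "velocity_series")
}

#' Velocity statistics
#'
#' Mean and population variance (denominator `N - 1`, the number of velocity
#' samples) of the per-tap velocities.
#'
#' @param v a [velocity_series()].
#' @return Named numeric vector `c(vel_avg, vel_var)`.
#' @export
velocity_stats <- function(v) {
  stopifnot(inherits(v, "velocity_series"))
  x <- v$values
  m <- sum(x) / length(x)
  c(vel_avg = m, vel_var = sum((x - m)^2) / length(x))
}

#' Decrement trend parameters
#'
#' The two slopes and breakpoint of the piecewise-linear trend fitted against
#' the peak ordinal (1..N): the first-segment slope, the incremental
#' second-segment slope (negative when amplitude or velocity decays late in
#' the sequence), and the ordinal at which the change occurs. The ordinal
#' axis, rather than wall time, matches how the clinical criteria reference
#' position within the 10-tap sequence.
#'
#' @param values numeric vector of per-tap values (peak amplitudes, or
#'   velocities from [velocity_series()]).
#' @return Named numeric vector `c(alpha1, alpha2, bp)`.
#' @export
decrement_features <- function(values) {
  if (inherits(values, "peak_set")) values <- values$amplitudes
  if (inherits(values, "velocity_series")) values <- values$values
  fit <- fit_piecewise(seq_along(values), values)
  c(alpha1 = fit$slope1, alpha2 = fit$slope2, bp = fit$breakpoint)
}

#' Halt and hesitation count
#'
#' Counts taps whose amplitude drops abruptly below the fitted amplitude
#' trend: the piecewise-linear trend is fitted to all peaks, and an interior
#' peak `n` is flagged when its residual `|fitted_n - A_n|` reaches
#' `alpha * (A_{n-1} + A_{n+1}) / 2` - i.e. the threshold is `alpha` times
#' the mean amplitude immediately before and after the event - and the peak
#' lies *below* the trend (only drops are clinical halts; upward outliers
#' are not). The default `alpha = 0.2` flags drops of at least 20 percent of
#' the neighbouring amplitude.
#'
#' @param peaks a [peak_set()]; needs at least 3 peaks (a flagged peak needs
#'   both neighbours), otherwise 0 is returned with a warning.
#' @param alpha detection-threshold fraction (default 0.2).
#' @return Integer count of flagged peaks.
#' @export
halt_hesitation_count <- function(peaks, alpha = 0.2) {
  stopifnot(inherits(peaks, "peak_set"))
  a <- peaks$amplitudes
  n <- length(a)
  if (n < 3L) {
    warning("fewer than 3 peaks: halt/hesitation count undefined, returning 0")
    return(0L)
  }
  fit <- fit_piecewise(seq_len(n), a)
  yhat <- fit$fitted
  count <- 0L
  for (i in 2:(n - 1L)) {
    theta <- alpha * (a[i - 1L] + a[i + 1L]) / 2
    resid <- yhat[i] - a[i]
    if (resid >= theta && a[i] < yhat[i]) count <- count + 1L
  }
  count
}

#' Tapping frequency and peak count
#'
#' `n_peaks` is the number of detected peaks; `freq` is the inter-peak rate
#' `(N - 1) / (t_N - t_1)` in Hz, which ignores any padding before the first
#' and after the last tap. A single peak yields frequency 0 with a warning.
#'
#' @param peaks a [peak_set()].
#' @return Named numeric vector `c(freq, n_peaks)`.
#' @export
frequency_and_count <- function(peaks) {
  stopifnot(inherits(peaks, "peak_set"))
  n <- length(peaks$indices)
  if (n < 2L) {
    warning("single peak: tapping frequency undefined, returning 0")
    return(c(freq = 0, n_peaks = n))
  }
  c(freq = (n - 1) / (peaks$times[n] - peaks$times[1]), n_peaks = n)
}

#' Assemble the 15-feature vector
#'
#' Computes all fifteen clinically aligned features in canonical order (see
#' [tap_feature_names()]): age; sex (0 = female, 1 = male); amplitude
#' variance, mean, breakpoint and two trend slopes; the same five for the
#' velocity series; tapping frequency; halt/hesitation count; and peak count.
#'
#' @param peaks a [peak_set()] with at least 2 peaks.
#' @param demo a [demographics()] object.
#' @param alpha halt/hesitation threshold fraction (default 0.2).
#' @return Named numeric vector of length 15.
#' @export
build_feature_vector <- function(peaks, demo, alpha = 0.2) {
  stopifnot(inherits(peaks, "peak_set"), inherits(demo, "demographics"))
  amp <- amplitude_stats(peaks)
  amp_tr <- decrement_features(peaks$amplitudes)
  if (length(peaks$indices) >= 2L) {
    v <- velocity_series(peaks)
    vel <- velocity_stats(v)
    vel_tr <- decrement_features(v$values)
  } else {
    # a single detected tap: the task was barely performed; velocity is
    # unmeasurable and reported as zero (flagged), not as an error
    warning("single peak: velocity features undefined, returning 0")
    vel <- c(vel_avg = 0, vel_var = 0)
    vel_tr <- c(alpha1 = 0, alpha2 = 0, bp = 0)
  }
  fc <- frequency_and_count(peaks)
  out <- c(
    age = demo$age,
    sex = if (demo$sex == "male") 1 else 0,
    amp_var = unname(amp["amp_var"]),
    amp_avg = unname(amp["amp_avg"]),
    amp_bp = unname(amp_tr["bp"]),
    amp_alpha1 = unname(amp_tr["alpha1"]),
    amp_alpha2 = unname(amp_tr["alpha2"]),
    vel_var = unname(vel["vel_var"]),
    vel_avg = unname(vel["vel_avg"]),
    vel_bp = unname(vel_tr["bp"]),
    vel_alpha1 = unname(vel_tr["alpha1"]),
    vel_alpha2 = unname(vel_tr["alpha2"]),
    freq = unname(fc["freq"]),
    hh = as.numeric(halt_hesitation_count(peaks, alpha = alpha)),
    n_peaks = unname(fc["n_peaks"])
  )
  stopifnot(identical(names(out), tap_feature_names()))
  out
}

#' Extract features from a hand-pose recording
#'
#' End-to-end extraction: thumb-index distance, palm normalization,
#' EMD-based cleaning, peak detection, and the 15-feature vector.
#'
#' @param series a [hand_pose_series()].
#' @param demo a [demographics()] object.
#' @param config a [run_config()] (preprocessing and feature parameters).
#' @return Named numeric vector of length 15.
#' @export
extract_features <- function(series, demo, config = run_config()) {
  raw <- distance_series(series, 4L, 8L)
  norm <- normalize_distance(raw, palm_size(series))
  prep <- preprocess_signal(
    norm, n_keep = config$n_keep, smooth_window = config$smooth_window,
    keep_residual = config$keep_residual,
    min_prominence = config$min_prominence,
    min_separation = config$min_separation)
  build_feature_vector(prep$peaks, demo, alpha = config$alpha)
}

#' Feature-score Pearson correlations
#'
#' Pearson correlation of each feature column with the severity label, the
#' screen used to check for redundant features before classification.
#' Constant features have undefined correlation and are reported as 0 and
#' flagged in the `constant` attribute.
#'
#' @param features matrix or data frame of feature vectors (rows =
#'   recordings).
#' @param labels numeric severity scores, one per row.
#' @return Named numeric vector of correlations with attribute `constant`.
#' @export
feature_label_correlations <- function(features, labels) {
  X <- as.matrix(features[, intersect(tap_feature_names(), colnames(features)),
                          drop = FALSE])
  if (nrow(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  if (length(labels) != nrow(X)) stop("labels length mismatch", call. = FALSE)
  const <- apply(X, 2, function(col) stats::var(col) == 0)
  r <- rep(0, ncol(X))
  names(r) <- colnames(X)
  if (stats::var(labels) > 0) {
    r[!const] <- apply(X[, !const, drop = FALSE], 2, stats::cor, y = labels)
  }
  attr(r, "constant") <- names(r)[const]
  r
}
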