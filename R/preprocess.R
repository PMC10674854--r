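#' Tapping-distance signal
#'
#' 1-D thumb-index distance series. Raw signals carry the recording's length
#' units; palm-normalized signals are dimensionless (palm-size units).
#'
#' @param values numeric vector, length >= 2. `NA` marks samples lost to pose
#'   dropouts.
#' @param fps frames per second.
#' @param normalized has palm normalization been applied?
#' @return An object of class `tap_signal`.
#' @export
tap_signal <- function(values, fps, normalized = FALSE) {
  if (length(values) < 2L) stop("signal needs at least 2 samples", call. = FALSE)
  if (!is.numeric(fps) || fps <= 0) stop("fps must be positive", call. = FALSE)
  structure(list(values = as.numeric(values), fps = as.numeric(fps),
                 normalized = isTRUE(normalized)),
            class = "tap_signal")
}

#' @export
print.tap_signal <- function(x, ...) {
  cat(sprintf("<tap_signal> %d samples @ %.5g fps, %s\n", length(x$values),
              x$fps, if (x$normalized) "palm-normalized" else "raw units"))
  invisible(x)
}

#' Per-frame palm size
#'
#' Euclidean distance between the wrist (landmark 0) and the middle-finger
#' MCP (landmark 9), the subject- and camera-geometry-dependent scale used to
#' normalize the tapping amplitude. Frames where the palm size is non-finite
#' or falls below `floor_frac` times the series median are flagged degenerate
#' and replaced by linear interpolation of their neighbours.
#'
#' @param series a [hand_pose_series()].
#' @param floor_frac degenerate threshold as a fraction of the median palm
#'   size (default `1e-6`).
#' @return Numeric vector of strictly positive palm sizes, one per frame,
#'   with attribute `degenerate_frames`.
#' @export
palm_size <- function(series, floor_frac = 1e-6) {
  stopifnot(inherits(series, "hand_pose_series"))
  p <- distance_series(series, 0L, 9L)$values
  med <- stats::median(p[is.finite(p) & p > 0])
  if (!is.finite(med)) stop("all frames have degenerate palm size", call. = FALSE)
  bad <- !is.finite(p) | p < floor_frac * med
  if (all(bad)) stop("all frames have degenerate palm size", call. = FALSE)
  if (any(bad)) {
    idx <- seq_along(p)
    p[bad] <- stats::approx(idx[!bad], p[!bad], xout = idx[bad], rule = 2)$y
  }
  attr(p, "degenerate_frames") <- which(bad)
  p
}

#' Palm-normalize a distance signal
#'
#' Divides the raw thumb-index distance by the per-frame palm size, making
#' amplitudes dimensionless and comparable across subjects and cameras.
#'
#' @param signal a raw [tap_signal()].
#' @param palm per-frame palm sizes from [palm_size()]; same length.
#' @return A normalized [tap_signal()].
#' @export
normalize_distance <- function(signal, palm) {
  stopifnot(inherits(signal, "tap_signal"))
  if (length(palm) != length(signal$values)) {
    stop("palm series length does not match the signal", call. = FALSE)
  }
  if (any(!is.finite(palm) | palm <= 0)) {
    stop("palm sizes must be finite and strictly positive", call. = FALSE)
  }
  tap_signal(signal$values / palm, fps = signal$fps, normalized = TRUE)
}

# --- empirical mode decomposition ------------------------------------------

# Plateau-aware local extrema of a series; returns midpoint indices of
# interior maxima and minima runs.
local_extrema <- function(x) {
  r <- rle(x)
  v <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(v)
  maxima <- integer(0); minima <- integer(0)
  if (k >= 3L) {
    for (i in 2:(k - 1L)) {
      mid <- as.integer(floor((starts[i] + ends[i]) / 2))
      if (v[i] > v[i - 1L] && v[i] > v[i + 1L]) maxima <- c(maxima, mid)
      else if (v[i] < v[i - 1L] && v[i] < v[i + 1L]) minima <- c(minima, mid)
    }
  }
  list(maxima = maxima, minima = minima)
}

# Cubic-spline envelope through the extrema, with up to two extrema mirrored
# about each end of the record to tame boundary divergence.
spline_envelope <- function(x, pos, L) {
  val <- x[pos]
  np <- length(pos)
  nl <- min(2L, np)
  lp <- 2L - pos[seq_len(nl)]
  lv <- val[seq_len(nl)]
  rp <- 2L * L - pos[np - seq_len(nl) + 1L]
  rv <- val[np - seq_len(nl) + 1L]
  xs <- c(lp, pos, rp)
  ys <- c(lv, val, rv)
  o <- order(xs)
  xs <- xs[o]; ys <- ys[o]
  keep <- !duplicated(xs)
  stats::spline(xs[keep], ys[keep], xout = seq_len(L), method = "fmm")$y
}

#' Empirical mode decomposition
#'
#' Standard sifting EMD: each intrinsic mode function (IMF) is obtained by
#' repeatedly subtracting the mean of the cubic-spline envelopes through the
#' local maxima and minima until the Cauchy-type stopping criterion
#' `sum((h_prev - h)^2) / sum(h_prev^2) < sd_thresh` is met; extraction stops
#' when the residual has fewer than two maxima or two minima (a monotone or
#' constant trend). IMFs are ordered highest-frequency first and the identity
#' `sum(IMFs) + residual == input` holds to floating-point precision.
#'
#' @param signal a [tap_signal()] or numeric vector (length >= 4, finite).
#' @param max_imfs maximum number of IMFs to extract.
#' @param sd_thresh sifting stop threshold (default 0.2, the conventional
#'   value).
#' @param max_sift maximum sifting iterations per IMF.
#' @return An object of class `emd_result`: list with `imfs` (possibly empty
#'   list of numeric vectors) and `residual`.
#' @export
emd_decompose <- function(signal, max_imfs = 12L, sd_thresh = 0.2,
                          max_sift = 60L) {
  x <- if (inherits(signal, "tap_signal")) signal$values else as.numeric(signal)
  if (length(x) < 4L) stop("EMD needs at least 4 samples", call. = FALSE)
  if (any(!is.finite(x))) stop("EMD input must be finite", call. = FALSE)
  L <- length(x)
  imfs <- list()
  residual <- x
  for (k in seq_len(max_imfs)) {
    ex <- local_extrema(residual)
    if (length(ex$maxima) < 2L || length(ex$minima) < 2L) break
    h <- residual
    for (s in seq_len(max_sift)) {
      ex <- local_extrema(h)
      if (length(ex$maxima) < 2L || length(ex$minima) < 2L) break
      upper <- spline_envelope(h, ex$maxima, L)
      lower <- spline_envelope(h, ex$minima, L)
      m <- (upper + lower) / 2
      h_new <- h - m
      sd_k <- sum((h - h_new)^2) / (sum(h^2) + 1e-300)
      h <- h_new
      if (sd_k < sd_thresh) break
    }
    imfs[[k]] <- h
    residual <- residual - h
  }
  structure(list(imfs = imfs, residual = residual), class = "emd_result")
}

#' @export
print.emd_result <- function(x, ...) {
  cat(sprintf("<emd_result> %d IMF(s) + residual, %d samples\n",
              length(x$imfs), length(x$residual)))
  invisible(x)
}

# --- smoothing --------------------------------------------------------------

#' Savitzky-Golay smoothing
#'
#' Local polynomial regression smoothing: each sample is replaced by the value
#' at its position of an order-`order` polynomial least-squares fit over a
#' centred window. Edges are handled by fitting the polynomial to the first
#' and last full windows and evaluating it at the edge positions, so peak
#' amplitudes near the record boundaries are preserved.
#'
#' @param x numeric vector.
#' @param window odd window length, `3 <= window < length(x)`.
#' @param order polynomial order (default 2).
#' @return Smoothed numeric vector of the same length.
#' @export
savgol_smooth <- function(x, window, order = 2L) {
  n <- length(x)
  if (window %% 2L == 0L || window < 3L || window >= n) {
    stop("window must be odd, >= 3 and < length(x)", call. = FALSE)
  }
  half <- (window - 1L) %/% 2L
  A <- outer(seq(-half, half), 0:order, `^`)
  proj <- solve(crossprod(A), t(A))          # (order+1) x window
  centre_coef <- proj[1L, ]                  # value of the fit at offset 0
  out <- stats::filter(x, rev(centre_coef), sides = 2L)
  out <- as.numeric(out)
  # polynomial edge handling
  left_fit <- A %*% (proj %*% x[seq_len(window)])
  right_fit <- A %*% (proj %*% x[(n - window + 1L):n])
  out[seq_len(half)] <- left_fit[seq_len(half)]
  out[(n - half + 1L):n] <- right_fit[(window - half + 1L):window]
  out
}

#' Reconstruct and clean a signal from its EMD
#'
#' Rebuilds the tapping signal from the `n_keep` highest-frequency IMFs (the
#' oscillatory content of the finger movement), then applies Savitzky-Golay
#' smoothing to suppress tremor and measurement ripple. By default the slow
#' residual trend is excluded and the residual's median is added back as a
#' constant baseline, so peak amplitudes remain on the original scale; set
#' `keep_residual = TRUE` to retain the full trend instead.
#'
#' @param emd an [emd_decompose()] result.
#' @param fps frames per second of the decomposed signal.
#' @param n_keep number of highest-frequency IMFs to retain (default 3). If
#'   fewer IMFs exist, all are used with a warning.
#' @param smooth_window odd Savitzky-Golay window; default
#'   `round(0.25 * fps)` forced odd. Use `0` or `NULL` to skip smoothing.
#' @param keep_residual retain the residual trend instead of its median.
#' @return A cleaned, normalized [tap_signal()].
#' @export
select_and_clean <- function(emd, fps, n_keep = 3L, smooth_window = NULL,
                             keep_residual = FALSE) {
  stopifnot(inherits(emd, "emd_result"))
  if (n_keep < 1L) stop("n_keep must be >= 1", call. = FALSE)
  k <- length(emd$imfs)
  if (k < n_keep && k > 0L) {
    warning(sprintf("only %d IMF(s) available; keeping all of them", k))
  }
  use <- seq_len(min(n_keep, k))
  base <- if (length(use)) Reduce(`+`, emd$imfs[use]) else
    rep(0, length(emd$residual))
  values <- if (keep_residual) base + emd$residual else
    base + stats::median(emd$residual)
  if (is.null(smooth_window)) smooth_window <- odd_window(0.25 * fps)
  if (!is.null(smooth_window) && smooth_window >= 3L) {
    if (smooth_window %% 2L == 0L) smooth_window <- smooth_window + 1L
    if (smooth_window < length(values)) {
      values <- savgol_smooth(values, smooth_window, order = 2L)
    }
  }
  tap_signal(values, fps = fps, normalized = TRUE)
}

odd_window <- function(w) {
  w <- max(3L, round(w))
  if (w %% 2L == 0L) w + 1L else as.integer(w)
}

# --- peak detection ---------------------------------------------------------

#' Detected tapping peaks
#'
#' @param indices strictly increasing frame indices of full finger openings.
#' @param fps frames per second.
#' @param amplitudes signal values at the peaks (palm-size units).
#' @return An object of class `peak_set` with fields `indices`, `times`
#'   (seconds, `(index - 1) / fps`), `amplitudes`, `fps`.
#' @export
peak_set <- function(indices, amplitudes, fps) {
  indices <- as.integer(indices)
  if (length(indices) < 1L) stop("a peak set needs at least one peak",
                                 call. = FALSE)
  if (is.unsorted(indices, strictly = TRUE)) {
    stop("peak indices must be strictly increasing", call. = FALSE)
  }
  if (length(amplitudes) != length(indices)) {
    stop("amplitudes and indices differ in length", call. = FALSE)
  }
  structure(list(indices = indices, times = (indices - 1) / fps,
                 amplitudes = as.numeric(amplitudes), fps = as.numeric(fps)),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat(sprintf("<peak_set> %d peaks over %.2f s, mean amplitude %.3f\n",
              length(x$indices), diff(range(x$times)), mean(x$amplitudes)))
  invisible(x)
}

# Topographic prominence of a local maximum: height above the higher of the
# two minima separating it from the nearest taller samples (or record ends).
peak_prominences <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    i <- p
    left_min <- h
    while (i > 1L) {
      i <- i - 1L
      if (x[i] > h) break
      if (x[i] < left_min) left_min <- x[i]
    }
    i <- p
    right_min <- h
    n <- length(x)
    while (i < n) {
      i <- i + 1L
      if (x[i] > h) break
      if (x[i] < right_min) right_min <- x[i]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Detect tapping peaks
#'
#' Finds local maxima of the cleaned signal (full finger openings) subject to
#' a minimum topographic prominence - expressed as a fraction of the signal
#' range so that the detector is amplitude-scale free - and a minimum
#' separation in seconds. When two candidate peaks are closer than
#' `min_separation`, the taller one wins.
#'
#' @param signal cleaned, normalized [tap_signal()].
#' @param min_prominence minimum prominence as a fraction of
#'   `max(signal) - min(signal)` (default 0.1).
#' @param min_separation minimum peak spacing in seconds (default 0.1: taps
#'   faster than 10 Hz are physiologically implausible).
#' @return A [peak_set()].
#' @export
detect_peaks <- function(signal, min_prominence = 0.1, min_separation = 0.1) {
  stopifnot(inherits(signal, "tap_signal"))
  x <- signal$values
  cand <- local_extrema(x)$maxima
  if (length(cand)) {
    rng <- diff(range(x))
    prom <- peak_prominences(x, cand)
    cand <- cand[prom >= min_prominence * rng]
  }
  if (length(cand) > 1L && min_separation > 0) {
    min_gap <- min_separation * signal$fps
    keep <- logical(length(cand))
    for (i in order(x[cand], cand, decreasing = c(TRUE, FALSE), method = "radix")) {
      if (!any(keep & abs(cand - cand[i]) < min_gap)) keep[i] <- TRUE
    }
    cand <- sort(cand[keep])
  }
  if (!length(cand)) {
    stop("no tapping peaks detected: recording unusable", call. = FALSE)
  }
  peak_set(cand, x[cand], signal$fps)
}

# --- pipeline ---------------------------------------------------------------

#' Preprocess a tapping-distance signal
#'
#' Full preprocessing chain for a (normalized) tapping signal: interpolation
#' of pose-dropout gaps (up to `max_gap` seconds; longer gaps reject the
#' recording, mirroring manual quality exclusion), EMD decomposition,
#' IMF selection + smoothing, and prominence-based peak detection.
#'
#' @param signal a normalized [tap_signal()] (see [normalize_distance()]).
#' @param n_keep,smooth_window,keep_residual passed to [select_and_clean()].
#' @param min_prominence,min_separation passed to [detect_peaks()].
#' @param max_gap longest interpolatable dropout run, seconds (default 0.5).
#' @return List with elements `clean` ([tap_signal()]), `peaks`
#'   ([peak_set()]) and `emd` ([emd_decompose()] result).
#' @export
preprocess_signal <- function(signal, n_keep = 3L, smooth_window = NULL,
                              keep_residual = FALSE, min_prominence = 0.1,
                              min_separation = 0.1, max_gap = 0.5) {
  stopifnot(inherits(signal, "tap_signal"))
  values <- interpolate_gaps(signal$values, signal$fps, max_gap)
  emd <- emd_decompose(tap_signal(values, signal$fps, signal$normalized))
  clean <- select_and_clean(emd, fps = signal$fps, n_keep = n_keep,
                            smooth_window = smooth_window,
                            keep_residual = keep_residual)
  peaks <- detect_peaks(clean, min_prominence = min_prominence,
                        min_separation = min_separation)
  list(clean = clean, peaks = peaks, emd = emd)
}

interpolate_gaps <- function(values, fps, max_gap) {
  bad <- !is.finite(values)
  if (!any(bad)) return(values)
  runs <- rle(bad)
  if (max(runs$lengths[runs$values]) > max_gap * fps) {
    stop(sprintf(
      "pose dropout longer than %.2g s: recording rejected", max_gap),
      call. = FALSE)
  }
  if (all(bad)) stop("signal has no finite samples", call. = FALSE)
  idx <- seq_along(values)
  values[bad] <- stats::approx(idx[!bad], values[!bad], xout = idx[bad],
                               rule = 2)$y
  values
}
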