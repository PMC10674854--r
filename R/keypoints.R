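#' Hand-pose time series
#'
#' Container for a per-frame 21-landmark 3D hand-pose recording following the
#' MediaPipe hand convention (0 = wrist, 4 = thumb tip, 8 = index tip,
#' 9 = middle-finger MCP). Coordinates may be in any consistent length unit
#' (metric world coordinates or normalized image coordinates): palm
#' normalization downstream removes the scale.
#'
#' Frames containing non-finite coordinates are retained and flagged (their
#' indices are stored in the `missing_frames` attribute); they are
#' interpolated later in the pipeline, never silently dropped.
#'
#' @param coords numeric array of dimension `L x 21 x 3` (frames x landmarks
#'   x xyz), or a list of `L` matrices each `21 x 3`.
#' @param fps frames per second, a single positive number.
#' @param subject_id opaque subject identifier string.
#' @param hand_side one of `"left"`, `"right"`, `"unknown"`.
#' @return An object of class `hand_pose_series`: a list with elements
#'   `coords` (L x 21 x 3 array), `fps`, `subject_id`, `hand_side` and an
#'   integer vector `missing_frames`.
#' @export
hand_pose_series <- function(coords, fps, subject_id = "anonymous",
                             hand_side = c("unknown", "left", "right")) {
  hand_side <- match.arg(hand_side)
  if (is.list(coords)) {
    bad <- which(!vapply(coords, function(m) is.matrix(m) &&
                           all(dim(m) == c(21L, 3L)), logical(1)))
    if (length(bad)) {
      stop("frame ", bad[1], " does not have 21 landmarks with 3 coordinates",
           call. = FALSE)
    }
    coords <- aperm(simplify2array(coords), c(3, 1, 2))
  }
  if (!is.array(coords) || length(dim(coords)) != 3L ||
      dim(coords)[2] != 21L || dim(coords)[3] != 3L) {
    stop("coords must be an L x 21 x 3 array", call. = FALSE)
  }
  if (dim(coords)[1] < 2L) stop("at least 2 frames are required", call. = FALSE)
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("fps must be a single positive number", call. = FALSE)
  }
  storage.mode(coords) <- "double"
  missing_frames <- which(apply(coords, 1, function(f) any(!is.finite(f))))
  structure(
    list(coords = coords, fps = as.numeric(fps), subject_id = subject_id,
         hand_side = hand_side, missing_frames = as.integer(missing_frames)),
    class = "hand_pose_series"
  )
}

#' @export
print.hand_pose_series <- function(x, ...) {
  cat(sprintf(
    "<hand_pose_series> %d frames @ %.5g fps (%.2f s), subject %s, hand %s\n",
    n_frames(x), x$fps, n_frames(x) / x$fps, x$subject_id, x$hand_side))
  if (length(x$missing_frames)) {
    cat(sprintf("  %d frame(s) flagged with non-finite landmarks\n",
                length(x$missing_frames)))
  }
  invisible(x)
}

n_frames <- function(series) dim(series$coords)[1]

#' Subject demographics
#'
#' @param age age in years (non-negative integer).
#' @param sex `"female"` or `"male"`; encoded 0/1 in the feature vector.
#' @return A list of class `demographics`.
#' @export
demographics <- function(age, sex = c("female", "male")) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || length(age) != 1L || !is.finite(age) || age < 0) {
    stop("age must be a single non-negative number", call. = FALSE)
  }
  structure(list(age = as.numeric(age), sex = sex), class = "demographics")
}

#' Read a hand-keypoint time series
#'
#' Two on-disk dialects are supported. CSV (canonical): header
#' `frame,landmark,x,y,z`, one row per (frame, landmark), optionally preceded
#' by comment lines such as `# fps=60`, `# subject_id=s01`, `# hand_side=left`.
#' JSON: an object with fields `fps`, optional `subject_id` / `hand_side`, and
#' `frames`, an array of frames each holding 21 `[x, y, z]` triples.
#'
#' @param path file path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @param fps frame rate override; required if the file carries none.
#' @return A [hand_pose_series()].
#' @export
read_keypoints <- function(path, format = c("auto", "csv", "json"), fps = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") read_keypoints_csv(path, fps) else
    read_keypoints_json(path, fps)
}

read_keypoints_csv <- function(path, fps = NULL) {
  head_lines <- readLines(path, n = 20L, warn = FALSE)
  meta <- parse_hash_metadata(head_lines)
  if (is.null(fps) && !is.null(meta$fps)) fps <- as.numeric(meta$fps)
  if (is.null(fps)) stop("fps not found in file metadata and not supplied",
                         call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("frame", "landmark", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop("keypoint CSV must have columns frame,landmark,x,y,z", call. = FALSE)
  }
  for (col in need) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1]
      stop(sprintf("non-numeric value in column '%s' near data row %d",
                   col, bad), call. = FALSE)
    }
  }
  frames <- sort(unique(df$frame))
  L <- length(frames)
  coords <- array(NA_real_, dim = c(L, 21L, 3L))
  fidx <- match(df$frame, frames)
  lm <- df$landmark
  if (any(lm < 0 | lm > 20)) {
    stop("landmark ids must lie in 0-20", call. = FALSE)
  }
  coords[cbind(fidx, lm + 1L, 1L)] <- df$x
  coords[cbind(fidx, lm + 1L, 2L)] <- df$y
  coords[cbind(fidx, lm + 1L, 3L)] <- df$z
  per_frame <- tapply(lm, fidx, function(v) length(unique(v)))
  short <- which(per_frame < 21L)
  if (length(short)) {
    stop(sprintf("frame %s is missing landmark(s): expected 21, found %d",
                 frames[short[1]], per_frame[short[1]]), call. = FALSE)
  }
  hand_pose_series(coords, fps = fps,
                   subject_id = meta$subject_id %||% "anonymous",
                   hand_side = meta$hand_side %||% "unknown")
}

read_keypoints_json <- function(path, fps = NULL) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(fps)) fps <- obj$fps
  if (is.null(fps)) stop("fps not found in JSON and not supplied", call. = FALSE)
  frames <- obj$frames
  if (is.null(frames)) stop("JSON must contain a 'frames' array", call. = FALSE)
  L <- length(frames)
  coords <- array(NA_real_, dim = c(L, 21L, 3L))
  for (i in seq_len(L)) {
    fr <- frames[[i]]
    if (length(fr) != 21L) {
      stop(sprintf("frame %d has %d landmarks, expected 21", i, length(fr)),
           call. = FALSE)
    }
    for (j in seq_len(21L)) {
      trip <- fr[[j]]
      if (length(trip) != 3L) {
        stop(sprintf("frame %d landmark %d is not an [x,y,z] triple", i, j - 1L),
             call. = FALSE)
      }
      v <- suppressWarnings(as.numeric(unlist(trip)))
      coords[i, j, ] <- v
    }
  }
  hand_pose_series(coords, fps = as.numeric(fps),
                   subject_id = obj$subject_id %||% "anonymous",
                   hand_side = obj$hand_side %||% "unknown")
}

#' Write a hand-keypoint time series
#'
#' Writes the canonical CSV dialect (`frame,landmark,x,y,z` with `# key=value`
#' metadata lines) or the JSON dialect. `read_keypoints()` round-trips either
#' to numerical identity.
#'
#' @param series a [hand_pose_series()].
#' @param path destination file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_keypoints <- function(series, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "hand_pose_series"))
  L <- n_frames(series)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("# fps=%.10g", series$fps),
                 sprintf("# subject_id=%s", series$subject_id),
                 sprintf("# hand_side=%s", series$hand_side),
                 "frame,landmark,x,y,z"), con)
    frame <- rep(seq_len(L) - 1L, each = 21L)
    landmark <- rep(0:20, times = L)
    flat <- aperm(series$coords, c(2, 1, 3))  # landmark-major within frame
    lines <- sprintf("%d,%d,%.17g,%.17g,%.17g", frame, landmark,
                     as.vector(flat[, , 1]), as.vector(flat[, , 2]),
                     as.vector(flat[, , 3]))
    writeLines(lines, con)
  } else {
    frames <- lapply(seq_len(L), function(i) {
      lapply(seq_len(21L), function(j) as.numeric(series$coords[i, j, ]))
    })
    jsonlite::write_json(
      list(fps = series$fps, subject_id = series$subject_id,
           hand_side = series$hand_side, frames = frames),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

parse_hash_metadata <- function(lines) {
  lines <- lines[startsWith(trimws(lines), "#")]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("#\\s*([A-Za-z_]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- trimws(m[3])
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Thumb-index distance signal
#'
#' Per-frame Euclidean distance between two landmarks, by default the thumb
#' tip (4) and index tip (8) whose separation carries the finger-tapping
#' kinematics. Frames with non-finite coordinates yield `NA` samples, which
#' the preprocessing stage interpolates.
#'
#' @param series a [hand_pose_series()].
#' @param a,b landmark indices in 0-20 (defaults 4 and 8).
#' @return A [tap_signal()] in the recording's raw length units.
#' @export
distance_series <- function(series, a = 4L, b = 8L) {
  stopifnot(inherits(series, "hand_pose_series"))
  if (a < 0 || a > 20 || b < 0 || b > 20) {
    stop("landmark indices must lie in 0-20", call. = FALSE)
  }
  d <- series$coords[, a + 1L, , drop = FALSE] -
    series$coords[, b + 1L, , drop = FALSE]
  v <- sqrt(rowSums(matrix(d, ncol = 3L)^2))
  v[!is.finite(v)] <- NA_real_
  tap_signal(v, fps = series$fps, normalized = FALSE)
}

#' Canonical feature-table column names
#'
#' The fifteen features of the scorer in fixed canonical order: age, sex,
#' amplitude variance/mean/breakpoint/slope1/slope2, velocity
#' variance/mean/breakpoint/slope1/slope2, tapping frequency, halt-hesitation
#' count, and peak count.
#'
#' @return Character vector of length 15.
#' @export
tap_feature_names <- function() {
  c("age", "sex",
    "amp_var", "amp_avg", "amp_bp", "amp_alpha1", "amp_alpha2",
    "vel_var", "vel_avg", "vel_bp", "vel_alpha1", "vel_alpha2",
    "freq", "hh", "n_peaks")
}

#' Read and write feature tables
#'
#' Feature CSVs hold one row per recording: `subject_id`, the 15 canonical
#' feature columns of [tap_feature_names()], and (optionally) `label`.
#'
#' @param features data frame with the canonical feature columns.
#' @param path file path.
#' @return `read_features()` returns the validated data frame;
#'   `write_features()` returns `path` invisibly.
#' @export
write_features <- function(features, path) {
  need <- tap_feature_names()
  miss <- setdiff(need, names(features))
  if (length(miss)) {
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  first <- intersect(c("subject_id", need, "label"), names(features))
  utils::write.csv(features[, c(first, setdiff(names(features), first))],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(tap_feature_names(), names(df))
  if (length(miss)) {
    stop("feature table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}
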