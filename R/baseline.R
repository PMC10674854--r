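#' Cutoffs for the rule-based severity classifier
#'
#' The MDS-UPDRS wording grades slowing as slight/mild/moderate and flags an
#' amplitude floor ("can only barely perform") without printing numeric
#' thresholds, so these are configuration values. The defaults are calibrated
#' on the synthetic severity grid: [calibrate_baseline_cutoffs()] places each
#' velocity cutoff at the midpoint of the mean per-tap velocities implied by
#' adjacent severity classes of the default profile, and the amplitude floor
#' midway between the class 3 and class 4 mean amplitudes.
#'
#' @param vel_slight,vel_mild,vel_moderate per-tap velocity (palm sizes/s)
#'   below which slowing counts as slight / mild / moderate.
#' @param decrement_slope second-segment amplitude slope (palm units per tap)
#'   below which a decrement is deemed present.
#' @param amp_floor mean amplitude (palm units) below which the task is
#'   deemed barely performable.
#' @param min_taps fewer detected taps than this is deemed barely
#'   performable (default 4).
#' @return A named list of class `baseline_cutoffs`.
#' @export
baseline_cutoffs <- function(vel_slight = 6.03, vel_mild = 4.24,
                             vel_moderate = 2.75, decrement_slope = -0.02,
                             amp_floor = 0.55, min_taps = 4L) {
  structure(list(vel_slight = vel_slight, vel_mild = vel_mild,
                 vel_moderate = vel_moderate,
                 decrement_slope = decrement_slope,
                 amp_floor = amp_floor, min_taps = as.integer(min_taps)),
            class = "baseline_cutoffs")
}

#' Calibrate baseline cutoffs from a severity profile
#'
#' Computes the expected mean per-tap velocity of each class as
#' `2 * mean amplitude * mean rate` (each tap contributes an opening and a
#' closing sweep of the mean amplitude per cycle) and places each slowing
#' cutoff at the midpoint of adjacent classes; the amplitude floor sits
#' midway between the class 3 and class 4 mean amplitudes, and the decrement
#' slope midway between the class 0 and class 1 mean second slopes.
#'
#' @param profile a severity profile (see [severity_profile()]).
#' @return A [baseline_cutoffs()] object.
#' @export
calibrate_baseline_cutoffs <- function(profile = severity_profile()) {
  mean_of <- function(cls, field) profile[[as.character(cls)]][[field]][1]
  vel <- vapply(0:4, function(cl) 2 * mean_of(cl, "amplitude") *
                  mean_of(cl, "rate"), numeric(1))
  mid <- function(a, b) (a + b) / 2
  baseline_cutoffs(
    vel_slight = mid(vel[1], vel[2]),
    vel_mild = mid(vel[2], vel[3]),
    vel_moderate = mid(vel[3], vel[4]),
    decrement_slope = mid(mean_of(0, "slope2"), mean_of(1, "slope2")),
    amp_floor = mid(mean_of(3, "amplitude"), mean_of(4, "amplitude")))
}

#' Rule-based severity classifier (literal MDS-UPDRS criteria)
#'
#' Operationalizes the finger-tapping rating criteria as a worst-criterion-
#' wins rule cascade over the extracted features:
#'
#' * interruptions (`hh`): 1-2 flags at least 1; 3-5 at least 2; more than 5
#'   at least 3;
#' * amplitude decrement (second slope below `decrement_slope`): breakpoint
#'   in the last third of the sequence flags at least 1; middle of the
#'   sequence at least 2; starting after the first tap (breakpoint <= 2) at
#'   least 3;
#' * slowing (`vel_avg` below the slight / mild / moderate cutoff): at least
#'   1 / 2 / 3;
#' * barely performable (`n_peaks < min_taps` or `amp_avg < amp_floor`): 4.
#'
#' The returned score is the maximum over triggered criteria (0 when none
#' trigger). Like its clinical source, the cascade is deliberately strict at
#' the class boundaries; it is not softened.
#'
#' @param features named numeric feature vector from
#'   [build_feature_vector()], or a data frame / matrix of such rows.
#' @param cutoffs a [baseline_cutoffs()] object.
#' @return Integer score(s) in 0-4.
#' @export
baseline_sp <- function(features, cutoffs = baseline_cutoffs()) {
  if (!is.null(dim(features))) {
    return(vapply(seq_len(nrow(features)), function(i) {
      row <- features[i, , drop = TRUE]
      baseline_sp(stats::setNames(as.numeric(row[tap_feature_names()]),
                                  tap_feature_names()), cutoffs)
    }, integer(1)))
  }
  f <- features
  score <- 0L
  hh <- f[["hh"]]
  if (hh > 5) score <- max(score, 3L)
  else if (hh >= 3) score <- max(score, 2L)
  else if (hh >= 1) score <- max(score, 1L)
  if (f[["amp_alpha2"]] < cutoffs$decrement_slope) {
    bp <- f[["amp_bp"]]
    n <- f[["n_peaks"]]
    if (bp <= 2) score <- max(score, 3L)
    else if (bp <= 2 * n / 3) score <- max(score, 2L)
    else score <- max(score, 1L)
  }
  vel <- f[["vel_avg"]]
  if (vel < cutoffs$vel_moderate) score <- max(score, 3L)
  else if (vel < cutoffs$vel_mild) score <- max(score, 2L)
  else if (vel < cutoffs$vel_slight) score <- max(score, 1L)
  if (f[["n_peaks"]] < cutoffs$min_taps || f[["amp_avg"]] < cutoffs$amp_floor) {
    score <- 4L
  }
  score
}
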