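#' Canonical looming-distance labels, positions and tactile delays
#'
#' The paradigm presents a visual stimulus looming along a 196 cm LED strip at
#' about 32 cm/s. Tactile targets are delivered when the stimulus reaches one
#' of five positions D1..D5 (visuo-tactile trials), or after the matching
#' temporal delay with no visual stimulus (tactile-only trials). The delay
#' lookup reproduces the values printed in the experimental protocol; note the
#' D1/D2 entries differ by a few hundredths of a second from the constant-speed
#' formula, so the lookup is kept verbatim and the formula is exposed
#' separately as [distance_to_delay()].
#'
#' @format Named numeric vectors indexed by `D1..D5`.
#' @name pps_distances
NULL

.pps_distances_cm <- c(D1 = 1, D2 = 49, D3 = 98, D4 = 147, D5 = 196)
.pps_delays_s <- c(D1 = 6.125, D2 = 4.564, D3 = 3.063, D4 = 1.531, D5 = 0)

#' @rdname pps_distances
#' @export
pps_distances_cm <- function() .pps_distances_cm

#' @rdname pps_distances
#' @export
pps_delays_s <- function() .pps_delays_s

#' Convert a looming distance to the tactile-delivery delay
#'
#' Time for a stimulus looming at constant `speed` to travel from the far end
#' of the strip to `distance_cm` from the participant:
#' `(strip_length - distance_cm) / speed`.
#'
#' @param distance_cm Position on the strip, cm from the participant.
#' @param speed Looming speed in cm/s (must be > 0).
#' @param strip_length Strip length in cm.
#' @return Delay in seconds.
#' @examples
#' distance_to_delay(147, 32, 196) # 1.531 s
#' @export
distance_to_delay <- function(distance_cm, speed = 32, strip_length = 196) {
  if (any(speed <= 0)) stop("`speed` must be positive", call. = FALSE)
  if (any(distance_cm < 0 | distance_cm > strip_length)) {
    stop("`distance_cm` must lie within [0, strip_length]", call. = FALSE)
  }
  (strip_length - distance_cm) / speed
}

#' Experimental design configuration
#'
#' Describes the factorial layout of the looming paradigm: participants,
#' the Light Location x Tactile Location conditions, the five distances with
#' their canonical tactile delays, and the per-condition trial counts
#' (defaults: 6 visuo-tactile repetitions per distance, 3 tactile-only
#' repetitions per distance, 3 catch trials, i.e. 30 + 15 + 3 = 48 trials
#' per condition).
#'
#' @param n_participants Number of participants (>= 1).
#' @param light_levels Levels of the Light Location factor.
#' @param tactile_levels Levels of the Tactile Location factor.
#' @param distances_cm Named, strictly increasing distances (cm).
#' @param delays_s Named delays (s), non-increasing with distance; defaults to
#'   the canonical printed lookup (see [pps_delays_s()]).
#' @param reps_vt_per_distance Visuo-tactile repetitions per distance.
#' @param reps_to_per_distance Tactile-only repetitions per distance.
#' @param n_catch Catch (visual-only) trials per condition.
#' @param looming_speed Looming speed, cm/s.
#' @param strip_length Strip length, cm.
#' @return An object of class `pps_design`.
#' @export
design_config <- function(n_participants = 40,
                          light_levels = c("face", "hand", "foot"),
                          tactile_levels = c("face", "hand", "foot"),
                          distances_cm = pps_distances_cm(),
                          delays_s = pps_delays_s(),
                          reps_vt_per_distance = 6,
                          reps_to_per_distance = 3,
                          n_catch = 3,
                          looming_speed = 32,
                          strip_length = 196) {
  if (length(n_participants) != 1 || is.na(n_participants) || n_participants < 1) {
    stop("`n_participants` must be a positive count", call. = FALSE)
  }
  if (is.null(names(distances_cm)) || is.null(names(delays_s))) {
    stop("`distances_cm` and `delays_s` must be named by distance level", call. = FALSE)
  }
  if (!identical(names(distances_cm), names(delays_s))) {
    stop("distance and delay labels do not match", call. = FALSE)
  }
  if (any(diff(distances_cm) <= 0)) {
    stop("`distances_cm` must be strictly increasing", call. = FALSE)
  }
  if (any(diff(delays_s) > 1e-12)) {
    stop("`delays_s` must be non-increasing with distance", call. = FALSE)
  }
  counts <- c(reps_vt_per_distance, reps_to_per_distance, n_catch)
  if (any(counts < 0)) stop("trial counts must be >= 0", call. = FALSE)
  if (looming_speed <= 0) stop("`looming_speed` must be positive", call. = FALSE)
  structure(list(
    n_participants = as.integer(n_participants),
    light_levels = light_levels,
    tactile_levels = tactile_levels,
    distances_cm = distances_cm,
    delays_s = delays_s,
    reps_vt_per_distance = as.integer(reps_vt_per_distance),
    reps_to_per_distance = as.integer(reps_to_per_distance),
    n_catch = as.integer(n_catch),
    looming_speed = looming_speed,
    strip_length = strip_length
  ), class = "pps_design")
}

#' Step-shaped visuo-tactile facilitation profile
#'
#' Builds the `distance_profile` matrix (light level x distance level) used by
#' [effect_config()]: distances at or nearer than the boundary receive the
#' facilitation offset `step` (negative = faster responses inside PPS),
#' farther distances receive 0. `boundary_after` names, per light level, the
#' last facilitated distance, so a boundary "between D3 and D4" is
#' `boundary_after = "D3"`.
#'
#' @param boundary_after Named character vector (one entry per light level) or
#'   a single label recycled over all light levels; `NA` means flat (no step).
#' @param step Facilitation offset in ms applied inside the boundary.
#' @param light_levels,distance_levels Factor levels (row/column order).
#' @return Numeric matrix, rows = light levels, columns = distance levels.
#' @export
step_profile <- function(boundary_after,
                         step = -30,
                         light_levels = c("face", "hand", "foot"),
                         distance_levels = names(pps_distances_cm())) {
  if (length(boundary_after) == 1 && is.null(names(boundary_after))) {
    boundary_after <- stats::setNames(rep(boundary_after, length(light_levels)),
                                      light_levels)
  }
  prof <- matrix(0, nrow = length(light_levels), ncol = length(distance_levels),
                 dimnames = list(light_levels, distance_levels))
  for (l in light_levels) {
    b <- boundary_after[[l]]
    if (is.na(b)) next
    k <- match(b, distance_levels)
    if (is.na(k)) stop("unknown boundary distance level: ", b, call. = FALSE)
    prof[l, seq_len(k)] <- step
  }
  prof
}

#' Default covariance of by-subject Light/Tactile Location effects
#'
#' Independent by-subject effects with a common SD (default 10 ms) for each
#' Light Location and Tactile Location level; rows/columns are named
#' `light:<level>` and `tact:<level>`.
#'
#' @param light_levels,tactile_levels Factor levels.
#' @param sd Common standard deviation, ms.
#' @return A named diagonal covariance matrix (ms^2).
#' @export
default_ranef_cov <- function(light_levels = c("face", "hand", "foot"),
                              tactile_levels = c("face", "hand", "foot"),
                              sd = 10) {
  nm <- c(paste0("light:", light_levels), paste0("tact:", tactile_levels))
  m <- diag(sd^2, length(nm))
  dimnames(m) <- list(nm, nm)
  m
}

#' Generative effect-structure configuration
#'
#' Parameters of the synthetic reaction-time world: a grand mean, a
#' delay-dependent tactile-only offset (default a bell peaking at the
#' mid-trial delay D3 with 25 ms amplitude, mirroring the reported mid-delay
#' slowing of tactile-only responses), a distance-dependent visuo-tactile
#' facilitation profile (default a -30 ms step with boundary D2-D3 for
#' face/hand light and D3-D4 for foot light), per-subject random effects, and
#' contamination (additive outliers, missed responses, catch false alarms).
#'
#' @param grand_mean Grand mean RT, ms.
#' @param delay_profile Named ms offsets for tactile-only trials by distance
#'   level (the distance label indexes the matching temporal delay).
#' @param distance_profile Matrix (light x distance) of ms offsets for
#'   visuo-tactile trials; see [step_profile()].
#' @param tactile_location_offsets Named ms offsets per tactile location.
#' @param subject_sd SD (ms) of the by-subject random intercept.
#' @param random_effect_cov Covariance matrix (ms^2) of by-subject Light and
#'   Tactile Location effects; named dimensions `light:<level>` /
#'   `tact:<level>`. Must be symmetric positive semi-definite.
#' @param residual_sd Trial-level residual SD, ms.
#' @param outlier_rate,outlier_shift Probability of an additive outlier and its
#'   ms shift.
#' @param miss_rate Probability that a real trial gets no response (MCAR).
#' @param catch_fa_rate Probability of a false alarm on a catch trial.
#' @param noise `"normal"` (default, matches the fitted Gaussian likelihood)
#'   or `"lognormal"` (multiplicative, heavier right tail).
#' @return An object of class `pps_effects`.
#' @export
effect_config <- function(grand_mean = 367,
                          delay_profile = c(D1 = 0, D2 = 5, D3 = 25, D4 = 5, D5 = 0),
                          distance_profile = step_profile(
                            c(face = "D2", hand = "D2", foot = "D3")),
                          tactile_location_offsets = c(face = 0, hand = 0, foot = 0),
                          subject_sd = 100,
                          random_effect_cov = default_ranef_cov(),
                          residual_sd = 60,
                          outlier_rate = 0.02,
                          outlier_shift = 600,
                          miss_rate = 0.01,
                          catch_fa_rate = 0.01,
                          noise = c("normal", "lognormal")) {
  noise <- match.arg(noise)
  sds <- c(subject_sd = subject_sd, residual_sd = residual_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  rates <- c(outlier_rate, miss_rate, catch_fa_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (!is.null(random_effect_cov)) {
    if (!isSymmetric(unname(random_effect_cov)) ||
        any(eigen(random_effect_cov, symmetric = TRUE,
                  only.values = TRUE)$values < -1e-8)) {
      stop("`random_effect_cov` must be symmetric positive semi-definite",
           call. = FALSE)
    }
  }
  structure(list(
    grand_mean = grand_mean,
    delay_profile = delay_profile,
    distance_profile = distance_profile,
    tactile_location_offsets = tactile_location_offsets,
    subject_sd = subject_sd,
    random_effect_cov = random_effect_cov,
    residual_sd = residual_sd,
    outlier_rate = outlier_rate,
    outlier_shift = outlier_shift,
    miss_rate = miss_rate,
    catch_fa_rate = catch_fa_rate,
    noise = noise
  ), class = "pps_effects")
}
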