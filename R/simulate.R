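#' Simulate a full visuo-tactile looming experiment
#'
#' Generates one long-format trial table with the configured design: for every
#' participant and every Light x Tactile condition, `5 * reps_vt` visuo-tactile
#' trials, `5 * reps_to` tactile-only trials and `n_catch` catch trials, in a
#' randomized within-condition order. Visuo-tactile RTs follow
#' `grand_mean + distance_profile[light, d]`, tactile-only RTs follow
#' `grand_mean + delay_profile[d]` (both plus tactile-location offsets,
#' by-subject effects and residual noise); outliers and misses are injected
#' afterwards. Identical `(design, effects, seed)` give identical tables.
#'
#' @param design A [design_config()] object.
#' @param effects An [effect_config()] object.
#' @param seed Integer seed; all randomness derives from it.
#' @return A `data.frame` with columns `participant`, `light_location`,
#'   `tactile_location`, `trial_type` (`VT`/`TO`/`catch`), `distance`
#'   (`NA` for catch), `rt_ms` (`NA` when unanswered) and `responded`.
#' @export
generate_dataset <- function(design = design_config(),
                             effects = effect_config(),
                             seed = 1L) {
  generate_trials(design, effects, seed, to_mode = "delay")
}

#' Simulate an experiment under one of the tactile-only hypotheses
#'
#' The three generative regimes correspond to the hypotheses compared by
#' [run_product_space()]:
#' * `H0`: tactile-only trials are drawn from the *same* linear predictor as
#'   visuo-tactile trials (distance profile and subject effects included);
#' * `H1`: tactile-only trials are a single constant mean plus residual noise
#'   (no delay structure, no subject effects, as in the constant-baseline
#'   model `RT = tau + eps`);
#' * `H2`: tactile-only trials carry their own delay-dependent profile
#'   (`delay_profile`), distinct from the visuo-tactile distance profile.
#'
#' Visuo-tactile and catch generation is identical across the three regimes.
#'
#' @param which One of `"H0"`, `"H1"`, `"H2"`.
#' @inheritParams generate_dataset
#' @return A trial `data.frame`; see [generate_dataset()].
#' @export
generate_under_hypothesis <- function(which, design = design_config(),
                                      effects = effect_config(), seed = 1L) {
  mode <- switch(as.character(which),
    H0 = "vt", H1 = "constant", H2 = "delay",
    stop("unknown hypothesis label: ", which, call. = FALSE))
  generate_trials(design, effects, seed, to_mode = mode)
}

# Shared generator, fully vectorized. `to_mode` selects the tactile-only
# predictor: "delay" (own bell profile), "constant" (grand mean only, no
# subject effects), "vt" (same predictor as visuo-tactile trials).
generate_trials <- function(design, effects, seed, to_mode) {
  stopifnot(inherits(design, "pps_design"), inherits(effects, "pps_effects"))
  dlev <- names(design$distances_cm)
  if (!all(dlev %in% names(effects$delay_profile)) ||
      !all(dlev %in% colnames(effects$distance_profile)) ||
      !all(design$light_levels %in% rownames(effects$distance_profile))) {
    stop("distance/light labels of `effects` do not match `design`",
         call. = FALSE)
  }
  if (!all(design$tactile_levels %in% names(effects$tactile_location_offsets))) {
    stop("tactile labels of `effects` do not match `design`", call. = FALSE)
  }
  set.seed(as.integer(seed))

  S <- design$n_participants
  ids <- sprintf("P%04d", seq_len(S))

  # by-subject effects
  intercepts <- stats::rnorm(S, 0, effects$subject_sd)
  re <- effects$random_effect_cov
  re_draws <- NULL
  if (!is.null(re)) {
    re_draws <- MASS::mvrnorm(S, mu = rep(0, ncol(re)), Sigma = re)
    if (S == 1) re_draws <- matrix(re_draws, nrow = 1)
    colnames(re_draws) <- colnames(re)
  }

  # fixed within-condition trial composition
  nb_vt <- length(dlev) * design$reps_vt_per_distance
  nb_to <- length(dlev) * design$reps_to_per_distance
  nb <- nb_vt + nb_to + design$n_catch
  if (nb == 0 || S == 0) {
    return(data.frame(participant = character(), light_location = character(),
                      tactile_location = character(), trial_type = character(),
                      distance = character(), rt_ms = numeric(),
                      responded = logical(), stringsAsFactors = FALSE))
  }
  b_type <- c(rep("VT", nb_vt), rep("TO", nb_to), rep("catch", design$n_catch))
  b_dist <- c(rep(dlev, each = design$reps_vt_per_distance),
              rep(dlev, each = design$reps_to_per_distance),
              rep(NA_character_, design$n_catch))

  conds <- expand.grid(light_location = design$light_levels,
                       tactile_location = design$tactile_levels,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nc <- nrow(conds)
  nblock <- S * nc
  n <- nblock * nb

  pid_i <- rep(seq_len(S), each = nc * nb)
  cond_i <- rep(rep(seq_len(nc), each = nb), times = S)
  light <- conds$light_location[cond_i]
  tact <- conds$tactile_location[cond_i]
  ttype <- rep(b_type, times = nblock)
  dist <- rep(b_dist, times = nblock)

  is_vt <- ttype == "VT"
  is_to <- ttype == "TO"
  is_catch <- ttype == "catch"

  mu <- rep(effects$grand_mean, n)
  mu[is_vt] <- mu[is_vt] +
    effects$distance_profile[cbind(light[is_vt], dist[is_vt])]
  if (to_mode == "delay") {
    mu[is_to] <- mu[is_to] + effects$delay_profile[dist[is_to]]
  } else if (to_mode == "vt") {
    mu[is_to] <- mu[is_to] +
      effects$distance_profile[cbind(light[is_to], dist[is_to])]
  }
  mu[!is_catch] <- mu[!is_catch] +
    effects$tactile_location_offsets[tact[!is_catch]]

  subj_eff <- intercepts[pid_i]
  if (!is.null(re_draws)) {
    lcol <- match(paste0("light:", light), colnames(re_draws))
    tcol <- match(paste0("tact:", tact), colnames(re_draws))
    if (!anyNA(lcol)) subj_eff <- subj_eff + re_draws[cbind(pid_i, lcol)]
    if (!anyNA(tcol)) subj_eff <- subj_eff + re_draws[cbind(pid_i, tcol)]
  }
  add_subj <- rep(TRUE, n)
  if (to_mode == "constant") add_subj[is_to] <- FALSE
  mu[add_subj] <- mu[add_subj] + subj_eff[add_subj]

  rt <- if (effects$noise == "lognormal" && effects$residual_sd > 0) {
    sdl <- effects$residual_sd / effects$grand_mean
    mu * exp(stats::rnorm(n, 0, sdl) - sdl^2 / 2)
  } else {
    mu + stats::rnorm(n, 0, effects$residual_sd)
  }

  real <- !is_catch
  out_hit <- real & stats::runif(n) < effects$outlier_rate
  rt[out_hit] <- rt[out_hit] + effects$outlier_shift
  responded <- rep(TRUE, n)
  responded[real & stats::runif(n) < effects$miss_rate] <- FALSE
  responded[is_catch] <- stats::runif(sum(is_catch)) < effects$catch_fa_rate
  rt[!responded] <- NA_real_
  rt[responded] <- pmax(rt[responded], 1)

  # randomize trial order within each participant x condition block
  gidx <- rep(seq_len(nblock), each = nb)
  perm <- unlist(lapply(split(seq_len(n), gidx),
                        function(ix) ix[sample.int(length(ix))]),
                 use.names = FALSE)

  res <- data.frame(participant = ids[pid_i], light_location = light,
                    tactile_location = tact, trial_type = ttype,
                    distance = dist, rt_ms = rt, responded = responded,
                    stringsAsFactors = FALSE)[perm, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write / read a long-format trial table
#'
#' The CSV uses the canonical header `participant, light_location,
#' tactile_location, trial_type, distance, rt_ms, responded`; a missing RT is
#' an empty field. `write_trials()` also emits a JSON metadata sidecar
#' (`<path>.meta.json`) recording the seed and any extra metadata supplied.
#'
#' @param trials Trial `data.frame` as produced by [generate_dataset()].
#' @param path Output CSV path.
#' @param seed Seed used to generate the data (recorded in the sidecar).
#' @param meta Optional named list of extra metadata for the sidecar.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   the trial `data.frame`.
#' @export
write_trials <- function(trials, path, seed = NULL, meta = list()) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  sidecar <- c(list(seed = seed, n_trials = nrow(trials),
                    written = "ppsbayes"), meta)
  jsonlite::write_json(sidecar, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant = "character",
                                       distance = "character"))
  df$distance[!is.na(df$distance) & df$distance == ""] <- NA_character_
  df$responded <- as.logical(df$responded)
  df$rt_ms <- as.numeric(df$rt_ms)
  df
}
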