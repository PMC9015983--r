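# Shared fixtures and independent oracles used across the suite.

# flat (no-effect) profiles
flat_delay <- c(D1 = 0, D2 = 0, D3 = 0, D4 = 0, D5 = 0)
flat_distance <- step_profile(c(face = NA, hand = NA, foot = NA))

# a quiet, small, fully deterministic effect configuration
quiet_effects <- function(...) {
  effect_config(delay_profile = flat_delay, distance_profile = flat_distance,
                subject_sd = 0, random_effect_cov = NULL, residual_sd = 0,
                outlier_rate = 0, miss_rate = 0, catch_fa_rate = 0, ...)
}

# independent log multivariate-normal density (chol-based), used by the
# conjugate enumeration / product-space oracles
lmvn <- function(y, Sigma) {
  cS <- chol(Sigma)
  -0.5 * length(y) * log(2 * pi) - sum(log(diag(cS))) -
    0.5 * sum(backsolve(cS, y, transpose = TRUE)^2)
}

# brute-force quartiles by linear interpolation of order statistics,
# written independently of stats::quantile
bf_quartile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# brute-force IQR filter oracle
bf_iqr_keep <- function(x, mult = 2 / 3) {
  q1 <- bf_quartile(x, 0.25)
  q3 <- bf_quartile(x, 0.75)
  iqr <- q3 - q1
  x[x >= q1 - mult * iqr & x <= q3 + mult * iqr]
}

# hand-made normalized cell table: one value per participant x tactile x
# distance for a single light level (plus optional extra lights)
make_normalized <- function(n_subj = 30, light = "foot",
                            profile = c(D1 = 0, D2 = 0, D3 = 0, D4 = 0, D5 = 0),
                            sd = 15, seed = 1) {
  set.seed(seed)
  g <- expand.grid(participant = sprintf("S%02d", seq_len(n_subj)),
                   distance = names(profile),
                   tactile_location = c("face", "hand", "foot"),
                   stringsAsFactors = FALSE)
  g$light_location <- light
  subj <- stats::rnorm(n_subj, 0, 10)
  g$rt_ms <- profile[g$distance] + subj[match(g$participant,
                                              sprintf("S%02d", seq_len(n_subj)))] +
    stats::rnorm(nrow(g), 0, sd)
  g
}

# generate -> filter -> aggregate in one step
cells_from <- function(trials) aggregate_cell_means(filter_trials(trials)$trials)
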