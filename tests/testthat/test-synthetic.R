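test_that("default design emits the full factorial trial count", {
  tr <- generate_dataset(seed = 5)
  expect_equal(nrow(tr), 40 * 9 * 48)
  blocks <- table(tr$participant,
                  paste(tr$light_location, tr$tactile_location))
  expect_true(all(blocks == 48))
  comp <- table(tr$trial_type)
  expect_equal(unname(comp[["VT"]]), 40 * 9 * 30)
  expect_equal(unname(comp[["TO"]]), 40 * 9 * 15)
  expect_equal(unname(comp[["catch"]]), 40 * 9 * 3)
  expect_true(all(is.na(tr$distance[tr$trial_type == "catch"])))
  expect_true(all(!is.na(tr$distance[tr$trial_type != "catch"])))
  # rt present iff responded, and positive when present
  expect_identical(is.na(tr$rt_ms), !tr$responded)
  expect_true(all(tr$rt_ms[tr$responded] > 0))
})

test_that("degenerate designs behave: empty design and noiseless limit", {
  des0 <- design_config(reps_vt_per_distance = 0, reps_to_per_distance = 0,
                        n_catch = 0)
  expect_equal(nrow(generate_dataset(des0, effect_config(), seed = 1)), 0)

  tr <- generate_dataset(effects = quiet_effects(grand_mean = 300), seed = 2)
  expect_true(all(tr$rt_ms[tr$responded] == 300))

  # noiseless with profiles: VT follows the distance step, TO the delay bell
  eff <- quiet_effects(grand_mean = 350)
  eff$delay_profile <- c(D1 = 0, D2 = 5, D3 = 25, D4 = 5, D5 = 0)
  eff$distance_profile <- step_profile(c(face = "D2", hand = "D2",
                                         foot = "D3"), step = -30)
  tr <- generate_dataset(effects = eff, seed = 3)
  vt <- tr[tr$trial_type == "VT", ]
  to <- tr[tr$trial_type == "TO", ]
  expect_equal(vt$rt_ms,
               350 + eff$distance_profile[cbind(vt$light_location,
                                                vt$distance)],
               ignore_attr = TRUE)
  expect_equal(to$rt_ms, 350 + unname(eff$delay_profile[to$distance]))
})

test_that("identical configuration and seed give identical trial tables", {
  a <- generate_dataset(seed = 11)
  b <- generate_dataset(seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_dataset(seed = 12)))
})

test_that("distance_to_delay reproduces the protocol geometry", {
  expect_equal(distance_to_delay(147, 32, 196), 1.53125)
  expect_lt(abs(distance_to_delay(147, 32, 196) - 1.531), 1e-3)
  expect_equal(distance_to_delay(196, 32, 196), 0)
  expect_lt(abs(distance_to_delay(98, 32, 196) - 3.063), 1e-3)
  expect_error(distance_to_delay(98, 0, 196), "speed")
  expect_error(distance_to_delay(-5, 32, 196), "strip_length")
  # the canonical lookup is the printed one, deliberately not the formula
  expect_equal(unname(pps_delays_s()[c("D3", "D4", "D5")]),
               c(3.063, 1.531, 0))
})

test_that("configuration errors are caught", {
  expect_error(design_config(n_participants = 0), "positive")
  expect_error(design_config(distances_cm = c(D1 = 10, D2 = 5),
                             delays_s = c(D1 = 1, D2 = 0)), "increasing")
  expect_error(generate_under_hypothesis("H9"), "unknown hypothesis")
  eff <- effect_config(delay_profile = c(DX = 1))
  expect_error(generate_dataset(effects = eff), "labels")
  expect_error(effect_config(outlier_rate = 1.5), "rates")
  expect_error(effect_config(subject_sd = -1), "standard deviations")
})

test_that("hypothesis regimes shape the tactile-only means as declared", {
  eff <- effect_config(outlier_rate = 0, miss_rate = 0)

  # H1: delay profile ignored; TO means flat over delays
  tr1 <- generate_under_hypothesis("H1", effects = eff, seed = 21)
  to1 <- tr1[tr1$trial_type == "TO", ]
  ms <- tapply(to1$rt_ms, to1$distance, mean)
  se <- tapply(to1$rt_ms, to1$distance,
               function(x) stats::sd(x) / sqrt(length(x)))
  expect_true(all(abs(ms - mean(to1$rt_ms)) < 3 * se))

  # H2: TO means by delay reproduce the configured bell within 2 SE
  tr2 <- generate_under_hypothesis("H2", effects = eff, seed = 22)
  to2 <- tr2[tr2$trial_type == "TO", ]
  # remove between-subject variability before comparing to the profile
  subj_m <- tapply(to2$rt_ms, to2$participant, mean)
  ctr <- to2$rt_ms - subj_m[to2$participant]
  ms2 <- tapply(ctr, to2$distance, mean)
  se2 <- tapply(ctr, to2$distance,
                function(x) stats::sd(x) / sqrt(length(x)))
  prof <- eff$delay_profile - mean(eff$delay_profile)
  expect_true(all(abs(ms2 - prof[names(ms2)]) < 2 * se2))

  # H0: TO and VT cell means agree within 2 SE
  tr0 <- generate_under_hypothesis("H0", effects = eff, seed = 23)
  key <- paste(tr0$light_location, tr0$tactile_location, tr0$distance)
  for (k in unique(key[tr0$trial_type != "catch"])) {
    yv <- tr0$rt_ms[key == k & tr0$trial_type == "VT"]
    yt <- tr0$rt_ms[key == k & tr0$trial_type == "TO"]
    sed <- sqrt(stats::var(yv) / length(yv) + stats::var(yt) / length(yt))
    expect_lt(abs(mean(yv) - mean(yt)), 3 * sed)
  }
})

test_that("simulated by-subject effect covariance converges to the spec", {
  sd_l <- 10; sd_t <- 10
  des <- design_config(n_participants = 2000, reps_vt_per_distance = 1,
                       reps_to_per_distance = 0, n_catch = 0)
  eff <- quiet_effects()
  eff$random_effect_cov <- default_ranef_cov(sd = sd_l)
  tr <- generate_dataset(des, eff, seed = 31)
  cm <- stats::aggregate(rt_ms ~ participant + light_location, tr, mean)
  wide <- stats::reshape(cm, idvar = "participant",
                         timevar = "light_location", direction = "wide")
  emp <- stats::cov(wide[, -1])
  # per-light subject mean = grand + e_light + mean(e_tact):
  # Var = sd_l^2 + sd_t^2/3, Cov = sd_t^2/3
  expect_true(all(abs(diag(emp) - (sd_l^2 + sd_t^2 / 3)) < 15))
  off <- emp[upper.tri(emp)]
  expect_true(all(abs(off - sd_t^2 / 3) < 12))
})

test_that("trial CSV round-trips with its metadata sidecar", {
  tr <- generate_dataset(design_config(n_participants = 2), seed = 7)
  path <- tempfile(fileext = ".csv")
  write_trials(tr, path, seed = 7, meta = list(note = "unit"))
  back <- read_trials(path)
  expect_equal(back$rt_ms, tr$rt_ms)
  expect_identical(back$responded, tr$responded)
  expect_identical(back$distance, tr$distance)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$seed, 7)
  expect_equal(meta$n_trials, nrow(tr))
  unlink(c(path, paste0(path, ".meta.json")))
})
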