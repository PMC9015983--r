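test_that("evidence categories follow the strict thresholds", {
  expect_equal(classify_evidence(0.986), "strong-alternative")
  expect_equal(classify_evidence(0.535), "inconclusive")
  expect_equal(classify_evidence(0), "very-strong-null")
  expect_equal(classify_evidence(1), "very-strong-alternative")
  # boundary values fall on the weaker side (strict > / <)
  expect_equal(classify_evidence(c(0.75, 0.95, 0.99)),
               c("inconclusive", "positive-alternative",
                 "strong-alternative"))
  expect_equal(classify_evidence(c(0.25, 0.05, 0.01)),
               c("inconclusive", "positive-null", "strong-null"))
  expect_equal(classify_evidence(c(0.7501, 0.0099)),
               c("positive-alternative", "very-strong-null"))
  expect_error(classify_evidence(1.2), "0, 1")
  expect_error(classify_evidence(-0.1), "0, 1")
})

test_that("IVS inclusion matches brute-force indicator enumeration", {
  # conjugate toy: fixed residual variance and prior scales, so every
  # indicator pattern's marginal likelihood is an exact Gaussian integral
  set.seed(7)
  n <- 30
  x1 <- stats::rnorm(n)
  x2 <- stats::rnorm(n)
  x3 <- stats::rnorm(n)
  y <- 2 + 6 * x1 + 0 * x2 + 1.5 * x3 + stats::rnorm(n, 0, 4)
  sig2 <- 16
  sc <- 10
  s_int <- 200
  X <- cbind(`(Intercept)` = 1, t1 = x1, t2 = x2, t3 = x3)

  pats <- expand.grid(g1 = 0:1, g2 = 0:1, g3 = 0:1)
  lw <- apply(pats, 1, function(g) {
    keep <- c(TRUE, g == 1)
    Xk <- X[, keep, drop = FALSE]
    Vk <- diag(c(s_int^2, rep(sc^2, sum(g))), sum(keep))
    lmvn(y, sig2 * diag(n) + Xk %*% Vk %*% t(Xk)) + sum(g) * log(0.5) +
      (3 - sum(g)) * log(0.5)
  })
  wts <- exp(lw - max(lw))
  wts <- wts / sum(wts)
  exact <- c(t1 = sum(wts[pats$g1 == 1]), t2 = sum(wts[pats$g2 == 1]),
             t3 = sum(wts[pats$g3 == 1]))

  spec <- pps_model_spec(fixed_terms = "distance",
                         prior_scales = c(t1 = sc, t2 = sc, t3 = sc),
                         intercept_scale = s_int, fixed_sigma2 = sig2)
  fit <- ppsbayes:::gibbs_hlm(y, X, assign = 0:3,
                              term_labels = c("t1", "t2", "t3"),
                              W = NULL, subject = NULL, spec = spec,
                              chains = 2, iter = 6000, warmup = 1000,
                              seed = 3, indicators = TRUE)
  m <- as.matrix(fit)
  sampled <- vapply(c("t1", "t2", "t3"),
                    function(t) mean(m[, paste0("g:", t)]), numeric(1))
  expect_lt(max(abs(sampled - exact)), 0.03)
})

test_that("IVS with all terms decisively included matches the plain fit", {
  # strong effects on every factor: inclusion saturates at 1, and the
  # coefficient posteriors should agree with the no-indicator sampler
  eff <- effect_config(
    delay_profile = c(D1 = 0, D2 = 10, D3 = 40, D4 = 10, D5 = 0),
    tactile_location_offsets = c(face = -25, hand = 0, foot = 25),
    outlier_rate = 0, miss_rate = 0)
  eff$distance_profile["foot", ] <- eff$distance_profile["foot", ] - 30
  tr <- generate_under_hypothesis("H2", design_config(n_participants = 20),
                                  eff, seed = 17)
  to <- cells_from(tr)
  to <- to[to$trial_type == "TO", ]
  spec <- pps_model_spec()
  ivs <- run_ivs(to, spec, chains = 2, iter = 2000, warmup = 500, seed = 5,
                 store_draws = TRUE)
  expect_true(all(c("distance", "tactile_location") %in%
                    ivs$inclusion$term[ivs$inclusion$inclusion > 0.99]))
  plain <- sample_posterior(spec, to, chains = 2, iter = 2000, warmup = 500,
                            seed = 6)
  mi <- as.matrix(ivs$draws)
  mp <- as.matrix(plain)
  for (cn in c("b:distance2", "b:tactile_location1")) {
    expect_lt(abs(mean(mi[, cn]) - mean(mp[, cn])),
              4 * stats::sd(mp[, cn]) / sqrt(200))
  }
})

test_that("pure noise shrinks all inclusions below the 0.5 prior", {
  # as the prior scale shrinks to zero the Bayes factor tends to 1 and the
  # inclusion to its 0.5 prior; at scales small relative to the noise the
  # Occam factor must pull every inclusion below the prior
  set.seed(23)
  cells <- expand.grid(participant = sprintf("S%02d", 1:15),
                       distance = paste0("D", 1:5),
                       light_location = c("face", "hand", "foot"),
                       tactile_location = "face",
                       stringsAsFactors = FALSE)
  cells$rt_ms <- stats::rnorm(nrow(cells), 400, 20)
  for (sc in c(15, 30)) {
    spec <- pps_model_spec(fixed_terms = c("distance", "light_location"),
                           random_terms = "intercept",
                           prior_scales = c(distance = sc,
                                            light_location = sc))
    ivs <- run_ivs(cells, spec, chains = 2, iter = 2000, warmup = 500,
                   seed = 11)
    expect_true(all(ivs$inclusion$inclusion < 0.5))
  }
})

test_that("product-space probabilities match exact marginal likelihoods", {
  # small conjugate setting (fixed sigma2, no random effects): each
  # hypothesis' marginal likelihood is an exact Gaussian integral
  set.seed(99)
  grid <- expand.grid(participant = sprintf("P%d", 1:3),
                      distance = c("D1", "D2"), light_location = "face",
                      tactile_location = "face", stringsAsFactors = FALSE)
  mk <- function(mu_fun, sd = 15) {
    g <- grid[rep(seq_len(nrow(grid)), each = 2), ]
    g$rt_ms <- mu_fun(g) + stats::rnorm(nrow(g), 0, sd)
    g
  }
  vt <- mk(function(g) 350 + ifelse(g$distance == "D1", -8, 8))
  to <- mk(function(g) 350 + ifelse(g$distance == "D1", -4, 4))
  sig2 <- 225
  s_int <- 200
  s_coef <- 20
  hset <- pps_hypothesis_set(fixed_terms = "distance", ranef = FALSE,
                             fixed_sigma2 = sig2, coef_scale = s_coef,
                             intercept_scale = s_int)

  X <- cbind(1, ifelse(c(vt$distance, to$distance) == "D1", 1, -1))
  nv <- nrow(vt)
  Xv <- X[1:nv, ]
  Xt <- X[(nv + 1):(2 * nv), ]
  V <- diag(c(s_int^2, s_coef^2))
  yv <- vt$rt_ms
  yt <- to$rt_ms
  m0 <- lmvn(c(yv, yt), sig2 * diag(2 * nv) + X %*% V %*% t(X))
  m_vt <- lmvn(yv, sig2 * diag(nv) + Xv %*% V %*% t(Xv))
  m1 <- m_vt + lmvn(yt, sig2 * diag(nv) + s_int^2 * matrix(1, nv, nv))
  m2 <- m_vt + lmvn(yt, sig2 * diag(nv) + Xt %*% V %*% t(Xt))
  w <- exp(c(m0, m1, m2) - max(c(m0, m1, m2)))
  exact <- w / sum(w)

  psm <- run_product_space(vt, to, hset, chains = 3, iter = 4000,
                           warmup = 1000, pilot_iter = 1500,
                           pilot_warmup = 500, seed = 5)
  expect_equal(sum(psm$p_h), 1)
  expect_lt(max(abs(psm$p_h - exact)), 0.05)
  expect_gt(psm$transitions, 0)
})

test_that("copying the visuo-tactile table into tactile-only favours H0", {
  tr <- generate_dataset(design_config(n_participants = 12), seed = 31)
  cells <- cells_from(tr)
  vt <- cells[cells$trial_type == "VT", ]
  to_copy <- vt
  to_copy$trial_type <- "TO"
  psm <- run_product_space(vt, to_copy, pps_hypothesis_set(),
                           chains = 3, iter = 800, warmup = 300,
                           pilot_iter = 400, pilot_warmup = 150, seed = 7)
  expect_equal(unname(which.max(psm$p_h)), 1)
  expect_equal(sum(psm$p_h), 1)
})
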