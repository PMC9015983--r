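full_cells <- function(n_subj = 4, seed = 1, sd = 10) {
  set.seed(seed)
  g <- expand.grid(participant = sprintf("S%02d", seq_len(n_subj)),
                   distance = paste0("D", 1:5),
                   light_location = c("face", "hand", "foot"),
                   tactile_location = c("face", "hand", "foot"),
                   stringsAsFactors = FALSE)
  g$rt_ms <- 350 + stats::rnorm(nrow(g), 0, sd)
  g
}

test_that("sum-to-zero designs have the expected column structure", {
  cells <- full_cells()
  d_main <- build_design(pps_model_spec(), cells)
  expect_equal(ncol(d_main$X), 1 + 4 + 2 + 2)
  # every contrast column sums to zero over the balanced grid
  expect_true(all(abs(colSums(d_main$X[, -1])) < 1e-9))

  d_int <- build_design(pps_model_spec(fixed_terms = character(0)), cells)
  expect_equal(ncol(d_int$X), 1)
  expect_true(all(d_int$X == 1))

  d_full <- build_design(pps_model_spec(fixed_terms = full_factorial_terms()),
                         cells)
  expect_equal(ncol(d_full$X), 45) # 1+4+2+2+8+8+4+16
  expect_equal(qr(d_full$X)$rank, 45)

  # random-effect design: intercept + 2 light + 2 tactile columns
  d_r <- build_design(pps_model_spec(random_terms = c("intercept",
                                                      "light_location",
                                                      "tactile_location")),
                      cells)
  expect_equal(ncol(d_r$W), 5)

  expect_error(build_design(pps_model_spec(), cells[, -2]), "lacks factor")
  expect_error(pps_model_spec(fixed_terms = "speed"), "fixed terms")
})

test_that("sampler matches the closed-form conjugate posterior", {
  # one coefficient, known residual variance: exact normal posterior
  set.seed(5)
  n <- 40
  y <- stats::rnorm(n, 320, 20)
  sig2 <- 400
  s0 <- 1000 # flat-ish prior on the mean
  post_prec <- n / sig2 + 1 / s0^2
  post_mean <- (sum(y) / sig2) / post_prec

  spec <- pps_model_spec(fixed_terms = character(0), random_terms = "none",
                         fixed_sigma2 = sig2, intercept_scale = s0)
  df <- data.frame(participant = "P1", rt_ms = y)
  d <- build_design(spec, df)
  fit <- ppsbayes:::gibbs_hlm(d$y, d$X, d$assign, d$term_labels, NULL, NULL,
                              spec, chains = 2, iter = 3000, warmup = 500,
                              seed = 8)
  s <- summarize_posterior(fit, pars = "b:(Intercept)")
  draws <- as.matrix(fit)[, "b:(Intercept)"]
  expect_lt(abs(mean(draws) - post_mean), 3 * s$mcse)
  expect_lt(abs(stats::sd(draws) - 1 / sqrt(post_prec)),
            0.15 / sqrt(post_prec))
})

test_that("sampler agrees with an independent JAGS fit of the same model", {
  set.seed(42)
  S <- 15
  df <- expand.grid(participant = sprintf("P%02d", 1:S),
                    distance = paste0("D", 1:5), stringsAsFactors = FALSE)
  u_true <- stats::rnorm(S, 0, 30)
  eff <- c(-10, -5, 0, 5, 10)
  df$rt_ms <- 350 + eff[match(df$distance, paste0("D", 1:5))] +
    u_true[match(df$participant, sprintf("P%02d", 1:S))] +
    stats::rnorm(nrow(df), 0, 20)
  spec <- pps_model_spec(fixed_terms = "distance",
                         random_terms = "intercept",
                         prior_scales = c(distance = 50),
                         intercept_scale = 1000)
  fit <- sample_posterior(spec, df, chains = 2, iter = 4000, warmup = 1000,
                          seed = 9)
  mm <- as.matrix(fit)

  library(rjags)
  d <- build_design(spec, df)
  jd <- list(y = d$y, X = d$X, n = length(d$y), p = ncol(d$X),
             subj = as.integer(d$subject), S = nlevels(d$subject),
             pv = c(1000^2, rep(50^2, ncol(d$X) - 1)))
  model_str <- "model{
    for (i in 1:n) { mu[i] <- inprod(X[i,], beta) + u[subj[i]]
                     y[i] ~ dnorm(mu[i], prec_e) }
    for (k in 1:p) { beta[k] ~ dnorm(0, 1/pv[k]) }
    for (s in 1:S) { u[s] ~ dnorm(0, prec_u) }
    prec_e ~ dgamma(2, 900)      # residual variance ~ IG(2, 900)
    prec_u ~ dgamma(1.5, 450)    # intercept variance ~ IW(3, 900), r = 1
    sigma2 <- 1/prec_e; omega <- 1/prec_u
  }"
  jm <- jags.model(textConnection(model_str), data = jd, n.chains = 2,
                   quiet = TRUE,
                   inits = list(.RNG.name = "base::Mersenne-Twister",
                                .RNG.seed = 77))
  update(jm, 1000, progress.bar = "none")
  samp <- coda.samples(jm, c("beta", "sigma2", "omega"), 3000,
                       progress.bar = "none")
  sm <- summary(samp)$statistics

  for (k in 1:5) {
    mine <- mm[, paste0("b:", colnames(d$X))[k]]
    ref <- sm[paste0("beta[", k, "]"), ]
    expect_lt(abs(mean(mine) - ref["Mean"]), 0.2 * ref["SD"])
    expect_lt(abs(stats::sd(mine) - ref["SD"]), 0.2 * ref["SD"])
  }
  expect_lt(abs(mean(mm[, "sigma2"]) - sm["sigma2", "Mean"]),
            0.25 * sm["sigma2", "SD"])
  expect_lt(abs(mean(mm[, "Omega[1,1]"]) - sm["omega", "Mean"]),
            0.3 * sm["omega", "SD"])
})

test_that("fitted cell predictions are invariant to the contrast scheme", {
  cells <- full_cells(n_subj = 6, seed = 3, sd = 8)
  cells$rt_ms <- cells$rt_ms +
    c(D1 = -10, D2 = -5, D3 = 0, D4 = 5, D5 = 10)[cells$distance]
  est <- lapply(c("sum", "helmert"), function(sch) {
    spec <- pps_model_spec(fixed_terms = "distance", random_terms = "none",
                           prior_scales = c(distance = 100),
                           contrasts = sch)
    fit <- sample_posterior(spec, cells, chains = 2, iter = 2500,
                            warmup = 500, seed = 4)
    ce <- cell_estimates(fit, by = "distance")
    ce$mode[order(ce$distance)]
  })
  expect_lt(max(abs(est[[1]] - est[[2]])), 2)
})

test_that("a zero-variance response yields effect HDIs covering zero", {
  cells <- full_cells(n_subj = 4, sd = 0)
  spec <- pps_model_spec()
  fit <- sample_posterior(spec, cells, chains = 2, iter = 1500, warmup = 500,
                          seed = 6)
  s <- summarize_posterior(fit, pars = grep("^b:distance", fit$par_names,
                                            value = TRUE))
  expect_true(all(s$hdi_low <= 0 & s$hdi_high >= 0))
})

test_that("the stacked log-density is invariant to row permutation", {
  tr <- generate_dataset(design_config(n_participants = 5), seed = 13)
  cells <- cells_from(tr)
  vt <- cells[cells$trial_type == "VT", ]
  to <- cells[cells$trial_type == "TO", ]
  hset <- pps_hypothesis_set()
  dat <- ppsbayes:::psm_prepare(vt, to, hset)
  datp <- ppsbayes:::psm_prepare(vt[sample(nrow(vt)), ],
                                 to[sample(nrow(to)), ], hset)
  for (m in 1:3) {
    st <- ppsbayes:::psm_init_state(m, dat, hset)
    st$u <- stats::rnorm(dat$S, 0, 5)
    if (m == 3) st$tau <- st$tau + stats::rnorm(dat$p)
    expect_equal(ppsbayes:::psm_loglik(m, st, dat, hset),
                 ppsbayes:::psm_loglik(m, st, datp, hset))
  }
})
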