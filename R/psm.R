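# Product-space (Carlin-Chib) comparison of the three hypotheses about the
# structure of tactile-only RTs relative to visuo-tactile RTs:
#   H0: one shared hierarchical predictor for both trial types
#   H1: full predictor for VT, a single constant tau (+ noise) for TO
#   H2: full predictor for VT, a separate coefficient vector tau for TO
# A categorical model index is sampled jointly with all three models'
# parameter blocks; inactive blocks are drawn from pilot-fitted normal
# pseudo-priors, and P(H|D) is the post-warmup visit proportion of the index.

#' Declare the hypothesis set for the product-space comparison
#'
#' @param fixed_terms Fixed-effect terms of the (shared) visuo-tactile
#'   predictor; the same contrast matrix is reused for the tactile-only
#'   equation of H0 (shared coefficients) and H2 (separate coefficients).
#' @param prior_probs Prior model probabilities, named `H0`, `H1`, `H2`
#'   (normalized internally).
#' @param shared_ranef If `TRUE` (default, matching the printed model
#'   formulas) H2 reuses the same by-participant random intercepts for both
#'   equations; if `FALSE` the tactile-only equation gets its own.
#' @param ranef Include by-participant random intercepts at all (the
#'   product-space sampler supports random intercepts; richer random slopes
#'   are available in [sample_posterior()] / [run_ivs()]).
#' @param contrasts Contrast scheme for the fixed effects.
#' @param coef_scale Prior sd (ms) of non-intercept coefficients.
#' @param intercept_scale Prior sd (ms) of intercepts and of the H1 constant.
#' @param sigma2_prior,sb_prior `c(shape, rate)` inverse-gamma priors for the
#'   residual and random-intercept variances.
#' @param fixed_sigma2 Optionally fix all models' residual variance (used by
#'   the conjugate test oracles).
#' @return An object of class `pps_hset`.
#' @export
pps_hypothesis_set <- function(fixed_terms = c("distance", "light_location",
                                               "tactile_location"),
                               prior_probs = c(H0 = 1, H1 = 1, H2 = 1) / 3,
                               shared_ranef = TRUE,
                               ranef = TRUE,
                               contrasts = c("sum", "helmert"),
                               coef_scale = 100,
                               intercept_scale = 1000,
                               sigma2_prior = c(shape = 2, rate = 900),
                               sb_prior = c(shape = 2, rate = 2500),
                               fixed_sigma2 = NULL) {
  contrasts <- match.arg(contrasts)
  stopifnot(length(prior_probs) == 3)
  if (is.null(names(prior_probs))) names(prior_probs) <- c("H0", "H1", "H2")
  prior_probs <- prior_probs / sum(prior_probs)
  structure(list(fixed_terms = fixed_terms, prior_probs = prior_probs,
                 shared_ranef = shared_ranef, ranef = ranef,
                 contrasts = contrasts, coef_scale = coef_scale,
                 intercept_scale = intercept_scale,
                 sigma2_prior = sigma2_prior, sb_prior = sb_prior,
                 fixed_sigma2 = fixed_sigma2),
            class = "pps_hset")
}

# log inverse-gamma density for a variance stored on the log scale
# (includes the Jacobian of v = exp(lv))
ldig_log <- function(lv, a, b) {
  a * log(b) - lgamma(a) - a * lv - b / exp(lv)
}

psm_prepare <- function(vt_cells, to_cells, hset) {
  vt <- as.data.frame(vt_cells)
  to <- as.data.frame(to_cells)
  if (!setequal(unique(vt$participant), unique(to$participant))) {
    stop("visuo-tactile and tactile-only tables cover different participants",
         call. = FALSE)
  }
  cols <- c("participant", "distance", "light_location", "tactile_location",
            "rt_ms")
  df <- rbind(cbind(vt[cols], .type = "VT"), cbind(to[cols], .type = "TO"))
  spec <- pps_model_spec(fixed_terms = hset$fixed_terms,
                         random_terms = "none", contrasts = hset$contrasts)
  d <- build_design(spec, df)
  is_vt <- df$.type == "VT"
  si <- as.integer(d$subject)
  p <- ncol(d$X)
  dinv <- rep(1 / hset$coef_scale^2, p)
  dinv[d$assign == 0L] <- 1 / hset$intercept_scale^2
  list(y = d$y, X = d$X, is_vt = is_vt, si = si, S = nlevels(d$subject),
       subject_levels = levels(d$subject), p = p, dinv = dinv,
       X_vt = d$X[is_vt, , drop = FALSE], X_to = d$X[!is_vt, , drop = FALSE],
       y_vt = d$y[is_vt], y_to = d$y[!is_vt],
       si_vt = si[is_vt], si_to = si[!is_vt],
       XtX_all = crossprod(d$X),
       XtX_vt = crossprod(d$X[is_vt, , drop = FALSE]),
       XtX_to = crossprod(d$X[!is_vt, , drop = FALSE]))
}

psm_init_state <- function(m, dat, hset) {
  st <- list(beta = c(mean(dat$y_vt), rep(0, dat$p - 1)),
             sig = max(stats::var(dat$y), 1e-6), sb = 2500)
  if (!is.null(hset$fixed_sigma2)) st$sig <- hset$fixed_sigma2
  if (m == 1L) {
    st$beta[1] <- mean(dat$y)
  } else if (m == 2L) {
    st$tau <- mean(dat$y_to)
  } else {
    st$tau <- c(mean(dat$y_to), rep(0, dat$p - 1))
  }
  if (hset$ranef) {
    st$u <- rep(0, dat$S)
    if (m == 3L && !hset$shared_ranef) st$u2 <- rep(0, dat$S)
  }
  st
}

# draw from N(A^-1 b, A^-1) given precision A and linear term b
draw_mvn_prec <- function(A, b) {
  cA <- chol(A)
  w <- backsolve(cA, b, transpose = TRUE)
  m <- backsolve(cA, w)
  as.vector(m + backsolve(cA, stats::rnorm(length(b))))
}

draw_subject_normal <- function(resid, si, S, sig, sb, weights_n) {
  Aii <- weights_n / sig + 1 / sb
  sums <- rowsum(resid, si)[, 1]
  # subjects absent from `resid` rows contribute prior draws
  full <- rep(0, S)
  full[sort(unique(si))] <- sums
  mns <- (full / sig) / Aii
  stats::rnorm(S, mns, 1 / sqrt(Aii))
}

psm_mu <- function(m, st, dat, hset) {
  mu <- numeric(length(dat$y))
  if (m == 1L) {
    mu <- as.vector(dat$X %*% st$beta)
    if (hset$ranef) mu <- mu + st$u[dat$si]
  } else if (m == 2L) {
    mu[dat$is_vt] <- as.vector(dat$X_vt %*% st$beta)
    if (hset$ranef) mu[dat$is_vt] <- mu[dat$is_vt] + st$u[dat$si_vt]
    mu[!dat$is_vt] <- st$tau
  } else {
    mu[dat$is_vt] <- as.vector(dat$X_vt %*% st$beta)
    mu[!dat$is_vt] <- as.vector(dat$X_to %*% st$tau)
    if (hset$ranef) {
      mu[dat$is_vt] <- mu[dat$is_vt] + st$u[dat$si_vt]
      uto <- if (hset$shared_ranef) st$u else st$u2
      mu[!dat$is_vt] <- mu[!dat$is_vt] + uto[dat$si_to]
    }
  }
  mu
}

psm_step <- function(m, st, dat, hset) {
  ae <- hset$sigma2_prior[["shape"]]; be <- hset$sigma2_prior[["rate"]]
  ab <- hset$sb_prior[["shape"]]; bb <- hset$sb_prior[["rate"]]
  sig <- st$sig

  if (m == 1L) {
    ystar <- dat$y - if (hset$ranef) st$u[dat$si] else 0
    st$beta <- draw_mvn_prec(dat$XtX_all / sig + diag(dat$dinv, dat$p),
                             crossprod(dat$X, ystar) / sig)
    if (hset$ranef) {
      resid <- dat$y - as.vector(dat$X %*% st$beta)
      st$u <- draw_subject_normal(resid, dat$si, dat$S, sig, st$sb,
                                  tabulate(dat$si, dat$S))
    }
  } else if (m == 2L) {
    yv <- dat$y_vt - if (hset$ranef) st$u[dat$si_vt] else 0
    st$beta <- draw_mvn_prec(dat$XtX_vt / sig + diag(dat$dinv, dat$p),
                             crossprod(dat$X_vt, yv) / sig)
    prec <- length(dat$y_to) / sig + 1 / hset$intercept_scale^2
    st$tau <- stats::rnorm(1, (sum(dat$y_to) / sig) / prec, 1 / sqrt(prec))
    if (hset$ranef) {
      resid <- dat$y_vt - as.vector(dat$X_vt %*% st$beta)
      st$u <- draw_subject_normal(resid, dat$si_vt, dat$S, sig, st$sb,
                                  tabulate(dat$si_vt, dat$S))
    }
  } else {
    uv <- if (hset$ranef) st$u[dat$si_vt] else 0
    ut <- if (!hset$ranef) 0 else if (hset$shared_ranef) st$u[dat$si_to]
          else st$u2[dat$si_to]
    st$beta <- draw_mvn_prec(dat$XtX_vt / sig + diag(dat$dinv, dat$p),
                             crossprod(dat$X_vt, dat$y_vt - uv) / sig)
    st$tau <- draw_mvn_prec(dat$XtX_to / sig + diag(dat$dinv, dat$p),
                            crossprod(dat$X_to, dat$y_to - ut) / sig)
    if (hset$ranef) {
      rv <- dat$y_vt - as.vector(dat$X_vt %*% st$beta)
      rt <- dat$y_to - as.vector(dat$X_to %*% st$tau)
      if (hset$shared_ranef) {
        resid <- numeric(length(dat$y))
        resid[dat$is_vt] <- rv
        resid[!dat$is_vt] <- rt
        st$u <- draw_subject_normal(resid, dat$si, dat$S, sig, st$sb,
                                    tabulate(dat$si, dat$S))
      } else {
        st$u <- draw_subject_normal(rv, dat$si_vt, dat$S, sig, st$sb,
                                    tabulate(dat$si_vt, dat$S))
        st$u2 <- draw_subject_normal(rt, dat$si_to, dat$S, sig, st$sb,
                                     tabulate(dat$si_to, dat$S))
      }
    }
  }

  if (hset$ranef) {
    # translation move along the likelihood-invariant intercept orbit
    # (fixed intercept up, random intercepts down); see gibbs_hlm
    v0 <- hset$intercept_scale^2
    S <- dat$S
    if (m == 3L && hset$shared_ranef) {
      prec <- S / st$sb + 2 / v0
      lin <- sum(st$u) / st$sb - st$beta[1] / v0 - st$tau[1] / v0
      t1 <- stats::rnorm(1, lin / prec, 1 / sqrt(prec))
      st$u <- st$u - t1
      st$beta[1] <- st$beta[1] + t1
      st$tau[1] <- st$tau[1] + t1
    } else {
      prec <- S / st$sb + 1 / v0
      lin <- sum(st$u) / st$sb - st$beta[1] / v0
      t1 <- stats::rnorm(1, lin / prec, 1 / sqrt(prec))
      st$u <- st$u - t1
      st$beta[1] <- st$beta[1] + t1
      if (m == 3L && !hset$shared_ranef) {
        lin2 <- sum(st$u2) / st$sb - st$tau[1] / v0
        t2 <- stats::rnorm(1, lin2 / prec, 1 / sqrt(prec))
        st$u2 <- st$u2 - t2
        st$tau[1] <- st$tau[1] + t2
      }
    }
    uu <- c(st$u, st$u2)
    st$sb <- 1 / stats::rgamma(1, ab + length(uu) / 2, bb + sum(uu^2) / 2)
  }
  if (is.null(hset$fixed_sigma2)) {
    rss <- sum((dat$y - psm_mu(m, st, dat, hset))^2)
    st$sig <- 1 / stats::rgamma(1, ae + length(dat$y) / 2, be + rss / 2)
  }
  st
}

psm_loglik <- function(m, st, dat, hset) {
  sum(stats::dnorm(dat$y, psm_mu(m, st, dat, hset), sqrt(st$sig), log = TRUE))
}

psm_logprior <- function(m, st, dat, hset) {
  lp <- sum(stats::dnorm(st$beta, 0,
                         c(hset$intercept_scale,
                           rep(hset$coef_scale, dat$p - 1)), log = TRUE))
  if (m == 2L) {
    lp <- lp + stats::dnorm(st$tau, 0, hset$intercept_scale, log = TRUE)
  } else if (m == 3L) {
    lp <- lp + sum(stats::dnorm(st$tau, 0,
                                c(hset$intercept_scale,
                                  rep(hset$coef_scale, dat$p - 1)),
                                log = TRUE))
  }
  if (hset$ranef) {
    uu <- c(st$u, st$u2)
    lp <- lp + sum(stats::dnorm(uu, 0, sqrt(st$sb), log = TRUE)) +
      ldig_log(log(st$sb), hset$sb_prior[["shape"]], hset$sb_prior[["rate"]])
  }
  if (is.null(hset$fixed_sigma2)) {
    lp <- lp + ldig_log(log(st$sig), hset$sigma2_prior[["shape"]],
                        hset$sigma2_prior[["rate"]])
  }
  lp
}

# The flat representation used for pseudo-priors works on *identified*
# coordinates: by-subject level means alpha_s = u_s + beta_int (and, for H2,
# the TO intercept offset delta = tau_int - beta_int, plus alpha2 for
# duplicated random intercepts). The likelihood-flat intercept direction then
# sits in a single coordinate (beta_int), so independent normal pseudo-priors
# fitted to pilot draws reproduce the posterior's correlation structure. The
# transform is unit-triangular (volume preserving), so pseudo densities are
# comparable across models without Jacobian terms.
psm_flatten <- function(m, st, hset) {
  v <- st$beta
  if (m == 2L) v <- c(v, st$tau)
  if (m == 3L) v <- c(v, st$tau - c(st$beta[1], rep(0, length(st$tau) - 1)))
  if (hset$ranef) {
    v <- c(v, st$u + st$beta[1])
    if (!is.null(st$u2)) {
      v <- c(v, st$u2 + st$tau[1])
    }
    v <- c(v, log(st$sb))
  }
  if (is.null(hset$fixed_sigma2)) v <- c(v, log(st$sig))
  v
}

psm_unflatten <- function(m, vec, dat, hset) {
  st <- list()
  i <- dat$p
  st$beta <- vec[1:i]
  if (m == 2L) { st$tau <- vec[i + 1]; i <- i + 1 }
  if (m == 3L) {
    st$tau <- vec[(i + 1):(i + dat$p)] +
      c(st$beta[1], rep(0, dat$p - 1))
    i <- i + dat$p
  }
  if (hset$ranef) {
    st$u <- vec[(i + 1):(i + dat$S)] - st$beta[1]; i <- i + dat$S
    if (m == 3L && !hset$shared_ranef) {
      st$u2 <- vec[(i + 1):(i + dat$S)] - st$tau[1]; i <- i + dat$S
    }
    st$sb <- exp(vec[i + 1]); i <- i + 1
  }
  st$sig <- if (is.null(hset$fixed_sigma2)) exp(vec[i + 1])
            else hset$fixed_sigma2
  st
}

psm_pilot <- function(m, dat, hset, iter, warmup, seed) {
  set.seed(seed)
  st <- psm_init_state(m, dat, hset)
  acc <- NULL
  for (it in seq_len(iter)) {
    st <- psm_step(m, st, dat, hset)
    if (it > warmup) {
      v <- psm_flatten(m, st, hset)
      if (is.null(acc)) acc <- matrix(NA_real_, iter - warmup, length(v))
      acc[it - warmup, ] <- v
    }
  }
  list(mean = colMeans(acc),
       sd = pmax(apply(acc, 2, stats::sd) * 1.1, 1e-6))
}

#' Product-space comparison of the three tactile-only hypotheses
#'
#' Runs the Carlin-Chib product-space sampler over `H0`, `H1`, `H2` (see
#' [pps_hypothesis_set()]): short pilot chains fit each model alone and
#' provide normal pseudo-priors (variances on the log scale), then joint
#' chains - one initialized at each hypothesis - sample the categorical model
#' index together with all three parameter blocks. `P(H|D)` is the fraction of
#' post-warmup index draws visiting each hypothesis.
#'
#' @param vt_cells,to_cells Visuo-tactile and tactile-only cell-mean tables
#'   covering the same participants.
#' @param hset A [pps_hypothesis_set()].
#' @param chains Number of joint chains (default 3, initialized at H0/H1/H2).
#' @param iter,warmup Joint-chain iterations and warmup.
#' @param pilot_iter,pilot_warmup Pilot-chain settings.
#' @param seed Integer seed.
#' @return An object of class `pps_psm` with `p_h` (named visit proportions
#'   summing to one), `per_chain` proportions, `transitions` (index switches
#'   post warmup), `stuck` flag (no switches at all; check the pseudo-prior
#'   pilot summaries if the data were expected to be ambiguous), `index`
#'   (list of index chains) and `meta`.
#' @export
run_product_space <- function(vt_cells, to_cells,
                              hset = pps_hypothesis_set(),
                              chains = 3, iter = 1500, warmup = 500,
                              pilot_iter = 800, pilot_warmup = 300,
                              seed = 1) {
  dat <- psm_prepare(vt_cells, to_cells, hset)
  set.seed(as.integer(seed))
  seeds <- sample.int(2147483000L, 3 + chains)
  pseudo <- lapply(1:3, function(m) psm_pilot(m, dat, hset, pilot_iter,
                                              pilot_warmup, seeds[m]))
  lpi <- log(hset$prior_probs)

  index_chains <- vector("list", chains)
  for (ch in seq_len(chains)) {
    set.seed(seeds[3 + ch])
    states <- lapply(1:3, function(m) psm_unflatten(m, pseudo[[m]]$mean,
                                                    dat, hset))
    m_cur <- ((ch - 1L) %% 3L) + 1L
    idx <- integer(iter)
    for (it in seq_len(iter)) {
      states[[m_cur]] <- psm_step(m_cur, states[[m_cur]], dat, hset)
      L <- numeric(3)
      for (k in 1:3) {
        if (k != m_cur) {
          vec <- stats::rnorm(length(pseudo[[k]]$mean), pseudo[[k]]$mean,
                              pseudo[[k]]$sd)
          states[[k]] <- psm_unflatten(k, vec, dat, hset)
        }
        v <- psm_flatten(k, states[[k]], hset)
        lps <- sum(stats::dnorm(v, pseudo[[k]]$mean, pseudo[[k]]$sd,
                                log = TRUE))
        L[k] <- lpi[k] + psm_loglik(k, states[[k]], dat, hset) +
          psm_logprior(k, states[[k]], dat, hset) - lps
      }
      pr <- exp(L - max(L))
      m_cur <- sample.int(3, 1, prob = pr)
      idx[it] <- m_cur
    }
    index_chains[[ch]] <- idx[(warmup + 1):iter]
  }

  all_idx <- unlist(index_chains)
  p_h <- vapply(1:3, function(k) mean(all_idx == k), numeric(1))
  names(p_h) <- c("H0", "H1", "H2")
  per_chain <- t(vapply(index_chains,
                        function(v) vapply(1:3, function(k) mean(v == k),
                                           numeric(1)),
                        numeric(3)))
  colnames(per_chain) <- names(p_h)
  transitions <- sum(vapply(index_chains,
                            function(v) sum(diff(v) != 0), numeric(1)))
  res <- structure(list(p_h = p_h, per_chain = per_chain,
                        transitions = transitions,
                        stuck = transitions == 0 && length(unique(all_idx)) == 1,
                        index = index_chains,
                        pseudo = lapply(pseudo, function(p)
                          list(mean = p$mean, sd = p$sd)),
                        meta = list(chains = chains, iter = iter,
                                    warmup = warmup, pilot_iter = pilot_iter,
                                    pilot_warmup = pilot_warmup, seed = seed)),
                   class = "pps_psm")
  res
}

#' @export
print.pps_psm <- function(x, ...) {
  cat("Product-space model comparison  P(H|D):\n")
  print(round(x$p_h, 4))
  cat("index transitions (post-warmup):", x$transitions,
      if (x$stuck) " [stuck: single model visited]" else "", "\n")
  invisible(x)
}
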