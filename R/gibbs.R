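# Conjugate Gibbs sampler for the hierarchical Gaussian cell-mean model
#
#   y = X beta + Z xi + eps,  eps ~ N(0, sigma2)
#   beta_k ~ N(0, pv_k),      xi_s ~ MVN(0, Omega) per participant
#
# with optional Kuo-Mallick term indicators: each non-intercept term block is
# multiplied by its own Bernoulli gamma. The (gamma, beta_block) pair is
# updated jointly from its full conditional: gamma from the block's marginal
# likelihood ratio (beta integrated out analytically), then beta from its
# conditional (posterior if active, prior if inactive). All other updates are
# standard conjugate draws (normal / inverse-gamma / inverse-Wishart).

gibbs_hlm <- function(y, X, assign, term_labels, W, subject, spec,
                      chains = 2, iter = 2000, warmup = 1000, seed = 1,
                      indicators = FALSE, indicator_prior = 0.5,
                      store_ranef = FALSE) {
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, iter > warmup, chains >= 1)
  if (indicator_prior <= 0 || indicator_prior >= 1) {
    stop("`indicator_prior` must lie in (0, 1)", call. = FALSE)
  }

  # blocks: with indicators, one per term (intercept always active);
  # without, one always-active block over all columns
  if (indicators && length(term_labels)) {
    tids <- sort(unique(assign))
    blocks <- lapply(tids, function(t) {
      list(cols = which(assign == t),
           label = if (t == 0L) "(Intercept)" else term_labels[t],
           indicator = t != 0L)
    })
  } else {
    blocks <- list(list(cols = seq_len(p), label = "(all)", indicator = FALSE))
  }
  ind_labels <- vapply(Filter(function(b) b$indicator, blocks),
                       `[[`, "", "label")
  if (indicators && length(term_labels) && any(lengths(lapply(blocks, `[[`, "cols")) == 0)) {
    stop("term with zero design columns", call. = FALSE)
  }

  # per-column prior variances; NA marks hierarchical (term-level IG scale)
  pv_fixed <- rep(NA_real_, p)
  pv_fixed[assign == 0L] <- spec$intercept_scale^2
  hier_terms <- character(0)
  for (t in seq_along(term_labels)) {
    lab <- term_labels[t]
    sc <- spec$prior_scales[[lab]]
    if (!is.null(sc)) {
      pv_fixed[assign == t] <- sc^2
    } else {
      hier_terms <- c(hier_terms, lab)
    }
  }
  a0 <- spec$coef_hyper[["shape"]]
  b0 <- (a0 - 1) * spec$coef_hyper[["mean_sd"]]^2
  ae <- spec$residual_prior[["shape"]]
  be <- spec$residual_prior[["rate"]]

  # intercept-translation move: when both X and W carry an all-ones column,
  # (beta_int, u_int) is likelihood-invariant along beta_int + t, u - t;
  # sampling t from its exact Gaussian conditional (a generalized Gibbs move
  # along the translation orbit) removes the slow random walk between the
  # fixed intercept and the mean of the random intercepts
  int_col <- which(assign == 0L)
  has_w <- !is.null(W) && ncol(W) > 0
  w_int <- if (has_w) which(colnames(W) == "r(Intercept)") else integer(0)
  do_translate <- length(int_col) == 1 && length(w_int) == 1 &&
    all(X[, int_col] == 1) && all(W[, w_int] == 1)
  if (has_w) {
    r <- ncol(W)
    si <- as.integer(subject)
    S <- nlevels(subject)
    nu0 <- r + 2
    S0 <- diag(spec$omega_scale, r)
    idx_s <- split(seq_len(n), si)
    WtW_s <- lapply(idx_s, function(ix) crossprod(W[ix, , drop = FALSE]))
    ns <- tabulate(si, S)
  }

  Xb <- lapply(blocks, function(b) X[, b$cols, drop = FALSE])
  XtX <- lapply(Xb, crossprod)

  par_names <- c(paste0("b:", colnames(X)),
                 if (length(ind_labels)) paste0("g:", ind_labels),
                 if (length(hier_terms)) paste0("s2:", hier_terms),
                 "sigma2",
                 if (has_w) {
                   ut <- which(upper.tri(diag(r), diag = TRUE), arr.ind = TRUE)
                   paste0("Omega[", ut[, 1], ",", ut[, 2], "]")
                 },
                 if (has_w && store_ranef) {
                   as.vector(outer(levels(subject), seq_len(if (has_w) r else 0),
                                   function(s, j) paste0("u:", s, ":", j)))
                 })

  set.seed(as.integer(seed))
  chain_seeds <- sample.int(2147483000L, chains)
  out_chains <- vector("list", chains)

  for (ch in seq_len(chains)) {
    set.seed(chain_seeds[ch])
    beta <- rep(0, p)
    beta[assign == 0L] <- mean(y)
    gam <- rep(1L, length(ind_labels))
    names(gam) <- ind_labels
    s2h <- stats::setNames(rep(spec$coef_hyper[["mean_sd"]]^2,
                               length(hier_terms)), hier_terms)
    sigma2 <- if (!is.null(spec$fixed_sigma2)) spec$fixed_sigma2
              else max(stats::var(y), 1e-6)
    if (has_w) {
      u <- matrix(0, S, r)
      Omega <- diag(spec$omega_scale, r)
      ucontrib <- rep(0, n)
    } else ucontrib <- rep(0, n)

    gamma_of_block <- function(b) if (b$indicator) gam[[b$label]] else 1L
    fit <- rep(0, n)
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      fit <- fit + Xb[[bi]] %*% beta[b$cols] * gamma_of_block(b)
    }
    fit <- as.vector(fit)

    keep <- matrix(NA_real_, iter - warmup, length(par_names),
                   dimnames = list(NULL, par_names))

    for (it in seq_len(iter)) {
      pv <- pv_fixed
      for (t in hier_terms) pv[assign == match(t, term_labels)] <- s2h[[t]]

      resid_nou <- y - ucontrib
      for (bi in seq_along(blocks)) {
        b <- blocks[[bi]]
        cols <- b$cols
        k <- length(cols)
        g_old <- gamma_of_block(b)
        cur <- as.vector(Xb[[bi]] %*% beta[cols]) * g_old
        rt <- resid_nou - (fit - cur)
        A <- XtX[[bi]] / sigma2 + diag(1 / pv[cols], k)
        bb <- crossprod(Xb[[bi]], rt) / sigma2
        cA <- chol(A)
        wv <- backsolve(cA, bb, transpose = TRUE)
        if (b$indicator) {
          logR <- -0.5 * (2 * sum(log(diag(cA))) + sum(log(pv[cols]))) +
            0.5 * sum(wv^2)
          p1 <- stats::plogis(stats::qlogis(indicator_prior) + logR)
          g <- stats::rbinom(1, 1, p1)
          gam[[b$label]] <- g
        } else g <- 1L
        if (g == 1L) {
          m <- backsolve(cA, wv)
          beta[cols] <- m + backsolve(cA, stats::rnorm(k))
        } else {
          beta[cols] <- stats::rnorm(k, 0, sqrt(pv[cols]))
        }
        fit <- fit - cur + as.vector(Xb[[bi]] %*% beta[cols]) * g
      }

      if (has_w) {
        resid_f <- y - fit
        if (r == 1) {
          w1 <- W[, 1]
          Aii <- rowsum(w1 * w1, si)[, 1] / sigma2 + 1 / Omega[1, 1]
          mns <- (rowsum(w1 * resid_f, si)[, 1] / sigma2) / Aii
          u[, 1] <- stats::rnorm(S, mns, 1 / sqrt(Aii))
        } else {
          Oinv <- chol2inv(chol(Omega))
          for (s in seq_len(S)) {
            ix <- idx_s[[s]]
            A <- WtW_s[[s]] / sigma2 + Oinv
            bs <- crossprod(W[ix, , drop = FALSE], resid_f[ix]) / sigma2
            cAs <- chol(A)
            ms <- backsolve(cAs, backsolve(cAs, bs, transpose = TRUE))
            u[s, ] <- ms + backsolve(cAs, stats::rnorm(r))
          }
        }
        if (do_translate) {
          Oinv <- chol2inv(chol(Omega))
          prec_t <- S * Oinv[w_int, w_int] + 1 / pv[int_col]
          lin_t <- sum(u %*% Oinv[, w_int]) - beta[int_col] / pv[int_col]
          tmove <- stats::rnorm(1, lin_t / prec_t, 1 / sqrt(prec_t))
          u[, w_int] <- u[, w_int] - tmove
          beta[int_col] <- beta[int_col] + tmove
          fit <- fit + tmove
        }
        ucontrib <- if (r == 1) W[, 1] * u[si, 1]
                    else rowSums(W * u[si, , drop = FALSE])
        Sc <- S0 + crossprod(u)
        Wdraw <- stats::rWishart(1, nu0 + S, chol2inv(chol(Sc)))[, , 1]
        Omega <- chol2inv(chol(Wdraw))
      }

      for (t in hier_terms) {
        cols <- which(assign == match(t, term_labels))
        s2h[[t]] <- 1 / stats::rgamma(1, a0 + length(cols) / 2,
                                      b0 + sum(beta[cols]^2) / 2)
      }

      if (is.null(spec$fixed_sigma2)) {
        res <- y - fit - ucontrib
        sigma2 <- 1 / stats::rgamma(1, ae + n / 2, be + sum(res^2) / 2)
      }

      if (it > warmup) {
        row <- c(beta,
                 if (length(ind_labels)) as.numeric(gam),
                 if (length(hier_terms)) as.numeric(s2h),
                 sigma2,
                 if (has_w) Omega[upper.tri(Omega, diag = TRUE)],
                 if (has_w && store_ranef) as.vector(u))
        keep[it - warmup, ] <- row
      }
    }
    out_chains[[ch]] <- keep
  }

  structure(list(chains = out_chains,
                 par_names = par_names,
                 term_labels = term_labels,
                 assign = assign,
                 indicator_terms = ind_labels,
                 meta = list(chains = chains, iter = iter, warmup = warmup,
                             seed = seed, indicators = indicators,
                             indicator_prior = indicator_prior)),
            class = "pps_draws")
}

#' Combine all chains of a posterior-draw object into one matrix
#' @param x A `pps_draws` object.
#' @param ... Unused.
#' @return Matrix of draws (rows) by parameters (columns).
#' @export
as.matrix.pps_draws <- function(x, ...) {
  do.call(rbind, x$chains)
}

#' Sample the posterior of a hierarchical cell-mean model
#'
#' Fits the Gaussian hierarchical linear model declared by `spec` to a
#' cell-mean table by conjugate Gibbs sampling and returns posterior draws for
#' the fixed effects, random effects' covariance, hierarchical prior scales
#' and the residual variance. A split-chain convergence gate (threshold 1.01
#' on the fixed effects) can warn or abort.
#'
#' @param spec A [pps_model_spec()].
#' @param cells Cell-mean table with factor columns and response `rt_ms`.
#' @param chains Number of chains (>= 2 recommended).
#' @param iter,warmup Iterations per chain and warmup to discard.
#' @param seed Integer seed.
#' @param gate `"warn"` (default), `"abort"`, or `"none"`: behaviour when any
#'   fixed effect's split-chain statistic exceeds 1.01.
#' @param store_ranef Store per-participant random-effect draws.
#' @return A `pps_draws` object with the design attached (`$design`).
#' @export
sample_posterior <- function(spec, cells, chains = 2, iter = 2000,
                             warmup = 1000, seed = 1,
                             gate = c("warn", "abort", "none"),
                             store_ranef = FALSE) {
  gate <- match.arg(gate)
  if (chains < 2) stop("`chains` must be >= 2", call. = FALSE)
  if (iter <= warmup) stop("`iter` must exceed `warmup`", call. = FALSE)
  d <- build_design(spec, cells)
  if (any(!is.finite(d$y))) {
    stop("non-finite response; initialization impossible", call. = FALSE)
  }
  fit <- gibbs_hlm(d$y, d$X, d$assign, d$term_labels, d$W, d$subject, spec,
                   chains = chains, iter = iter, warmup = warmup, seed = seed,
                   indicators = FALSE, store_ranef = store_ranef)
  fit$design <- d
  fit$spec <- spec
  if (gate != "none") {
    fx <- grep("^b:", fit$par_names, value = TRUE)
    rh <- vapply(fx, function(pn) split_rhat(lapply(fit$chains,
                                                    function(m) m[, pn])),
                 numeric(1))
    fit$rhat_fixed <- rh
    bad <- names(rh)[rh > 1.01]
    if (length(bad)) {
      msg <- paste0("split-chain statistic > 1.01 for: ",
                    paste(bad, collapse = ", "))
      if (gate == "abort") stop(msg, call. = FALSE) else warning(msg,
                                                                 call. = FALSE)
    }
  }
  fit
}

#' Posterior cell estimates from a fitted model
#'
#' Posterior draws of predicted cell means for each combination of the
#' factors in `by`, averaging (equal weights) over the levels of any other
#' factors in the model.
#'
#' @param fit A `pps_draws` object from [sample_posterior()].
#' @param by Character vector of factor names to condition on.
#' @param mass HDI mass for the summary.
#' @return A `data.frame`: one row per `by` combination with posterior `mode`,
#'   `hdi_low`, `hdi_high`.
#' @export
cell_estimates <- function(fit, by = c("distance", "light_location"),
                           mass = 0.95) {
  d <- fit$design
  stopifnot(!is.null(d))
  lv <- d$levels
  grid <- expand.grid(lv, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  spec <- fit$spec
  if (length(spec$fixed_terms)) {
    fml <- stats::reformulate(spec$fixed_terms)
    needed <- unique(unlist(strsplit(spec$fixed_terms, ":", fixed = TRUE)))
    cfun <- contrast_fun(spec$contrasts)
    for (v in names(lv)) grid[[v]] <- factor(grid[[v]], levels = lv[[v]])
    carg <- stats::setNames(lapply(needed, function(.) cfun), needed)
    Xg <- stats::model.matrix(fml, grid, contrasts.arg = carg)
  } else {
    Xg <- matrix(1, nrow(grid), 1)
  }
  gkey <- do.call(paste, c(grid[by], sep = "\r"))
  draws <- as.matrix.pps_draws(fit)[, paste0("b:", colnames(d$X)), drop = FALSE]
  out <- unique(grid[by])
  rownames(out) <- NULL
  okey <- do.call(paste, c(out[by], sep = "\r"))
  est <- matrix(NA_real_, nrow(out), 3,
                dimnames = list(NULL, c("mode", "hdi_low", "hdi_high")))
  for (i in seq_len(nrow(out))) {
    xrow <- colMeans(Xg[gkey == okey[i], , drop = FALSE])
    dr <- as.vector(draws %*% xrow)
    h <- hdi(dr, mass)
    est[i, ] <- c(posterior_mode(dr), h[1], h[2])
  }
  cbind(out, as.data.frame(est))
}
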