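#' Posterior mode of a sample by kernel density estimation
#'
#' Argmax of a Gaussian kernel density estimate with Silverman's rule-of-thumb
#' bandwidth (`bw = "nrd0"`); falls back to the midpoint of the most populated
#' histogram bin if the KDE fails, and returns the common value for constant
#' samples.
#'
#' @param x Numeric vector of draws.
#' @return Scalar mode estimate.
#' @export
posterior_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(NA_real_)
  if (stats::sd(x) == 0) return(x[1])
  d <- tryCatch(stats::density(x, bw = "nrd0"), error = function(e) NULL)
  if (is.null(d)) {
    h <- graphics::hist(x, breaks = "FD", plot = FALSE)
    return(h$mids[which.max(h$counts)])
  }
  d$x[which.max(d$y)]
}

#' Highest-density interval of a sample
#'
#' The narrowest contiguous interval containing at least `mass` of the draws
#' (computed by sliding a window over the sorted sample). For a fixed sample
#' it is never wider than the equal-tailed interval of the same mass.
#'
#' @param x Numeric vector of draws.
#' @param mass Probability mass (default 0.95).
#' @return Numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  stopifnot(mass > 0, mass <= 1)
  xs <- sort(x[is.finite(x)])
  n <- length(xs)
  if (n == 0) return(c(NA_real_, NA_real_))
  w <- max(1L, ceiling(mass * n))
  if (w >= n) return(c(xs[1], xs[n]))
  widths <- xs[w:n] - xs[1:(n - w + 1)]
  i <- which.min(widths)
  c(xs[i], xs[i + w - 1])
}

#' Split-chain potential-scale-reduction statistic
#'
#' Each chain is split in half and the classical between/within variance
#' ratio is computed over the resulting sub-chains. Values near 1 indicate
#' convergence; the pipeline's gate uses 1.01.
#'
#' @param chains List of numeric vectors (one per chain).
#' @return Scalar statistic (1 for zero-variance draws).
#' @export
split_rhat <- function(chains) {
  halves <- unlist(lapply(chains, function(v) {
    m <- length(v) %/% 2
    if (m < 2) return(list(v))
    list(v[1:m], v[(m + 1):(2 * m)])
  }), recursive = FALSE)
  halves <- Filter(function(v) length(v) >= 2, halves)
  if (length(halves) < 2) return(NA_real_)
  m <- length(halves)
  nn <- length(halves[[1]])
  mus <- vapply(halves, mean, numeric(1))
  s2s <- vapply(halves, stats::var, numeric(1))
  Wv <- mean(s2s)
  Bv <- nn * stats::var(mus)
  if (Wv == 0) return(1)
  sqrt(((nn - 1) / nn * Wv + Bv / nn) / Wv)
}

#' Summarize posterior draws: mode, 95% HDI and convergence diagnostics
#'
#' For each requested parameter: KDE mode, highest-density interval,
#' effective sample size (via \pkg{coda}), split-chain convergence statistic
#' and the Monte-Carlo standard error of the posterior mean
#' (`sd / sqrt(ESS)`). Refuses to summarize fewer than `min_draws` total
#' post-warmup draws.
#'
#' @param draws A `pps_draws` object (or a list of chain matrices).
#' @param pars Character vector of parameter names (default: all).
#' @param mass HDI mass.
#' @param min_draws Minimum total draws required (default 1000).
#' @return A `data.frame` with one row per parameter: `par`, `mode`,
#'   `hdi_low`, `hdi_high`, `ess`, `rhat`, `mcse`.
#' @export
summarize_posterior <- function(draws, pars = NULL, mass = 0.95,
                                min_draws = 1000) {
  chains <- if (inherits(draws, "pps_draws")) draws$chains else draws
  total <- sum(vapply(chains, nrow, integer(1)))
  if (total < min_draws) {
    stop("only ", total, " post-warmup draws; need >= ", min_draws,
         " (increase `iter` or lower `min_draws`)", call. = FALSE)
  }
  if (is.null(pars)) pars <- colnames(chains[[1]])
  all_m <- do.call(rbind, chains)
  rows <- lapply(pars, function(pn) {
    x <- all_m[, pn]
    per_chain <- lapply(chains, function(m) m[, pn])
    h <- hdi(x, mass)
    ess <- if (stats::sd(x) == 0) length(x) else {
      sum(vapply(per_chain,
                 function(v) unname(coda::effectiveSize(coda::mcmc(v))),
                 numeric(1)))
    }
    data.frame(par = pn, mode = posterior_mode(x), hdi_low = h[1],
               hdi_high = h[2], ess = ess, rhat = split_rhat(per_chain),
               mcse = stats::sd(x) / sqrt(max(ess, 1)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
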