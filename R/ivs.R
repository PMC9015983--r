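#' Categorize a posterior probability / inclusion proportion
#'
#' Evidence bands used throughout the pipeline: values above 0.99 / 0.95 /
#' 0.75 support the alternative very strongly / strongly / positively; values
#' below 0.01 / 0.05 / 0.25 support the null correspondingly; anything in
#' `[0.25, 0.75]` is inconclusive. Thresholds are strict (`>` / `<`), so a
#' value exactly at a boundary falls on the weaker side.
#'
#' @param p Numeric vector of proportions in `[0, 1]`.
#' @return Character vector of categories.
#' @export
classify_evidence <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("`p` must lie in [0, 1]", call. = FALSE)
  }
  out <- rep("inconclusive", length(p))
  out[p > 0.75] <- "positive-alternative"
  out[p > 0.95] <- "strong-alternative"
  out[p > 0.99] <- "very-strong-alternative"
  out[p < 0.25] <- "positive-null"
  out[p < 0.05] <- "strong-null"
  out[p < 0.01] <- "very-strong-null"
  out
}

#' Indicator variable selection over fixed-effect terms
#'
#' Kuo-Mallick selection: every non-intercept term's coefficient block is
#' multiplied by its own Bernoulli indicator (prior probability
#' `indicator_prior`), and the term's posterior inclusion proportion is the
#' posterior mean of that indicator. Indicators are updated from the block's
#' analytically-integrated (marginal) likelihood ratio, which mixes well even
#' for multi-column blocks. No heredity rule is enforced: an interaction may
#' be selected while its margins are not.
#'
#' @param cells Cell-mean table (response `rt_ms`).
#' @param spec A [pps_model_spec()]; its `fixed_terms` are the selection
#'   candidates.
#' @param indicator_prior Prior inclusion probability per term, in (0, 1).
#' @param chains,iter,warmup MCMC settings.
#' @param seed Integer seed.
#' @param store_draws Keep the full draw matrices in the result.
#' @return An object of class `pps_ivs`: `inclusion` (`data.frame` with
#'   `term`, `inclusion`, `category`), `conditional` (per-term posterior
#'   summaries of the coefficients given inclusion), and `meta`.
#' @export
run_ivs <- function(cells, spec = pps_model_spec(),
                    indicator_prior = 0.5, chains = 2, iter = 2000,
                    warmup = 500, seed = 1, store_draws = FALSE) {
  if (length(spec$fixed_terms) == 0) {
    stop("`spec` has no candidate terms for selection", call. = FALSE)
  }
  d <- build_design(spec, cells)
  fit <- gibbs_hlm(d$y, d$X, d$assign, d$term_labels, d$W, d$subject, spec,
                   chains = chains, iter = iter, warmup = warmup, seed = seed,
                   indicators = TRUE, indicator_prior = indicator_prior)
  m <- as.matrix.pps_draws(fit)
  terms <- fit$indicator_terms
  inclusion <- vapply(terms, function(t) mean(m[, paste0("g:", t)]),
                      numeric(1))
  tab <- data.frame(term = terms, inclusion = unname(inclusion),
                    category = classify_evidence(unname(inclusion)),
                    row.names = NULL)
  conditional <- lapply(terms, function(t) {
    act <- m[, paste0("g:", t)] == 1
    cols <- paste0("b:", colnames(d$X)[d$assign == match(t, d$term_labels)])
    if (sum(act) < 10) {
      return(data.frame(coefficient = cols, mode = NA_real_,
                        hdi_low = NA_real_, hdi_high = NA_real_))
    }
    do.call(rbind, lapply(cols, function(cn) {
      x <- m[act, cn]
      h <- hdi(x)
      data.frame(coefficient = cn, mode = posterior_mode(x),
                 hdi_low = h[1], hdi_high = h[2])
    }))
  })
  names(conditional) <- terms
  structure(list(inclusion = tab, conditional = conditional,
                 draws = if (store_draws) fit,
                 meta = list(indicator_prior = indicator_prior,
                             chains = chains, iter = iter, warmup = warmup,
                             seed = seed)),
            class = "pps_ivs")
}

#' @export
print.pps_ivs <- function(x, ...) {
  cat("Indicator variable selection (prior inclusion ",
      x$meta$indicator_prior, ")\n", sep = "")
  print(x$inclusion, row.names = FALSE)
  invisible(x)
}
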