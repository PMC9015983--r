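#' Repeated-measures sample-size computation
#'
#' The a-priori sample size for a paired repeated-measures comparison with
#' Bonferroni correction over `m` comparisons:
#'
#' `n_raw = 2 * sigma^2 * (z_{1 - alpha/(2m)} + z_{power})^2 / delta^2`
#'
#' where `z` is the standard-normal quantile. The returned `n` is `n_raw`
#' truncated to an integer (truncation reconciles the formula with the
#' planning value used for this paradigm: alpha 0.05, power 0.90, delta
#' 10 ms, sigma 10 and m = 36 give n_raw 40.11 and n = 40). The variance
#' input is interpreted on the standard-deviation scale (`sigma = 10` means
#' `sigma^2 = 100`); the output restates this interpretation.
#'
#' @param alpha Type-I error rate (0, 1).
#' @param power Target power (0, 1).
#' @param delta Minimal meaningful difference, ms (> 0).
#' @param sigma Standard-deviation-scale variance input, ms.
#' @param m Number of Bonferroni comparisons (>= 1).
#' @return A list: `n` (truncated integer), `n_raw`, and `inputs` (including
#'   the note on the sigma interpretation).
#' @export
rm_anova_sample_size <- function(alpha = 0.05, power = 0.90, delta = 10,
                                 sigma = 10, m = 36) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must lie in (0, 1)", call. = FALSE)
  if (power <= 0 || power >= 1) stop("`power` must lie in (0, 1)", call. = FALSE)
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  za <- stats::qnorm(1 - alpha / (2 * m))
  zb <- stats::qnorm(power)
  n_raw <- 2 * sigma^2 * (za + zb)^2 / delta^2
  list(n = as.integer(floor(n_raw)), n_raw = n_raw,
       inputs = list(alpha = alpha, power = power, delta = delta,
                     sigma = sigma, m = m,
                     note = "sigma enters on the sd scale (sigma^2 used)"))
}
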