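#' Declare a hierarchical linear model for cell-mean reaction times
#'
#' A model specification names the fixed-effect terms (factors and `:`
#' interactions over `distance`, `light_location`, `tactile_location`), the
#' by-participant random terms, the contrast coding, and the priors. Distance
#' is always treated as a 5-level categorical factor.
#'
#' Priors: each fixed-effect coefficient gets an independent normal prior
#' `N(0, sigma_term^2)`. A term listed in `prior_scales` uses that fixed scale
#' (sd, ms); otherwise the term's variance gets a conjugate inverse-gamma
#' hyperprior with shape `coef_hyper["shape"]` and rate such that the prior
#' mean scale is `coef_hyper["mean_sd"]`. The intercept always uses the fixed
#' `intercept_scale`. The residual variance has an inverse-gamma prior (or can
#' be fixed via `fixed_sigma2`, used by the conjugate test oracles), and the
#' random-effect covariance an inverse-Wishart prior.
#'
#' @param fixed_terms Character vector of fixed-effect terms, e.g.
#'   `c("distance", "light_location", "distance:light_location")`. An
#'   interaction may only appear if its margins' columns exist in the data,
#'   but margins need not be in the model (no heredity enforcement).
#' @param random_terms Subset of `c("intercept", "light_location",
#'   "tactile_location")`, or `"none"` for no random effects.
#' @param contrasts `"sum"` (sum-to-zero, default) or `"helmert"`.
#' @param prior_scales Optional named numeric: fixed prior sd (ms) per term.
#' @param intercept_scale Prior sd (ms) of the intercept.
#' @param coef_hyper `c(shape, mean_sd)` of the inverse-gamma hyperprior on
#'   hierarchical term variances (prior mean variance `mean_sd^2`).
#' @param residual_prior `c(shape, rate)` of the inverse-gamma prior on the
#'   residual variance (rate in ms^2).
#' @param fixed_sigma2 If non-`NULL`, the residual variance is held fixed at
#'   this value instead of being sampled.
#' @param omega_scale Diagonal (ms^2) of the inverse-Wishart scale matrix for
#'   the random-effect covariance; degrees of freedom are `r + 2`.
#' @param response Label of the response the model is meant for (free text,
#'   e.g. `"TO"`, `"VT"`, `"normalized"`); informational.
#' @return An object of class `pps_model_spec`.
#' @export
pps_model_spec <- function(fixed_terms = c("distance", "light_location",
                                           "tactile_location"),
                           random_terms = "intercept",
                           contrasts = c("sum", "helmert"),
                           prior_scales = NULL,
                           intercept_scale = 1000,
                           coef_hyper = c(shape = 2, mean_sd = 50),
                           residual_prior = c(shape = 2, rate = 900),
                           fixed_sigma2 = NULL,
                           omega_scale = 900,
                           response = "rt_ms") {
  contrasts <- match.arg(contrasts)
  if (identical(random_terms, "none")) random_terms <- character(0)
  ok_r <- c("intercept", "light_location", "tactile_location")
  if (!all(random_terms %in% ok_r)) {
    stop("`random_terms` must be drawn from ", paste(ok_r, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(prior_scales) && any(prior_scales <= 0)) {
    stop("prior scales must be positive", call. = FALSE)
  }
  vars <- unique(unlist(strsplit(fixed_terms, ":", fixed = TRUE)))
  ok_f <- c("distance", "light_location", "tactile_location")
  if (length(fixed_terms) && !all(vars %in% ok_f)) {
    stop("fixed terms must be built from ", paste(ok_f, collapse = ", "),
         call. = FALSE)
  }
  structure(list(
    fixed_terms = fixed_terms, random_terms = random_terms,
    contrasts = contrasts, prior_scales = prior_scales,
    intercept_scale = intercept_scale, coef_hyper = coef_hyper,
    residual_prior = residual_prior, fixed_sigma2 = fixed_sigma2,
    omega_scale = omega_scale, response = response
  ), class = "pps_model_spec")
}

#' Expand all two- and three-way interactions of the experimental factors
#' @return Character vector of the 7 factorial terms.
#' @export
full_factorial_terms <- function() {
  c("distance", "light_location", "tactile_location",
    "distance:light_location", "distance:tactile_location",
    "light_location:tactile_location",
    "distance:light_location:tactile_location")
}

contrast_fun <- function(scheme) {
  switch(scheme, sum = stats::contr.sum, helmert = stats::contr.helmert)
}

#' Build fixed- and random-effect design matrices from a cell-mean table
#'
#' Factor levels are taken from the data in sorted order (distance labels
#' D1..D5 sort naturally), giving a deterministic column ordering. Fixed
#' effects use full-rank sum-to-zero (or Helmert) contrasts; random effects
#' are by-participant columns for the requested terms (intercept plus
#' sum-to-zero light/tactile columns).
#'
#' @param spec A [pps_model_spec()].
#' @param cells Cell-mean table (one row per cell) with the factor columns and
#'   the response column `rt_ms`.
#' @return A list with `X` (fixed design), `assign` (integer term id per
#'   column, 0 = intercept), `term_labels`, `W` (per-row random-effect design,
#'   or `NULL`), `ranef_names`, `subject` (factor), `levels` (named list), and
#'   `y`.
#' @export
build_design <- function(spec, cells) {
  needed <- unique(unlist(strsplit(spec$fixed_terms, ":", fixed = TRUE)))
  miss <- setdiff(needed, names(cells))
  if (length(miss)) stop("data lacks factor column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(cells)
  fac_cols <- intersect(c("distance", "light_location", "tactile_location"),
                        names(df))
  for (v in fac_cols) df[[v]] <- factor(df[[v]], levels = sort(unique(df[[v]])))
  cfun <- contrast_fun(spec$contrasts)

  if (length(spec$fixed_terms) == 0) {
    X <- matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
    assign <- 0L
    term_labels <- character(0)
  } else {
    fml <- stats::reformulate(spec$fixed_terms)
    carg <- stats::setNames(lapply(needed, function(.) cfun), needed)
    mf <- stats::model.frame(fml, df)
    X <- stats::model.matrix(fml, mf, contrasts.arg = carg)
    assign <- attr(X, "assign")
    term_labels <- attr(stats::terms(fml), "term.labels")
    if (qr(X)$rank < ncol(X)) {
      stop("rank-deficient fixed-effect design; check factor levels",
           call. = FALSE)
    }
  }

  subject <- factor(df$participant)
  W <- NULL
  ranef_names <- character(0)
  if (length(spec$random_terms)) {
    Wl <- list()
    if ("intercept" %in% spec$random_terms) {
      Wl$intercept <- matrix(1, nrow(df), 1,
                             dimnames = list(NULL, "r(Intercept)"))
    }
    for (v in setdiff(spec$random_terms, "intercept")) {
      f <- factor(df[[v]], levels = sort(unique(df[[v]])))
      C <- cfun(nlevels(f))
      M <- C[as.integer(f), , drop = FALSE]
      colnames(M) <- paste0("r", v, seq_len(ncol(M)))
      Wl[[v]] <- M
    }
    W <- do.call(cbind, Wl)
    ranef_names <- colnames(W)
  }
  list(X = X, assign = as.integer(assign), term_labels = term_labels,
       W = W, ranef_names = ranef_names, subject = subject,
       levels = lapply(df[fac_cols], levels),
       y = df[["rt_ms"]])
}
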