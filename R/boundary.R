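#' Locate the PPS boundary from normalized RTs by consecutive-distance
#' contrasts
#'
#' For one Light Location level, each adjacent distance pair (D1-D2, D2-D3,
#' D3-D4, D4-D5) is tested by indicator variable selection: a model with an
#' always-present mean, a by-participant random intercept and a single
#' difference term (coded -1/2, +1/2) whose Bernoulli indicator yields the
#' contrast's inclusion proportion. The declared boundary is the adjacent
#' pair with the largest inclusion proportion above `threshold`; when the top
#' candidates lie within `tie_tol` of each other the nearer pair is declared
#' and the tie flagged. `method = "joint"` instead fits one model with four
#' cumulative step terms, one indicator each.
#'
#' @param normalized Normalized cell-mean table from [normalize_vt()].
#' @param light Light Location level to analyse.
#' @param distances_cm Named distance lookup (label -> cm).
#' @param threshold Positive-evidence threshold for declaring a boundary.
#' @param tie_tol Two candidate contrasts within this distance of the maximum
#'   inclusion are treated as tied.
#' @param indicator_prior Prior inclusion probability of the difference term.
#' @param chains,iter,warmup MCMC settings per contrast.
#' @param seed Integer seed.
#' @param method `"per-contrast"` (default) or `"joint"`.
#' @return An object of class `pps_boundary_row`: `light`, `contrasts` (a
#'   `data.frame` with `pair`, `d_low_cm`, `d_high_cm`, `inclusion`,
#'   `category`), `boundary` (`c(low, high)` in cm, or `NULL`), `tie` flag.
#' @export
consecutive_contrasts <- function(normalized, light,
                                  distances_cm = pps_distances_cm(),
                                  threshold = 0.75, tie_tol = 0.05,
                                  indicator_prior = 0.5,
                                  chains = 2, iter = 1500, warmup = 500,
                                  seed = 1,
                                  method = c("per-contrast", "joint")) {
  method <- match.arg(method)
  df <- as.data.frame(normalized)
  df <- df[df$light_location == light, , drop = FALSE]
  dlev <- names(distances_cm)
  if (!all(dlev %in% df$distance)) {
    stop("normalized table lacks distance level(s) ",
         paste(setdiff(dlev, unique(df$distance)), collapse = ", "),
         " for light level '", light, "'", call. = FALSE)
  }
  npair <- length(dlev) - 1
  pair_lab <- paste0(dlev[-length(dlev)], "-", dlev[-1])

  prior_holder <- pps_model_spec(fixed_terms = "distance",
                                 random_terms = "intercept")
  set.seed(as.integer(seed))
  seeds <- sample.int(2147483000L, npair)

  incl <- numeric(npair)
  if (method == "per-contrast") {
    for (j in seq_len(npair)) {
      sub <- df[df$distance %in% dlev[c(j, j + 1)], , drop = FALSE]
      x <- ifelse(sub$distance == dlev[j + 1], 0.5, -0.5)
      X <- cbind(`(Intercept)` = 1, step = x)
      subject <- factor(sub$participant)
      W <- matrix(1, nrow(sub), 1, dimnames = list(NULL, "r(Intercept)"))
      fit <- gibbs_hlm(sub$rt_ms, X, assign = c(0L, 1L),
                       term_labels = "step", W = W, subject = subject,
                       spec = prior_holder, chains = chains, iter = iter,
                       warmup = warmup, seed = seeds[j], indicators = TRUE,
                       indicator_prior = indicator_prior)
      incl[j] <- mean(as.matrix.pps_draws(fit)[, "g:step"])
    }
  } else {
    d_idx <- match(df$distance, dlev)
    Xs <- vapply(seq_len(npair), function(j) as.numeric(d_idx > j),
                 numeric(nrow(df)))
    colnames(Xs) <- paste0("step", seq_len(npair))
    X <- cbind(`(Intercept)` = 1, Xs)
    subject <- factor(df$participant)
    W <- matrix(1, nrow(df), 1, dimnames = list(NULL, "r(Intercept)"))
    fit <- gibbs_hlm(df$rt_ms, X, assign = c(0L, seq_len(npair)),
                     term_labels = colnames(Xs), W = W, subject = subject,
                     spec = prior_holder, chains = chains, iter = iter,
                     warmup = warmup, seed = seeds[1], indicators = TRUE,
                     indicator_prior = indicator_prior)
    m <- as.matrix.pps_draws(fit)
    incl <- vapply(seq_len(npair),
                   function(j) mean(m[, paste0("g:step", j)]), numeric(1))
  }

  contrasts <- data.frame(pair = pair_lab,
                          d_low_cm = unname(distances_cm[-length(dlev)]),
                          d_high_cm = unname(distances_cm[-1]),
                          inclusion = incl,
                          category = classify_evidence(incl))
  cand <- which(incl > threshold)
  boundary <- NULL
  tie <- FALSE
  if (length(cand)) {
    best <- max(incl[cand])
    near_best <- cand[incl[cand] >= best - tie_tol]
    tie <- length(near_best) > 1
    pick <- near_best[which.min(contrasts$d_low_cm[near_best])]
    boundary <- c(contrasts$d_low_cm[pick], contrasts$d_high_cm[pick])
  }
  structure(list(light = light, contrasts = contrasts, boundary = boundary,
                 tie = tie, threshold = threshold, method = method),
            class = "pps_boundary_row")
}

#' Boundary scan over all Light Location levels
#'
#' Applies [consecutive_contrasts()] to every light level present in the
#' normalized table.
#'
#' @inheritParams consecutive_contrasts
#' @param lights Light levels to scan (default: all present).
#' @param ... Passed on to [consecutive_contrasts()].
#' @return A list of `pps_boundary_row` objects (class `pps_boundary`), named
#'   by light level.
#' @export
boundary_scan <- function(normalized, lights = NULL, seed = 1, ...) {
  if (is.null(lights)) lights <- sort(unique(normalized$light_location))
  set.seed(as.integer(seed))
  seeds <- sample.int(2147483000L, length(lights))
  out <- Map(function(l, s) consecutive_contrasts(normalized, l,
                                                  seed = s, ...),
             lights, seeds)
  names(out) <- lights
  class(out) <- "pps_boundary"
  out
}

#' @export
print.pps_boundary_row <- function(x, ...) {
  cat("Light =", x$light, "\n")
  print(x$contrasts, row.names = FALSE)
  if (is.null(x$boundary)) {
    cat("no boundary declared (no contrast >", x$threshold, ")\n")
  } else {
    cat("boundary between", x$boundary[1], "and", x$boundary[2], "cm",
        if (x$tie) "[tie]" else "", "\n")
  }
  invisible(x)
}
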