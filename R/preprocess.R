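#' Interquartile-range outlier filter for reaction times
#'
#' Keeps values inside `[Q1 - multiplier*IQR, Q3 + multiplier*IQR]` (bounds
#' inclusive), with quartiles computed by linear interpolation of order
#' statistics (`stats::quantile` type 7). The default multiplier is the 2/3
#' used for RT cleaning in this paradigm. An empty input yields an empty
#' output with a zero-count report rather than an error.
#'
#' @param rts Numeric vector of reaction times (ms), no `NA`s.
#' @param multiplier IQR multiplier (default `2/3`).
#' @return A list with `kept` (the surviving values) and `report` (one-row
#'   `data.frame`: `lower_ms`, `upper_ms`, `n_removed_outlier`, `n_kept`).
#' @export
iqr_filter <- function(rts, multiplier = 2 / 3) {
  if (length(rts) == 0) {
    return(list(kept = numeric(0),
                report = data.frame(lower_ms = NA_real_, upper_ms = NA_real_,
                                    n_removed_outlier = 0L, n_kept = 0L)))
  }
  if (anyNA(rts)) stop("`rts` must not contain NA; remove non-responses first",
                       call. = FALSE)
  q <- stats::quantile(rts, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - multiplier * iqr
  hi <- q[2] + multiplier * iqr
  keep <- rts >= lo & rts <= hi
  list(kept = rts[keep],
       report = data.frame(lower_ms = lo, upper_ms = hi,
                           n_removed_outlier = sum(!keep),
                           n_kept = sum(keep)))
}

#' Drop non-responses and catch trials from a trial table
#'
#' Removes trials without a response; catch (visual-only) trials are excluded
#' from RT analyses regardless of whether they were (erroneously) answered.
#'
#' @param trials Trial `data.frame` (see [generate_dataset()]).
#' @return The analyzable subset of `trials`.
#' @export
remove_nonresponses <- function(trials) {
  trials[trials$responded & trials$trial_type != "catch", , drop = FALSE]
}

#' Per-participant IQR filtering of a trial table
#'
#' Applies [remove_nonresponses()] and then [iqr_filter()] to each
#' participant's pooled RTs (visuo-tactile and tactile-only together, the
#' default) or separately within each trial type x condition cell
#' (`by_condition = TRUE`).
#'
#' @param trials Trial `data.frame`.
#' @param multiplier IQR multiplier.
#' @param by_condition If `TRUE`, filter within participant x trial type x
#'   light x tactile x distance groups instead of pooling.
#' @return A list with `trials` (the kept rows) and `report` (per-participant
#'   `data.frame` with filter bounds, `n_removed_outlier`,
#'   `n_removed_nonresponse` and `n_kept`; bounds are `NA` when
#'   `by_condition = TRUE` since they vary within participant).
#' @export
filter_trials <- function(trials, multiplier = 2 / 3, by_condition = FALSE) {
  real <- trials[trials$trial_type != "catch", , drop = FALSE]
  answered <- real[real$responded, , drop = FALSE]
  n_miss <- tapply(!real$responded, real$participant, sum)

  if (!by_condition) {
    groups <- answered$participant
  } else {
    groups <- interaction(answered$participant, answered$trial_type,
                          answered$light_location, answered$tactile_location,
                          answered$distance, drop = TRUE)
  }
  keep <- rep(TRUE, nrow(answered))
  bounds <- list()
  for (g in unique(groups)) {
    idx <- which(groups == g)
    f <- iqr_filter(answered$rt_ms[idx], multiplier)
    keep[idx] <- answered$rt_ms[idx] >= f$report$lower_ms &
      answered$rt_ms[idx] <= f$report$upper_ms
    bounds[[as.character(g)]] <- f$report
  }
  kept <- answered[keep, , drop = FALSE]

  ids <- sort(unique(real$participant))
  report <- data.frame(
    participant = ids,
    lower_ms = NA_real_, upper_ms = NA_real_,
    n_removed_outlier = as.integer(tapply(!keep, answered$participant, sum)[ids]),
    n_removed_nonresponse = as.integer(n_miss[ids]),
    n_kept = as.integer(tapply(keep, answered$participant, sum)[ids]),
    row.names = NULL
  )
  report$n_removed_outlier[is.na(report$n_removed_outlier)] <- 0L
  report$n_kept[is.na(report$n_kept)] <- 0L
  if (!by_condition) {
    for (id in ids) {
      if (!is.null(bounds[[id]])) {
        report[report$participant == id, c("lower_ms", "upper_ms")] <-
          bounds[[id]][, c("lower_ms", "upper_ms")]
      }
    }
  }
  list(trials = kept, report = report)
}

#' Aggregate filtered trials to per-participant cell means
#'
#' Arithmetic mean RT per (participant, trial type, distance, light location,
#' tactile location) cell, with the number of contributing trials. Cells
#' present in `expected` (a `data.frame` of key columns) but absent from the
#' output are reported in the `"gaps"` attribute.
#'
#' @param trials Filtered trial `data.frame`.
#' @param expected Optional `data.frame` of expected key combinations.
#' @return A `data.frame` (class `pps_cells`) with key columns, `rt_ms` (cell
#'   mean) and `n_trials`; attribute `gaps` lists missing expected cells.
#' @export
aggregate_cell_means <- function(trials, expected = NULL) {
  key_cols <- c("participant", "trial_type", "distance",
                "light_location", "tactile_location")
  if (nrow(trials) == 0) {
    out <- data.frame(participant = character(), trial_type = character(),
                      distance = character(), light_location = character(),
                      tactile_location = character(), rt_ms = numeric(),
                      n_trials = integer())
  } else {
    key <- trials[key_cols]
    out <- stats::aggregate(trials$rt_ms, by = key, FUN = mean)
    names(out)[ncol(out)] <- "rt_ms"
    n <- stats::aggregate(trials$rt_ms, by = key, FUN = length)
    out$n_trials <- as.integer(n$x)
    out <- out[do.call(order, out[key_cols]), , drop = FALSE]
    rownames(out) <- NULL
  }
  gaps <- NULL
  if (!is.null(expected)) {
    have <- do.call(paste, c(out[key_cols], sep = "\r"))
    want <- do.call(paste, c(expected[key_cols], sep = "\r"))
    gaps <- unique(expected[!(want %in% have), key_cols, drop = FALSE])
    rownames(gaps) <- NULL
  }
  structure(out, gaps = gaps, class = c("pps_cells", "data.frame"))
}

#' Normalize visuo-tactile cell means against tactile-only baselines
#'
#' For every (participant, distance, light, tactile) key with both a
#' visuo-tactile and a tactile-only cell mean, returns `mean(VT) - mean(TO)`.
#' Keys missing their tactile-only counterpart are skipped (never imputed) and
#' listed in the `"skipped"` attribute.
#'
#' @param cells Cell-mean table from [aggregate_cell_means()] containing both
#'   `VT` and `TO` rows.
#' @return A `data.frame` (class `pps_cells`) with key columns and `rt_ms`
#'   holding the normalized difference (ms); attribute `skipped` lists keys
#'   that lacked a counterpart; attribute `normalized` is `TRUE`.
#' @export
normalize_vt <- function(cells) {
  key_cols <- c("participant", "distance", "light_location", "tactile_location")
  vt <- cells[cells$trial_type == "VT", , drop = FALSE]
  to <- cells[cells$trial_type == "TO", , drop = FALSE]
  m <- merge(vt[, c(key_cols, "rt_ms")], to[, c(key_cols, "rt_ms")],
             by = key_cols, suffixes = c("_vt", "_to"))
  m$rt_ms <- m$rt_ms_vt - m$rt_ms_to
  out <- m[, c(key_cols, "rt_ms")]
  out <- out[do.call(order, out[key_cols]), , drop = FALSE]
  rownames(out) <- NULL

  have <- do.call(paste, c(out[key_cols], sep = "\r"))
  all_keys <- unique(rbind(vt[key_cols], to[key_cols]))
  want <- do.call(paste, c(all_keys[key_cols], sep = "\r"))
  skipped <- all_keys[!(want %in% have), , drop = FALSE]
  rownames(skipped) <- NULL
  structure(out, skipped = skipped, normalized = TRUE,
            class = c("pps_cells", "data.frame"))
}
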