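# B-scan and volume level aggregation of per-A-scan thicknesses.

#' Summarize a boundary trace to B-scan statistics
#'
#' Mean and sample standard deviation of the per-A-scan thicknesses over
#' valid A-scans, and the percentage error `100 * sd / mean` (the
#' within-B-scan coefficient of variation). A B-scan is summarizable when at
#' least two A-scans are valid and the valid fraction reaches
#' `min_valid_fraction`; unsummarizable scans carry `NA` statistics and are
#' treated as discarded downstream.
#'
#' @param trace a [segment_bscan()] result.
#' @param index B-scan position within the volume.
#' @param min_valid_fraction minimum fraction of valid A-scans.
#' @return one-row data frame: `index`, `n_total`, `n_valid`, `mean_um`,
#'   `sd_um`, `pct_error`, `summarizable`.
#' @export
summarize_bscan <- function(trace, index = 1L, min_valid_fraction = 0.5) {
  th <- trace$thickness_um[trace$valid]
  n_total <- nrow(trace)
  n_valid <- length(th)
  ok <- n_valid >= 2L && n_valid / n_total >= min_valid_fraction
  m <- if (ok) mean(th) else NA_real_
  s <- if (ok) stats::sd(th) else NA_real_
  data.frame(
    index = as.integer(index),
    n_total = n_total,
    n_valid = n_valid,
    mean_um = m,
    sd_um = s,
    pct_error = if (ok) 100 * s / m else NA_real_,
    summarizable = ok
  )
}

#' Apply the percentage-error discard rule
#'
#' Flags as retained exactly the summarizable B-scans whose percentage error
#' does not exceed `threshold`; scans strictly above the threshold are
#' discarded. Order is preserved.
#'
#' @param summaries data frame of [summarize_bscan()] rows.
#' @param threshold percentage-error cutoff (default 25).
#' @return `summaries` with a logical `retained` column.
#' @export
filter_bscans <- function(summaries, threshold = 25) {
  summaries$retained <- summaries$summarizable &
    !is.na(summaries$pct_error) & summaries$pct_error <= threshold
  summaries
}

#' Inverse-SD weighted volume mean thickness
#'
#' The volume mean is the weighted average of the retained B-scan means with
#' weights `1/SD` (or `sqrt(n)/SD` with `weighting = "sem"`). The reported
#' uncertainty is the standard error among B-scans: the unweighted sample SD
#' of the retained means divided by `sqrt(n_retained)`; it is `NA` when
#' fewer than two B-scans are retained. A zero-SD B-scan would have infinite
#' weight; it instead receives the largest finite retained weight times
#' `zero_sd_weight_factor` (all weights are equal if no finite weight
#' exists).
#'
#' @param summaries data frame from [filter_bscans()] (rows without a
#'   `retained` column are filtered on `summarizable`).
#' @param weighting `"sd"` or `"sem"`.
#' @param zero_sd_weight_factor see [seg_params()].
#' @return list of class `"volume_thickness"`: `weighted_mean`, `se`,
#'   `n_retained`, `retained_indices`, `reason` (`NA` unless no estimate
#'   could be formed).
#' @export
volume_mean <- function(summaries, weighting = c("sd", "sem"),
                        zero_sd_weight_factor = 10) {
  weighting <- match.arg(weighting)
  keep <- if ("retained" %in% names(summaries)) {
    summaries$retained
  } else {
    summaries$summarizable
  }
  rows <- summaries[keep, , drop = FALSE]
  if (nrow(rows) == 0L) {
    return(structure(
      list(weighted_mean = NA_real_, se = NA_real_, n_retained = 0L,
           retained_indices = integer(0),
           reason = "no B-scans retained"),
      class = "volume_thickness"
    ))
  }
  w <- switch(weighting,
              sd = 1 / rows$sd_um,
              sem = sqrt(rows$n_valid) / rows$sd_um)
  finite <- is.finite(w)
  if (!all(finite)) {
    w[!finite] <- if (any(finite)) max(w[finite]) * zero_sd_weight_factor else 1
  }
  wm <- sum(w * rows$mean_um) / sum(w)
  se <- if (nrow(rows) >= 2L) stats::sd(rows$mean_um) / sqrt(nrow(rows)) else NA_real_
  structure(
    list(weighted_mean = wm, se = se, n_retained = nrow(rows),
         retained_indices = rows$index, reason = NA_character_),
    class = "volume_thickness"
  )
}

#' @export
print.volume_thickness <- function(x, ...) {
  if (x$n_retained == 0L) {
    cat(sprintf("Volume thickness: no estimate (%s)\n", x$reason))
  } else {
    cat(sprintf("Volume thickness: %.2f um (SE %s, %d B-scan%s retained)\n",
                x$weighted_mean,
                if (is.na(x$se)) "n/a" else sprintf("%.2f um", x$se),
                x$n_retained, if (x$n_retained == 1L) "" else "s"))
  }
  invisible(x)
}
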