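# Boundary detection: sclera anchor, then ORL and IRL on the axial
# intensity slope, per A-scan. Depths are micrometres from the top of the
# frame; pixel k (1-based) maps to depth (k-1) * axial_spacing, so depth 0
# is the innermost (vitreous) edge and depth increases toward the sclera.

#' Locate the scleral band centre in each A-scan
#'
#' On the coarsely smoothed B-scan the sclera is the brightest structure, so
#' its centre is taken as the absolute intensity maximum of each column.
#' When a column has several equal maxima the smallest depth is returned.
#'
#' @param smoothed_bscan matrix from [smooth_coarse()] (or a single column).
#' @param axial_spacing depth pixel pitch, micrometres per pixel.
#' @return numeric vector of sclera centre depths in micrometres, one per
#'   A-scan.
#' @export
locate_sclera <- function(smoothed_bscan, axial_spacing) {
  m <- if (is.null(dim(smoothed_bscan))) {
    matrix(as.numeric(smoothed_bscan), ncol = 1L)
  } else {
    smoothed_bscan
  }
  idx <- unname(apply(m, 2L, which.max))  # which.max: first (lowest depth) tie-break
  (idx - 1) * axial_spacing
}

# Shared candidate-selection rules, operating on an extrema_core() list.
orl_from_extrema <- function(ex, sclera_depth, axial_spacing) {
  depth <- (ex$pos[ex$is_min] - 1) * axial_spacing
  cand <- depth < sclera_depth
  if (!any(cand)) return(NA_real_)
  max(depth[cand])  # first valley encountered scanning up from the sclera
}

irl_from_extrema <- function(ex, orl_depth, min_irl_offset, axial_spacing) {
  depth <- (ex$pos[!ex$is_min] - 1) * axial_spacing
  value <- ex$value[!ex$is_min]
  cand <- (orl_depth - depth) > min_irl_offset  # strictly more than the offset
  if (!any(cand)) return(NA_real_)
  depth <- depth[cand]
  value <- value[cand]
  best <- value == max(value)
  max(depth[best])  # amplitude tie broken toward the ORL (smallest thickness)
}

#' Detect the outer retinal boundary in one A-scan
#'
#' Scanning from the sclera centre toward decreasing depth, returns the
#' depth of the first strict local minimum (valley) of the intensity slope.
#'
#' @param slope_column numeric vector of axial slopes for one A-scan (from
#'   [axial_slope()]).
#' @param sclera_depth sclera centre depth (um) for the same column.
#' @param axial_spacing depth pixel pitch, micrometres per pixel.
#' @return ORL depth in micrometres, or `NA` if no valley exists above the
#'   sclera.
#' @export
detect_orl <- function(slope_column, sclera_depth, axial_spacing) {
  extent <- (length(slope_column) - 1) * axial_spacing
  if (!is.finite(sclera_depth) || sclera_depth < 0 || sclera_depth > extent) {
    stop_param("`sclera_depth` lies outside the column extent")
  }
  orl_from_extrema(extrema_core(slope_column), sclera_depth, axial_spacing)
}

#' Detect the inner retinal boundary in one A-scan
#'
#' Among strict local maxima (peaks) of the slope profile lying strictly
#' more than `min_irl_offset` above the outer boundary, returns the depth of
#' the highest-valued peak; equal amplitudes are resolved toward the peak
#' closest to the ORL (the conservative, smallest-thickness choice).
#'
#' @inheritParams detect_orl
#' @param orl_depth outer boundary depth (um) for the same column.
#' @param min_irl_offset exclusion-zone width in micrometres (default 120).
#' @return IRL depth in micrometres, or `NA` if no admissible peak exists.
#' @export
detect_irl <- function(slope_column, orl_depth, min_irl_offset = 120,
                       axial_spacing) {
  if (!is.numeric(min_irl_offset) || length(min_irl_offset) != 1L ||
      !is.finite(min_irl_offset) || min_irl_offset <= 0) {
    stop_param("`min_irl_offset` must be a single positive number")
  }
  irl_from_extrema(extrema_core(slope_column), orl_depth, min_irl_offset,
                   axial_spacing)
}

#' Segment every A-scan of a B-scan
#'
#' Runs the full boundary-detection chain: coarse smoothing and sclera
#' localization, axial slope computation, then per-column ORL and IRL
#' detection. Retinal thickness is the ORL-IRL distance. A-scans where a
#' stage fails are flagged (`no_valley`, `no_peak`, `out_of_frame`) and
#' carry no thickness; failures never abort the B-scan.
#'
#' @param bscan numeric matrix, depth rows by A-scan columns.
#' @param params a [seg_params()] object.
#' @param axial_spacing,lateral_spacing pixel pitch in micrometres per pixel.
#' @return a data frame of class `"boundary_trace"` with one row per A-scan:
#'   `ascan`, `sclera_um`, `orl_um`, `irl_um`, `thickness_um`, `valid`,
#'   `reason`.
#' @export
segment_bscan <- function(bscan, params = seg_params(), axial_spacing,
                          lateral_spacing) {
  if (!is.matrix(bscan) || !is.numeric(bscan)) {
    stop_format("`bscan` must be a numeric matrix")
  }
  if (nrow(bscan) < 3L) stop_format("B-scan has fewer than 3 depth samples")
  if (anyNA(bscan) || !all(is.finite(bscan))) {
    stop_format("B-scan intensities must be finite")
  }
  n_depth <- nrow(bscan)
  n_ascans <- ncol(bscan)

  sm <- smooth_coarse(bscan, params$sigma_coarse, axial_spacing,
                      lateral_spacing, axes = params$coarse_axes)
  slope_img <- axial_slope(
    if (params$slope_source == "smoothed") sm else bscan,
    params$sigma_slope, axial_spacing
  )
  sclera_um <- locate_sclera(sm, axial_spacing)
  sclera_idx <- round(sclera_um / axial_spacing) + 1

  orl_um <- irl_um <- rep(NA_real_, n_ascans)
  reason <- rep("none", n_ascans)
  for (j in seq_len(n_ascans)) {
    if (sclera_idx[j] >= n_depth) {
      # band centre on the deepest row: band likely clipped by the frame
      reason[j] <- "out_of_frame"
      next
    }
    ex <- extrema_core(slope_img[, j])
    orl <- orl_from_extrema(ex, sclera_um[j], axial_spacing)
    if (is.na(orl)) {
      reason[j] <- "no_valley"
      next
    }
    orl_um[j] <- orl
    irl <- irl_from_extrema(ex, orl, params$min_irl_offset, axial_spacing)
    if (is.na(irl)) {
      reason[j] <- "no_peak"
      next
    }
    irl_um[j] <- irl
  }
  valid <- reason == "none"
  out <- data.frame(
    ascan = seq_len(n_ascans),
    sclera_um = sclera_um,
    orl_um = orl_um,
    irl_um = irl_um,
    thickness_um = ifelse(valid, orl_um - irl_um, NA_real_),
    valid = valid,
    reason = reason,
    stringsAsFactors = FALSE
  )
  attr(out, "axial_spacing") <- axial_spacing
  class(out) <- c("boundary_trace", "data.frame")
  out
}

#' Segment every B-scan of a volume
#'
#' @param volume an [oct_volume()] object.
#' @param params a [seg_params()] object.
#' @return list of [segment_bscan()] traces, one per B-scan.
#' @export
segment_volume <- function(volume, params = seg_params()) {
  stopifnot(inherits(volume, "oct_volume"))
  lapply(volume$frames, segment_bscan, params = params,
         axial_spacing = volume$axial_spacing,
         lateral_spacing = volume$lateral_spacing)
}

#' Segment and aggregate a volume in one call
#'
#' Convenience pipeline: [segment_volume()], per-B-scan summaries, the
#' percentage-error discard rule, and the inverse-SD weighted volume mean.
#'
#' @inheritParams segment_volume
#' @return list with elements `traces` (per-B-scan boundary traces),
#'   `bscans` (summary data frame with `retained` flags) and `volume`
#'   (a `"volume_thickness"` object).
#' @export
analyze_volume <- function(volume, params = seg_params()) {
  traces <- segment_volume(volume, params)
  summaries <- do.call(rbind, lapply(seq_along(traces), function(i) {
    summarize_bscan(traces[[i]], index = i,
                    min_valid_fraction = params$min_valid_fraction)
  }))
  summaries <- filter_bscans(summaries, params$pct_error_threshold)
  vt <- volume_mean(summaries, weighting = params$weighting,
                    zero_sd_weight_factor = params$zero_sd_weight_factor)
  list(traces = traces, bscans = summaries, volume = vt)
}
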