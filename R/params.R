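#' Segmentation parameters
#'
#' Bundles the constants of the boundary-detection and aggregation pipeline.
#' All scales and offsets are in micrometres and converted to pixels per
#' volume through the spacing metadata, so the same parameters apply at any
#' scan resolution.
#'
#' @param sigma_coarse Gaussian scale (um) of the coarse blur used for
#'   sclera localization. Default 20.
#' @param sigma_slope Gaussian scale (um) applied along depth before the
#'   intensity slope is differentiated. Default 2.
#' @param min_irl_offset minimum separation (um) between the outer retinal
#'   boundary (ORL) and an admissible inner-boundary (IRL) slope peak.
#'   Default 120.
#' @param pct_error_threshold B-scans whose percentage error (coefficient of
#'   variation of A-scan thickness, percent) exceeds this value are
#'   discarded. Default 25.
#' @param min_valid_fraction minimum fraction of successfully segmented
#'   A-scans for a B-scan to be summarizable. Default 0.5.
#' @param coarse_axes whether the coarse blur acts on `"both"` axes
#'   (default) or `"axial"` only.
#' @param slope_source image the slope stage differentiates:
#'   `"smoothed"` (default) uses the coarse-smoothed B-scan, which makes the
#'   first-valley rule robust to speckle; `"raw"` differentiates the
#'   original B-scan and reproduces boundary localization at native
#'   resolution on low-noise data.
#' @param weighting B-scan weight in the volume mean: `"sd"` (default,
#'   weight 1/SD) or `"sem"` (weight sqrt(n)/SD).
#' @param zero_sd_weight_factor a retained B-scan with zero SD receives the
#'   largest finite weight among retained scans multiplied by this factor,
#'   so a perfectly uniform scan dominates without producing an infinite
#'   weight. Default 10.
#' @return a list of class `"seg_params"`.
#' @export
seg_params <- function(sigma_coarse = 20,
                       sigma_slope = 2,
                       min_irl_offset = 120,
                       pct_error_threshold = 25,
                       min_valid_fraction = 0.5,
                       coarse_axes = c("both", "axial"),
                       slope_source = c("smoothed", "raw"),
                       weighting = c("sd", "sem"),
                       zero_sd_weight_factor = 10) {
  coarse_axes <- match.arg(coarse_axes)
  slope_source <- match.arg(slope_source)
  weighting <- match.arg(weighting)
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
      stop_param(sprintf("`%s` must be a single positive number", nm))
    }
  }
  chk_pos(sigma_coarse, "sigma_coarse")
  chk_pos(sigma_slope, "sigma_slope")
  chk_pos(min_irl_offset, "min_irl_offset")
  chk_pos(pct_error_threshold, "pct_error_threshold")
  chk_pos(zero_sd_weight_factor, "zero_sd_weight_factor")
  if (!is.numeric(min_valid_fraction) || length(min_valid_fraction) != 1L ||
      is.na(min_valid_fraction) ||
      min_valid_fraction <= 0 || min_valid_fraction > 1) {
    stop_param("`min_valid_fraction` must be in (0, 1]")
  }
  structure(
    list(
      sigma_coarse = sigma_coarse,
      sigma_slope = sigma_slope,
      min_irl_offset = min_irl_offset,
      pct_error_threshold = pct_error_threshold,
      min_valid_fraction = min_valid_fraction,
      coarse_axes = coarse_axes,
      slope_source = slope_source,
      weighting = weighting,
      zero_sd_weight_factor = zero_sd_weight_factor
    ),
    class = "seg_params"
  )
}

#' @export
print.seg_params <- function(x, ...) {
  cat("Segmentation parameters:\n")
  cat(sprintf("  sigma_coarse: %g um (%s axes), sigma_slope: %g um (on %s image)\n",
              x$sigma_coarse, x$coarse_axes, x$sigma_slope, x$slope_source))
  cat(sprintf("  min IRL offset: %g um, discard threshold: %g%%, min valid fraction: %g\n",
              x$min_irl_offset, x$pct_error_threshold, x$min_valid_fraction))
  cat(sprintf("  volume weighting: 1/%s (zero-SD factor %g)\n",
              toupper(x$weighting), x$zero_sd_weight_factor))
  invisible(x)
}

#' Read segmentation parameters from a key=value configuration file
#'
#' Plain-text configuration: one `key=value` pair per line, `#` comments and
#' blank lines ignored. Keys are the arguments of [seg_params()]; unknown
#' keys raise a configuration error.
#'
#' @param path file to read.
#' @param base parameters to override; defaults to `seg_params()` defaults.
#' @return a `"seg_params"` object.
#' @export
read_params_config <- function(path, base = seg_params()) {
  if (!file.exists(path)) stop_config(sprintf("config file not found: %s", path))
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  overrides <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop_config(sprintf("malformed config line (expected key=value): '%s'", ln))
    }
    key <- trimws(sub("=.*", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(formals(seg_params))) {
      stop_config(sprintf("unknown segmentation parameter: '%s'", key))
    }
    num <- suppressWarnings(as.numeric(val))
    overrides[[key]] <- if (is.na(num)) val else num
  }
  do.call(seg_params, utils::modifyList(unclass(base), overrides))
}
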