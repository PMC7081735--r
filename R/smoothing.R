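# Gaussian smoothing and axial differentiation, parametrized in physical
# units (micrometres) so the algorithm is independent of pixel pitch.

# Normalized Gaussian kernel sampled at integer pixel offsets, truncated at
# 4 sigma (minimum radius 1 so smoothing is never a no-op).
gaussian_kernel_px <- function(sigma_px) {
  r <- max(1L, as.integer(ceiling(4 * sigma_px)))
  k <- stats::dnorm(seq.int(-r, r), sd = sigma_px)
  k / sum(k)
}

# Mirror indices about the ends without repeating the edge sample
# (… 3 2 | 1 2 3 … n | n-1 n-2 …). Works for any pad size.
reflect_indices <- function(n, r) {
  if (n == 1L) return(rep(1L, n + 2L * r))
  i <- seq.int(1L - r, n + r)
  period <- 2L * (n - 1L)
  j <- (i - 1L) %% period
  ifelse(j >= n, period - j, j) + 1L
}

#' Gaussian smoothing along depth with a physically specified scale
#'
#' Smooths each column of `x` along its rows (the depth/axial direction) with
#' a Gaussian kernel of standard deviation `sigma_um`, converted to pixels
#' via `spacing_um`. Boundaries are handled by mirror reflection, so constant
#' inputs are preserved exactly and linear ramps are preserved away from the
#' borders.
#'
#' @param x numeric vector (one A-scan profile) or matrix (depth rows by
#'   A-scan columns).
#' @param sigma_um smoothing scale in micrometres; must be positive.
#' @param spacing_um pixel pitch along the smoothing axis, in micrometres
#'   per pixel.
#' @return an object of the same shape as `x`.
#' @examples
#' z <- seq(0, 400, by = 4)
#' profile <- plogis((z - 200) / 5)
#' sm <- gaussian_smooth(profile, sigma_um = 20, spacing_um = 4)
#' @export
gaussian_smooth <- function(x, sigma_um, spacing_um) {
  if (!is.numeric(sigma_um) || length(sigma_um) != 1L || !is.finite(sigma_um) ||
      sigma_um <= 0) {
    stop_param("`sigma_um` must be a single positive number")
  }
  if (!is.numeric(spacing_um) || length(spacing_um) != 1L ||
      !is.finite(spacing_um) || spacing_um <= 0) {
    stop_param("`spacing_um` must be a single positive number")
  }
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), ncol = 1L) else x
  n <- nrow(m)
  if (n == 1L) return(x)
  k <- gaussian_kernel_px(sigma_um / spacing_um)
  r <- (length(k) - 1L) %/% 2L
  # Offset accumulation with reflected indexing: every output sample is the
  # same weighted sum in the same order, so constant inputs are preserved
  # bit-exactly (an extremum detector downstream relies on that).
  refl <- reflect_indices(n, r)  # maps padded index (i + r) -> source row
  rows <- seq_len(n)
  sm <- matrix(0, n, ncol(m))
  for (o in seq.int(-r, r)) {
    sm <- sm + k[o + r + 1L] * m[refl[rows + o + r], , drop = FALSE]
  }
  if (vec) as.numeric(sm) else sm
}

#' Coarse two-dimensional smoothing of a B-scan
#'
#' First smoothing stage of the segmentation: a Gaussian blur at physical
#' scale `sigma_um` used to make the bright scleral band the dominant
#' structure before per-column maximum localization. By default both axes
#' are smoothed at the same physical sigma (with per-axis pixel conversion);
#' `axes = "axial"` restricts the blur to the depth direction.
#'
#' @param bscan numeric matrix, depth rows by A-scan columns.
#' @param sigma_um physical smoothing scale in micrometres (default 20).
#' @param axial_spacing,lateral_spacing pixel pitch in micrometres per pixel
#'   along depth and across A-scans. `lateral_spacing` is only required when
#'   `axes = "both"`.
#' @param axes smooth `"both"` axes (default) or the `"axial"` axis only.
#' @return smoothed matrix with the dimensions of `bscan`.
#' @export
smooth_coarse <- function(bscan, sigma_um = 20, axial_spacing,
                          lateral_spacing = NULL, axes = c("both", "axial")) {
  axes <- match.arg(axes)
  if (!is.matrix(bscan) || !is.numeric(bscan)) {
    stop_format("`bscan` must be a numeric matrix")
  }
  out <- gaussian_smooth(bscan, sigma_um, axial_spacing)
  if (axes == "both" && ncol(bscan) > 1L) {
    if (is.null(lateral_spacing)) {
      stop_param("`lateral_spacing` is required for 2D smoothing")
    }
    out <- t(gaussian_smooth(t(out), sigma_um, lateral_spacing))
  }
  out
}

#' Axial intensity slope of a B-scan
#'
#' Smooths each column along depth with a Gaussian of physical scale
#' `sigma_um` (default 2) and differentiates by central differences
#' (one-sided at the borders), returning the intensity slope in intensity
#' units per micrometre. The slope is positive where intensity increases
#' with depth.
#'
#' @inheritParams smooth_coarse
#' @param sigma_um pre-differentiation smoothing scale in micrometres.
#' @return matrix (or vector, matching the input) of slopes.
#' @export
axial_slope <- function(bscan, sigma_um = 2, axial_spacing) {
  vec <- is.null(dim(bscan))
  m <- if (vec) matrix(as.numeric(bscan), ncol = 1L) else bscan
  n <- nrow(m)
  if (n < 3L) stop_format("at least 3 depth samples are required to compute a slope")
  s <- gaussian_smooth(m, sigma_um, axial_spacing)
  d <- (s[c(2:n, n), , drop = FALSE] - s[c(1L, 1:(n - 1L)), , drop = FALSE]) /
    (2 * axial_spacing)
  d[1L, ] <- (s[2L, ] - s[1L, ]) / axial_spacing
  d[n, ] <- (s[n, ] - s[n - 1L, ]) / axial_spacing
  if (vec) as.numeric(d) else d
}
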