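# Synthetic rodent OCT phantom: piecewise-constant layers with logistic
# boundary transitions, a Gaussian bright scleral band, and multiplicative
# gamma speckle. Ground truth is the transition midpoint / band centre,
# which coincides with the slope extremum the detector targets.

#' Specification of a synthetic OCT phantom volume
#'
#' Defaults emulate a Spectralis-style rodent acquisition: 7 B-scans spaced
#' 240 um apart, 768 A-scans per B-scan, 496 depth pixels at 3.87 um/px
#' (about a 1.9 mm axial window). The retina (bounded by the inner boundary
#' `irl_depth` and outer boundary `orl_depth`) sits above a dimmer choroid
#' and the bright scleral band, the brightest structure in the frame. Rat
#' choroid is thin, on the order of 100 um, so the default band centre is
#' 130 um below the outer retinal boundary. Boundary surfaces are low-order
#' polynomials of lateral position and B-scan index: a quadratic bowl of
#' depth `surface_sag` across the frame plus a linear per-B-scan shift
#' `bscan_tilt`, applied to all three surfaces so true thickness stays
#' uniform (vary `irl_depth`/`orl_depth` across specs for thickness
#' families).
#'
#' @param n_bscans,n_ascans,n_depth volume geometry in pixels.
#' @param axial_spacing,lateral_spacing,bscan_spacing physical pitch, um.
#' @param irl_depth,orl_depth,sclera_center boundary depths (um from frame
#'   top) at the frame centre.
#' @param sclera_band_sd Gaussian half-width (SD, um) of the scleral band.
#' @param surface_sag quadratic lateral sag (um) of all surfaces.
#' @param bscan_tilt per-B-scan linear depth shift (um per B-scan index
#'   from the central B-scan).
#' @param levels named intensities (arbitrary linear units, non-negative)
#'   for `vitreous`, `retina`, `choroid`, `sclera`; the sclera must be
#'   strictly brightest.
#' @param transition_scale logistic steepness (um) of the boundary
#'   transitions.
#' @param speckle_k shape of the unit-mean multiplicative gamma speckle;
#'   smaller is noisier, `Inf` disables speckle. Default 50 (contrast of
#'   about 14 percent, plausible after ART frame averaging).
#' @param additive_sd additive Gaussian read-noise SD (intensity units).
#' @param distractors list of extra intensity edges (see
#'   [inject_distractor()]).
#' @param seed integer seed making [generate_volume()] deterministic.
#' @return list of class `"phantom_spec"`.
#' @export
phantom_spec <- function(n_bscans = 7L, n_ascans = 768L, n_depth = 496L,
                         axial_spacing = 3.87, lateral_spacing = 11.0,
                         bscan_spacing = 240,
                         irl_depth = 800, orl_depth = 1000,
                         sclera_center = 1130, sclera_band_sd = 25,
                         surface_sag = 15, bscan_tilt = 0,
                         levels = c(vitreous = 0.04, retina = 0.60,
                                    choroid = 0.25, sclera = 1.0),
                         transition_scale = 5,
                         speckle_k = 50, additive_sd = 0,
                         distractors = list(), seed = 1L) {
  spec <- structure(
    list(n_bscans = as.integer(n_bscans), n_ascans = as.integer(n_ascans),
         n_depth = as.integer(n_depth),
         axial_spacing = axial_spacing, lateral_spacing = lateral_spacing,
         bscan_spacing = bscan_spacing,
         irl_depth = irl_depth, orl_depth = orl_depth,
         sclera_center = sclera_center, sclera_band_sd = sclera_band_sd,
         surface_sag = surface_sag, bscan_tilt = bscan_tilt,
         levels = levels, transition_scale = transition_scale,
         speckle_k = speckle_k, additive_sd = additive_sd,
         distractors = distractors, seed = as.integer(seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  with(spec, {
    if (n_bscans < 1L || n_ascans < 1L || n_depth < 3L) {
      stop_spec("geometry must have >= 1 B-scan, >= 1 A-scan, >= 3 depth pixels")
    }
    if (axial_spacing <= 0 || lateral_spacing <= 0 || bscan_spacing < 0) {
      stop_spec("spacings must be positive (bscan_spacing may be 0)")
    }
    req <- c("vitreous", "retina", "choroid", "sclera")
    if (!all(req %in% names(levels)) || any(levels < 0)) {
      stop_spec("`levels` must name non-negative vitreous/retina/choroid/sclera intensities")
    }
    if (levels[["sclera"]] <= max(levels[c("vitreous", "retina", "choroid")])) {
      stop_spec("the sclera must be strictly the brightest layer")
    }
    if (transition_scale <= 0) stop_spec("`transition_scale` must be positive")
    if (sclera_band_sd <= 0) stop_spec("`sclera_band_sd` must be positive")
    if (speckle_k <= 0) stop_spec("`speckle_k` must be positive (Inf disables speckle)")
    if (additive_sd < 0) stop_spec("`additive_sd` must be non-negative")
    # worst-case surface shift across the lateral span and B-scan stack
    shift <- abs(surface_sag) + abs(bscan_tilt) * (n_bscans - 1) / 2
    if (!(irl_depth + 120 < orl_depth && orl_depth < sclera_center)) {
      stop_spec("layer order must satisfy irl_depth + 120 < orl_depth < sclera_center")
    }
    if (irl_depth - shift < 3 * transition_scale) {
      stop_spec("inner boundary too close to the top of the frame")
    }
    extent <- (n_depth - 1) * axial_spacing
    if (sclera_center + shift + 3 * sclera_band_sd > extent) {
      stop_spec("scleral band extends beyond the bottom of the frame")
    }
    invisible(NULL)
  })
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("OCT phantom spec: %d B-scan(s) x %d A-scan(s) x %d depth px\n",
              x$n_bscans, x$n_ascans, x$n_depth))
  cat(sprintf("  spacing: %.3g um/px axial, %.3g um/px lateral, %g um between B-scans\n",
              x$axial_spacing, x$lateral_spacing, x$bscan_spacing))
  cat(sprintf("  boundaries: IRL %g um, ORL %g um, sclera centre %g um (band SD %g um)\n",
              x$irl_depth, x$orl_depth, x$sclera_center, x$sclera_band_sd))
  cat(sprintf("  speckle k = %g, additive SD = %g, %d distractor(s), seed %d\n",
              x$speckle_k, x$additive_sd, length(x$distractors), x$seed))
  invisible(x)
}

# Boundary surfaces at lateral pixel x (1-based) and B-scan b: shared
# quadratic sag + linear tilt so layer ordering is preserved everywhere.
phantom_surface_shift <- function(spec, x, b) {
  u <- if (spec$n_ascans > 1L) 2 * (x - 1) / (spec$n_ascans - 1) - 1 else 0
  v <- b - (spec$n_bscans + 1) / 2
  spec$surface_sag * u^2 + spec$bscan_tilt * v
}

phantom_truth_row <- function(spec, x, b) {
  s <- phantom_surface_shift(spec, x, b)
  data.frame(
    bscan = as.integer(b), ascan = as.integer(x),
    irl_um = spec$irl_depth + s, orl_um = spec$orl_depth + s,
    sclera_um = spec$sclera_center + s,
    thickness_um = spec$orl_depth - spec$irl_depth
  )
}

# Clean (noise-free) intensity profiles for A-scan indices `xs` of B-scan
# `b`: one column per A-scan, vectorized over the lateral position.
phantom_clean_columns <- function(spec, xs, b) {
  z <- (seq_len(spec$n_depth) - 1) * spec$axial_spacing
  s <- phantom_surface_shift(spec, xs, b)  # length(xs) surface shifts
  lv <- spec$levels
  ts <- spec$transition_scale
  zirl <- outer(z, spec$irl_depth + s, "-")
  zorl <- outer(z, spec$orl_depth + s, "-")
  zsc <- outer(z, spec$sclera_center + s, "-")
  m <- lv[["vitreous"]] +
    (lv[["retina"]] - lv[["vitreous"]]) * stats::plogis(zirl / ts) +
    (lv[["choroid"]] - lv[["retina"]]) * stats::plogis(zorl / ts) +
    (lv[["sclera"]] - lv[["choroid"]]) * exp(-zsc^2 / (2 * spec$sclera_band_sd^2))
  for (d in spec$distractors) {
    zd <- zorl + d$offset_um  # depth relative to the distractor's leading edge
    m <- m + d$amplitude *
      (stats::plogis(zd / d$scale_um) -
         stats::plogis((zd - d$width_um) / d$scale_um))
  }
  m
}

phantom_profile <- function(spec, x, b) {
  as.numeric(phantom_clean_columns(spec, x, b))
}

phantom_apply_noise <- function(m, spec) {
  if (is.finite(spec$speckle_k)) {
    m <- m * matrix(stats::rgamma(length(m), shape = spec$speckle_k,
                                  rate = spec$speckle_k), nrow(m))
  }
  if (spec$additive_sd > 0) {
    m <- m + matrix(stats::rnorm(length(m), sd = spec$additive_sd), nrow(m))
  }
  pmax(m, 0)
}

#' Generate one synthetic A-scan with its ground truth
#'
#' Noise (if enabled in the spec) is drawn from the current RNG state; call
#' `set.seed()` first for reproducibility, or use [generate_volume()], which
#' seeds itself from the spec.
#'
#' @param spec a [phantom_spec()].
#' @param x lateral (A-scan) index, 1-based.
#' @param b B-scan index, 1-based.
#' @return list with `profile` (numeric intensity vector over depth) and
#'   `truth` (one-row data frame of true boundary depths and thickness, um).
#' @export
generate_ascan <- function(spec, x = 1L, b = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (x < 1L || x > spec$n_ascans || b < 1L || b > spec$n_bscans) {
    stop_spec("A-scan or B-scan index outside the spec geometry")
  }
  prof <- phantom_profile(spec, x, b)
  prof <- as.numeric(phantom_apply_noise(matrix(prof, ncol = 1L), spec))
  list(profile = prof, truth = phantom_truth_row(spec, x, b))
}

#' Generate a synthetic OCT volume with ground truth
#'
#' Deterministic given `spec$seed`: the same spec yields bit-identical
#' volumes; changing only the seed changes the speckle realization but not
#' the ground truth.
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an [oct_volume()]) and `truth` (data frame
#'   with one row per (B-scan, A-scan): true IRL/ORL/sclera depths and
#'   thickness in um).
#' @export
generate_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  xs <- seq_len(spec$n_ascans)
  frames <- vector("list", spec$n_bscans)
  truth <- vector("list", spec$n_bscans)
  for (b in seq_len(spec$n_bscans)) {
    clean <- phantom_clean_columns(spec, xs, b)
    frames[[b]] <- phantom_apply_noise(clean, spec)
    truth[[b]] <- phantom_truth_row(spec, xs, b)  # vectorized over A-scans
  }
  vol <- oct_volume(frames,
                    axial_spacing = spec$axial_spacing,
                    lateral_spacing = spec$lateral_spacing,
                    bscan_spacing = spec$bscan_spacing,
                    meta = list(source = "octseg phantom", seed = spec$seed))
  list(volume = vol, truth = do.call(rbind, truth))
}

#' Add a distractor intensity edge inside the retina
#'
#' Appends a narrow bright band whose rising (leading) edge sits at
#' `orl_depth - offset_um`, creating an extra slope peak at that depth.
#' Used to probe the IRL exclusion-zone rule.
#'
#' @param spec a [phantom_spec()].
#' @param offset_um distance (um) of the leading edge above the outer
#'   boundary; the band must fall strictly inside the retina.
#' @param amplitude intensity step height (same units as `levels`).
#' @param scale_um logistic steepness of the band edges; defaults to the
#'   spec's `transition_scale`.
#' @param width_um band width in micrometres (default 15).
#' @return the modified `"phantom_spec"`.
#' @export
inject_distractor <- function(spec, offset_um, amplitude,
                              scale_um = spec$transition_scale,
                              width_um = 15) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.numeric(offset_um) || offset_um <= 0) {
    stop_spec("`offset_um` must be positive")
  }
  if (spec$orl_depth - offset_um <= spec$irl_depth ||
      width_um >= offset_um) {
    stop_spec("distractor band falls outside the retina span")
  }
  if (scale_um <= 0) stop_spec("`scale_um` must be positive")
  if (width_um <= 0) stop_spec("`width_um` must be positive")
  spec$distractors <- c(spec$distractors,
                        list(list(offset_um = offset_um, amplitude = amplitude,
                                  scale_um = scale_um, width_um = width_um)))
  spec
}
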