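# Reading and writing OCT volumes as image stacks with a JSON spacing
# sidecar, plus tabular/overlay result writers.

#' Construct an OCT volume
#'
#' @param frames list of numeric matrices (depth rows by A-scan columns),
#'   all with identical dimensions, finite and non-negative.
#' @param axial_spacing,lateral_spacing micrometres per pixel along depth
#'   and across A-scans; must be positive.
#' @param bscan_spacing micrometres between consecutive B-scans (0 is legal
#'   for single-frame stacks).
#' @param meta free-form named list of provenance (subject id, timepoint,
#'   eye, ...).
#' @return list of class `"oct_volume"`.
#' @export
oct_volume <- function(frames, axial_spacing, lateral_spacing,
                       bscan_spacing = 0, meta = list()) {
  if (!is.list(frames) || length(frames) == 0L) {
    stop_format("`frames` must be a non-empty list of matrices")
  }
  if (!all(vapply(frames, function(f) is.matrix(f) && is.numeric(f), logical(1)))) {
    stop_format("every frame must be a numeric matrix")
  }
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_format("all frames must share identical dimensions")
  }
  for (f in frames) {
    if (anyNA(f) || !all(is.finite(f))) stop_format("frame intensities must be finite")
    if (any(f < 0)) stop_format("frame intensities must be non-negative")
  }
  chk <- function(x, nm, strict) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        (if (strict) x <= 0 else x < 0)) {
      stop_config(sprintf("`%s` must be a single %s number", nm,
                          if (strict) "positive" else "non-negative"))
    }
  }
  chk(axial_spacing, "axial_spacing", TRUE)
  chk(lateral_spacing, "lateral_spacing", TRUE)
  chk(bscan_spacing, "bscan_spacing", FALSE)
  structure(
    list(frames = frames, axial_spacing = axial_spacing,
         lateral_spacing = lateral_spacing, bscan_spacing = bscan_spacing,
         meta = meta),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("OCT volume: %d B-scan(s) of %d x %d px (depth x A-scans)\n",
              length(x$frames), d[1], d[2]))
  cat(sprintf("  spacing: %.4g um/px axial, %.4g um/px lateral, %g um between B-scans\n",
              x$axial_spacing, x$lateral_spacing, x$bscan_spacing))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

# One grayscale matrix from a decoded PNG/TIFF array: average the colour
# channels, ignoring alpha.
as_gray <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    nc <- dim(a)[3]
    ch <- if (nc >= 3L) 1:3 else 1L
    out <- a[, , ch[1]]
    if (length(ch) > 1L) {
      for (k in ch[-1]) out <- out + a[, , k]
      out <- out / length(ch)
    }
    return(out)
  }
  stop_format("unsupported image array layout")
}

read_stack_file <- function(file) {
  ext <- tolower(tools::file_ext(file))
  if (ext %in% c("tif", "tiff")) {
    fr <- tiff::readTIFF(file, all = TRUE, info = TRUE)
    if (!is.list(fr)) fr <- list(fr)
    lapply(fr, as_gray)
  } else if (ext == "png") {
    list(as_gray(png::readPNG(file)))
  } else {
    stop_format(sprintf("unsupported frame format: '%s'", file))
  }
}

sidecar_candidates <- function(path) {
  c(paste0(tools::file_path_sans_ext(path), ".json"),
    paste0(path, ".json"),
    file.path(path, "sidecar.json"))
}

read_sidecar <- function(file) {
  meta <- tryCatch(jsonlite::read_json(file, simplifyVector = TRUE),
                   error = function(e) {
                     stop_config(sprintf("malformed sidecar JSON '%s': %s",
                                         file, conditionMessage(e)))
                   })
  req <- c("axial_um_per_px", "lateral_um_per_px", "bscan_spacing_um")
  missing <- setdiff(req, names(meta))
  if (length(missing)) {
    stop_config(sprintf("sidecar '%s' lacks required key(s): %s",
                        file, paste(missing, collapse = ", ")))
  }
  for (k in req) {
    if (!is.numeric(meta[[k]]) || length(meta[[k]]) != 1L || !is.finite(meta[[k]])) {
      stop_config(sprintf("sidecar key '%s' must be a single number", k))
    }
  }
  meta
}

# Physical spacing from embedded TIFF resolution tags (pixels per unit).
# Only a fallback: explicit sidecar calibration is preferred.
spacing_from_tags <- function(frame) {
  xr <- attr(frame, "x.resolution")
  yr <- attr(frame, "y.resolution")
  unit <- attr(frame, "resolution.unit")
  if (is.null(xr) || is.null(yr) || is.null(unit)) return(NULL)
  per_um <- switch(as.character(unit), inch = 25400, cm = 1e4, NULL)
  if (is.null(per_um) || xr <= 0 || yr <= 0) return(NULL)
  list(axial_um_per_px = per_um / yr, lateral_um_per_px = per_um / xr)
}

#' Load an OCT volume from an image stack
#'
#' Reads a multi-page TIFF, a single PNG/TIFF frame, or a directory of
#' equally sized grayscale frames ordered lexicographically. Physical
#' spacing comes from a JSON sidecar with required keys `axial_um_per_px`,
#' `lateral_um_per_px` and `bscan_spacing_um`; when `sidecar` is `NULL` the
#' loader looks for `<input>.json` (or `sidecar.json` inside a frame
#' directory) and, as a last resort for TIFF input, embedded resolution
#' tags. Extra sidecar keys are kept as volume metadata.
#'
#' @param path TIFF file or frame directory.
#' @param sidecar optional explicit sidecar path.
#' @return an [oct_volume()].
#' @export
load_volume <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop_io(sprintf("input not found: %s", path))
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
    files <- files[order(basename(files), method = "radix")]
    if (length(files) == 0L) stop_format(sprintf("no frames found in '%s'", path))
    frames <- unlist(lapply(files, read_stack_file), recursive = FALSE)
  } else {
    frames <- read_stack_file(path)
  }
  if (length(frames) == 0L) stop_format("empty image stack")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_format("frames have mismatched dimensions")
  }

  meta <- NULL
  if (!is.null(sidecar)) {
    if (!file.exists(sidecar)) stop_config(sprintf("sidecar not found: %s", sidecar))
    meta <- read_sidecar(sidecar)
  } else {
    found <- Filter(file.exists, sidecar_candidates(path))
    if (length(found)) {
      meta <- read_sidecar(found[[1]])
    } else {
      tags <- spacing_from_tags(frames[[1]])
      if (!is.null(tags)) {
        if (length(frames) > 1L) {
          stop_config("B-scan spacing unavailable from embedded tags; provide a sidecar")
        }
        meta <- c(tags, list(bscan_spacing_um = 0))
      }
    }
  }
  if (is.null(meta)) {
    stop_config(sprintf("no spacing metadata for '%s': provide a JSON sidecar", path))
  }

  extra <- meta[setdiff(names(meta),
                        c("axial_um_per_px", "lateral_um_per_px", "bscan_spacing_um"))]
  oct_volume(lapply(frames, function(f) { attributes(f) <- list(dim = dim(f)); f }),
             axial_spacing = meta$axial_um_per_px,
             lateral_spacing = meta$lateral_um_per_px,
             bscan_spacing = meta$bscan_spacing_um,
             meta = as.list(extra))
}

#' Write an OCT volume as a multi-page TIFF with a JSON sidecar
#'
#' Intensities are rescaled by the volume maximum to fit the 16-bit range
#' (a positive affine map, to which segmentation is invariant); the scale
#' factor is recorded in the sidecar.
#'
#' @param volume an [oct_volume()].
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path minus extension>.json`.
#' @return invisibly, a list with the TIFF and sidecar paths.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "oct_volume"))
  mx <- max(vapply(volume$frames, max, numeric(1)))
  scale <- if (mx > 0) mx else 1
  frames <- lapply(volume$frames, function(f) pmin(pmax(f / scale, 0), 1))
  ok <- tryCatch({
    tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_io(sprintf("cannot write TIFF '%s'", path))
  sidecar <- paste0(tools::file_path_sans_ext(path), ".json")
  jsonlite::write_json(
    c(list(axial_um_per_px = volume$axial_spacing,
           lateral_um_per_px = volume$lateral_spacing,
           bscan_spacing_um = volume$bscan_spacing,
           intensity_scale = scale),
      volume$meta),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(list(tiff = path, sidecar = sidecar))
}

fmt_fixed <- function(x, digits) {
  ifelse(is.na(x), NA_character_, sprintf(paste0("%.", digits, "f"), x))
}

draw_curve <- function(img, depth_um, axial_spacing, rgb) {
  rows <- round(depth_um / axial_spacing) + 1
  for (j in seq_along(rows)) {
    r <- rows[j]
    if (!is.na(r) && r >= 1 && r <= dim(img)[1]) img[r, j, ] <- rgb
  }
  img
}

#' Write segmentation results for one volume
#'
#' Writes `boundaries.csv` (per-A-scan boundary depths, validity and
#' thickness), `bscan_summary.csv` (per-B-scan statistics and retained
#' flags), `volume_summary.json` (weighted mean, SE, retained count; `null`
#' mean with an explicit reason when no B-scan survives filtering) and,
#' optionally, one overlay PNG per B-scan with the IRL (purple), ORL
#' (green) and sclera (yellow) curves drawn on the image.
#'
#' @param volume the segmented [oct_volume()].
#' @param traces list of [segment_bscan()] traces for the same volume.
#' @param summaries B-scan summary data frame (from [filter_bscans()]).
#' @param volume_summary a `"volume_thickness"` object.
#' @param outdir output directory, created if needed.
#' @param overlays write overlay PNGs (default `TRUE`).
#' @param digits fixed decimal places for CSV numbers (default 3), so
#'   re-reading reproduces values rounded to that precision exactly.
#' @return invisibly, the named vector of written paths.
#' @export
write_results <- function(volume, traces, summaries, volume_summary, outdir,
                          overlays = TRUE, digits = 3) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir) || file.access(outdir, 2L) != 0L) {
    stop_io(sprintf("output directory '%s' is not writable", outdir))
  }
  ax <- volume$axial_spacing

  bounds <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    data.frame(bscan = i, ascan = tr$ascan,
               sclera_um = fmt_fixed(tr$sclera_um, digits),
               orl_um = fmt_fixed(tr$orl_um, digits),
               irl_um = fmt_fixed(tr$irl_um, digits),
               thickness_um = fmt_fixed(tr$thickness_um, digits),
               valid = tr$valid, reason = tr$reason,
               stringsAsFactors = FALSE)
  }))
  boundaries_csv <- file.path(outdir, "boundaries.csv")
  utils::write.csv(bounds, boundaries_csv, row.names = FALSE, quote = FALSE)

  bs <- summaries
  for (col in c("mean_um", "sd_um", "pct_error")) bs[[col]] <- fmt_fixed(bs[[col]], digits)
  bscan_csv <- file.path(outdir, "bscan_summary.csv")
  utils::write.csv(bs, bscan_csv, row.names = FALSE, quote = FALSE)

  vs <- volume_summary
  json_path <- file.path(outdir, "volume_summary.json")
  jsonlite::write_json(
    list(weighted_mean_um = vs$weighted_mean, se_um = vs$se,
         n_retained = vs$n_retained, retained_indices = vs$retained_indices,
         reason = vs$reason),
    json_path, auto_unbox = TRUE, digits = NA, na = "null"
  )

  paths <- c(boundaries = boundaries_csv, bscan_summary = bscan_csv,
             volume_summary = json_path)
  if (overlays) {
    mx <- max(vapply(volume$frames, max, numeric(1)))
    for (i in seq_along(traces)) {
      f <- volume$frames[[i]] / if (mx > 0) mx else 1
      img <- array(rep(f, 3L), dim = c(dim(f), 3L))
      tr <- traces[[i]]
      img <- draw_curve(img, tr$sclera_um, ax, c(1, 0.9, 0.2))
      img <- draw_curve(img, tr$orl_um, ax, c(0.2, 1, 0.3))
      img <- draw_curve(img, tr$irl_um, ax, c(0.7, 0.3, 1))
      p <- file.path(outdir, sprintf("overlay_b%02d.png", i))
      png::writePNG(img, p)
      paths[sprintf("overlay_b%02d", i)] <- p
    }
  }
  invisible(paths)
}
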