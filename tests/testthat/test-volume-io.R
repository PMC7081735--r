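write_sidecar <- function(path, axial = 3.87, lateral = 11, bscan = 240, ...) {
  jsonlite::write_json(list(axial_um_per_px = axial, lateral_um_per_px = lateral,
                            bscan_spacing_um = bscan, ...),
                       path, auto_unbox = TRUE)
}

test_that("multi-page TIFF volumes round-trip with their spacing metadata", {
  td <- withr::local_tempdir()
  frames <- lapply(1:7, function(i) matrix(runif(60 * 40), 60, 40))
  vol <- oct_volume(frames, 3.87, 11, 240, meta = list(eye = "OD"))
  paths <- write_volume(vol, file.path(td, "vol.tif"))
  back <- load_volume(paths$tiff)

  expect_length(back$frames, 7)
  expect_equal(dim(back$frames[[1]]), c(60, 40))
  expect_equal(back$axial_spacing, 3.87)
  expect_equal(back$lateral_spacing, 11)
  expect_equal(back$bscan_spacing, 240)
  expect_equal(back$meta$eye, "OD")
  # 16-bit quantization: intensities preserved to ~1/65535 after rescaling
  # by the volume-wide maximum that write_volume normalized with
  mx <- max(unlist(frames))
  expect_lt(max(abs(back$frames[[1]] * mx - frames[[1]])), 2 * mx / 65535)

  # a second write/load preserves everything again
  paths2 <- write_volume(back, file.path(td, "vol2.tif"))
  back2 <- load_volume(paths2$tiff)
  expect_equal(back2$frames, back$frames, tolerance = 1e-4)
  expect_equal(back2$bscan_spacing, 240)
})

test_that("explicit sidecar metadata passes through", {
  td <- withr::local_tempdir()
  tiff::writeTIFF(lapply(1:7, function(i) matrix(runif(496 * 80), 496, 80)),
                  file.path(td, "v.tif"), bits.per.sample = 16)
  sc <- file.path(td, "meta.json")
  write_sidecar(sc, subject = "rat01")
  vol <- load_volume(file.path(td, "v.tif"), sidecar = sc)
  expect_equal(vol$axial_spacing, 3.87)
  expect_equal(vol$meta$subject, "rat01")
})

test_that("PNG frame directories load in lexicographic order", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "stack"))
  for (i in 1:3) {
    png::writePNG(matrix(i / 10, 30, 20),
                  file.path(td, "stack", sprintf("frame_%02d.png", i)))
  }
  write_sidecar(file.path(td, "stack", "sidecar.json"), bscan = 0)
  vol <- load_volume(file.path(td, "stack"))
  expect_length(vol$frames, 3)
  expect_equal(vol$bscan_spacing, 0)
  expect_equal(vapply(vol$frames, function(f) f[1, 1], numeric(1)),
               c(1, 2, 3) / 10, tolerance = 0.05)
})

test_that("single-frame stacks are legal, degenerate inputs are not", {
  td <- withr::local_tempdir()
  tiff::writeTIFF(matrix(0.5, 20, 10), file.path(td, "one.tif"))
  write_sidecar(file.path(td, "one.json"), bscan = 0)
  vol <- load_volume(file.path(td, "one.tif"))
  expect_length(vol$frames, 1)
  expect_equal(vol$bscan_spacing, 0)

  # mixed frame sizes
  dir.create(file.path(td, "ragged"))
  png::writePNG(matrix(0.1, 30, 20), file.path(td, "ragged", "a.png"))
  png::writePNG(matrix(0.1, 31, 20), file.path(td, "ragged", "b.png"))
  write_sidecar(file.path(td, "ragged", "sidecar.json"))
  expect_error(load_volume(file.path(td, "ragged")), class = "octseg_format_error")

  # empty directory
  dir.create(file.path(td, "empty"))
  expect_error(load_volume(file.path(td, "empty")), class = "octseg_format_error")

  # no spacing metadata at all
  tiff::writeTIFF(matrix(0.5, 20, 10), file.path(td, "naked.tif"))
  expect_error(load_volume(file.path(td, "naked.tif")), class = "octseg_config_error")

  # sidecar lacking a required key
  tiff::writeTIFF(matrix(0.5, 20, 10), file.path(td, "part.tif"))
  jsonlite::write_json(list(axial_um_per_px = 3.87), file.path(td, "part.json"),
                       auto_unbox = TRUE)
  expect_error(load_volume(file.path(td, "part.tif")), class = "octseg_config_error")
})

test_that("oct_volume enforces its invariants", {
  f <- matrix(1, 10, 5)
  expect_error(oct_volume(list(), 1, 1), class = "octseg_format_error")
  expect_error(oct_volume(list(f, matrix(1, 9, 5)), 1, 1),
               class = "octseg_format_error")
  expect_error(oct_volume(list(matrix(-1, 2, 2)), 1, 1),
               class = "octseg_format_error")
  expect_error(oct_volume(list(f), 0, 1), class = "octseg_config_error")
  expect_error(oct_volume(list(f), 1, 1, bscan_spacing = -1),
               class = "octseg_config_error")
  expect_silent(oct_volume(list(f), 1, 1, bscan_spacing = 0))
})

test_that("result files are complete and CSV numbers re-read at fixed precision", {
  td <- withr::local_tempdir()
  spec <- small_spec(n_bscans = 3L)
  gen <- generate_volume(spec)
  ana <- analyze_volume(gen$volume)
  paths <- write_results(gen$volume, ana$traces, ana$bscans, ana$volume,
                         file.path(td, "out"))

  expect_true(all(file.exists(paths)))
  expect_length(grep("^overlay", names(paths)), 3)

  bounds <- read.csv(paths[["boundaries"]])
  expect_equal(nrow(bounds), 3 * spec$n_ascans)
  all_th <- unlist(lapply(ana$traces, function(tr) tr$thickness_um))
  expect_equal(bounds$thickness_um, round(all_th, 3))

  summ <- read.csv(paths[["bscan_summary"]])
  expect_equal(summ$mean_um, round(ana$bscans$mean_um, 3))
  expect_equal(summ$retained, ana$bscans$retained)

  js <- jsonlite::read_json(paths[["volume_summary"]])
  expect_equal(js$weighted_mean_um, ana$volume$weighted_mean)
  expect_equal(js$n_retained, 3L)

  # overlays are valid PNGs of the frame size
  img <- png::readPNG(paths[["overlay_b01"]])
  expect_equal(dim(img), c(spec$n_depth, spec$n_ascans, 3))
})

test_that("a volume with no retained B-scans reports an explicit null estimate", {
  td <- withr::local_tempdir()
  spec <- small_spec(n_bscans = 2L, speckle_k = 30)
  gen <- generate_volume(spec)
  tr <- segment_volume(gen$volume)
  summ <- do.call(rbind, lapply(seq_along(tr), function(i) summarize_bscan(tr[[i]], i)))
  summ <- filter_bscans(summ, threshold = 0.0001)  # discard everything
  vt <- volume_mean(summ)
  paths <- write_results(gen$volume, tr, summ, vt, file.path(td, "none"),
                         overlays = FALSE)
  js <- jsonlite::read_json(paths[["volume_summary"]])
  expect_null(js$weighted_mean_um)
  expect_equal(js$n_retained, 0L)
  expect_match(js$reason, "retained")
})

test_that("unwritable output directories raise an I/O error", {
  td <- withr::local_tempdir()
  blocker <- file.path(td, "blocker")
  writeLines("x", blocker)  # a regular file where a directory is needed
  spec <- small_spec(n_bscans = 1L)
  gen <- generate_volume(spec)
  ana <- analyze_volume(gen$volume)
  expect_error(
    suppressWarnings(
      write_results(gen$volume, ana$traces, ana$bscans, ana$volume,
                    file.path(blocker, "out"))
    ),
    class = "octseg_io_error"
  )
})
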