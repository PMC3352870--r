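make_random_volume <- function(nb = 5L, nd = 32L, na = 24L, seed = 42L) {
  set.seed(seed)
  oct_volume(replicate(nb, matrix(runif(nd * na), nd, na), simplify = FALSE),
             axial_spacing_um = 3.9, lateral_spacing_um = 15,
             bscan_spacing_um = 30)
}

test_that("raw float64 volumes round-trip bit-identically", {
  vol <- make_random_volume()
  f <- tempfile(fileext = ".raw")
  save_volume(vol, f, format = "raw", dtype = "float64")
  back <- load_volume(f)
  expect_identical(back$bscans, vol$bscans)
  expect_equal(back$axial_spacing_um, vol$axial_spacing_um)
  expect_equal(back$lateral_spacing_um, vol$lateral_spacing_um)
  expect_equal(back$bscan_spacing_um, vol$bscan_spacing_um)
  # save -> load -> save is byte-stable
  f2 <- tempfile(fileext = ".raw")
  save_volume(back, f2, format = "raw", dtype = "float64")
  expect_identical(readBin(f, "raw", file.info(f)$size),
                   readBin(f2, "raw", file.info(f2)$size))
})

test_that("tiff stacks round-trip through float32 and are byte-stable", {
  vol <- make_random_volume(nb = 3L)
  f <- tempfile(fileext = ".tif")
  save_volume(vol, f, format = "tiff_stack")
  back <- load_volume(f)
  expect_equal(back$n_bscans, 3L)
  for (b in 1:3) {
    expect_lt(max(abs(back$bscans[[b]] - vol$bscans[[b]])), 1e-6)
  }
  # saving the same object twice is deterministic
  f2 <- tempfile(fileext = ".tif")
  save_volume(vol, f2, format = "tiff_stack")
  expect_identical(readBin(f, "raw", file.info(f)$size),
                   readBin(f2, "raw", file.info(f2)$size))
  # a further save/load cycle stays within the 32-bit quantization step
  f3 <- tempfile(fileext = ".tif")
  save_volume(back, f3, format = "tiff_stack")
  again <- load_volume(f3)
  for (b in 1:3) {
    expect_lt(max(abs(again$bscans[[b]] - back$bscans[[b]])), 1e-9)
  }
})

test_that("sidecar dimensions drive the loaded grid", {
  # the acquisition-protocol geometry: 145 B-scans x 384 A-scans
  nb <- 145L; nd <- 8L; na <- 384L
  f <- tempfile(fileext = ".raw")
  con <- file(f, "wb")
  writeBin(as.integer(rep(128L, nb * nd * na)), con, size = 1L)
  close(con)
  jsonlite::write_json(
    list(n_bscans = nb, n_depth = nd, n_ascans = na, dtype = "uint8",
         axial_spacing_um = 3.9, lateral_spacing_um = 15,
         bscan_spacing_um = 30, intensity_range = c(0, 255)),
    paste0(f, ".json"), auto_unbox = TRUE)
  vol <- load_volume(f)
  expect_equal(vol$n_bscans, 145L)
  expect_equal(vol$n_ascans, 384L)
  expect_equal(vol$n_depth, 8L)
  expect_equal(vol$bscans[[1]][1, 1], 128 / 255)
})

test_that("metadata inconsistencies are hard errors, never truncation", {
  f <- tempfile(fileext = ".raw")
  writeBin(rep(0.5, 100), f, size = 8L)
  jsonlite::write_json(
    list(n_bscans = 2, n_depth = 10, n_ascans = 10, dtype = "float64",
         axial_spacing_um = 3.9, lateral_spacing_um = 15, bscan_spacing_um = 30),
    paste0(f, ".json"), auto_unbox = TRUE)
  expect_error(load_volume(f), class = "onhquant_metadata_error")
  # missing sidecar
  f2 <- tempfile(fileext = ".raw")
  writeBin(rep(0.5, 100), f2, size = 8L)
  expect_error(load_volume(f2), class = "onhquant_metadata_error")
  # missing spacing key
  jsonlite::write_json(
    list(n_bscans = 1, n_depth = 10, n_ascans = 10, dtype = "float64"),
    paste0(f2, ".json"), auto_unbox = TRUE)
  expect_error(load_volume(f2), class = "onhquant_metadata_error")
})

test_that("volume invariants are enforced at construction", {
  m <- matrix(0, 16, 16)
  expect_error(oct_volume(list(m, matrix(0, 16, 8)), 4, 15, 30),
               class = "onhquant_format_error")
  expect_error(oct_volume(list(m), 0, 15, 30), class = "onhquant_metadata_error")
  expect_error(oct_volume(list(matrix(0, 4, 4)), 4, 15, 30),
               class = "onhquant_format_error")
})

test_that("reports serialize exactly and validate their invariants", {
  rep <- onh_report(onhv_mm3 = 0.6, onhh_mm = 0.4,
                    area_profile_mm2 = c(1, 2, 3), threshold_px = 20,
                    bscan_spacing_um = 100,
                    meta = list(n_bscans = 3))
  f <- tempfile(fileext = ".json")
  save_report(rep, f)
  expect_true(grepl('"onhv_mm3": 0.6', paste(readLines(f), collapse = "")))
  back <- load_report(f)
  expect_identical(back$onhv_mm3, rep$onhv_mm3)
  expect_identical(back$area_profile_mm2, rep$area_profile_mm2)
  expect_identical(back$onhh_mm, rep$onhh_mm)

  fc <- tempfile(fileext = ".csv")
  save_report(rep, fc)
  csv <- load_report(fc)
  expect_equal(sum(csv$area_mm2, na.rm = TRUE), 6)

  # area profile inconsistent with declared B-scan count
  expect_error(
    onh_report(0.6, 0.4, c(1, 2, 3), 20, meta = list(n_bscans = 5)),
    class = "onhquant_validation_error")
  # volume must integrate the area profile
  expect_error(
    onh_report(0.9, 0.4, c(1, 2, 3), 20, bscan_spacing_um = 100),
    class = "onhquant_validation_error")
  expect_error(save_report(rep, file.path(tempdir(), "no/such/dir/x.json")),
               class = "onhquant_io_error")
})
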