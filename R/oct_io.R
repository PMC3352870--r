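#' OCT volume container
#'
#' An `oct_volume` is an ordered stack of B-scans (2D grayscale matrices,
#' rows = axial depth from the vitreous side, columns = A-scans) together with
#' the physical spacing metadata needed to convert pixel measurements into
#' millimetres. Intensities are stored normalized to \[0, 1\].
#'
#' @param bscans list of numeric matrices, all the same dimension; row 1 is
#'   the top (vitreous side) of each B-scan, column 1 the left edge.
#' @param axial_spacing_um axial (depth) pixel pitch in micrometres.
#' @param lateral_spacing_um lateral pitch across A-scans in micrometres.
#' @param bscan_spacing_um distance between consecutive B-scans in
#'   micrometres.
#' @param intensity_range declared min/max of the stored values (length 2).
#' @param meta free-form named list of provenance information.
#'
#' @return An object of class `oct_volume` with fields `bscans`, `n_bscans`,
#'   `n_ascans`, `n_depth`, the three spacings, `intensity_range` and `meta`.
#' @export
oct_volume <- function(bscans, axial_spacing_um, lateral_spacing_um,
                       bscan_spacing_um, intensity_range = c(0, 1),
                       meta = list()) {
  if (!is.list(bscans) || length(bscans) < 1L) {
    onh_error("onhquant_format_error", "'bscans' must be a non-empty list of matrices")
  }
  dims <- vapply(bscans, function(b) {
    if (!is.matrix(b) || !is.numeric(b)) {
      onh_error("onhquant_format_error", "every B-scan must be a numeric matrix")
    }
    dim(b)
  }, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    onh_error("onhquant_format_error", "all B-scans must share identical dimensions")
  }
  n_depth <- dims[1, 1]; n_ascans <- dims[2, 1]
  if (n_ascans < 8L || n_depth < 8L) {
    onh_error("onhquant_format_error", "B-scans must be at least 8x8 pixels")
  }
  sp <- c(axial_spacing_um, lateral_spacing_um, bscan_spacing_um)
  if (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0)) {
    onh_error("onhquant_metadata_error", "all three spacings must be strictly positive")
  }
  if (length(intensity_range) != 2L || intensity_range[2] <= intensity_range[1]) {
    onh_error("onhquant_metadata_error", "intensity_range must be (min, max) with max > min")
  }
  structure(list(
    bscans = bscans,
    n_bscans = length(bscans),
    n_ascans = n_ascans,
    n_depth = n_depth,
    axial_spacing_um = as.numeric(axial_spacing_um),
    lateral_spacing_um = as.numeric(lateral_spacing_um),
    bscan_spacing_um = as.numeric(bscan_spacing_um),
    intensity_range = as.numeric(intensity_range),
    meta = meta
  ), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat(sprintf(
    "<oct_volume> %d B-scans x %d A-scans x %d depth px\n  spacing (um): axial %.3g, lateral %.3g, inter-B-scan %.3g\n",
    x$n_bscans, x$n_ascans, x$n_depth,
    x$axial_spacing_um, x$lateral_spacing_um, x$bscan_spacing_um
  ))
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    onh_error("onhquant_metadata_error", sprintf("sidecar file not found: %s", sc))
  }
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

need_keys <- function(sc, keys, where) {
  miss <- setdiff(keys, names(sc))
  if (length(miss)) {
    onh_error("onhquant_metadata_error",
              sprintf("sidecar %s is missing required keys: %s",
                      where, paste(miss, collapse = ", ")))
  }
}

#' Load an OCT volume from disk
#'
#' Two dependency-light dialects are supported: `tiff_stack` (one multi-page
#' grayscale TIFF, page k = B-scan k) and `raw` (little-endian float64,
#' float32 or uint8 samples in (bscan, depth, ascan) order). Both carry a
#' JSON sidecar named `<path>.json` with the spacings and, for raw files, the
#' grid dimensions. Intensities are rescaled to \[0, 1\] according to the
#' declared `intensity_range`. Vendor-proprietary containers are deliberately
#' not parsed.
#'
#' @param path file to read.
#' @param format `"auto"` (by extension), `"tiff_stack"` or `"raw"`.
#' @param axial_spacing_um,lateral_spacing_um,bscan_spacing_um optional
#'   overrides for the sidecar spacings (required if no sidecar exists for a
#'   TIFF stack).
#' @return An [oct_volume].
#' @export
load_volume <- function(path, format = c("auto", "tiff_stack", "raw"),
                        axial_spacing_um = NULL, lateral_spacing_um = NULL,
                        bscan_spacing_um = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    onh_error("onhquant_io_error", sprintf("no such file: %s", path))
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tif", "tiff")) "tiff_stack" else "raw"
  }
  overrides <- list(axial_spacing_um = axial_spacing_um,
                    lateral_spacing_um = lateral_spacing_um,
                    bscan_spacing_um = bscan_spacing_um)
  if (format == "tiff_stack") load_volume_tiff(path, overrides)
  else load_volume_raw(path, overrides)
}

resolve_spacings <- function(sc, overrides) {
  out <- list()
  for (k in c("axial_spacing_um", "lateral_spacing_um", "bscan_spacing_um")) {
    out[[k]] <- overrides[[k]] %||% sc[[k]]
    if (is.null(out[[k]])) {
      onh_error("onhquant_metadata_error",
                sprintf("spacing '%s' is neither in the sidecar nor given explicitly", k))
    }
  }
  out
}

load_volume_tiff <- function(path, overrides) {
  sc <- if (file.exists(sidecar_path(path))) read_sidecar(path) else list()
  sp <- resolve_spacings(sc, overrides)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]  # collapse grayscale-as-RGB
    p
  })
  rng <- as.numeric(sc$intensity_range %||% c(0, 1))
  bscans <- lapply(pages, function(p) (p - rng[1]) / (rng[2] - rng[1]))
  oct_volume(bscans, sp$axial_spacing_um, sp$lateral_spacing_um,
             sp$bscan_spacing_um, intensity_range = c(0, 1),
             meta = list(source = path, format = "tiff_stack",
                         stored_intensity_range = rng))
}

raw_dtype_size <- c(float64 = 8L, float32 = 4L, uint8 = 1L)

load_volume_raw <- function(path, overrides) {
  sc <- read_sidecar(path)
  need_keys(sc, c("n_bscans", "n_depth", "n_ascans", "dtype"), path)
  sp <- resolve_spacings(sc, overrides)
  dtype <- match.arg(sc$dtype, names(raw_dtype_size))
  nb <- as.integer(sc$n_bscans); nd <- as.integer(sc$n_depth); na <- as.integer(sc$n_ascans)
  n <- as.numeric(nb) * nd * na
  expect_bytes <- n * raw_dtype_size[[dtype]]
  actual <- file.info(path)$size
  if (!isTRUE(actual == expect_bytes)) {
    onh_error("onhquant_metadata_error",
              sprintf("declared %d x %d x %d %s volume needs %.0f bytes but file has %.0f",
                      nb, nd, na, dtype, expect_bytes, actual))
  }
  con <- file(path, "rb"); on.exit(close(con))
  x <- if (dtype == "uint8") {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  } else {
    readBin(con, "double", n = n, size = raw_dtype_size[[dtype]], endian = "little")
  }
  rng <- as.numeric(sc$intensity_range %||% if (dtype == "uint8") c(0, 255) else c(0, 1))
  x <- (x - rng[1]) / (rng[2] - rng[1])
  # samples are ordered (bscan, depth, ascan) row-major: ascan varies fastest
  bscans <- vector("list", nb)
  per <- nd * na
  for (b in seq_len(nb)) {
    slab <- x[((b - 1) * per + 1):(b * per)]
    bscans[[b]] <- t(matrix(slab, nrow = na, ncol = nd))
  }
  oct_volume(bscans, sp$axial_spacing_um, sp$lateral_spacing_um,
             sp$bscan_spacing_um, intensity_range = c(0, 1),
             meta = list(source = path, format = "raw", dtype = dtype,
                         stored_intensity_range = rng))
}

#' Save an OCT volume
#'
#' Writes the volume in one of the documented dialects plus its JSON sidecar
#' (`<path>.json`). The raw `float64` dtype round-trips double-precision
#' intensities bit-identically; `float32` and `uint8` store at reduced
#' precision, and TIFF pages are 32-bit integer samples (quantization step
#' about 2.3e-10).
#'
#' @param volume an [oct_volume].
#' @param path output file.
#' @param format `"tiff_stack"` or `"raw"`.
#' @param dtype raw sample type: `"float64"`, `"float32"` or `"uint8"`.
#' @return `path`, invisibly.
#' @export
save_volume <- function(volume, path, format = c("raw", "tiff_stack"),
                        dtype = c("float64", "float32", "uint8")) {
  stopifnot(inherits(volume, "oct_volume"))
  format <- match.arg(format); dtype <- match.arg(dtype)
  sc <- list(
    n_bscans = volume$n_bscans, n_depth = volume$n_depth,
    n_ascans = volume$n_ascans,
    axial_spacing_um = volume$axial_spacing_um,
    lateral_spacing_um = volume$lateral_spacing_um,
    bscan_spacing_um = volume$bscan_spacing_um,
    intensity_range = if (format == "raw" && dtype == "uint8") c(0, 255) else c(0, 1),
    format = format
  )
  if (format == "raw") {
    sc$dtype <- dtype
    con <- file(path, "wb")
    for (b in volume$bscans) {
      slab <- as.vector(t(b))  # ascan fastest within each depth row
      if (dtype == "uint8") {
        writeBin(as.integer(round(pmin(pmax(slab, 0), 1) * 255)), con, size = 1L)
      } else {
        writeBin(as.numeric(slab), con, size = raw_dtype_size[[dtype]],
                 endian = "little")
      }
    }
    close(con)
  } else {
    tiff::writeTIFF(volume$bscans, path, bits.per.sample = 32L)
  }
  jsonlite::write_json(sc, sidecar_path(path), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' ONH quantification report
#'
#' Container for the pipeline's outputs: ONH volume (mm^3), ONH maximum
#' height (mm), the per-B-scan edema area profile (mm^2), the threshold and
#' parameters used, per-B-scan reference heights and quality flags.
#'
#' @param onhv_mm3 ONH volume in mm^3.
#' @param onhh_mm ONH maximum height in mm.
#' @param area_profile_mm2 numeric vector, edema area per B-scan.
#' @param threshold_px applied reference threshold (axial pixels).
#' @param params named list of quantification parameters used.
#' @param per_bscan_flags logical vector, `TRUE` where a B-scan was flagged
#'   and contributed zero area.
#' @param reference_px per-B-scan reference height (pixels), `NA` if flagged.
#' @param bscan_spacing_um inter-B-scan spacing used for the integration.
#' @param meta free-form provenance list.
#' @return An object of class `onh_report`.
#' @export
onh_report <- function(onhv_mm3, onhh_mm, area_profile_mm2, threshold_px,
                       params = list(), per_bscan_flags = NULL,
                       reference_px = NULL, bscan_spacing_um = NULL,
                       meta = list()) {
  n <- length(area_profile_mm2)
  per_bscan_flags <- per_bscan_flags %||% rep(FALSE, n)
  reference_px <- reference_px %||% rep(NA_real_, n)
  if (length(per_bscan_flags) != n || length(reference_px) != n) {
    onh_error("onhquant_validation_error",
              "per-B-scan fields must match the length of area_profile_mm2")
  }
  if (!is.null(meta$n_bscans) && meta$n_bscans != n) {
    onh_error("onhquant_validation_error",
              "area_profile length disagrees with the declared number of B-scans")
  }
  if (onhv_mm3 < 0 || onhh_mm < 0) {
    onh_error("onhquant_validation_error", "ONHV and ONHH must be non-negative")
  }
  if (!is.null(bscan_spacing_um)) {
    expect <- sum(area_profile_mm2) * bscan_spacing_um * 1e-3
    if (abs(expect - onhv_mm3) > 1e-8 * max(1, abs(onhv_mm3))) {
      onh_error("onhquant_validation_error",
                "onhv_mm3 is not the integral of the area profile over the B-scan spacing")
    }
  }
  structure(list(
    onhv_mm3 = as.numeric(onhv_mm3), onhh_mm = as.numeric(onhh_mm),
    area_profile_mm2 = as.numeric(area_profile_mm2),
    threshold_px = as.numeric(threshold_px), params = params,
    per_bscan_flags = as.logical(per_bscan_flags),
    reference_px = as.numeric(reference_px),
    bscan_spacing_um = bscan_spacing_um, meta = meta
  ), class = "onh_report")
}

#' @export
print.onh_report <- function(x, ...) {
  cat(sprintf("<onh_report>\n  ONHV: %.4f mm^3\n  ONHH: %.4f mm\n", x$onhv_mm3, x$onhh_mm))
  cat(sprintf("  %d B-scans (%d flagged), threshold %g px\n",
              length(x$area_profile_mm2), sum(x$per_bscan_flags), x$threshold_px))
  invisible(x)
}

#' Save / load an ONH report
#'
#' JSON is the canonical format and round-trips all numeric fields at full
#' double precision; CSV is a flat export with one row per B-scan plus
#' summary rows.
#'
#' @param report an [onh_report].
#' @param path output file.
#' @param format `"json"` or `"csv"` (default by extension).
#' @return `path` invisibly for `save_report`; an [onh_report] (JSON) or
#'   data frame (CSV) for `load_report`.
#' @export
save_report <- function(report, path, format = c("auto", "json", "csv")) {
  stopifnot(inherits(report, "onh_report"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  }
  ok <- tryCatch(suppressWarnings({
    if (format == "json") {
      jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
    } else {
      n <- length(report$area_profile_mm2)
      rows <- data.frame(
        record = c(rep("bscan", n), "summary_onhv_mm3", "summary_onhh_mm",
                   "summary_threshold_px"),
        bscan_index = c(seq_len(n), NA, NA, NA),
        reference_px = c(report$reference_px, NA, NA, NA),
        area_mm2 = c(report$area_profile_mm2, NA, NA, NA),
        flagged = c(report$per_bscan_flags, NA, NA, NA),
        value = c(rep(NA_real_, n), report$onhv_mm3, report$onhh_mm,
                  report$threshold_px)
      )
      utils::write.csv(rows, path, row.names = FALSE)
    }
    TRUE
  }), error = function(e) e)
  if (!isTRUE(ok)) {
    onh_error("onhquant_io_error",
              sprintf("could not write report to %s: %s", path, conditionMessage(ok)))
  }
  invisible(path)
}

#' @rdname save_report
#' @export
load_report <- function(path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  }
  if (format == "csv") return(utils::read.csv(path))
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  onh_report(x$onhv_mm3, x$onhh_mm, x$area_profile_mm2, x$threshold_px,
             params = as.list(x$params),
             per_bscan_flags = x$per_bscan_flags,
             reference_px = x$reference_px,
             bscan_spacing_um = x$bscan_spacing_um,
             meta = as.list(x$meta))
}
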