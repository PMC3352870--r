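#' Quantification parameters
#'
#' @param threshold_px reference threshold in native axial pixels (default
#'   20). The threshold is deliberately defined in pixels; physical
#'   conversion uses the axial spacing.
#' @param margin_frac fraction of A-scans at each lateral edge pooled into
#'   the peripheral reference height (default 0.10, must be in (0, 0.25\]).
#' @param threshold_sign `"below_reference"` (default): the baseline plane
#'   lies `threshold_px` below (toward the RPE) the peripheral ILM reference,
#'   so normal eyes retain a positive pedestal volume. `"above_reference"`
#'   places it on the opposite side.
#' @return A list of class `quantify_params`.
#' @export
quantify_params <- function(threshold_px = 20, margin_frac = 0.10,
                            threshold_sign = c("below_reference", "above_reference")) {
  threshold_sign <- match.arg(threshold_sign)
  if (threshold_px < 0) {
    onh_error("onhquant_parameter_error", "threshold_px must be >= 0")
  }
  if (margin_frac <= 0 || margin_frac > 0.25) {
    onh_error("onhquant_parameter_error", "margin_frac must be in (0, 0.25]")
  }
  structure(list(threshold_px = as.numeric(threshold_px),
                 margin_frac = as.numeric(margin_frac),
                 threshold_sign = threshold_sign),
            class = "quantify_params")
}

#' Flatten a B-scan on the fitted RPE
#'
#' Shifts each A-scan so the fitted RPE becomes a horizontal reference line,
#' removing the natural retinal curvature. Heights are computed directly
#' from the traces at sub-pixel precision (`ilm_height = rpe - ilm`); no
#' image is resampled, which avoids interpolation bias in the areas.
#'
#' @param ilm ILM [layer_trace], valid at every A-scan.
#' @param rpe fitted RPE [layer_trace] (full width, from the spline).
#' @param n_depth optional image depth; heights exceeding it (ILM above the
#'   image top after shifting) are clamped there and the B-scan flagged.
#' @return A list of class `flattened_bscan` with `ilm_height` (pixels, per
#'   A-scan), `rpe_row` (the constant reference row, median of the RPE
#'   trace), `shift_applied` and `flagged`.
#' @export
flatten_bscan <- function(ilm, rpe, n_depth = NULL) {
  if (!all(ilm$valid) || !all(rpe$valid)) {
    onh_error("onhquant_segmentation_error",
              "flattening needs both traces valid at every A-scan")
  }
  if (length(ilm$rows) != length(rpe$rows)) {
    onh_error("onhquant_parameter_error", "ILM and RPE traces differ in width")
  }
  rpe_row <- stats::median(rpe$rows)
  shift <- rpe$rows - rpe_row
  h <- rpe$rows - ilm$rows
  flagged <- FALSE
  if (!is.null(n_depth) && any(h > n_depth)) {
    h <- pmin(h, n_depth)
    flagged <- TRUE
  }
  structure(list(ilm_height = h, rpe_row = rpe_row, shift_applied = shift,
                 flagged = flagged),
            class = "flattened_bscan")
}

#' Peripheral reference height
#'
#' Pooled mean ILM height over the leftmost and rightmost
#' `ceiling(margin_frac * n)` A-scans of a flattened B-scan. For a 15-degree
#' ONH scan these edge margins sit outside the disc and approximate the
#' normal peripapillary retinal thickness.
#'
#' @param flat a [flatten_bscan()] result.
#' @param margin_frac edge fraction per side (default 0.10).
#' @return Reference height in pixels.
#' @export
reference_height <- function(flat, margin_frac = 0.10) {
  h <- flat$ilm_height
  n <- length(h)
  m <- ceiling(margin_frac * n)
  if (m < 1L || 2L * m > n) {
    onh_error("onhquant_parameter_error", "margin windows are empty or overlap")
  }
  mean(c(h[seq_len(m)], h[(n - m + 1L):n]))
}

#' Edema area on one flattened B-scan
#'
#' The edema is the area enclosed between the ILM and the baseline plane
#' derived from the peripheral reference height and the pixel threshold:
#' with `threshold_sign = "below_reference"` the baseline is
#' `reference - threshold_px` and the area integrates
#' `max(0, ilm_height - baseline)` across A-scans.
#'
#' @param flat a [flatten_bscan()] result.
#' @param params a [quantify_params] object.
#' @param lateral_spacing_um,axial_spacing_um pixel pitches in micrometres.
#' @param reference optional precomputed reference height (pixels); computed
#'   from `flat` otherwise.
#' @return Area in mm^2 (never negative).
#' @export
edema_area <- function(flat, params = quantify_params(), lateral_spacing_um,
                       axial_spacing_um, reference = NULL) {
  ref <- reference %||% reference_height(flat, params$margin_frac)
  b <- if (params$threshold_sign == "below_reference") {
    ref - params$threshold_px
  } else {
    ref + params$threshold_px
  }
  excess <- pmax(0, flat$ilm_height - b)
  sum(excess) * lateral_spacing_um * axial_spacing_um * 1e-6
}

#' ONH volume from the per-B-scan area profile
#'
#' @param areas_mm2 per-B-scan edema areas (mm^2, all >= 0).
#' @param bscan_spacing_um inter-B-scan spacing in micrometres.
#' @return Volume in mm^3: `sum(areas) * spacing(mm)`.
#' @export
onh_volume <- function(areas_mm2, bscan_spacing_um) {
  if (any(areas_mm2 < 0)) {
    onh_error("onhquant_parameter_error", "areas must be non-negative")
  }
  sum(areas_mm2) * bscan_spacing_um * 1e-3
}

#' ONH maximum height
#'
#' Maximum ILM elevation above the fitted RPE over all B-scans and A-scans,
#' in mm. Because heights are trace differences, the value is identical
#' whether computed before or after flattening.
#'
#' @param segmentation a [segment_volume()] result, or a numeric matrix /
#'   list of per-B-scan height vectors.
#' @param axial_spacing_um axial pixel pitch in micrometres.
#' @return Height in mm.
#' @export
onh_height <- function(segmentation, axial_spacing_um) {
  hmax <- if (inherits(segmentation, "volume_segmentation")) {
    vals <- vapply(seq_len(segmentation$n_bscans), function(b) {
      if (segmentation$flags[b]) return(NA_real_)
      max(segmentation$rpe[[b]]$rows - segmentation$ilm[[b]]$rows)
    }, numeric(1))
    max(vals, na.rm = TRUE)
  } else if (is.list(segmentation)) {
    max(vapply(segmentation, max, numeric(1)))
  } else {
    max(segmentation)
  }
  hmax * axial_spacing_um * 1e-3
}

#' Quantify a segmented OCT volume
#'
#' Assembles the per-B-scan pipeline (flatten on the RPE, peripheral
#' reference, thresholded edema area) and integrates areas into the ONH
#' volume and maximum height. Flagged B-scans contribute zero area and are
#' listed in the report; if more than 20% of B-scans are flagged the volume
#' is considered unreliable and a quantification error is raised.
#'
#' @param volume an [oct_volume].
#' @param segmentation the matching [segment_volume()] result.
#' @param params a [quantify_params] object.
#' @return An [onh_report].
#' @export
quantify_volume <- function(volume, segmentation, params = quantify_params()) {
  stopifnot(inherits(volume, "oct_volume"),
            inherits(segmentation, "volume_segmentation"))
  nb <- volume$n_bscans
  flags <- segmentation$flags
  areas <- numeric(nb); refs <- rep(NA_real_, nb); hmax_px <- rep(NA_real_, nb)
  for (b in seq_len(nb)) {
    if (flags[b]) next
    fl <- flatten_bscan(segmentation$ilm[[b]], segmentation$rpe[[b]],
                        n_depth = volume$n_depth)
    if (fl$flagged) { flags[b] <- TRUE; next }
    refs[b] <- reference_height(fl, params$margin_frac)
    areas[b] <- edema_area(fl, params, volume$lateral_spacing_um,
                           volume$axial_spacing_um, reference = refs[b])
    hmax_px[b] <- max(fl$ilm_height)
  }
  if (mean(flags) > 0.20) {
    onh_error("onhquant_quantification_error",
              sprintf("%d of %d B-scans flagged (> 20%%); volume unreliable",
                      sum(flags), nb))
  }
  onhv <- onh_volume(areas, volume$bscan_spacing_um)
  onhh <- max(hmax_px, na.rm = TRUE) * volume$axial_spacing_um * 1e-3
  onh_report(
    onhv_mm3 = onhv, onhh_mm = onhh, area_profile_mm2 = areas,
    threshold_px = params$threshold_px,
    params = unclass(params),
    per_bscan_flags = flags, reference_px = refs,
    bscan_spacing_um = volume$bscan_spacing_um,
    meta = list(n_bscans = nb,
                axial_spacing_um = volume$axial_spacing_um,
                lateral_spacing_um = volume$lateral_spacing_um)
  )
}

#' End-to-end ONH quantification
#'
#' Convenience wrapper: segment every B-scan of a volume and quantify the
#' result under one resolved configuration. The pipeline is deterministic:
#' identical volumes and configurations give identical reports.
#'
#' @param volume an [oct_volume].
#' @param config configuration overrides or a resolved [onh_config()] list.
#' @param ilm optional precomputed ILM traces (see [segment_volume()]).
#' @return An [onh_report].
#' @export
quantify_onh <- function(volume, config = onh_config(), ilm = NULL) {
  config <- resolve_config(config)
  seg <- segment_volume(volume, config, ilm = ilm)
  params <- quantify_params(config[["quantify.threshold_px"]],
                            config[["quantify.margin_frac"]],
                            config[["quantify.threshold_sign"]])
  quantify_volume(volume, seg, params)
}
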