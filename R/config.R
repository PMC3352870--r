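#' Pipeline configuration
#'
#' The full pipeline is controlled by a flat list of namespaced keys, all
#' with documented defaults. [resolve_config()] merges user overrides into
#' the defaults and rejects unknown keys, so typos never silently fall back
#' to defaults; every CLI run writes the fully resolved configuration next
#' to its outputs.
#'
#' Keys and defaults:
#' \itemize{
#'   \item `preprocess.median_window` (3), `preprocess.gaussian_sigma`
#'     (1.5), `preprocess.stages` (`c("median","gaussian")`)
#'   \item `segmentation.ilm_threshold` (0.25), `segmentation.ilm_smooth_px`
#'     (3), `segmentation.mask_offset_px` (30), `segmentation.n_per_ascan`
#'     (3), `segmentation.band_halfwidth` (15), `segmentation.gap_min` (20),
#'     `segmentation.intensity_floor_rel` (0.5), `segmentation.n_knots` (5),
#'     `segmentation.order_rule` ("gap_low_order")
#'   \item `quantify.threshold_px` (20), `quantify.margin_frac` (0.10),
#'     `quantify.threshold_sign` ("below_reference")
#' }
#'
#' @return Named list of defaults.
#' @export
onh_config <- function() {
  list(
    preprocess.median_window = 3L,
    preprocess.gaussian_sigma = 1.5,
    preprocess.stages = c("median", "gaussian"),
    segmentation.ilm_threshold = 0.25,
    segmentation.ilm_smooth_px = 3L,
    segmentation.mask_offset_px = 30,
    segmentation.n_per_ascan = 3L,
    segmentation.band_halfwidth = 15,
    segmentation.gap_min = 20L,
    segmentation.intensity_floor_rel = 0.5,
    segmentation.n_knots = 5L,
    segmentation.order_rule = "gap_low_order",
    quantify.threshold_px = 20,
    quantify.margin_frac = 0.10,
    quantify.threshold_sign = "below_reference"
  )
}

#' @rdname onh_config
#' @param overrides named list of configuration overrides (possibly already
#'   resolved; idempotent).
#' @export
resolve_config <- function(overrides = list()) {
  base <- onh_config()
  if (is.null(overrides) || !length(overrides)) return(base)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown)) {
    onh_error("onhquant_parameter_error",
              sprintf("unknown configuration key(s): %s",
                      paste(unknown, collapse = ", ")))
  }
  base[names(overrides)] <- overrides
  base
}
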