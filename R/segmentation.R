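#' Per-A-scan layer trace
#'
#' A `layer_trace` stores one retinal surface on one B-scan as a floating
#' point row position per A-scan (1-based matrix rows; sub-pixel precision)
#' plus a validity mask.
#'
#' @param rows numeric vector of row positions (may contain `NA`).
#' @param valid logical vector; defaults to `is.finite(rows)`.
#' @return An object of class `layer_trace`.
#' @export
layer_trace <- function(rows, valid = is.finite(rows)) {
  rows <- as.numeric(rows)
  valid <- as.logical(valid)
  if (length(valid) != length(rows)) {
    onh_error("onhquant_parameter_error", "valid mask must match rows in length")
  }
  if (any(valid & !is.finite(rows))) {
    onh_error("onhquant_parameter_error", "valid positions must be finite")
  }
  structure(list(rows = rows, valid = valid), class = "layer_trace")
}

#' @export
print.layer_trace <- function(x, ...) {
  cat(sprintf("<layer_trace> %d A-scans, %d valid, rows %.1f..%.1f\n",
              length(x$rows), sum(x$valid),
              suppressWarnings(min(x$rows[x$valid])),
              suppressWarnings(max(x$rows[x$valid]))))
  invisible(x)
}

#' Detect the inner limiting membrane (ILM)
#'
#' Stand-in for the OCT device's ILM segmentation: per A-scan, the first
#' axial position (from the vitreous side) where the smoothed intensity
#' crosses `min_intensity`. The crossing is refined to sub-pixel precision by
#' linear interpolation between the two straddling pixels. Columns with no
#' crossing are marked invalid. Precomputed ILM traces (e.g. exported from
#' the device) can be supplied to the pipeline instead via [load_ilm_csv()].
#'
#' @param bscan denoised B-scan matrix, intensities in \[0, 1\].
#' @param min_intensity detection threshold (default 0.25).
#' @param smooth_px running-mean window applied along each A-scan before
#'   thresholding (odd; default 3).
#' @return A [layer_trace].
#' @export
segment_ilm <- function(bscan, min_intensity = 0.25, smooth_px = 3L) {
  nd <- nrow(bscan); na <- ncol(bscan)
  sm <- bscan
  if (smooth_px > 1L) {
    sm <- conv_depth_cpp(bscan, rep(1 / smooth_px, smooth_px))
  }
  hit <- sm >= min_intensity
  first <- max.col(t(hit), ties.method = "first")
  valid <- hit[cbind(first, seq_len(na))]
  rows <- rep(NA_real_, na)
  for (a in which(valid)) {
    r <- first[a]
    if (r > 1L) {
      v0 <- sm[r - 1L, a]; v1 <- sm[r, a]
      frac <- if (v1 > v0) (min_intensity - v0) / (v1 - v0) else 1
      rows[a] <- (r - 1L) + min(max(frac, 0), 1)
    } else {
      rows[a] <- 1
    }
  }
  layer_trace(rows, valid)
}

#' Read precomputed ILM traces
#'
#' CSV dialect for supplying device-exported ILM segmentations: columns
#' `bscan_index`, `ascan_index`, `row` (all 1-based; `row` may be
#' fractional). Missing (bscan, ascan) cells are marked invalid.
#'
#' @param path CSV file.
#' @param n_bscans,n_ascans expected grid size.
#' @return A list of [layer_trace] objects, one per B-scan.
#' @export
load_ilm_csv <- function(path, n_bscans, n_ascans) {
  d <- utils::read.csv(path)
  need <- c("bscan_index", "ascan_index", "row")
  if (!all(need %in% names(d))) {
    onh_error("onhquant_format_error",
              "ILM CSV needs columns bscan_index, ascan_index, row")
  }
  lapply(seq_len(n_bscans), function(b) {
    rows <- rep(NA_real_, n_ascans)
    sel <- d$bscan_index == b & d$ascan_index >= 1 & d$ascan_index <= n_ascans
    rows[d$ascan_index[sel]] <- d$row[sel]
    layer_trace(rows)
  })
}

#' Suppress bright inner layers above the ILM
#'
#' Zeroes every pixel above `ilm row + offset_px` in each column, so that the
#' brightest remaining spots most likely belong to the RPE. Columns with an
#' invalid ILM use the median valid ILM row.
#'
#' @param bscan B-scan matrix.
#' @param ilm [layer_trace] of the ILM; must be valid on at least half of the
#'   A-scans.
#' @param offset_px cut depth below the ILM in pixels (default 30); must
#'   exceed the bright nerve-fiber-layer band but stay above the RPE.
#' @return Matrix of the same shape with the upper region set to 0.
#' @export
mask_upper_layers <- function(bscan, ilm, offset_px = 30) {
  nd <- nrow(bscan); na <- ncol(bscan)
  if (mean(ilm$valid) < 0.5) {
    onh_error("onhquant_segmentation_error",
              "ILM valid on fewer than 50% of A-scans; cannot mask upper layers")
  }
  cut <- ilm$rows
  cut[!ilm$valid] <- stats::median(ilm$rows[ilm$valid])
  cut <- cut + offset_px
  keep <- outer(seq_len(nd), cut, ">=")
  keep[, cut > nd] <- TRUE  # cut below the image: nothing to mask
  bscan * keep
}

#' RPE candidate pixels
#'
#' Bright-spot candidates for the retinal pigment epithelium on one masked
#' B-scan, with the maximal runs of consecutive candidate-bearing A-scans
#' ("segments"). The optic disc, where the RPE is absent, shows up as a gap
#' splitting the candidates into two segments.
#'
#' @param masked output of [mask_upper_layers()].
#' @param n_per_ascan provisional brightest pixels kept per A-scan (default 3).
#' @param band_halfwidth propagation band half-width in rows (default 15).
#' @param gap_min runs separated by more than this many empty columns start a
#'   new segment (default 20).
#' @param floor_rel candidate intensity floor as a fraction of the mean
#'   anchor intensity (default 0.5); columns below it contribute no candidate
#'   (this is what creates the disc gap).
#' @param dark_floor_abs absolute brightness both quarter-width anchor
#'   A-scans must exceed, else the B-scan is rejected (default 0.05).
#' @return An object of class `rpe_candidates` with fields `points` (data
#'   frame `ascan`, `row`, `intensity`), `segments` (list of A-scan index
#'   ranges) and `n_segments`.
#' @details The search band is seeded from the brightest pixels of the
#'   A-scans at 25% and 75% of the width and propagated column-to-column in
#'   both directions from each anchor (each anchor covers its half of the
#'   B-scan). The next column's accepted candidate must lie within
#'   `band_halfwidth` rows of the running band center, which then updates to
#'   the accepted row; among admissible provisional candidates the brightest
#'   wins, ties going to the smaller row.
#' @export
detect_rpe_candidates <- function(masked, n_per_ascan = 3L,
                                  band_halfwidth = 15, gap_min = 20L,
                                  floor_rel = 0.5, dark_floor_abs = 0.05) {
  nd <- nrow(masked); na <- ncol(masked)
  n_per <- max(1L, as.integer(n_per_ascan))
  # provisional candidates: the n_per brightest (positive) pixels per column
  prov_rows <- matrix(NA_integer_, n_per, na)
  prov_int <- matrix(NA_real_, n_per, na)
  for (a in seq_len(na)) {
    col <- masked[, a]
    ord <- order(col, seq_len(nd), decreasing = c(TRUE, FALSE), method = "radix")
    top <- ord[seq_len(n_per)]
    pos <- col[top] > 0
    prov_rows[pos, a] <- top[pos]
    prov_int[pos, a] <- col[top][pos]
  }
  a1 <- max(1L, round(0.25 * na)); a2 <- min(na, round(0.75 * na))
  anchor_int <- c(prov_int[1L, a1], prov_int[1L, a2])
  if (all(is.na(anchor_int)) || all(anchor_int < dark_floor_abs, na.rm = TRUE)) {
    onh_error("onhquant_segmentation_error",
              "both anchor A-scans are dark; B-scan rejected")
  }
  floor_abs <- floor_rel * mean(anchor_int, na.rm = TRUE)

  acc_row <- rep(NA_real_, na); acc_int <- rep(NA_real_, na)
  accept_run <- function(cols, center) {
    for (a in cols) {
      rows <- prov_rows[, a]; ints <- prov_int[, a]
      ok <- !is.na(rows) & ints >= floor_abs & abs(rows - center) <= band_halfwidth
      if (any(ok)) {
        pick <- which(ok)[order(ints[ok], -rows[ok], decreasing = TRUE)[1L]]
        acc_row[a] <<- rows[pick]; acc_int[a] <<- ints[pick]
        center <- rows[pick]
      }
    }
  }
  mid <- na %/% 2L
  seed1 <- prov_rows[1L, a1]; seed2 <- prov_rows[1L, a2]
  if (!is.na(seed1)) {
    accept_run(a1:1L, seed1)
    accept_run(a1:mid, seed1)
  }
  if (!is.na(seed2)) {
    accept_run(a2:na, seed2)
    accept_run(a2:(mid + 1L), seed2)
  }
  have <- which(!is.na(acc_row))
  segments <- list()
  if (length(have)) {
    brk <- c(0L, which(diff(have) > gap_min + 1L), length(have))
    for (i in seq_len(length(brk) - 1L)) {
      run <- have[(brk[i] + 1L):brk[i + 1L]]
      segments[[i]] <- c(first = run[1L], last = run[length(run)])
    }
  }
  structure(list(
    points = data.frame(ascan = have, row = acc_row[have],
                        intensity = acc_int[have]),
    segments = segments,
    n_segments = length(segments),
    floor_abs = floor_abs,
    n_ascans = na
  ), class = "rpe_candidates")
}

#' @export
print.rpe_candidates <- function(x, ...) {
  cat(sprintf("<rpe_candidates> %d points in %d segment(s) over %d A-scans\n",
              nrow(x$points), x$n_segments, x$n_ascans))
  invisible(x)
}

#' Spline order from the RPE segment count
#'
#' The RPE spline order depends on how many RPE segments were detected. With
#' the default rule a disc gap (two or more segments) selects order 2, since
#' extrapolating across the gap is more stable at lower order, while a single
#' uninterrupted segment selects order 3 to follow the full retinal
#' curvature. The opposite mapping is selectable.
#'
#' @param n_segments number of detected RPE segments (>= 1).
#' @param rule `"gap_low_order"` (default) or `"gap_high_order"`.
#' @return 2 or 3.
#' @export
choose_spline_order <- function(n_segments, rule = c("gap_low_order", "gap_high_order")) {
  rule <- match.arg(rule)
  if (length(n_segments) != 1L || is.na(n_segments) || n_segments < 1) {
    onh_error("onhquant_segmentation_error", "no RPE segments detected")
  }
  gap <- n_segments >= 2
  if (rule == "gap_low_order") (if (gap) 2L else 3L) else (if (gap) 3L else 2L)
}

#' Least-squares RPE spline through the ONH
#'
#' Fits a least-squares B-spline of the given order to the RPE candidate
#' points and evaluates it at every A-scan, including across the disc gap —
#' this evaluation is the hypothetical extension of the peripapillary RPE
#' through the optic nerve head. Interior knots are placed at uniform
#' quantiles of the candidate A-scan positions so every knot interval
#' contains data and the fit stays well-posed even with a wide gap.
#'
#' @param candidates an [rpe_candidates] object (or a data frame with
#'   `ascan` and `row` columns).
#' @param order spline (polynomial) order, 2 or 3; default chosen from the
#'   segment count via [choose_spline_order()].
#' @param n_knots number of interior knots (default 5).
#' @param width number of A-scans to evaluate (defaults to the candidate
#'   object's width).
#' @param order_rule passed to [choose_spline_order()] when `order` is NULL.
#' @return A list with `trace` (a full-width, all-valid [layer_trace]) and
#'   `fit` (class `spline_fit`: `order`, `knots`, `coefficients`, `rss`).
#' @export
fit_rpe_spline <- function(candidates, order = NULL, n_knots = 5L,
                           width = NULL, order_rule = "gap_low_order") {
  pts <- if (inherits(candidates, "rpe_candidates")) candidates$points else candidates
  width <- width %||% candidates$n_ascans
  if (is.null(order)) {
    order <- choose_spline_order(candidates$n_segments, rule = order_rule)
  }
  if (!order %in% c(2L, 3L)) {
    onh_error("onhquant_parameter_error", "spline order must be 2 or 3")
  }
  x <- pts$ascan; y <- pts$row
  n_knots <- as.integer(n_knots)
  if (length(x) < order + n_knots + 1L) {
    onh_error("onhquant_segmentation_error",
              sprintf("only %d candidate points for a fit needing at least %d",
                      length(x), order + n_knots + 1L))
  }
  knots <- numeric(0)
  if (n_knots > 0L) {
    knots <- stats::quantile(x, probs = seq_len(n_knots) / (n_knots + 1L),
                             type = 7, names = FALSE)
    knots <- unique(knots[knots > 1 & knots < width])
  }
  bknots <- c(1, width)
  X <- splines::bs(x, knots = knots, degree = order, intercept = TRUE,
                   Boundary.knots = bknots)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    onh_error("onhquant_segmentation_error",
              "underdetermined RPE spline fit (rank-deficient basis)")
  }
  rss <- sum(fit$residuals^2)
  Xa <- splines::bs(seq_len(width), knots = knots, degree = order,
                    intercept = TRUE, Boundary.knots = bknots)
  rows <- as.numeric(Xa %*% fit$coefficients)
  list(
    trace = layer_trace(rows, valid = rep(TRUE, width)),
    fit = structure(list(order = order, knots = knots,
                         coefficients = fit$coefficients, rss = rss,
                         boundary_knots = bknots),
                    class = "spline_fit")
  )
}

#' Segment a whole OCT volume
#'
#' Runs denoising, ILM detection (or uses supplied ILM traces), upper-layer
#' masking, RPE candidate selection and RPE spline fitting on every B-scan.
#' B-scans where segmentation fails are flagged, not fatal.
#'
#' @param volume an [oct_volume].
#' @param config resolved configuration list from [onh_config()].
#' @param ilm optional list of precomputed ILM [layer_trace]s (one per
#'   B-scan), e.g. from [load_ilm_csv()].
#' @return An object of class `volume_segmentation` with per-B-scan `ilm`
#'   and `rpe` traces, `fits`, `n_segments` and logical `flags`.
#' @export
segment_volume <- function(volume, config = onh_config(), ilm = NULL) {
  stopifnot(inherits(volume, "oct_volume"))
  config <- resolve_config(config)
  dn <- denoise_params(config[["preprocess.median_window"]],
                       config[["preprocess.gaussian_sigma"]],
                       config[["preprocess.stages"]])
  nb <- volume$n_bscans
  ilms <- vector("list", nb); rpes <- vector("list", nb)
  fits <- vector("list", nb); nseg <- rep(NA_integer_, nb)
  flags <- rep(FALSE, nb); notes <- rep("", nb)
  for (b in seq_len(nb)) {
    res <- tryCatch({
      img <- denoise_bscan(volume$bscans[[b]], dn)
      tr_ilm <- if (!is.null(ilm)) ilm[[b]] else {
        segment_ilm(img, config[["segmentation.ilm_threshold"]],
                    config[["segmentation.ilm_smooth_px"]])
      }
      masked <- mask_upper_layers(img, tr_ilm, config[["segmentation.mask_offset_px"]])
      cand <- detect_rpe_candidates(
        masked,
        n_per_ascan = config[["segmentation.n_per_ascan"]],
        band_halfwidth = config[["segmentation.band_halfwidth"]],
        gap_min = config[["segmentation.gap_min"]],
        floor_rel = config[["segmentation.intensity_floor_rel"]]
      )
      sp <- fit_rpe_spline(cand, n_knots = config[["segmentation.n_knots"]],
                           width = volume$n_ascans,
                           order_rule = config[["segmentation.order_rule"]])
      list(ilm = tr_ilm, rpe = sp$trace, fit = sp$fit, nseg = cand$n_segments)
    }, onhquant_segmentation_error = function(e) e)
    if (inherits(res, "error")) {
      flags[b] <- TRUE; notes[b] <- conditionMessage(res)
    } else {
      ilms[[b]] <- res$ilm; rpes[[b]] <- res$rpe
      fits[[b]] <- res$fit; nseg[b] <- res$nseg
    }
  }
  structure(list(ilm = ilms, rpe = rpes, fits = fits, n_segments = nseg,
                 flags = flags, flag_notes = notes,
                 n_bscans = nb, n_ascans = volume$n_ascans,
                 n_depth = volume$n_depth),
            class = "volume_segmentation")
}

#' @export
print.volume_segmentation <- function(x, ...) {
  cat(sprintf("<volume_segmentation> %d B-scans, %d flagged\n",
              x$n_bscans, sum(x$flags)))
  invisible(x)
}
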