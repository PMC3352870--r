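# Render a single bright band into an image. `peaked = TRUE` gives the band
# a Gaussian cross-section so each column has a unique brightest pixel at
# the band center; otherwise the band is flat-topped with fractional edge
# coverage.
band_image <- function(nd, na, center_rows, halfwidth = 2, intensity = 1,
                       background = 0, peaked = FALSE) {
  img <- matrix(background, nd, na)
  r <- seq_len(nd)
  for (a in seq_len(na)) {
    cov <- if (peaked) {
      exp(-(r - center_rows[a])^2 / (2 * (halfwidth / 2)^2))
    } else {
      pmin(pmax(r - (center_rows[a] - halfwidth) + 0.5, 0), 1) -
        pmin(pmax(r - (center_rows[a] + halfwidth) + 0.5, 0), 1)
    }
    img[, a] <- background + (intensity - background) * cov
  }
  img
}

test_that("ILM detection recovers a noise-free phantom surface within 1 row", {
  ph <- make_phantom(small_spec(noise = "none"))
  b <- ceiling(ph$volume$n_bscans / 2)
  tr <- segment_ilm(ph$volume$bscans[[b]])
  expect_true(all(tr$valid))
  expect_lt(max(abs(tr$rows - ph$truth$ilm_surface[b, ])), 1.0)
})

test_that("an all-zero B-scan yields an all-invalid ILM trace", {
  tr <- segment_ilm(matrix(0, 64, 32))
  expect_false(any(tr$valid))
})

test_that("ILM error stays small under default speckle noise", {
  ph <- make_phantom(small_spec(seed = 5))
  cfg <- onh_config()
  errs <- sapply(c(1, 8, 15), function(b) {
    img <- denoise_bscan(ph$volume$bscans[[b]])
    tr <- segment_ilm(img)
    mean(abs(tr$rows[tr$valid] - ph$truth$ilm_surface[b, tr$valid]))
  })
  expect_lt(max(errs), 2.0)
})

test_that("masking removes the upper of two bands and can be a no-op", {
  nd <- 100L; na <- 40L
  upper <- band_image(nd, na, rep(30, na))
  lower <- band_image(nd, na, rep(70, na))
  img <- pmax(upper, lower)
  ilm <- layer_trace(rep(30, na))
  out <- mask_upper_layers(img, ilm, offset_px = 20)  # cut at row 50
  expect_equal(max(out[1:45, ]), 0)
  expect_identical(out[55:nd, ], img[55:nd, ])
  # cut below the image: identity
  expect_identical(mask_upper_layers(img, ilm, offset_px = nd), img)
  # mostly-invalid ILM is a segmentation error
  bad <- layer_trace(c(rep(30, 10), rep(NA_real_, na - 10)))
  expect_error(mask_upper_layers(img, bad, 20),
               class = "onhquant_segmentation_error")
})

test_that("after masking, the brightest pixel per column tracks the true RPE", {
  ph <- make_phantom(small_spec(noise = "none"))
  b <- ceiling(ph$volume$n_bscans / 2)
  img <- denoise_bscan(ph$volume$bscans[[b]])
  tr <- segment_ilm(img)
  masked <- mask_upper_layers(img, tr, 30)
  gap <- onhquant:::phantom_surfaces(ph$truth$spec)$gap[b, ]
  peak <- apply(masked[, !gap], 2, which.max)
  err <- abs(peak - ph$truth$rpe_surface[b, !gap])
  expect_gte(mean(err <= 2), 0.95)
})

test_that("candidate detection finds one full-width segment on a smooth band", {
  na <- 200L
  center <- 80 + 20 * ((seq_len(na) - 100) / 100)^2  # gentle parabola
  img <- band_image(150L, na, center, peaked = TRUE)
  cand <- detect_rpe_candidates(img)
  expect_equal(cand$n_segments, 1L)
  expect_equal(nrow(cand$points), na)
  expect_lt(max(abs(cand$points$row - center[cand$points$ascan])), 1.0)
})

test_that("a 60-column dark gap splits the candidates into two segments", {
  na <- 200L
  center <- rep(80, na)
  img <- band_image(150L, na, center, peaked = TRUE)
  img[, 71:130] <- 0
  cand <- detect_rpe_candidates(img)
  expect_equal(cand$n_segments, 2L)
})

test_that("most candidates stay near the true RPE under speckle noise", {
  ph <- make_phantom(small_spec(seed = 9))
  b <- ceiling(ph$volume$n_bscans / 2)
  img <- denoise_bscan(ph$volume$bscans[[b]])
  masked <- mask_upper_layers(img, segment_ilm(img), 30)
  cand <- detect_rpe_candidates(masked)
  gap <- onhquant:::phantom_surfaces(ph$truth$spec)$gap[b, ]
  keep <- !gap[cand$points$ascan]
  err <- abs(cand$points$row[keep] - ph$truth$rpe_surface[b, cand$points$ascan[keep]])
  expect_gte(mean(err <= 3), 0.90)
})

test_that("widening the propagation band never loses candidates", {
  ph <- make_phantom(small_spec(seed = 13))
  for (b in c(3L, 8L)) {
    img <- denoise_bscan(ph$volume$bscans[[b]])
    masked <- mask_upper_layers(img, segment_ilm(img), 30)
    counts <- sapply(c(5, 10, 15, 25, 40), function(hw) {
      nrow(detect_rpe_candidates(masked, band_halfwidth = hw)$points)
    })
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("spline order follows the segment count and rejects zero segments", {
  expect_identical(choose_spline_order(1), 3L)
  expect_identical(choose_spline_order(2), 2L)
  expect_identical(choose_spline_order(5), 2L)
  expect_identical(choose_spline_order(2, rule = "gap_high_order"), 3L)
  expect_error(choose_spline_order(0), class = "onhquant_segmentation_error")
  # purity
  expect_identical(choose_spline_order(2), choose_spline_order(2))
})

test_that("an exact parabola is reproduced by an order-2 spline fit", {
  x <- seq_len(200)
  y <- 100 + 0.002 * (x - 100)^2
  cand <- data.frame(ascan = x, row = y)
  res <- fit_rpe_spline(cand, order = 2, n_knots = 0, width = 200L)
  expect_lte(res$fit$rss, 1e-8)
  expect_lt(max(abs(res$trace$rows - y)), 1e-6)
})

test_that("the spline bridges a removed central half of a parabola", {
  x <- seq_len(200)
  y <- 100 + 0.002 * (x - 100)^2
  keep <- x <= 50 | x > 150
  cand <- structure(list(points = data.frame(ascan = x[keep], row = y[keep]),
                         n_segments = 2L, n_ascans = 200L),
                    class = "rpe_candidates")
  res <- fit_rpe_spline(cand)  # defaults: order from segments (2), 5 knots
  expect_lt(max(abs(res$trace$rows[!keep] - y[!keep])), 0.5)
})

test_that("gap extrapolation stays accurate under candidate noise", {
  x <- seq_len(200)
  y <- 100 + 0.002 * (x - 100)^2
  keep <- x <= 50 | x > 150
  set.seed(21)
  rmse <- sapply(1:20, function(s) {
    cand <- structure(list(
      points = data.frame(ascan = x[keep], row = y[keep] + rnorm(sum(keep), 0, 2)),
      n_segments = 2L, n_ascans = 200L), class = "rpe_candidates")
    res <- fit_rpe_spline(cand)
    sqrt(mean((res$trace$rows[!keep] - y[!keep])^2))
  })
  expect_lte(mean(rmse), 4)
})

test_that("underdetermined fits raise a segmentation error", {
  cand <- data.frame(ascan = c(1, 50, 100), row = c(10, 12, 11))
  expect_error(fit_rpe_spline(cand, order = 3, n_knots = 5, width = 100L),
               class = "onhquant_segmentation_error")
})

test_that("fitted RPE matches the true surface on a noise-free gap phantom", {
  ph <- make_phantom(small_spec(noise = "none"))
  for (b in c(3L, ceiling(ph$volume$n_bscans / 2))) {
    img <- denoise_bscan(ph$volume$bscans[[b]])
    masked <- mask_upper_layers(img, segment_ilm(img), 30)
    cand <- detect_rpe_candidates(masked)
    res <- fit_rpe_spline(cand, width = ph$volume$n_ascans)
    err <- abs(res$trace$rows - ph$truth$rpe_surface[b, ])
    expect_gte(mean(err <= 1.0), 0.95)
  }
})

test_that("segment_volume flags unsegmentable B-scans instead of failing", {
  ph <- make_phantom(small_spec(noise = "none"))
  vol <- ph$volume
  vol$bscans[[2]] <- matrix(0, vol$n_depth, vol$n_ascans)  # dead B-scan
  seg <- segment_volume(vol)
  expect_true(seg$flags[2])
  expect_false(any(seg$flags[-2]))
})
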