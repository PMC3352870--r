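test_that("flattening constant and tilted parallel surfaces gives exact heights", {
  n <- 50L
  fl <- flatten_bscan(layer_trace(rep(50, n)), layer_trace(rep(150, n)))
  expect_equal(fl$ilm_height, rep(100, n))
  expect_equal(fl$shift_applied, rep(0, n))

  tilt <- 100 + 0.5 * seq_len(n)
  fl2 <- flatten_bscan(layer_trace(tilt - 37), layer_trace(tilt))
  expect_equal(fl2$ilm_height, rep(37, n))
  # flattened RPE deviates from the reference row by construction 0
  expect_equal(tilt - fl2$shift_applied, rep(fl2$rpe_row, n))
})

test_that("swelling amplitude survives the flatten step on phantom traces", {
  A <- 30
  ph <- make_phantom(small_spec(swell_amplitude_px = A, noise = "none"))
  b <- ceiling(ph$volume$n_bscans / 2)
  img <- denoise_bscan(ph$volume$bscans[[b]])
  ilm <- segment_ilm(img)
  masked <- mask_upper_layers(img, ilm, 30)
  rpe <- fit_rpe_spline(detect_rpe_candidates(masked),
                        width = ph$volume$n_ascans)$trace
  fl <- flatten_bscan(ilm, rpe)
  baseline <- reference_height(fl, 0.10)
  expect_lt(abs((max(fl$ilm_height) - baseline) - A), 1.5)
})

test_that("reference height pools the two edge margins", {
  h <- c(rep(80, 10), rep(0, 80), rep(120, 10))
  fl <- structure(list(ilm_height = h), class = "flattened_bscan")
  expect_equal(reference_height(fl, 0.10), 100)
  expect_equal(reference_height(structure(list(ilm_height = rep(55, 40)),
                                          class = "flattened_bscan"), 0.1), 55)
})

test_that("edema area matches closed forms and a trapezoid oracle", {
  p <- quantify_params(threshold_px = 0)
  # everything at or below the baseline: zero area
  fl <- structure(list(ilm_height = rep(100, 200)), class = "flattened_bscan")
  expect_equal(edema_area(fl, p, 15, 4, reference = 150), 0)
  # rectangular bump of 40 px over 100 A-scans:
  # 40 * 100 * 15 * 4 = 240000 um^2 = 0.24 mm^2
  h <- c(rep(100, 50), rep(140, 100), rep(100, 50))
  flr <- structure(list(ilm_height = h), class = "flattened_bscan")
  expect_equal(edema_area(flr, p, 15, 4, reference = 100), 0.24)
  # Gaussian profile vs numeric integration of its positive part
  a <- seq_len(400)
  prof <- 100 + 60 * exp(-((a - 200)^2) / (2 * 50^2))
  flg <- structure(list(ilm_height = prof), class = "flattened_bscan")
  got <- edema_area(flg, p, 15, 4, reference = 100)
  dense <- seq(0.5, 400.5, by = 0.01)
  oracle <- sum(pmax(0, 60 * exp(-((dense - 200)^2) / (2 * 50^2)))) * 0.01 * 15 * 4 * 1e-6
  expect_lt(abs(got - oracle) / oracle, 0.005)
})

test_that("volume integration is exact arithmetic and additive in spacing", {
  expect_equal(onh_volume(c(1, 2, 3), 100), 0.6)
  expect_equal(onh_volume(numeric(5), 100), 0)
  areas <- c(0.3, 0.1, 0.7)
  expect_equal(onh_volume(areas, 200), 2 * onh_volume(areas, 100))
  expect_error(onh_volume(c(1, -1), 100), class = "onhquant_parameter_error")
})

test_that("increasing the threshold never decreases the edema area", {
  a <- seq_len(300)
  prof <- 90 + 50 * exp(-((a - 150)^2) / (2 * 40^2))
  fl <- structure(list(ilm_height = prof), class = "flattened_bscan")
  areas <- sapply(c(0, 5, 10, 20, 40), function(thr) {
    edema_area(fl, quantify_params(threshold_px = thr), 15, 4)
  })
  expect_true(all(diff(areas) >= 0))
})

test_that("ONH height is max trace separation in mm and flatten-invariant", {
  n <- 60L
  ilm <- layer_trace(150 - 100 - 20 * exp(-((seq_len(n) - 30)^2) / 50) + 0.3 * seq_len(n))
  rpe <- layer_trace(rep(150, n) + 0.3 * seq_len(n))
  expect_equal(onh_height(list(rpe$rows - ilm$rows), 4), max(rpe$rows - ilm$rows) * 4e-3)
  # flat retina: 100 px at 4 um = 0.4 mm
  expect_equal(onh_height(list(rep(100, n)), 4), 0.4)
  # flattening does not change heights
  fl <- flatten_bscan(ilm, rpe)
  expect_equal(max(fl$ilm_height), max(rpe$rows - ilm$rows))
})

test_that("zero-amplitude phantoms reduce to the flat-retina closed form", {
  sp <- small_spec(swell_amplitude_px = 0, noise = "none")
  rep <- quantify_onh(make_phantom(sp)$volume)
  flat_mm3 <- 20 * sp$n_ascans * sp$n_bscans *
    sp$axial_spacing_um * sp$lateral_spacing_um * sp$bscan_spacing_um * 1e-9
  expect_lt(abs(rep$onhv_mm3 - flat_mm3) / flat_mm3, 0.02)
  expect_lt(abs(rep$onhh_mm - sp$retina_thickness_px * sp$axial_spacing_um * 1e-3),
            1.5 * sp$axial_spacing_um * 1e-3)
})

test_that("quantify_volume flags propagate and excessive flags are fatal", {
  ph <- make_phantom(small_spec(noise = "none"))
  seg <- segment_volume(ph$volume)
  # flag a quarter of the B-scans -> quantification error
  seg_bad <- seg
  seg_bad$flags[seq_len(ceiling(0.25 * ph$volume$n_bscans))] <- TRUE
  expect_error(quantify_volume(ph$volume, seg_bad),
               class = "onhquant_quantification_error")
  # a single flagged B-scan contributes zero area
  seg1 <- seg
  seg1$flags[4] <- TRUE
  rep1 <- quantify_volume(ph$volume, seg1)
  expect_equal(rep1$area_profile_mm2[4], 0)
  expect_true(rep1$per_bscan_flags[4])
})

test_that("ONHV is strictly monotone in swelling amplitude at zero noise", {
  vols <- sapply(c(0, 20, 45, 80), function(A) {
    quantify_onh(make_phantom(small_spec(swell_amplitude_px = A,
                                         noise = "none"))$volume)$onhv_mm3
  })
  expect_true(all(diff(vols) > 0))
})
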