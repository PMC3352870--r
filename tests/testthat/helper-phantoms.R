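# Reduced phantom grids used throughout the tests. The geometry keeps the
# physical field of the full acquisition protocol (15 degrees laterally,
# ~4.4 mm across B-scans) while cutting the B-scan count and axial depth so
# a full-volume pipeline run takes about a second.

# Full-width grid: needed whenever swelling sigma is large (up to 60 lateral
# px), so the 10% reference margins stay far from the swelling.
accept_spec <- function(...) {
  defaults <- list(n_bscans = 29L, n_ascans = 384L, n_depth = 320L,
                   bscan_spacing_um = 150, rpe_center_row = 220)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# Small grid for unit tests with modest swellings.
small_spec <- function(...) {
  defaults <- list(n_bscans = 15L, n_ascans = 256L, n_depth = 256L,
                   bscan_spacing_um = 290, rpe_center_row = 180,
                   swell_sigma_px = 25, disc_radius_px = 30,
                   retina_thickness_px = 80)
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# Ground-truth surfaces as layer_trace objects for one B-scan.
truth_traces <- function(truth, b) {
  list(ilm = layer_trace(truth$ilm_surface[b, ]),
       rpe = layer_trace(truth$rpe_surface[b, ]))
}
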