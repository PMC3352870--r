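---
title: "Quantifying optic nerve head volume from 3D SDOCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying optic nerve head volume from 3D SDOCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Papilledema — optic disc swelling from raised intracranial pressure — is
classically graded from fundus photographs, a coarse ordinal scale.
Spectral-domain OCT images the swollen optic nerve head (ONH) in 3D, but the
standard device outputs (peripapillary RNFL thickness from a ring scan) use a
fixed-diameter circle that largely misses the swelling itself. `onhquant`
computes two volumetric outcome measures directly from the raw B-scan stack:

* **ONHV** (mm³): the volume of tissue enclosed between the inner limiting
  membrane (ILM) and a baseline plane derived from a hypothetical extension
  of the retinal pigment epithelium (RPE) through the disc;
* **ONHH** (mm): the maximum ILM elevation above that RPE reference surface.

The central difficulty is that the RPE — the natural outer reference — is
absent at the disc itself and often obscured by the edema, so its
peripapillary course has to be extrapolated *through* the ONH.

## The pipeline

Each B-scan passes through five stages:

1. **Denoising.** A median filter (window 3 px) suppresses speckle impulses,
   then Gaussian smoothing (σ = 1.5 px) stabilizes gradients. Both stages
   use reflect padding so the borders do not acquire artificial dark
   gradients that would mimic layer boundaries. A constant image is a fixed
   point of both filters, and both are convex/selection operators, so the
   [0, 1] intensity range is preserved.
2. **ILM detection.** Per A-scan, the first crossing of a 0.25 intensity
   threshold from the vitreous side, after a 3-px running mean along depth;
   the crossing is refined to sub-pixel precision by linear interpolation
   between the straddling pixels. This is a deliberate stand-in for the
   device's own ILM segmentation, which can be supplied instead as a CSV of
   traces (`load_ilm_csv()`).
3. **Upper-layer suppression.** All pixels above `ILM + 30 px` are zeroed,
   removing the bright nerve-fiber-layer band so that the brightest
   remaining pixels per column belong, with high probability, to the RPE.
   Columns whose cut would fall below the image are left untouched (the
   degenerate limit of the operation).
4. **RPE candidates and spline.** The three brightest pixels per column are
   provisional candidates. The A-scans at 25% and 75% of the width act as
   anchors: a search band (half-width 15 px) propagates column-to-column
   from each anchor toward its edge and toward the center, accepting per
   column the brightest in-band candidate above an intensity floor (50% of
   the mean anchor brightness) and re-centering on it. At the disc, where
   the RPE is absent, columns fall below the floor and produce a gap;
   maximal runs separated by more than 20 empty columns form *segments*.
   A least-squares B-spline is then fit to the accepted candidates and
   evaluated at every A-scan — including across the gap. That evaluation is
   the hypothetical RPE extension through the ONH.
5. **Flattening and integration.** Heights are taken directly from the
   traces (`height = RPE − ILM`, sub-pixel), which makes flattening a pure
   bookkeeping step: no image resampling, hence no interpolation bias. The
   peripheral reference height is the pooled mean height over the leftmost
   and rightmost 10% of A-scans; the baseline plane sits 20 px below it;
   each B-scan contributes the area of ILM height above the baseline, and
   areas integrate over the inter-B-scan spacing into ONHV. ONHH is the
   maximum height times the axial pixel pitch.

Because the baseline is *measured* from the same flattened heights, any
constant detection bias in the ILM (the threshold crossing sits slightly
vitreal of the true interface) cancels out of ONHV exactly; only spatially
varying errors survive, and those average out over ~10⁵ A-scans.

## Parameters that matter

| key | default | units | role |
|---|---|---|---|
| `preprocess.median_window` | 3 | px | speckle impulse suppression |
| `preprocess.gaussian_sigma` | 1.5 | px | gradient stabilization |
| `segmentation.ilm_threshold` | 0.25 | — | ILM crossing level on [0,1] intensities |
| `segmentation.mask_offset_px` | 30 | px | cut below ILM; must clear the RNFL band but stay above the RPE |
| `segmentation.band_halfwidth` | 15 | px | candidate propagation band |
| `segmentation.gap_min` | 20 | columns | minimum gap splitting RPE segments |
| `segmentation.intensity_floor_rel` | 0.5 | — | candidate floor relative to anchor brightness; creates the disc gap |
| `segmentation.n_knots` | 5 | — | interior spline knots |
| `quantify.threshold_px` | 20 | axial px | offset of the baseline plane below the reference |
| `quantify.margin_frac` | 0.10 | — | edge fraction per side for the reference height |

The 20-px threshold is kept in native axial pixels on purpose: it is an
operating parameter of the method, and converting it to micrometres would
silently change the measurement when the axial pitch differs.

## Design choices made where the design was open

* **Spline order rule.** The spline order depends on the number of detected
  RPE segments; the direction of that dependence was an open choice. The
  default maps a disc gap (≥ 2 segments) to order 2 and a single segment to
  order 3: extrapolating across a gap is more stable at lower polynomial
  order, while an uninterrupted RPE can afford order 3 to follow the full
  retinal curvature. We verified on gap phantoms that order 2 gives the
  lower extrapolation error before freezing the rule; the opposite mapping
  remains selectable (`segmentation.order_rule = "gap_high_order"`).
* **Knot placement.** Interior knots sit at uniform *quantiles* of the
  candidate A-scan positions rather than uniformly across the width. With
  uniform knots, a wide disc gap can swallow the entire support of an
  interior basis function, making the least-squares problem singular;
  quantile knots guarantee every knot interval contains data. Since any
  global quadratic lies in the span of a degree-2 spline space regardless of
  knots, this choice does not reduce the space needed for the RPE bowl.
* **Threshold side.** The baseline plane lies *below* the peripheral
  reference (toward the RPE). This yields a strictly positive pedestal
  volume in normal eyes — consistent with a threshold "selected to include
  most of the ONH" and with non-zero control volumes — and makes ONHV
  monotone in swelling amplitude. The opposite convention is available via
  `quantify.threshold_sign`.
* **Reference window.** "Left and right side" is made concrete as a pooled
  mean over 10% edge margins per side: for a 15° scan these margins sit
  outside the disc in all but pathologically wide swellings.
* **Per-B-scan independence.** One spline is fit per B-scan with no
  regularization across B-scans; whether the original design shared
  information across slices is unknown, and independence keeps failures
  local (a B-scan that cannot be segmented is flagged and contributes zero
  area; more than 20% flagged B-scans invalidate the volume).

## The phantom: what it emulates, and what it does not

`phantom_spec()` describes a synthetic eye: a quadratic-bowl resting RPE, a
retina of constant thickness, a radially symmetric Gaussian swelling of the
ILM centered on the disc, a circular RPE gap (the disc), bright RNFL and RPE
bands rendered with one-pixel anti-aliased edges, unit-mean multiplicative
gamma speckle (shape 4) and additive Gaussian read noise (σ = 0.02). The
default grid mirrors the acquisition protocol the pipeline targets: 145
B-scans × 384 A-scans over a 15°×15° field, 496 depth pixels at ~3.9 µm.

Because the ILM elevation field is an analytic sum of Gaussians,
`analytic_truth()` gives the exact ONHV implied by the pipeline's own
baseline rule in closed form: the flat pedestal, truncated Gaussian
integrals over the rectangular field (via the normal CDF), and the mean
Gaussian tail that contaminates the reference margins. The closed form is
valid as long as the contamination does not exceed the threshold (otherwise
the positive-part integrand would clip and an error is raised); an internal
dense-grid integrator validates it to 0.1% in the tests.

What the phantom does **not** emulate: vascular shadowing, motion artifacts
between B-scans, asymmetric or multi-lobed edema, a physiological optic cup,
intensity roll-off with depth, or segmentation-hostile pathology (peripapillary
atrophy, drusen). Passing the phantom suite therefore demonstrates the
geometry, calibration and statistics of the method — not robustness to every
clinical artifact. Reliability and discrimination numbers obtained on
phantom cohorts characterize the algorithm under the phantom's noise model,
not any patient population.

## Numerical choices

* Heights, traces and shifts are kept in floating point throughout;
  flattening never resamples images.
* Candidate ties (equal brightness) resolve to the smaller row (more
  superficial) for determinism.
* The Mann-Whitney AUC is evaluated from the smaller tail of the rank-sum
  so that swapping the group labels returns exactly `1 − AUC` in floating
  point.
* The ICC is the single-measure *consistency* form from the two-way model
  with random subjects and fixed sessions, `(MS_S − MS_E) / (MS_S + (k−1)
  MS_E)`; sessions here are exchangeable repeats on one device, which is
  the situation the consistency form describes. Absolute-agreement variants
  are deliberately not implemented.
* Percentiles use linear interpolation between closest ranks (base R
  type 7), fixed for cross-implementation determinism.
* The main pipeline contains no randomness: identical volumes and resolved
  configurations produce byte-identical reports.

## Problem sizes used by the test and acceptance runs

The validation suites run phantoms at 29 B-scans × 384 A-scans × 320 depth
px with a 150 µm inter-B-scan spacing (and a 15 × 256 × 256 grid for unit
tests). The full lateral width is retained because the reference margins and
the widest test swellings (σ = 60 lateral px) must keep the same geometric
relationship as on the full protocol grid; the B-scan count and depth carry
no such constraint and are reduced proportionally, keeping the physical
field extent. One full-volume pipeline run then takes about one second.

## Worked example

```{r}
library(onhquant)

# a patient-like phantom: 60 px (~230 um) peak swelling
sp <- phantom_spec(swell_amplitude_px = 60, swell_sigma_px = 40, seed = 7)
ph <- make_phantom(sp)
report <- quantify_onh(ph$volume)
report
analytic_truth(sp, threshold_px = 20, margin_frac = 0.10)$true_onhv_mm3
```

## Known limitations

* The ILM stand-in is a threshold crossing; on low-contrast or shadowed
  scans the device segmentation (supplied via CSV) should be preferred.
* The closed-form truth requires a radially symmetric swelling; asymmetric
  phantoms would need the numeric integrator.
* Clinical normative values (cutoffs in mm³) depend on device, protocol and
  population; the `normative_percentile()` machinery computes cutoffs from
  whatever control sample it is given and makes no population claim.
* Marginal regression against intracranial pressure (GEE with the
  `lp_weight()` weighting) is out of scope; the per-eye tables exported by
  `cmd_cohort()` carry the clustering identifiers needed to fit such models
  in a statistics environment.
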