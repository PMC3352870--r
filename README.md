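# onhquant

Automatic quantification of optic nerve head (ONH) swelling from 3D
spectral-domain OCT volume scans, in R.

Papilledema — disc swelling from raised intracranial pressure, as in
idiopathic intracranial hypertension — is usually graded from fundus photos
or from peripapillary RNFL thickness, a 2D ring-scan measure that misses
most of the swollen tissue. `onhquant` implements a fully automatic 3D
alternative: from an ordered stack of B-scans it measures

* **ONHV**, the ONH volume in mm³, and
* **ONHH**, the maximum ONH height in mm.

## Method

On each B-scan the algorithm (i) denoises (median + Gaussian, reflect
padding), (ii) detects the inner limiting membrane (ILM) as the first
suprathreshold crossing per A-scan — or accepts device-exported ILM traces —
(iii) masks everything above `ILM + 30 px` so the brightest remaining pixels
belong to the retinal pigment epithelium (RPE), (iv) selects RPE candidate
pixels with a search band seeded at the quarter-width A-scans, and fits a
least-squares B-spline (order 2 with a disc gap, order 3 without) that
extends the peripapillary RPE *through* the ONH, then (v) flattens the
B-scan on that surface. With per-A-scan heights `h(a) = RPE(a) − ILM(a)`,
the peripheral reference `r` (pooled mean of `h` over the 10% edge margins)
and the pixel threshold `t = 20`, each B-scan contributes the edema area

```
area = Σ_a max(0, h(a) − (r − t)) · lateral_spacing · axial_spacing
```

and `ONHV = Σ_b area_b · bscan_spacing`, `ONHH = max h · axial_spacing`.

The package also ships

* a **phantom generator** (`make_phantom()`): layered synthetic ONH volumes
  with a parameterized Gaussian swelling, gamma speckle, and closed-form
  ground-truth ONHV/ONHH (`analytic_truth()`) — the test substrate for the
  whole pipeline;
* the **evaluation statistics**: two-way mixed-effects consistency ICC
  (`icc_two_way_mixed()`), rank-based ROC AUC (`mann_whitney_auc()`),
  normative percentile cutoffs (`normative_percentile()`), and the
  measurement-distance weight `lp_weight(d) = 100 / (d + 1)`;
* readers/writers for multi-page TIFF stacks and raw volumes with JSON
  sidecars, JSON/CSV reports, and a CLI (`exec/onhquant`) with `phantom`,
  `quantify`, `cohort` and `stats` subcommands.

## Worked example

```r
library(onhquant)

# a patient-like phantom: 60 px (~230 um) peak swelling over a 40-px-sigma
# Gaussian, default acquisition grid (145 x 384 x 496) with speckle noise
sp <- phantom_spec(swell_amplitude_px = 60, swell_sigma_px = 40, seed = 7)
ph <- make_phantom(sp)

report <- quantify_onh(ph$volume)
report
#> <onh_report>
#>   ONHV: 2.4334 mm^3
#>   ONHH: 0.6246 mm
#>   145 B-scans (0 flagged), threshold 20 px

analytic_truth(sp, threshold_px = 20, margin_frac = 0.10)$true_onhv_mm3
#> [1] 2.483173
ph$truth$true_onhh_mm
#> [1] 0.624
```

The measured volume (2.43 mm³) sits within 2% of the closed-form truth
(2.48 mm³) under full speckle noise, and the measured maximum height is
within a fifth of an axial pixel of the true 0.624 mm. Values of this
magnitude are what moderate papilledema produces; a flat control retina
yields the positive "pedestal" volume implied by the 20-px threshold.

`save_report(report, "report.json")` round-trips all numbers at full
precision; `cmd_quantify("scan.tif", "out/")` does the same from a file and
also writes a per-B-scan CSV and the fully resolved configuration.

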