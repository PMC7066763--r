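---
title: "Quantitative CMR post-processing: models, estimators and phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CMR post-processing: models, estimators and phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrquant)
```

`cmrquant` implements the standardized quantitative measurements of a
cardiovascular-MR reading workflow on explicit, declared conventions.
This vignette is the package's own account of those conventions: the
models and their assumptions, the tunable parameters and why their
defaults are what they are, what the synthetic phantoms do and do not
emulate, and the numerical choices a maintainer would want written down.
It states no empirical result that the test suite and acceptance script
do not themselves compute.

## Coordinate and statistical conventions

Stated once, used everywhere:

- Distances are millimeters; the origin is the image corner; `x` runs
  along columns, `y` along rows; pixels are half-open unit boxes, so the
  1-based array element `[i, j]` has its center at
  `((j - 0.5)·sx, (i - 0.5)·sy)`.
- A pixel belongs to an ROI iff its **center** is inside the polygon under
  the even-odd rule. This is reproducible and orientation-free, which
  matters more than sub-pixel accuracy for clinical ROI statistics.
- All standard deviations are sample (n − 1) SDs, matching common
  clinical analysis software.
- Contours are closed polygons, canonicalized to counterclockwise
  orientation at construction; self-intersection is rejected.

## Ventricular volumetry

Simpson (summation-of-discs) volume is `Σ areaᵢ · (thickness + gap)` over
included slices. Every slice — including the last — contributes the full
`thickness + gap`: a literal reading of the standard mass formula.
Reference ranges are convention-specific, so this and the papillary mode
are echoed in every result.

- **ED/ES selection** picks one global phase each (argmax/argmin of the
  summed endocardial volume); ties go to the earlier phase for
  determinism.
- **Papillary muscles** default to the blood pool
  (`papillary_mode = "in_blood_pool"`), the common clinical convention;
  `"in_mass"` moves the planimetered papillary polygons from cavity to
  myocardium, so volume drops and mass rises by exactly 1.05 × the
  papillary volume — an identity the tests assert.
- **Basal descent** is deliberately kept out of the integral: volumetry
  consumes explicit per-slice inclusion flags, and a separate helper
  (`basal_slice_inclusion`) implements the "≥ 50% of the blood pool
  surrounded by myocardium" heuristic on masks. No single convention for
  the rule is agreed, so it must not be hard-wired into the core sum.
- **Mass-only slices** (epicardial contour without endocardial — basal
  crescent, apical cap) contribute epicardial area only.
- **Area-length** methods (`0.85·A²/L`, `0.85·A₁·A₂/L`) are provided for
  rapid estimates and always tagged with their method name, because a
  report must state the analysis technique when they are used. On a
  perfect prolate spheroid the single-plane estimate reproduces the
  analytic volume to 0.14% (the coefficient identity
  `0.85·π²/2 ≈ 4π/3`).
- The LV/RV stroke-volume consistency check flags a relative difference
  above 10% — a declared default; the underlying guidance says only
  "nearly equal".

## AHA segmentation

Sector boundaries start at the anterior RV insertion point and sweep
toward the inferior insertion point the shorter way around — through the
septum — with sequential ids per tier (basal 1–6, mid 7–12, apical 13–16
in 90° sectors, apex 17). The rotational direction is therefore derived
from the two insertion points rather than fixed as clockwise or
counterclockwise, which makes the assignment orientation-independent.
One consequence worth stating: with six 60° sectors, diametric opposition
always moves a point exactly three sectors, so the sector opposite
mid-anteroseptal is mid-inferolateral (segment 11). The tests verify the
assignment against a brute-force angle table.

## LGE quantification

- **n-SD**: threshold = remote mean + n·SD from an operator-drawn remote
  ROI; n = 5 by default (the recommended starting point for infarction).
  Masks are monotone nonincreasing in n by construction, and on a
  pure-noise myocardium the expected false-positive rate at n = 5 is
  `P(Z > 5) ≈ 2.9e-7` per pixel — the suite checks 0 false pixels over
  100 seeded 10⁴-pixel phantoms.
- **FWHM**: threshold = half the **maximum within the operator-selected
  scar ROI**, not the global myocardial maximum — the literal reading of
  the method. The result is invariant under intensity scaling but not
  under offsets; both properties are tested, because misreading this
  invariance is a common source of irreproducibility.
- **Manual corrections** are set algebra clipped to the myocardium;
  adding masks (no-reflow cores, which count as infarct in acute MI) sets
  the `no_reflow_included` flag.
- **Transmural extent** casts radial chords at 1° steps (quarter-pixel
  sampling); per chord, transmurality = enhanced length / wall length;
  the segment value is the chord mean mapped to the five categories with
  intervals closed on the right, so a mean of exactly 25% falls in
  "1–25%" (a declared tie rule; the category list itself fixes no
  estimator).
- No grey-zone / intermediate-intensity adjustment is implemented: no
  formula for it is established, and guessing one would silently change
  scar fractions.

## Semi-quantitative perfusion

Curves carry one sample per RR interval; missing frames are rejected
rather than interpolated. The named metrics have no canonical estimators,
so the package declares them as configuration:

- **Foot detection**: first frame above baseline mean + 2·SD, sustained
  for two frames; requires ≥ 5 declared baseline frames.
- **Maximal upslope**: maximum least-squares slope in a sliding window
  (default 3 samples) between foot and peak; the normalized variant
  divides by the blood-pool upslope computed identically and records the
  flag. Because the windowed slope is linear in the curve, the
  hypoperfused/normal ratio equals the constructed amplitude ratio
  exactly in the noise-free limit.
- **Time to peak** is referenced to contrast arrival (not series start —
  the ambiguity is real, so the choice is recorded in the output);
  ties resolve to the earliest maximum; a peak on the last frame warns of
  truncation.
- **Upslope integral**: trapezoidal area of the baseline-subtracted curve
  anchored one frame *before* the detected foot. The arrival instant lies
  between the last sub-threshold and first supra-threshold frame;
  dropping that sliver would bias the area low by a systematic ~2%.

## Relaxometry

- **Map ROIs**: conservative septal ROI by convention; ROIs under 20
  pixels are flagged as unreliable; focal fibrosis seen on LGE can be
  excluded via a mask. Results carry the Z-score and the mean ± 2 SD
  normal range of the supplied local reference — reference ranges are
  site- and sequence-specific and are therefore user inputs, never
  built-ins.
- **ECV** is computed as `(ΔR1_myo / ΔR1_blood) × (100 − Hct%)` with
  `ΔR1 = 1/T1_post − 1/T1_native`. The published equation's stacked
  reciprocals omit explicit minus signs (typography); the
  relaxation-rate-difference reading is the standard one and is the only
  physically sensible interpretation, so it is implemented without a
  fallback. The ratio is invariant under a common time-unit rescaling of
  all four T1s (tested).
- **T2\***: `S₀·exp(−TE/T2*)` fitted by nonlinear least squares
  (log-linear start, positivity-bounded). Truncation (`"auto"`) drops the
  latest echo while ≥ 3 points remain and either the refit improves R² by
  more than ε = 0.001 or the dropped sample sits at or below the supplied
  noise floor. The truncation literature names the remedy but no stopping
  rule; this one is declared configuration. Truncation never activates on
  noise-free data (tested). Interpretation flags use the 1.5 T cutoffs —
  normal ≈ 40 ms, < 20 ms iron overload, < 10 ms high risk — as strict
  inequalities; 3 T flagging is refused without an explicit override
  because no validated 3 T cutoffs exist.
- **T2-weighted edema**: myocardium/skeletal-muscle SI ratio, positive at
  ≥ 1.9 (triple-IR spin echo; a local cutoff is preferable and the value
  is configurable), plus an optional pixel map at ratio ≥ 2. The two
  cutoffs are deliberately separate parameters because they come from
  different rules.

## 2D phase-contrast flow

Per-phase flow rate is the ROI sum of signed pixel velocity × pixel area
(ml/s); antegrade/retrograde volumes sum the positive/negative per-phase
flows × frame duration; net, regurgitant fraction, cardiac output/index,
lung split and Qp/Qs follow the standard identities. Additional
conventions:

- Per-phase ROIs are the expected input; copying one ROI to all phases is
  supported but flagged in QC.
- Background phase-offset correction is **never** auto-applied; an
  explicit static-tissue-ROI constant subtraction is available.
- `recenter_venc` shifts the ±VENC window (width preserved) and wraps
  out-of-window pixels by 2·VENC — e.g. a true 175 cm/s stored as
  −125 cm/s at VENC 150 is recovered exactly in a (−100, 200) window.
  Applying the inverse window restores the input (involution, tested).
- Peak velocity is reported under a named convention: `single_pixel`
  (max |v|) or `k_neighborhood` (max of 4-connected neighborhood means,
  robust to isolated noisy pixels). Packages differ here, so the tag is
  part of the result.
- QC warns below 8 pixels across the vessel, below 11 frames per cycle,
  and when |RPA + LPA − MPA|/MPA exceeds 5% — the conservation identity
  is stated in guidance without a tolerance; 5% is a declared default.

## The phantom world

Phantoms are the package's entire test surface; every truth value is
closed-form, never produced by the code under test, and identical specs
(including seed) give bit-identical output.

- **LV**: prolate-spheroid endocardium (defaults a = 40, b = 25 mm — a
  normal-sized adult LV), epicardial contours dilated in-plane by a 10 mm
  wall, shrinking linearly to an exact EF of 60%. Shell volume
  `π²abt + 2πat²` is exact for the in-plane dilation. Contours are
  128-gons (area deficit ≈ 0.04%, far below test tolerances).
- **RV**: annular-sector ("crescent") cross-section scaled along the long
  axis; volume `A₀·4L/3`. The same solid is not re-sliced axially — an
  axial reslicing of a crescent has no tractable closed-form contour set —
  so orientation is metadata, and orientation-equivalence is exercised on
  ellipsoidal geometry instead.
- **Decay series**: `S₀e^(−TE/T2*)` with optional gaussian noise and a
  noise floor applied as `max(signal + noise, floor)`. The floor is
  applied after the noise so samples stay at or above it — the plateau a
  magnitude image actually shows and the input the truncation logic must
  survive. (A literal "clip, then add noise" would produce negative
  samples at realistic SDs.)
- **Perfusion**: flat baseline plus gamma-variate
  `A(t−t₀)^α e^{−(t−t₀)/β}` (α = 2, β = 3 s, peak at baseline + 100 SI),
  blood pool leading by 3 s at 4× amplitude. Pixel noise is emulated by
  averaging `n_pixels` (default 30) iid noisy copies per segment — the
  moral equivalent of sector-mean extraction from a dynamic series, which
  is how the metrics are computed on real data. "SNR 20" in the
  acceptance suite is per-pixel SNR (peak 100, SD 5) under this
  averaging; a raw single-trace SNR of 20 would make any
  max-of-windowed-slopes estimator ratio-biased by construction.
- **Flow**: Poiseuille disc `v(r) = v_max(1 − r²/R²)` (mean velocity
  v_max/2), sin² systolic lobe, optional reverse diastolic lobe, R = 12
  px by default (QC-passing), optional declared aliasing.
- **LGE**: annular myocardium, gaussian remote intensities
  (N(100, 10)), wedge scar of set angular span and transmural depth at
  mean 400; truth mask recorded before noise; scenes whose scar mean is
  within 1 SD of remote are refused as unusable.

What a green test does **not** establish: the phantoms are static (no
motion, no registration errors), have no coil-sensitivity shading, no
partial-volume mixing at boundaries beyond pixel discretization, no
dark-rim or susceptibility artifacts, and gaussian (not Rician) noise
away from the floor. Contour placement — the dominant error source in
practice — is outside the model entirely: contours are inputs.

## Known limitations

- No automatic segmentation; no multi-plane rotational long-axis
  volumetry; no absolute perfusion quantification (deconvolution); no
  peri-infarct grey-zone analysis; no dark-blood LGE handling; no
  synthetic-ECV hematocrit estimation; no 4D flow. These are either
  interactive/visual procedures or methods without an established
  computable specification.
- The CLI covers phantom generation, volumetry, ECV, T2* and report
  rendering; perfusion, LGE and flow are driven through the R API.
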