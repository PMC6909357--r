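---
title: "Methods: automated tracking and motility analysis of 3D chemotaxis assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated tracking and motility analysis of 3D chemotaxis assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(celltrax)
```

`celltrax` quantifies the migration of cells embedded in a 3D collagen gel
from phase-contrast time-lapse stacks. The gel geometry keeps the cells in a
single focal plane, so although the cells migrate in 3D the analysis is a 2D
single-particle tracking problem: detect bright blobs per frame, link them
through time, and reduce the trajectories to speed, directionality and mean
squared displacement. This vignette documents the model behind each stage,
the parameters that matter, the numerical conventions, and what the
synthetic validation does and does not establish.

## Coordinate and calibration conventions

All positions are calibrated: `x = (column - 1) * pixel_size`,
`y = (row - 1) * pixel_size`, origin at the centre of the top-left pixel,
`y` increasing downward, frames 0-based. Pixel size (µm/px) and frame
interval (min) come from `calibration()` and are supplied by the user, never
parsed from image metadata — time-lapse files routinely carry stale or
missing tags, and the imaging workflow this package mirrors assigns the
properties manually. Typical values: 2 min intervals for dendritic cells,
15 min for slow carcinoma cells such as MDA-MB-231.

Stacks are written as multi-page 32-bit-float TIFF with stored value =
intensity / 65535. Any intensity on an 8- or 16-bit scale therefore
round-trips to float32 precision (~6e-8 relative); integer TIFFs from other
software are read back on their native scale. Trajectory CSVs (both the
spots-in-tracks layout and the concatenated three-column layout consumed by
spreadsheet-based quantification suites) are plain UTF-8/LF/comma files that
round-trip coordinates losslessly.

## Preprocessing

The static background (collagen texture, illumination gradients, debris) is
estimated as the **average-intensity time projection** and subtracted from
every frame. A structure that never moves is removed exactly; a cell that
occupies a site during 1 of T frames keeps roughly `A * (1 - 1/T)` of its
amplitude. Negative differences are clipped at 0 by default
(`clip_negative`), mirroring unsigned-integer image arithmetic; a
preserve-sign mode exists because phase-contrast cells can be darker than
their surroundings.

Contrast is then normalized per frame with a **bounded saturated fraction**
(default 0.001, i.e. 0.1 %, split equally between the tails: the
`floor(n*f/2)` lowest and highest pixels saturate). Cut values are order
statistics, `low = v[k+1]`, `high = v[n-k]` with `k = floor(n*f/2)`, and
`[low, high]` maps linearly onto `[0, 255]` with clamping. A constant frame
maps to all zeros — together with exact self-subtraction this makes the
whole preprocessing exactly zero on a static scene, which the tests assert
literally. Histogram equalization is deliberately not implemented; the
workflow this mirrors switches it off. The `[0, 255]` output scale is what
gives the default detector threshold of 25 its meaning.

## Detection

Cells are detected as peaks of the scale-normalized Laplacian of Gaussian.
For an estimated blob diameter `d` the filter scale is
`sigma = d / (2 * sqrt(2))`, because in 2D a scale-normalized LoG responds
maximally to a disc of radius `sigma * sqrt(2)`. The response is
`-sigma^2 * (Laplacian of the sigma-smoothed frame)`, computed by FFT
convolution with a sampled, DC-corrected kernel and reflection padding, so
bright blobs give positive peaks and constant offsets give exactly zero.
Scales below 0.8 px are rejected as unresolvable.

Strict 8-neighbour local maxima at or above the quality threshold are kept;
maxima closer than `d/2` are suppressed keeping the higher quality (ties
resolve in raster order, for determinism). Quality is the response value at
the integer maximum. Sub-pixel localization fits a 1D parabola per axis
through the three response values around the peak; the vertex offset
`(R_- - R_+) / (2 (R_- - 2 R_0 + R_+))` is clamped to half a pixel, and
non-concave curvature (impossible at an interior strict maximum, possible at
frame borders where refinement is skipped) yields offset 0.

The default threshold (25) is a calibration input, not a universal constant:
the quality scale depends on the intensity scale of the processed frames.
The "auto" initial threshold is implemented as Otsu's method on the
histogram of the frame's local-maxima qualities — a documented,
deterministic rule standing in for the interactive auto-threshold of GUI
tools. The same Otsu rule powers the "auto" track filters (duration, mean
quality, keep-above). Blob diameter defaults: 30 µm (DC-like), 40 µm for
larger carcinoma cells.

## Tracking

Linking is two exact linear assignment passes, with squared Euclidean
distance costs (µm²) and no splitting or merging — a dividing cell ends its
track, which for the short movies this targets is the desired behaviour.

* **Frame-to-frame pass:** for each consecutive frame pair, spots link if
  their distance is at most `linking_max_distance` (default 50 µm); every
  spot may instead "die" or "be born" at an alternative cost of
  `alternative_cost_factor` (1.05) times the maximum feasible cost in that
  matrix. Without the alternative cost the problem is ill-posed; 1.05 keeps
  it just above every real link so links are preferred whenever allowed.
* **Gap-closing pass:** one global assignment between all segment ends and
  segment starts. A join is feasible if the start is 1 to
  `gap_closing_max_frame_gap` (default 8, inclusive — up to 7 missed
  detections) frames after the end and within
  `gap_closing_max_distance` (50 µm); the cost is the plain squared
  distance, not scaled by gap length — the simplest rule consistent with the
  distance-and-gap limits the workflow prescribes.

Both passes use a Jonker–Volgenant-style shortest-augmenting-path solver on
the augmented square matrix (links | diagonal deaths / diagonal births |
zero slack block), which is optimal, deterministic (ties resolve to the
lowest index by construction) and verified against exhaustive enumeration
over all partial matchings on hundreds of random instances. Tracks carry
their closed gaps as missing frames; `regularize_tracks()` fills them by
linear interpolation (interpolated spots are flagged and carry quality 0)
before any statistic is computed, so the time base is uniform.

`subsample_tracks()` draws a seeded uniform sample of whole tracks,
preserving order — needed both for like-for-like comparisons against
manually tracked subsets and for the origin plot's 256-series limit, which
is enforced with an explicit error (and an override) rather than silently
truncating.

## Motility statistics

* **Speed** = total path length / elapsed time (µm/min). On the uniform
  frame grid this equals the time-weighted mean instantaneous speed. The
  definition uses path length, so positional noise inflates it slightly;
  this bias is shared by all per-frame displacement methods at a given
  frame rate.
* **Directionality ratio** = net displacement / path length, one value per
  track in `[0, 1]`; tracks with zero path length are undefined and excluded
  from summaries. By the triangle inequality, deleting interior points of a
  track can only raise this ratio — which is exactly why smoothed,
  straightened manual tracks read as more directional than automated ones.
  The property is asserted as a test over random tracks.
* **MSD** is time-averaged over overlapping intervals per track,
  `MSD_i(k dt) = mean_t |r(t+k) - r(t)|^2`, then ensemble-averaged across
  tracks per lag with SEM and track count. Lags beyond half the longest
  track are flagged `low_confidence`: they average few intervals and have
  high variance. Ballistic tracks give `(v k dt)^2` exactly; seeded
  Monte-Carlo ensembles reproduce log-log slopes 1 (Brownian) and 2
  (ballistic) within 10 %.
* **Condition comparison** is a two-sided Mann–Whitney U test on per-track
  speed or directionality, with group means ± SEM. The exact null
  distribution is used whenever both groups have fewer than 50 tracks and
  there are no ties (verified against a combinatorial count: fully separated
  10-vs-10 samples give p = 2/C(20,10) ≈ 1.08e-5); otherwise the normal
  approximation with tie correction applies.

## The synthetic generator

`simulation_config()` + `simulate_tracks()` + `render_video()` emulate the
processed appearance of a chemotaxis movie: bright cells on a dark
background (the generator produces post-subtraction-like data; raw-like data
for preprocessing tests is obtained by switching on the static texture at
high amplitude).

Motion is a biased persistent random walk: the heading performs a wrapped
Gaussian walk with spread `persistence_sd` (rad/step); the step direction is
the normalized mix `(1-b) * heading + b * (+x)` where `b` is `bias_weight`
(the +x axis stands for the chemokine gradient); step lengths are
`max(0, Normal(speed_mean, speed_sd)) * frame_interval`; boundaries reflect,
keeping track lengths uniform for the statistics tests. Rendering places an
isotropic Gaussian bump (sd = `blob_diameter/4`, so the visible blob spans
roughly the stated diameter) at each true position, over a static smoothed
noise texture, plus per-pixel Gaussian noise, clipped at 0. The pixel noise
stream is seeded with `seed + 1` so trajectories and pixels are
independently reproducible. `vanish_probability` hides a cell for a frame,
creating the detection gaps that exercise gap closing. `min_separation`
rejection-samples the initial placement (dart throwing with whole-pattern
restarts, since sequential rejection can deadlock near the packing limit).

Defaults describe a dendritic-cell-like acquisition: 2 µm/px, 2 min frames,
121 frames (4 h), 30 µm cells, 30 cells in a 256 px field, speeds around
5 µm/min. The speeds are a plausibility choice, not a measured value — the
source workflow reports motility only graphically, so no numeric speed is
reproduced from it.

What the generator does **not** emulate: cell shape and its deformation,
uneven illumination, z-drift, cell division, gel fiber structure beyond a
static texture, or density-dependent interactions. Passing the synthetic
validation therefore demonstrates the correctness of the algorithms under
the stated point-blob model, not performance on any particular microscope's
data; on real data the blob diameter and quality threshold must be tuned
(the workflow's own guidance), and a plausible detection rate is on the
order of 100–150 tracks per video at 4x magnification.

## Validation fixture regimes

Two fixture families deserve explanation, because their parameters are
chosen to *construct* the regimes the validation claims are scoped to:

* the **detection fixture** (20 cells, 50 frames, 256², peak-to-noise 5)
  uses slow, diffusive motion (`speed_mean` 1 µm/min, `persistence_sd` 1.2)
  and `min_separation` 90 µm, so cells stay several blob radii apart for the
  whole movie. Localization accuracy is only a meaningful quantity for
  non-overlapping blobs: when two 30 µm cells come within ~20 µm their bumps
  merge and the combined peak sits between them, which is a property of the
  scene, not a detector defect.
* the **tracking-identity fixture** (12 cells, 512², `min_separation`
  150 µm) realizes the regime "every per-step displacement below half the
  nearest-neighbour distance", in which identity preservation is provable;
  the test asserts that realized precondition before asserting zero swaps.

With these regimes the measured figures are: recall and precision 1.0,
localization RMSE ≈ 0.24 px, 100 % track recovery with 0 identity swaps,
stable across seeds. Problem sizes throughout the suite (50–121 frames,
256–512 px, up to 200 Monte-Carlo tracks) are chosen so the full suite runs
in about a minute while every Monte-Carlo bound keeps a wide margin.

## Numerical choices and degenerate inputs

* Convolution is FFT-based with symmetric (reflection) padding; kernels are
  DC-corrected so constants map to exactly 0.
* Contrast cuts are order statistics (no interpolation), making the
  sort-based oracle comparison exact.
* `low == high` (constant frame) yields all zeros; empty detection results,
  empty cost matrices and all-forbidden assignments are legal and return
  empty structures (all-forbidden with augmentation = everything births and
  deaths; without augmentation it is an error).
* Equal-quality neighbouring maxima and equal-cost assignments resolve by
  raster / lowest-index order: reruns are bit-identical.
* A 1x1 link whose cost exceeds birth + death is correctly left unlinked.
* Zero-length paths have undefined directionality (`NA`, excluded), and
  two-spot tracks have a single MSD lag.

## Known limitations

* Tracking is 2D; genuinely z-resolved 3D tracking is out of scope (the
  assay geometry is what makes 2D adequate).
* No motion-model prediction (Kalman) and no split/merge events; dense
  scenes with crossing cells will swap identities where trajectories
  genuinely intersect within a frame interval.
* The quality threshold is intensity-scale dependent by design; there is no
  absolute calibration across instruments.
* Speed estimates inflate with localization noise and frame rate, as for
  any path-length-based estimator; compare conditions at matched settings
  only.
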