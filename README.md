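# celltrax

Automated cell tracking and motility analysis for 3D chemotaxis time-lapse
assays.

Cells embedded in a collagen gel next to a chemoattractant reservoir are
imaged by phase-contrast time-lapse microscopy; because the gel holds the
cells in (effectively) one focal plane, the movie can be analysed as a 2D
single-particle tracking problem. `celltrax` implements that whole analysis
in R, for cell biologists who want to quantify chemotaxis of dendritic
cells, cancer cells, T cells or similar migratory cells without manual
tracking:

1. **Preprocessing** — the time-average projection of the stack is
   subtracted from every frame (removing the static collagen texture and
   out-of-focus background), then intensities are normalized with a bounded
   saturated-pixel fraction (default 0.1 %) onto `[0, 255]`.
2. **Detection** — cells are found per frame as peaks of the
   scale-normalized Laplacian-of-Gaussian response
   `R = -sigma^2 * Laplacian(G_sigma * I)` with `sigma = d/(2*sqrt(2))` for an
   estimated blob diameter `d` (30 µm for DCs, 40 µm for MDA-MB-231 cells),
   a quality threshold (default 25), non-maximum suppression within `d/2`,
   and sub-pixel localization by parabolic interpolation.
3. **Tracking** — two-pass linear assignment (LAP): frame-to-frame linking
   with squared-distance costs (max 50 µm), then global gap closing between
   segment ends and starts (max 50 µm, max frame gap 8), with birth/death
   alternatives at 1.05 x the maximum feasible cost. No splits or merges.
   The assignment core is an exact Jonker–Volgenant-style solver.
4. **Statistics** — per track: speed = path length / elapsed time (µm/min)
   and directionality ratio = net displacement / path length in `[0, 1]`;
   per condition: time-averaged mean squared displacement
   `MSD(k*dt) = <|r(t+k) - r(t)|^2>_t` ensemble-averaged across tracks with
   SEM, origin-aligned trajectory plots (up to 256 series), and two-sided
   Mann–Whitney comparisons between conditions.

A synthetic video generator (biased persistent random walks rendered as
Gaussian blobs over collagen-like texture with pixel noise) provides ground
truth so that every stage is validated end to end without microscope data.

## Worked example

Simulate a chemokine condition (30 cells, 2 h at 2 min intervals, bias 0.5
toward +x), run the full pipeline, and summarize:

```r
library(celltrax)

cfg <- simulation_config(n_cells = 30, n_frames = 61, bias_weight = 0.5,
                         image_size = c(512, 512), seed = 42)
fx    <- make_fixture(cfg, "demo")                       # stack.tif + truth.csv + config.yaml
stack <- read_stack(fx$stack, calibration(pixel_size = 2, frame_interval = 2))

pcfg <- pipeline_config(calibration = calibration(2, 2),
                        condition_label = "chemokine")
res  <- run_pipeline(pcfg, stack, "demo_out", preprocess = FALSE)
#> stack: 61 frames 512 x 512 px
#> detected 1767 spots (29.0 per frame)
#> 44 segments -> 34 tracks

res$summary
#> <motility_summary> 'chemokine': 34 tracks
#>   speed 4.76 +/- 0.088 um/min, directionality 0.681 +/- 0.038
```

29 detections per frame on a 30-cell movie, 44 raw segments closed into 34
tracks (a few cells wander across the field border and re-enter as new
tracks). Mean speed 4.76 µm/min matches the simulated 5 µm/min minus the
small loss from sub-pixel noise and reflection; directionality 0.681 is the
chemotactic signature (an unbiased run gives ≈ 0.42 at this track length).
`tidy(res$summary)` returns the per-track table, `autoplot(res$summary)`
the log-log MSD curve, and

```r
compare_conditions(random_summary, chemokine_summary, feature = "directionality")
```

prints the Mann–Whitney U, the two-sided p value and group means ± SEM.
A command-line front end with `simulate`, `preprocess`, `detect`, `track`,
`stats`, `run` and `compare` subcommands lives at `inst/cli/celltrax.R`.

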