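# collmigr

Quantification of collective cell migration under directional control.

Confluent epithelial monolayers migrate collectively: neighboring cells
couple through cadherin junctions and align their motion. When such a
tissue is steered by an external directional cue — most potently a DC
electric field, to which many epithelia respond by migrating toward the
cathode (electrotaxis) — the native coordination of the tissue and the
imposed command compete. Quantifying that competition requires a small set
of standard measurements, which this package implements end to end:

- **PIV** — gridded velocity fields from phase-contrast time-lapse stacks
  by windowed FFT cross-correlation with subpixel (three-point Gaussian)
  peak localization, signal-to-noise gating and normalized-median outlier
  filtering.
- **Order parameters** — per frame, over the `N` valid velocity vectors
  `v⃗ᵢ`:

  - *directionality* = `(1/N) Σᵢ cos θᵢ`, with `θᵢ` the angle between `v⃗ᵢ`
    and the horizontal field axis (+1 parallel with the field, −1
    antiparallel);
  - *coordination* = `‖(1/N) Σᵢ v⃗ᵢ/‖v⃗ᵢ‖‖`, the polarization order
    parameter of collective-motion theory (1 = perfectly aligned tissue,
    0 = isotropic motion);
  - mean speed, mean x-velocity, neighbor velocity correlation, and polar
    distributions of velocity angles.
- **Kymographs and edges** — x-velocity space–time heat maps (10 min/row,
  ~42 µm/column by default), texture-based tissue segmentation,
  leading/trailing edge displacement traces, and a wound-closure rate
  estimator for two facing tissues.
- **Synthetic ground truth** — a Vicsek-style agent simulator whose
  alignment `coupling` tunes collectivity (standing in for
  calcium/E-cadherin junction strength) and whose `field_bias` stands in
  for the electrotactic command, plus a speckle-image renderer and
  moving-edge scenario generator, so every stage of the pipeline is
  verifiable against known truth without microscopy data.

## Worked example

Simulate tissues of increasing coupling, convert trajectories to velocity
fields, and compute the migration metrics:

```r
library(collmigr)

for (cp in c(0.5, 1, 5)) {
  cfg <- sim_config(n_agents = 256, box_width = 320, box_height = 320,
                    coupling = cp, noise = 0.8, field_bias = 0,
                    n_frames = 60, seed = 1)
  fields <- trajectory_fields(simulate_monolayer(cfg), grid_spacing = 40)
  s <- metric_timeseries(fields)
  cat(sprintf("coupling=%.1f  speed=%.2f um/min  coordination=%.2f\n",
      cp, mean(s$speed, na.rm = TRUE),
      mean(s$coordination[30:59], na.rm = TRUE)))
}
#> coupling=0.5  speed=1.16 um/min  coordination=0.60
#> coupling=1.0  speed=1.14 um/min  coordination=0.78
#> coupling=5.0  speed=0.34 um/min  coordination=0.84
```

Coordination rises with coupling while speed falls — the adhesion/speed
trade-off of strongly coupled tissues. Switching a horizontal command on
mid-run aligns migration with the field axis:

```r
bias <- c(rep(0, 29), rep(2, 30))           # command on from frame 30
cfg <- sim_config(n_agents = 256, box_width = 320, box_height = 320,
                  coupling = 1, noise = 0.8, field_bias = bias,
                  n_frames = 60, seed = 1)
s <- metric_timeseries(trajectory_fields(simulate_monolayer(cfg), 40))
cat(sprintf("directionality before: %.2f   after: %.2f\n",
    mean(s$directionality[1:29], na.rm = TRUE),
    mean(s$directionality[45:59], na.rm = TRUE)))
#> directionality before: 0.34   after: 0.96
```

PIV recovers a programmed subpixel drift from rendered speckle images:

```r
s <- render_speckle(c(2.5, -1.5), c(160, 160), 2, seed = 11,
                    pixel_size = 1.3, frame_interval = 5)
f <- compute_piv(s$frames[[1]], s$frames[[2]], piv_params())
median(f$u[f$valid]); median(f$v[f$valid])
#> [1] 2.567
#> [1] -1.402
```

For real data, `run_pipeline(run_config("movie.tif", pixel_size = 1.3,
frame_interval = 5, ...))` runs stack → PIV → metrics → kymograph → edge
traces and writes `fields.csv`, `metrics.csv`, `polar.csv`, `kymo.csv`,
`edges.csv` and a `summary.json` (including the directionality 4 h after
stimulation onset and the maximum smoothed speed). A thin command-line
wrapper with the same subcommands ships in `inst/cli/collmigr.R`.

## Limitations

The simulator is a minimal stand-in: it reproduces the statistical
structure of tunable-collectivity tissues (alignment, noise, bias, the
speed/coordination trade-off, free edges) but none of the mechanics of
real monolayers (see the methods vignette). Multi-pass/deforming-window
PIV, optical flow and nuclear tracking are out of scope.
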