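# ernetdyn

Quantitative image analysis of the peripheral endoplasmic reticulum (ER)
network in 2-D fluorescence microscopy, for cell biologists measuring
how perturbations remodel ER architecture and dynamics.

The peripheral ER is a planar polygonal network of membrane tubules
meeting at three-way junctions, interspersed with flat cisternae
(sheets). Its density and mobility change under genetic and
pharmacological perturbation, and two families of read-outs capture
this:

- **Morphometry.** A fluorescence frame is segmented (percentile
  normalization, Otsu thresholding, optionally phase-congruency ridge
  enhancement; cisternae by morphological opening plus region-based
  active-contour refinement) and thinned to a single-pixel-wide
  skeleton. Each skeleton pixel is classified by its 8-neighbor count
  *n*: end point (*n* ≤ 1), tubule (*n* = 2), junction (*n* ≥ 3). The
  package reports the junction/tubule ratio, branch lengths, and the
  **polygonal regions** fully enclosed by skeleton and cisternae, with
  area *A*, perimeter *P*, circularity 4π*A*/*P*², and elongation
  (major/minor axis ratio of the second-moment ellipse).
- **Dynamics.** Junction objects (junction-class skeleton clusters
  larger than 3 px, masked by the raw intensity and Gaussian-blurred)
  are tracked with a linear-assignment-problem (LAP) linker: squared
  Euclidean cost, 7 px maximum linking distance, birth/death
  alternatives at the radius cost, then a second assignment stage that
  closes gaps up to 3 frames within 10 px. Tracks longer than 10 frames
  yield instantaneous speeds (cumulative velocity distribution) and a
  diffusion coefficient from the ensemble mean squared displacement,
  MSD(τ) = 4*D*τ (+ a localization-noise intercept), fitted over lags
  1–4.
- **Kinetics.** Background-subtracted integrated ROI traces for
  photoactivation (PA-GFP-KDEL) and synchronized-release (RUSH) assays,
  with the two standard normalizations (initial → 0 / max → 1, and
  max-division), plus fixed-distance radial read-outs at 8, 12 and
  16 µm from the activation site.

Because real micrographs ship with no ground truth, the package
includes a first-class synthetic generator: jittered-Voronoi tubule
networks (generic Voronoi vertices are exactly three-way, matching ER
topology), Gaussian PSF blur, Poisson-Gaussian noise, Brownian junction
motion with a chosen *D*, diffusive photoactivation spread, and
saturating transport traces — every stage of the pipeline is validated
against this known truth.

## Worked example

```r
library(ernetdyn)

## ground-truthed synthetic network and micrograph
net <- generate_network(256, 256, 30, jitter = 0.35,
                        pixel_size_um = 0.1, seed = 1)
net
#> <NetworkGroundTruth> 256 x 256 px (0.1 um/px), 58 nodes (40 interior),
#>   69 edges, 12 bounded cells
frame <- render_network(net, psf_sigma_px = 1.2, tubule_intensity = 100,
                        background = 5, noise = "poisson_gauss", seed = 1)

## morphometry
res <- run_morphometry(default_config(), frames = list(example = frame))
res$reports$example
#> <MorphometryReport> J/T ratio 0.0586, 37 junctions, 12 polygons
#>   (mean 20.7 um^2), 72 branches

## junction tracking and diffusion on a Brownian time lapse
cfg <- default_config()
cfg$synth$width_px <- 320L; cfg$synth$height_px <- 320L
cfg$synth$n_seed_points <- 35L; cfg$synth$n_frames <- 30L
cfg$synth$d_um2_s <- 0.05; cfg$seed <- 1L
dyn <- run_dynamics(cfg)
dyn$diffusion
#> <DiffusionEstimate> D = 0.04826 um^2/s (lags 1-4, R2 0.999, 46 tracks)
dyn$velocities
#> <VelocityStats> 1183 velocities, median 1.357 um/s
```

The 12 detected polygons match the 12 bounded ground-truth cells, and
the fitted *D* = 0.048 µm²/s recovers the simulated 0.05 µm²/s. Track
tables, velocity CDFs, overlay PNGs and JSON run reports are written to
`cfg$out_dir` when set; every report carries the configuration hash,
seed and package version.

A thin command-line wrapper drives the same pipelines:

```sh
inst/exec/er-netdyn synth --config config.yaml --out run1/ --seed 2
inst/exec/er-netdyn morph --config config.yaml --out run1/
```

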