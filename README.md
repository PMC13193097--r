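# lysoquant

Quantification of lysosome spatial organization and motility from
time-lapse fluorescence microscopy.

Lysosomes appear in live-cell imaging as hundreds of punctate spots whose
positioning (perinuclear clustering vs. peripheral scattering) and motion
(caged, diffusive, or motor-driven) report on the organelle-positioning
machinery. lysoquant re-implements a complete punctum-analysis pipeline as
a tested, reusable R package:

* **Detection** — 8-bit conversion, global thresholding (default
  intensity 100, strict), 8-connected component labeling, binary-moment
  centroids, per-frame counts and areas.
* **Cell-region geometry** — a concave cell outline from the puncta
  themselves via a Delaunay **alpha shape** (α = 0.02, i.e. circumradius
  < 50 px); a 60 px (7.8 µm at 0.13 µm/px) **peripheral rim** and a 40 px
  (5.2 µm) **perinuclear annulus** as Euclidean distance bands.
* **Spatial statistics** — the uncorrected **Ripley's K** estimator
  K(r) = A/(n(n−1)) · #{i≠j : d_ij ≤ r} over radii 1–250 px, against the
  CSR baseline πr², averaged over the first 50 frames per video and
  across videos with 95% confidence bands.
* **Motility** — Crocker–Grier-style trajectory linking (search range
  9 px, memory 5 frames, minimum track length 20 detections), pooled
  **ensemble MSD**, and the power-law fit **EMSD(τ) = 4Dτ^α** by log–log
  least squares; α < 1 subdiffusive, α = 1 Brownian, α > 1 superdiffusive.
* **Intensity metrics** — the **perinuclear index** (I<5 − I>10) × 100
  and **CTCF** = integrated density − area × mean background.
* **Synthetic data** — ground-truthed cell geometries, point patterns
  (CSR / Thomas-clustered / hard-core), trajectories (Brownian / confined
  / directed), and rendered 8-bit TIFF stacks, so every stage is testable
  without microscopy data.

## Worked example

Simulate a clustered punctum pattern inside a 900 µm² cell, render it,
and run the spatial pipeline:

```r
library(lysoquant)

geom  <- make_cell_geometry(cell_area_um2 = 900, nucleus_fraction = 0.12,
                            pixel_size_um = 0.13, shape = "blob", seed = 7)
scene <- simulate_point_pattern("clustered", n = 80, window = geom,
                                n_frames = 10, n_parents = 8,
                                cluster_sd = 18, seed = 7)
stack <- render_stack(scene, render_params(noise_sd = 0,
                                           image_shape = geom$shape))
cfg   <- pipeline_config(radii = c(10, 25, 50, 100), max_frames = 10)
res   <- run_spatial_pipeline(stack, cfg)

res$counts$mean_count
#> [1] 66
cbind(res$mean_k, csr = round(csr_baseline(res$mean_k$r_px), 1))
#>   r_px          k     csr
#> 1   10   369.0771   314.2
#> 2   25  3106.3510  1963.5
#> 3   50  7792.8297  7854.0
#> 4  100 15477.4473 31415.9
```

The mean detected count (66) sits a little below the 80 simulated spots
because clustered puncta occasionally touch and merge. K(r) exceeds the
CSR baseline πr² at small radii — the clustering signature — and falls
below it at radii comparable to the cell size, the expected downward bias
of the uncorrected estimator.

Motility: simulate Brownian particles, link them, and fit the EMSD power
law:

```r
ms     <- simulate_trajectories("brownian", n_particles = 120,
                                n_frames = 60, window = c(250, 250),
                                D = 0.4, seed = 8)
tracks <- filter_tracks(link_trajectories(scene_detections(ms),
                                          link_params()), min_length = 20)
fit    <- fit_power_law(emsd(tracks, max_lag = 30))
fit
#> Power-law diffusion fit: EMSD(tau) = 4 D tau^alpha
#>   alpha = 1.021 (SE 0.00378)   D = 0.3935 px^2/frame^alpha
#>   R^2 = 0.9998   lags 1-15   regime: brownian (|alpha - 1| band 0.1)
```

The fitted exponent α ≈ 1 and D ≈ 0.4 px²/frame recover the simulation
truth through the full link → filter → EMSD → fit chain.
`run_motility_pipeline()` performs the same analysis per region (whole
cell / perinuclear / peripheral) from an image stack, and
`perinuclear_index()` / `ctcf()` compute the intensity metrics.

See `vignettes/lysoquant-methods.Rmd` for the models, parameter
conventions, and numerical choices.

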