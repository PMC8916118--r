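# tomomorph

Morphometry and spatial statistics for cryo-electron tomography
annotations of neuronal processes.

Cryo-ET studies of developing axons produce three kinds of quantitative
annotation: manually traced actin filaments (polylines), picked ribosome
coordinates (3D point patterns), and manually measured organelle
dimensions (scalar tables). `tomomorph` implements the downstream
quantitative analyses for all three, plus a minimal subtomogram-averaging
engine, as tested, reusable R functions:

* **Filament morphometry** — resampling traces into 10-nm segments,
  per-filament arc length, per-segment orientation against a reference
  axis (folded to [0°, 90°]), and per-region median/IQR summaries.
* **Ribosome spatial statistics** — 3D nearest-neighbour (NN) distances;
  a Gaussian fit *a*·exp(−(x−μ)²/2σ²) to the NN histogram below 40 nm;
  polysome/monosome classification (fraction of particles with NN in
  [25, 35] nm, the inter-ribosome spacing of a polysome, and the fraction
  beyond 50 nm); distance-linked chain extraction for visualization; and
  plot-back tables of aligned orientations.
* **Organelle statistics** — per-group medians and quartiles,
  Mann–Whitney rank-sum tests (exact by enumeration for pooled n ≤ 16
  without ties, tie-corrected normal approximation otherwise), and
  structure-enrichment densities per surveyed tomogram.
* **Subtomogram averaging** — exhaustive coarse-to-fine rigid alignment
  over a ZXZ Euler grid with FFT translation search under a ±60° missing
  wedge mask, odd/even half-set averaging with Fourier-coverage
  normalization, Fourier shell correlation
  FSC(s) = Re⟨F₁, F₂⟩ₛ / √(⟨|F₁|²⟩ₛ⟨|F₂|²⟩ₛ), and threshold-crossing
  (0.143 / 0.5) resolution with adaptive bandpass between iterations.
* **Synthetic data** — generators for filament sets, chained + isolated
  particle patterns, wedge-masked noisy particle volumes, and measurement
  tables, each a pure function of config + seed and each emitting ground
  truth, so every analysis is validated by parameter recovery.
* **I/O** — the 5-column ASCII point-file dialect (`object contour x y z`),
  MRC2014 mode-2 volumes, and measurement CSVs with closed vocabularies.

## Worked example

```r
library(tomomorph)

# a synthetic pick set at the study scale: ~1,614 particles composed of
# helical chains (spacing ~ N(29.5, 3.4) nm), scattered pairs, monosomes
g  <- gen_particles(particle_sim_config(seed = 42))
nn <- nn_distances(g$particles)

fit_gaussian(nn)
#> <gaussian_fit> mu 29.44 nm, sigma 3.93 nm (n = 1323 in (0, 40) nm; sample 29.63 +/- 3.65)

cl <- classify_nn(nn)
sprintf("in-window %.1f%%, isolated %.1f%%",
        100 * cl$fraction_in_window, 100 * cl$fraction_isolated)
#> "in-window 67.5%, isolated 13.1%"
```

The fitted mean recovers the generating chain spacing (29.5 nm); 67.5% of
particles sit in the 25–35 nm polysome window and 13.1% are farther than
50 nm from any neighbour — single-replicate estimates of the generator's
70% / 13% composition targets. Filaments work the same way:

```r
fg <- gen_filaments(filament_sim_config(seed = 42))   # 325 mature-branch traces
summarize_filaments(fg$traces)$stats
#>         region   n median_length       q1       q3     iqr n_segments n_short
#>  mature_branch 325        175.5    137.8    229.8    92.0       6365       0

mann_whitney_u(c(1, 2), c(3, 4))
#> <rank_sum_result> U = 0 (n1 = 2, n2 = 2), p = 0.3333 [exact]
```

A full report (filament tables, NN histogram + fit, fractions, chains,
organelle summaries + tests, subtomogram FSC/resolution, manifest) is one
call — or one shell command via the thin wrapper in `inst/scripts/`:

```r
run_pipeline(default_run_config(seed = 1, outdir = "report"))
```

## Package layout

| Path | Contents |
|---|---|
| `R/model_io.R` | point-file / MRC2014 / CSV readers and writers |
| `R/synthetic.R` | synthetic-data generators + configs |
| `R/filaments.R` | resampling, lengths, angles, summaries |
| `R/ribosomes.R` | NN distances, Gaussian fit, classification, chains |
| `R/organelles.R` | group summaries, rank-sum tests, enrichment |
| `R/subtomo.R`, `src/rotate.cpp` | alignment, averaging, FSC, resolution |
| `R/pipeline.R` | config-driven orchestration and report bundle |
| `vignettes/tomomorph-methods.Rmd` | model, conventions, design decisions |

See the methods vignette for the statistical conventions (quantile rule,
angle folding, remainder handling), the synthetic composition arithmetic,
and the known limitations of each estimator.
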