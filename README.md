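# pamp

Screening candidate **migrastatic** drugs — compounds meant to stop tumour
cells from migrating and invading, rather than from proliferating — needs a
readout of how cells *move* and *look* over many hours, without labels or
phototoxicity. Quantitative phase imaging (QPI) provides exactly that: the
optical phase delay through a cell is proportional to its dry mass per unit
area,

```
M(x, y) = phi(x, y) * lambda / (2 * pi * alpha)        [pg/um^2]
```

with `phi` the reconstructed phase (radians), `lambda` the illumination
wavelength (0.66 um by default) and `alpha` the specific refraction
increment (0.18 um^3/pg). `pamp` implements the full assessment pipeline on
20-hour, 5-minute-interval QPI time-lapse recordings:

* **Morphometry** per cell and frame: Mass `= sum(w h M)`, Area `= N w h`,
  Perimeter (Moore boundary tracing), Circularity
  `= 100 * 4 pi Area / Perimeter^2`, density `= Mass/Area`, and the
  dry-mass-weighted centre of gravity (WCG).
* **Migration dynamics** per track: step speeds
  `|WCG(t_n) - WCG(t_n-1)| / (t_n - t_n-1)`, path length, Euclidean
  displacement, and the meandering index (net displacement / path length).
* **Invasive-phenotype calling**: a cell is invasive at the evaluation time
  when Euclidean displacement > 100 um *and* meandering index > 25%.
* **Inference**: per-period treated-vs-control comparison of per-cell mean
  speeds with a variance-gated two-sample t-test (F-test p < 0.05 selects
  Welch, otherwise pooled), percent speed change, significance stars.
* **Segmentation and tracking** (density thresholding with hysteresis,
  watershed splitting, optimal bipartite frame linking with gap closing and
  division handling), **control QC**, and per-period
  circularity/density summaries.
* A **synthetic movie generator** (`simulate_movie()`) producing phase
  stacks with exact ground truth — anisotropic Gaussian dry-mass cells on
  persistent random walks — plus an off-axis **hologram forward model and
  Fourier sideband reconstruction** (`simulate_hologram()`,
  `reconstruct_phase()`), so the entire pipeline validates itself without
  microscope data.

Intended users: imaging/analysis people building or validating QPI
migration screens, and anyone needing a ground-truthed testbed for
cell-tracking morphometry code.

## Worked example

A control and a half-speed "drug" arm, simulated and pushed through the
whole pipeline (6 h at 5-minute intervals to keep the example quick):

```r
library(pamp)
cfg <- list(
  seed = 7,
  movies = list(
    list(condition = "CNT", batch = 1, is_control = TRUE,
         sim = list(n_cells = 10, field_size = c(384, 384), n_frames = 73)),
    list(condition = "DRUG", batch = 1,
         sim = list(n_cells = 10, field_size = c(384, 384), n_frames = 73,
                    drug_effect = 0.5))),
  analysis = list(periods = list(c(0, 3), c(3, 6)), eval_times_h = c(6),
                  min_steps = 6))
res <- run_pipeline(cfg)
print(res)
#> pamp_run: 2 conditions
#> speed comparisons vs batch control:
#>   condition      period mean_treated mean_control speed_change_pct variant
#> 1      DRUG 00.00-03.00         14.6         31.2            -53.3   welch
#> 2      DRUG 03.00-06.00         15.6         32.7            -52.4   welch
#>        t_p stars
#> 1 2.77e-04   ***
#> 2 8.02e-06   ***
print(res$qc$CNT)
#> QC report: cells 10 -> 10
#>   mass -0.0%, area -0.9%, speed period2 vs 1 +4.8%
#>   flags: none
```

Reading the output: the simulated compound halves migration speed, and the
pipeline recovers that — treated cells average ~15 um/h against ~31–33 um/h
in the control, a −53% change in both analysis periods, highly significant
under the variance-gated t-test (`welch` chosen because the F-test rejected
equal variances; `***` means p < 0.001). The control QC raises no flags:
cell count kept, mass/area stable, speed steady between periods —
i.e. nothing that would confound a migrastatic readout. `res$invasive`
holds the per-condition invasive fractions (0% here — 6 h is too short for
100-um displacements at these speeds; use 20 h recordings for that
readout), `res$features` the full per-cell-per-frame morphometric tables.

A thin CLI wraps the same functions:

```sh
Rscript exec/pamp simulate --out movie.tif --seed 4
Rscript exec/pamp features movie.tif --out features.csv
Rscript exec/pamp run --config study.yaml --out results/
```

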