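# cardiot2

Respiratory motion-registered whole-heart 3D T2 mapping: simulation,
reconstruction, registration and fitting for free-breathing T2-prepared 3D
radial cardiac MRI.

## What this is for

Quantitative myocardial T2 maps detect edema and inflammation, but routine
2D mapping acquires a few thick breath-held slices and can miss focal
disease. The alternative implemented here is a free-breathing, isotropic
whole-heart acquisition: three ECG-triggered T2-prepared 3D radial bSSFP
volumes (spiral-phyllotaxis readouts, preps 0/30/60 ms, one interleave of
49 lines every other heartbeat, each preceded by a superior–inferior
navigator). The package provides the complete processing chain plus the
synthetic data to exercise it:

* **Bloch sequence simulator** — exact per-TR rotation/relaxation evolution
  of the T2-prepared bSSFP train over the full 672-heartbeat schedule;
  heart-rate bias curves of the fitted T2 (`t2_bias_curve()`).
* **Trajectory** — 3D radial spiral phyllotaxis with SI navigators
  (`spiral_phyllotaxis()`).
* **Dynamic numerical phantom** — multi-tissue thorax (myocardium / blood /
  liver-like background / lesion) with quasi-periodic respiratory
  translation, simulated coils and seeded noise; its T2-prepared radial
  k-space is synthesized through a Kaiser–Bessel NUFFT
  (`simulate_acquisition()`).
* **Self-navigation** — SI projections, PCA respiratory amplitude,
  equal-count binning into four respiratory states (`project_si()`,
  `extract_respiratory_signal()`, `assign_bins()`).
* **Motion-resolved compressed sensing** — per-prep, per-bin reconstruction
  minimizing ½Σ_b‖E_b x_b−y_b‖² + λ′Σ‖x_{b+1}−x_b‖₁ (finite differences
  along the respiratory dimension, nonlinear conjugate gradient,
  Pipe-style density compensation) (`motion_resolved_recon()`), plus the
  1D self-navigated baseline (`selfnav_recon()`).
* **Registration** — respiratory bins to end-expiration (translation +
  non-rigid block matching with demons refinement), then the three
  averaged prepared volumes to each other (`register_and_average_bins()`,
  `register_preps()`).
* **Fitting and QC** — voxel-wise S(τ) = A·e^(−τ/T2) + B (offset absorbs
  T1 recovery during the readout train; exactly-determined 3-point solve),
  regional CoV, and sigmoid edge sharpness T2(x) = a/(1+e^(−k(b+x)))+c
  averaged over five adjacent septum-to-blood lines (`map_volume()`,
  `region_stats()`, `sharpness()`).

Raw datasets live in a single-file binary container with ISMRMRD-style
field naming (`write_raw()` / `read_raw()`); volumes and maps are written
as NIfTI-1. A thin command-line front end with per-stage subcommands is
installed at `system.file("cli", "cardiot2", package = "cardiot2")`.

## Worked example

The end-to-end phantom study — simulate the full 112-interleave, 4-coil
acquisition at 48³, self-navigate, reconstruct four respiratory states per
prep, register, fit — runs in a few minutes:

```r
library(cardiot2)
res <- run_pipeline(default_run_config(matrix = 48, seed = 42))
#> [..] simulating acquisition (matrix 48, 4 coils)
#> [..] self-navigation: SI projection + PCA binning
#> [..] motion-resolved CS reconstruction (lambda = 0.05, 15 it)
#> [..]   CG objective: 1.665e+10 -> 3.503e+08 (15 iterations)
#> [..] registering respiratory bins to end-expiration
#> [..] registering prepared volumes
#> [..] voxel-wise T2 fitting (three_param)
#> [..] done: myocardial T2 40.8 ms (CoV 19.7%)

maps <- res$tissue_maps
region_stats(res$map, maps$label == 3)$mean_t2_ms   # LV blood pool
#> [1] 256.5
region_stats(res$map, maps$lesion_mask)$mean_t2_ms  # septal lesion
#> [1] 59.1
```

Reading these numbers: the phantom's blood pool (true T2 250 ms) and
lesion (60 ms) are recovered almost exactly. The myocardium (true
46 ms) reads 40.8 ms — which is what the acquisition itself encodes: the
Bloch-simulated apparent T2 of a T1/T2 = 1050/46 ms tissue at 67 bpm is
40.9 ms, because the steady-state magnetization entering the three
preparations differs (see the vignette's discussion of heart-rate
dependence). The reconstruction chain is accurate to well under a percent
against what the data contain.

The heart-rate bias curve itself:

```r
t2_bias_curve(sequence_params(), heart_rates_bpm = c(40, 60, 80, 90))
#>   hr_bpm fitted_t2_ms bias_percent valid
#> 1     40     47.47704    -5.045922  TRUE
#> 2     60     43.67002   -12.659953  TRUE
#> 3     80     40.11689   -19.766225  TRUE
#> 4     90     38.57071   -22.858573  TRUE
```

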