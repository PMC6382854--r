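# mapquant

Quantification of cortical microtubule arrays, plasma-membrane particle
densities, and microtubule-associated protein (MAP) behavior from light
and electron microscopy.

Plant cells organize their microtubules along the cell cortex, where the
array guides cellulose synthase complexes (CSCs) at the plasma membrane.
MAPs such as the companion-of-cellulose-synthase protein CC1 bundle
microtubules, diffuse along the microtubule lattice, and reorganize the
array under salt stress. Quantifying those behaviors requires a chain of
small, well-defined image and track analyses that are usually scattered
across ImageJ macros, MATLAB scripts and tracking tools. `mapquant`
implements that chain as one tested R package, together with
synthetic-data generators that carry ground-truth sidecars so every stage
can be validated closed-loop.

## What it computes

| Stage | Quantity | Definition |
|---|---|---|
| `coverage()` | microtubule coverage `C` | `C = A_mt / A_cell`, Sobel edge pixels over the closed cell region |
| `particle_density()` | CSC density `rho` | `rho = (N_particles - N_golgi) / A_cell` with two-scale Laplacian-of-Gaussian detection (sigma 0.2 / 0.8 um, prominence tolerances 800 / 120) |
| `bundling()` | mean fiber diameter `d` | `2 * EDT - 1` sampled on the skeleton of the segmented fiber mask |
| `time_phased_subtract()`, `extract_kymograph()` | tip velocities `v` | frame(t+1) - frame(t) masks; kymograph slopes in um/min |
| `msd()`, `ensemble_D()` | diffusion coefficient `D` | time-averaged `MSD(tau) = 2 D tau`, `D = slope / 2` over lags 1-10 |
| `lifetimes()` | foci lifetime `L` | first appearance to disappearance, per substrate class |
| `detect_dips()`, `spacing_stats()`, `row_angles()` | gold-label geometry | dip centers on TEM transects; spacings, labels/row, inter-row angles |
| `pearson_coloc()`, `van_steensel_ccf()` | co-localization | Pearson `r` and its profile over lateral channel shifts |
| `kyte_doolittle()`, `classify_pairs()`, `degree_of_labeling()`, ... | sequence / labeling | hydropathy windows, BLOSUM62 classing, conjugate and DOL formulas, mean residue ellipticity |

The imaging primitives underneath (Gaussian smoothing, Sobel gradients,
Laplacian-of-Gaussian ridges, Otsu thresholding, 3x3 median despeckling,
8-connected component filtering, morphological closing, skeletonization,
and prominence-based maxima detection in the sense of ImageJ's "Find
Maxima" noise tolerance) are exported and tested against brute-force
reference implementations.

## Worked example

```r
library(mapquant)

# a synthetic cortical array with known fiber mask and coverage
sim <- gen_mt_array(seed = 42, n_fibers = 10)
cv  <- coverage(sim$image)
cv
#> <coverage_result> coverage 0.291 (4885 / 16793 px, threshold 1.535e+04)
verify_stage("coverage", cv, sim$truth, expected_seed = 42)
#> $truth_coverage     0.359
#> $estimated_coverage 0.291
#> $coverage_bias     -0.068

# gold-label spacing from a TEM transect
tem <- gen_tem_transect(seed = 42, n_dips = 200)
spacing_stats(detect_dips(tem$profile))
#> <spacing_stats> 9.98 +/- 2.3 nm (mean +/- SD, n = 198)

# lattice diffusion of single molecules along microtubules
tr <- gen_lattice_tracks(seed = 42, n_tracks = 50)
ensemble_D(tr$tracks, frame_interval = 0.1)[c("mean_D", "sd_D", "n")]
#> mean_D 0.0782   sd_D 0.0128   n 50
```

The coverage estimate sits within a tenth of the generated truth; the
transect pipeline recovers the generated 10 nm spacing distribution; and
the mean-squared-displacement fit recovers the generating diffusion
coefficient within a few percent.

Each stage can also be driven from a YAML config through `run_stage()`,
or from a shell via the thin wrapper in `inst/scripts/mapquant.R`.

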