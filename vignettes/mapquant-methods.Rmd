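---
title: "Quantifying cortical microtubule arrays and MAP behavior: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cortical microtubule arrays and MAP behavior: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapquant)
```

`mapquant` packages the image- and track-level measurements used to
characterize plant cortical microtubule arrays and the behavior of
microtubule-associated proteins (MAPs): array coverage, membrane particle
density, fiber-diameter bundling, tip dynamics, lattice diffusion,
gold-label geometry on TEM transects, co-localization, and a handful of
sequence and labeling formulas. This vignette explains each procedure,
the parameters that matter, the synthetic data the package validates
itself against, and the design decisions taken where the methods
literature leaves room.

## The imaging primitives

Every stage composes a small set of operators, all floating point with
reflective (edge-repeating) boundaries and 8-connectivity:

* **Gaussian smoothing** — separable convolution, kernel truncated at
  3.5 sigma. For a `calibrated_image` the sigma argument is a physical
  length and converts internally as `sigma / pixel_size`.
* **Sobel gradient magnitude** — Euclidean magnitude of the two 3x3
  responses; a step of height *h* scores 4*h* on its flanking columns.
* **Laplacian-of-Gaussian ridge response** (`log_ridge`) — the 5-point
  Laplacian of the Gaussian-smoothed image, negated so bright ridges and
  spots score positive. The smoothing scale is in pixels, matching the
  convention of the Laplacian plugins used in this field (default 1.5).
* **Otsu threshold** — 256-bin between-class-variance maximization over
  the image range; ties average (so the threshold shifts exactly with
  additive offsets and scales with positive gain). A constant image is an
  error, not a threshold.
* **Despeckle** — the classic 3x3 median.
* **Component filtering** — 8-connected components below a pixel-count
  gate are cleared; the gate is inclusive (a 20-px component survives a
  20-px minimum).
* **Region closing** — dilation by a disc, morphological closing, hole
  filling; the result is always a superset of the input. The disc radius
  is exposed (default 5 px) because the original "expansion and closing"
  protocol does not state one; note that the radius inflates any closed
  region by roughly its own width at the rim, which matters for small
  cells.
* **Skeletonization** — Zhang-Suen thinning to 8-connected unit-width
  curves.
* **Prominence maxima** (`find_maxima`) — the semantics of ImageJ's
  *Find Maxima* noise tolerance: flooding downward from each summit, a
  summit is a separate maximum only if it stands more than the tolerance
  above the saddle where its basin meets a higher basin. An equal-valued
  summit plateau reports its centroid. A constant image has no maxima,
  and the single surviving global summit must clear the tolerance over
  the image minimum. Plain local-maximum detection would make the
  published tolerances (800 and 120 on a 16-bit scale) meaningless,
  which is why the prominence reading is the contract here.

Each primitive is tested against an independent brute-force
implementation (direct convolution loops, exhaustive threshold scans,
flood-fill labeling, widest-path prominence search) on randomized small
images.

## Array coverage

`coverage()` thresholds the Sobel magnitude (explicit per-image
threshold, or Otsu of the nonzero gradients in auto mode, which makes the
result invariant to intensity rescaling), closes the edge pixels into an
enclosed region, keeps the largest component as the cell, and reports
edge pixels inside the cell over cell area. Edge pixels — not filled
fibers — define the microtubule area, mirroring the edge-detection origin
of the published analysis; the chosen threshold is recorded in the result
for reproducibility. Degenerate inputs are handled explicitly: a
featureless frame with an explicit threshold yields coverage 0 over the
whole field, and a constant image in auto mode is an error.

The synthetic ladder used to validate the stage spans coverages of about
0.15–0.4, the regime of interphase cortical arrays; validation asserts
the estimate within ±0.1 of the generated truth and strictly increasing
across the ladder. Very sparse arrays (a handful of fibers in an
otherwise featureless cell) recover the cell region poorly, because the
closing step needs enough structure to enclose — the stage is not
validated there.

## Membrane particle density

`particle_density()` reproduces the two-scale count subtraction: a cell
mask (Gaussian sigma 1.33 um, then Otsu, largest component, holes
filled), particle detection as prominence maxima of the
Laplacian-of-Gaussian of the 0.2-um-smoothed image at tolerance 800, and
Golgi detection at the 0.8 um scale with tolerance 120. The density is
`(N_particles - N_golgi) / A_cell` in um^-2 — subtraction happens at
count level, never by matching points, exactly as published; Golgi
bright enough to register at the particle scale are therefore counted in
both terms and cancel. A negative numerator flags the result invalid
rather than clamping. The published tolerances are absolute intensities;
they presume a 16-bit intensity scale, and both are configurable for
data on other scales. `foci_per_window()` reports particle counts in a
50 x 50 px window for density comparisons on cortical crops.

## Bundling as mean fiber diameter

`bundling()` detects the cell at a wide scale, segments fibers as the
despeckled Laplacian ridge response above a threshold with a 20-px size
gate, skeletonizes the mask, and reads the local fiber diameter at every
skeleton pixel from the Euclidean distance transform. The distance is
taken to the object boundary — half a pixel inside the nearest
background pixel center — so `diameter = 2 * EDT - 1`: a one-pixel line
scores 1 px and a width-w ribbon scores w. (Measuring to background
pixel centers instead would overestimate every diameter by one pixel;
the ribbon calibration fixes the convention.)

One point deserves emphasis for anyone comparing bundling between
conditions: the ridge response scales with brightness, and a per-image
Otsu threshold normalizes that scale away, clamping the segmented width
of a fiber regardless of how many microtubules it contains. The original
protocol used a per-image *user* threshold "covering all microtubules" —
an absolute, comparable scale. Comparative analyses with this package
should do the same: fix one threshold across the image set (the
monotonicity validation uses a shared threshold of 500 response units on
the default generator photometry). Physically, bundles widen the
measured diameter only through their real lateral extent; brightness
alone does not widen a Laplacian segmentation.

## Tip dynamics

`time_phased_subtract()` forms `frame(t + shift) - frame(t)` (default
shift one frame) and thresholds at `k_sigma` (default 3) robust standard
deviations of the difference image, estimated by the median absolute
deviation so the filament itself does not inflate the noise scale.
Positive pixels mark newly appeared structure (growth), negative pixels
mark loss. The threshold multiple is a declared choice — the source
protocols state none.

`extract_kymograph()` samples each frame along a polyline at 1-px arc
steps with bilinear interpolation, averaging a default of 3 samples
perpendicular to the line; `velocity_from_trace()` converts a traced
segment to um/min (the field's unit, even though inputs are in seconds),
reporting shrinkage as a positive magnitude with `kind = "shrink"`.
`auto_tip_traces()` provides a reproducible stand-in for manual tracing:
the tip per subtracted pair is the extremal pixel of the
component-filtered masks (isolated suprathreshold pixels are noise and
are dropped), and runs of consistent displacement sign at least three
frames long become constant-velocity events by least squares. Validation
recovers generated velocities of 2–10 um/min with median relative error
well under 10% and segments a growth-then-shrink movie into exactly two
events.

## Lattice diffusion, lifetimes and bundle counts

`msd()` computes the time-averaged mean squared displacement over lags
1..min(10, N/4) frames, dropping lags with fewer than 10 contributing
pairs, and fits an unweighted line with free intercept. Motion is
measured along the filament axis, so the 1-D convention `D = slope / 2`
is the default; the dimensionality is switchable (`slope / 4` for 2-D)
because source analyses rarely state it. The lag cap is the usual
bias–variance compromise for time-averaged MSD; the intercept absorbs
localization noise. Negative fitted slopes are reported but flagged. The
estimator is validated as unbiased (mean recovery within 5% over 200
simulated tracks) and exactly equal to the brute-force double loop.

Lifetimes run from first appearance to disappearance:
`(last - first + 1) * frame_interval`, so a single-frame appearance
lives one frame. Group summaries (median, quartiles) are reported for
single versus bundled microtubules; the validation uses group sizes of
60 single and 37 bundled tracks — the published experiment's n — with
bundle lifetimes generated at twice the single mean.

`classify_substrate()` quantizes integrated, background-subtracted
cross-section intensities by a single-microtubule unit intensity (the
median of user-designated single-microtubule cross-sections), rounding
to the nearest integer in [1, cap]; intensity steps discriminate up to
about five microtubules, hence the default cap.

## Gold-label geometry on TEM transects

`detect_dips()` finds local minima more than `k_sigma` (default 3)
robust standard deviations below the profile median, separates them
greedily deepest-first, and refines centers by three-point parabolic
interpolation, making detection invariant to affine intensity changes.
The minimum separation defaults to 3 nm, about three dip half-widths for
5-nm gold: a separation gate must sit at the resolution limit of the dip
shape, not at the expected label spacing — a gate at half the mean
spacing would censor the lower tail of the very spacing distribution
being measured (with a 10.0 ± 2.4 nm distribution, roughly 2% of true
spacings fall below 5 nm). A 3-sigma depth gate on thousands of noise
minima admits occasional false dips by construction; deep dips (the
generator default is 15 sigma) keep the pipeline's recall above 0.98.

`spacing_stats()` pools successive-neighbor distances; `row_angles()`
fits each row's direction by total least squares (principal axis) and
folds the angle between adjacent rows into [0°, 90°]; `labels_per_row()`
summarizes counts. `row_length()` multiplies mean labels per row by mean
spacing — the approximation used when reporting row lengths (8 labels x
10 nm ≈ 80 nm); the `(n - 1)`-gap alternative is exposed but not the
default. Row membership is supplied (from truth or manual grouping);
automatic row clustering is deliberately out of scope because rows were
grouped visually in the source workflow.

## Co-localization

`pearson_coloc()` is the Pearson coefficient over masked pixels.
`van_steensel_ccf()` shifts channel B along image columns (the lateral
x direction; a row variant is available) one pixel at a time up to
±20 px, computing a true Pearson coefficient over the valid overlap at
each shift — no zero padding, so every value is a genuine correlation.
A peak at shift 0 indicates co-localization; the synthetic dual-channel
generator validates that the peak lands on the generated shift and that
a fully co-localized pair yields a unimodal curve with its maximum at 0.

## Sequence and labeling formulas

`kyte_doolittle()` slides an unweighted window (default 5 residues,
odd) over the standard hydropathy scale; scores are reported only where
the full window fits — terminal positions are omitted rather than
computed on shrunken windows, since the source figures do not specify
termini handling. `classify_pairs()` marks aligned positions identical,
similar (substitution score >= 0 in the embedded BLOSUM62 table, which
is cross-checked against the Biostrings copy in the test suite), or
dissimilar; gaps are dissimilar. The labeling formulas are evaluated
exactly as printed: conjugate concentration
`((A280 - A490 * CF) / eps) * df` with CF = 0.1 and eps = 0.803 per
mg/mL for the His-tagged CC1 N-terminus; degree of labeling
`(A490 * Mwt * df) / (eps_dye * conjugate)` with Mwt = 16,122 Da and
eps_dye = 70,000; mean residue ellipticity
`(theta * 0.1) / (n * c * d)`. Over-correction (`A490 * CF >= A280`)
and zero denominators are errors, not NaNs.

## The synthetic data and what passing tests mean

Every generator is deterministic given `(seed, parameters)` and stores
the *realized* draws in its truth sidecar, so downstream estimates are
compared against what was actually rendered, not nominal parameters.
The noise model throughout is Poisson shot noise on the rendered signal
plus additive Gaussian read noise, emulating EMCCD acquisition without
modeling EM gain.

Defaults encode the study conditions the package targets:

* `gen_mt_array` — curvilinear fibers of 3-px FWHM inside an elliptical
  cell (bright cytoplasmic background 4000 over exterior 150, fiber
  amplitude 10,000 on a 16-bit-like scale, peak SNR 10). Bundles are
  members packed ~0.5 px apart (the ~30 nm microtubule lattice spacing
  at typical confocal sampling) that weave individually by ±0.8 px, so
  bundles are loosely fasciculated, as micrographs show, and physically
  wider than single fibers.
* `gen_particle_movie` — diffraction-limited foci (sigma 0.2 um,
  amplitude 20,000) and Golgi-like blobs (sigma 0.8 um, amplitude
  25,000) over a lit membrane (4000) at 0.13 um/px. The amplitudes were
  set from the Laplacian response arithmetic so that the published
  prominence tolerances (800 and 120) sit well inside the response of
  the structure they target and below everything else. Structures are
  placed a few pixels inside the cell rim; foci at the optical cell edge
  are ambiguous in any real quantification.
* `gen_lattice_tracks` — 1-D Brownian steps `N(0, sqrt(2 D dt))`,
  default 50 tracks of 500 frames at 0.1 s and D = 0.076 um^2/s, the
  published in vitro conditions. Lifetimes are exponential per substrate
  class (the source states no distribution; exponential is the natural
  memoryless default) and truncated to the movie.
* `gen_tem_transect` — inverted-Gaussian dips (half-width 1 nm, depth
  15 sigma of the profile noise) whose spacings are drawn from
  N(10.0, 2.4) nm at 0.5 nm per sample, truncated at the 2-px resolvable
  limit by redrawing (truncation moves the realized mean by well under
  0.01 nm at these parameters; a hard error here would make large runs
  fail stochastically on the rare sub-limit draw).
* `gen_gold_rows` — row pairs at folded-normal angles (2.8° ± 3°) with
  per-row label counts drawn around 8 ± 5 and clipped to [2, 41],
  matching the published row statistics.
* `gen_tip_movie` — a straight filament whose tip moves at
  piecewise-constant velocity with sub-pixel soft ends; growth/shrink
  speeds in um/min with switches at stated times.
* `gen_dual_channel` — channel B foci are channel A foci translated by a
  column shift for a chosen fraction, independent elsewhere; a zero
  co-localized fraction flags the truth shift undefined.

What the generators do **not** emulate bounds what passing tests show:
no photobleaching or blinking, no drift (inputs are assumed registered),
no depth-dependent background, no filament crossings in tip movies, and
point-spread functions are isotropic Gaussians. Recovery on these
synthetic conditions demonstrates that the estimators are implemented
correctly and are unbiased under their stated assumptions — not that
real micrographs meet those assumptions.

## Conventions and numerical choices

* Coordinates are 1-based (row, col), R's native indexing; subpixel
  positions are real-valued in the same frame with pixel centers at
  integers.
* Convolutions use half-sample reflective boundaries; all filters
  operate in double precision regardless of input depth.
* Otsu ties average; maxima tie-breaks attach a pixel to the
  highest-peaked adjacent basin, earliest on exact ties.
* Physical calibration is supplied by the user; acquisition metadata is
  never parsed. All physical results equal pixel-unit results times the
  stated calibration (tested as an invariant).
* Validation problem sizes: 160–320 px synthetic cells, 100-seed oracle
  sweeps on images up to 32 x 32 px, 20-seed recovery ensembles — sizes
  at which the full suite runs in a few minutes while keeping estimator
  standard errors well inside the asserted tolerances.

## Known limitations

The cell masks from smoothed-Otsu detection bias a few percent small
when the interior intensity distribution is heavy-tailed, which
propagates into density estimates (validated at the ensemble level, ±10%
of truth over 20 seeded movies, rather than per image). The bundling
metric saturates for brightness-only differences, as discussed above.
Track formation (detection and linking) is out of scope — tracks enter
as tables, matching workflows where tracking is done by a dedicated tool
and curated by hand. Catastrophe/rescue statistics, Manders and Costes
co-localization variants, and fiber orientation analysis are not
implemented.
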