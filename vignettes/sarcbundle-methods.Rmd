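---
title: "Methods: regional sarcomere analysis of 2D cardiac muscle bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional sarcomere analysis of 2D cardiac muscle bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Two-dimensional cardiac muscle bundles (2DMBs) are micropatterned,
high-aspect-ratio rectangles (~308 um x 44 um, 7:1) of purified
hiPSC-derived cardiomyocytes on a soft (~8 kPa) substrate. Because the
substrate is compliant, these tissues reach physiologic fractional
shortening, which is precisely what breaks sarcomere *tracking*: z-discs
move in and out of the focal plane and travel several pixels per frame at
100 frames/s. `sarcbundle` therefore never tracks. Every frame is analyzed
independently:

1. **Detection** — a difference-of-Gaussians (DoG) band-pass at the z-disc
   scale, thresholded at a quantile of the positive response, followed by
   8-connected components. Components above a minimum area become z-discs
   with intensity-weighted centroids and second-moment orientations.
   Z-discs are paired into sarcomeres when their separation lies in the
   physiologic gate (1.0-3.0 um by default) and the connecting vector is
   perpendicular (within 30 degrees) to both stripes; each disc keeps its
   two best-scoring partners and only mutual acceptances survive. The
   score favors lengths near the frame's median candidate length,
   penalized by angular misalignment; equal scores break toward the
   partner with the smaller (row, col).
2. **Segmentation** — background noise is estimated from a small corner
   patch (mean, sd over a 20 x 20 px region by default); pixels below
   `mean + 3 sd` are zeroed; the image is Gaussian-blurred (sigma = 2 px),
   binarized with Otsu's threshold, and the convex hull of the foreground
   and its minimum-area rotated rectangle define the tissue boundary.
3. **Partitioning** — each sarcomere midpoint is projected into the
   rectangle's frame; the longitudinal coordinate bins into left / center
   / right thirds, the transverse coordinate into top / bottom halves
   (half-open bins, last bin closed, so boundary points are
   deterministic). The u = 0 end is anchored at the rectangle end with the
   smaller column coordinate so labels are stable across frames; which
   physical end is "left" is an arbitrary but consistent convention.
4. **Denoising** — the per-frame average sarcomere length of a region is a
   noisy quasi-periodic signal. A Gaussian process with the sum kernel
   Periodic + RBF + Matern (nu = 2.5) plus an observation-noise term is
   fitted by maximizing the marginal likelihood; the posterior mean is the
   denoised signal and `sd(raw - denoised)` is the reported noise level.
5. **Phase detection** — the denoised signal is mean-centred; in each
   positive block the high-value zone (samples above 80% of the block
   peak) is searched inward until the Savitzky-Golay derivative falls
   below a user-set threshold, which delimits the relaxed plateau; the
   minimum inside the following negative block is the peak contraction;
   the next plateau's start is the relaxation end.
6. **Features** — 35 structural and functional metrics per (movie,
   region), and a paired baseline-vs-treated comparison (percent change of
   the mean and a two-sided paired t-test).

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `band_sigma_narrow` / `band_sigma_wide` | 1 / 2.5 | px | band-pass matched to ~1 px stripe cross-sections; the wide scale stays below the minimum stripe spacing so adjacent z-discs are not merged |
| `zdisc_threshold_quantile` | 0.6 | — | median-level thresholds admit noise blobs when the tissue contracts and the stripe response weakens; 0.6 was stable across spacing and noise in the generator's range |
| `min_zdisc_area` | 20 | px^2 | a real z-disc spans the myofibril width; sub-um^2 components are noise |
| `min_sarc_len` / `max_sarc_len` | 1.0 / 3.0 | um | physiologic sarcomere range |
| `angle_tolerance` | 30 | deg | sarcomere axis vs stripe normal |
| `noise_k` | 3 | — | suppression threshold `mean + k sd` of the background patch |
| `blur_sigma` | 2 | px | bridges the stripe gaps so Otsu sees tissue vs background, not stripe vs gap |
| `high_zone_fraction` | 0.80 | — | plateau candidate zone within a positive block |
| `derivative_threshold` | 0.1 | um/s | plateau flatness; user-set in principle, the default keeps the CLI runnable |
| `sg_window` / `sg_polyorder` | 11 / 3 | samples / — | ~0.1 s window at 100 fps, cubic: preserves ramps exactly, suppresses sample noise |
| `max_zdiscs_per_frame` | 1500 | count | the documented failure mode floods frames with several thousand false positives while a real tissue holds O(10^2); the cap sits between the regimes |

GP hyperparameters (output scales, lengthscales, period, observation
noise) are fitted per signal. Initialization: the period starts at the
dominant FFT peak of the mean-centred signal, lengthscales at a quarter
period, output scales split the signal variance equally, and the noise
scale starts at `sd(diff(y))/sqrt(2)`. Optimization is L-BFGS-B on
log-parameters with analytic gradients (max 300 iterations, relative
tolerance 1e-5); the period is bounded to [1/3, 3] times its
initialization so the optimizer cannot jump to a harmonic. Inputs are
standardized internally and results de-standardized. Fitting is
deterministic, so "seeded" reproducibility is trivially bit-exact.

## Interpretation choices the source left open

* **Kernel composition** — "combines" is read as a **sum** of the three
  components, the standard reading that keeps each component's role
  separable (periodicity, smooth trend, rough local structure). A
  product composition (Periodic x RBF) is available via
  `kernel_config(composition = "product")`.
* **80% zone** — the high-value zone is defined on the **mean-centred**
  signal, because the blocks themselves are defined there.
* **"Searches inward"** — from the zone's left boundary rightward and from
  the right boundary leftward, each stopping at the first sample whose
  absolute derivative is below the threshold: left stop = relaxed start,
  right stop = contraction onset. If no sample qualifies the zone boundary
  is used and the event is flagged (`fallback`).
* **Complete events** — an event needs all four time points away from the
  recording edges. A recording that starts on a plateau truncates the
  first cycle's relaxed start; the final cycle's relaxation end cannot be
  confirmed because its following plateau runs into the recording edge.
  So k recorded cycles yield k - 2 complete events by construction; all
  period and timing statistics use complete events only.
* **Relaxed/peak length percentiles** — computed over the **pooled
  individual sarcomere lengths** of all frames in the phase (percentiles
  of a per-frame mean would be degenerate); the shortening amplitude, by
  contrast, is the difference of the **averaged (denoised) signal** at the
  relaxed and peak states, matching the feature table's phrasing about
  average sarcomere lengths.
* **Contraction period** — mean inter-onset interval of *consecutive*
  complete events, so a skipped beat does not bias it.
* **One GP per region** — hyperparameters are fitted independently per
  region rather than shared; regions genuinely differ in noise because
  they average fewer sarcomeres.
* **Feature count** — the reference metric table enumerates 35 metrics;
  `feature_schema()` documents the one-to-one mapping.
* **Config files** — the CLI round-trips configurations as JSON rather
  than YAML (no YAML parser is available in the supported dependency
  set); the schema is exactly `pipeline_config`.

## The synthetic generator: what it emulates and what it does not

`generate_length_waveform()` produces per-cycle plateau / raised-cosine
descent / raised-cosine ascent sarcomere-length traces (defaults: L0 =
2.0 um, A = 0.3 um, T = 1.0 s, d_c = 0.2 s, d_e = 0.3 s, 100 fps) with
optional i.i.d. Gaussian noise; raised-cosine ramps are C1-smooth so the
GP and derivative stages see physiologic-looking curvature, and a
linear-ramp variant exists for analytic phase tests. `render_movie()`
draws the rotated rectangular tissue with Gaussian-profile stripes
(~1 px cross-section, to avoid aliasing at sub-pixel spacings) whose
center-to-center spacing equals the waveform value, over a uniform
background; the tissue shortens about its centroid along the long axis
only. Intensities default to background 100, diffuse tissue body 370,
stripe peak 1000 on the uint16 scale, with additive Gaussian pixel noise
(the tests use sd = 45, about 5% of the stripe peak); the source data's
intensity statistics are not documented anywhere, so these are the
package's own choices, fixed once.

The generator does **not** emulate: out-of-focus z-disc disappearance,
myofibril-scale disorder (stripes span the full tissue width),
photobleaching, intensity texture, or neighboring tissues in the crop.
A green end-to-end test therefore establishes that the pipeline's
geometry, signal processing and bookkeeping are correct, not that the
detector is robust to every real-world artifact — the QC stage exists
precisely because one such artifact (the z-disc flood) is known and not
yet predictable from video quality.

End-to-end validation movies use a scaled-down tissue
(`geometry_preset("mini")`: 100 um x 30 um at 0.25 um/px, rotated 10
degrees) so a 3 x 3 parameter grid of 5-cycle movies runs in minutes on
one CPU; the full-size preset (`"2dmb"`) exercises the same code paths
and is used in single-frame geometry tests.

## Numerical notes

* Gaussian blur uses reflected boundaries and dense separable operators;
  Otsu uses a 256-bin histogram over the observed intensity range.
* The minimum-area rectangle is found by rotating calipers over hull edge
  directions; the reported angle is the long axis against the column
  axis, mapped to (-90, 90].
* Savitzky-Golay edges are handled by evaluating the first/last window's
  fitted polynomial derivative at the edge positions, preserving
  polynomial exactness everywhere.
* Half-contraction and half-relaxation times use linear interpolation
  between samples; the level is the midpoint of the denoised value at the
  phase's two endpoints, per event.
* The GP adds a 1e-8 jitter to the kernel diagonal; a constant input
  short-circuits to `denoised = constant, noise_level = 0`.
* Degenerate inputs: frames with no above-noise pixels raise a
  `segmentation_failure` condition carrying the frame index (the pipeline
  records it and continues; QC flags the movie if > 10% of frames fail).

## Known limitations

* One tissue per movie; improper crops showing neighboring tissues are
  out of scope (they surface as inflated rectangle dimensions).
* Temporal tracking of individual sarcomeres is deliberately absent.
* The phase heuristic takes the global minimum per negative block; it
  does not model notched (multi-peak) contractions or alternans.
* GP fitting is exact (dense Cholesky), O(n^3) per signal; signals of a
  few thousand frames are fine, hour-long recordings are not.
* The z-disc flood failure is detected post hoc, not predicted.
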