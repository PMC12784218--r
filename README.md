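# sarcbundle

Regional sarcomere detection and contractility analysis for 2D cardiac
muscle bundles (2DMBs).

## What problem this solves, and for whom

2DMBs are micropatterned rectangles (~308 μm × 44 μm) of purified
hiPSC-derived cardiomyocytes beating on a soft (~8 kPa) substrate. With an
α-actinin fluorescent reporter, z-discs appear as bright stripes and every
sarcomere in the tissue is resolvable in high-frame-rate (100 fps) movies.
These tissues reach physiologic fractional shortening — which is exactly
why sarcomere *tracking* pipelines fail on them: z-discs drift out of
focus and move several pixels per frame. `sarcbundle` is for cardiac
tissue-engineering and disease-modeling labs that need automated,
high-throughput readouts of sarcomere structure and contractile function
from such movies, including *regional* heterogeneity within a tissue, and
paired drug-effect statistics across many tissues.

## The method in brief

Each frame is processed independently (no temporal tracking):

* **Z-disc detection**: difference-of-Gaussians band-pass → quantile
  threshold → connected components → intensity-weighted centroids.
  Z-discs pair into sarcomeres when their separation `ℓ` satisfies
  `ℓ_min ≤ ℓ ≤ ℓ_max` (default 1–3 μm) and the pair vector is ⊥ to both
  stripes; mutual-best acceptance.
* **Tissue segmentation**: noise suppression at `μ_bg + k·σ_bg`, Gaussian
  blur, Otsu threshold, convex hull, minimum-area rotated rectangle.
* **Partitioning**: sarcomere midpoints map to longitudinal thirds
  (left/center/right) and transverse halves (top/bottom) of the rectangle.
* **Denoising**: per-region average-length signal `ȳ(t)` is smoothed by GP
  regression with the sum kernel
  `k = k_Per + k_RBF + k_Matérn(ν=5/2) + σ_n²δ`, hyperparameters fitted by
  marginal-likelihood maximization; the posterior mean is the denoised
  signal and `noise_level = sd(raw − denoised)`.
* **Phase detection**: on the mean-centred denoised signal, each positive
  block's relaxed plateau is found by searching inward from the 80%-of-peak
  zone until the Savitzky–Golay derivative `|dℓ/dt|` drops below a
  threshold; the minimum of the following negative block is peak
  contraction. The three time points delimit relaxed, contraction and
  expansion phases.
* **Features**: 35 metrics per (movie, region) — counts, period/frequency,
  relaxed/peak sarcomere-length distributions, shortening amplitude,
  shortening/lengthening velocities, seven timing intervals, tissue
  geometry, sarcomere densities, noise level (`feature_schema()` documents
  each) — plus paired baseline-vs-treated comparison
  (Δ% of the mean and a paired t-test).

A synthetic movie generator (`simulate_movie()`) renders a rotated striped
tissue following a prescribed contraction waveform with known ground
truth, so the whole pipeline is testable without external data.

## Worked example

```r
library(sarcbundle)

# simulate a 5-beat movie of a small bundle (ground truth: L0 = 2.0 um,
# A = 0.4 um, T = 1.0 s)
params <- waveform_params(resting_length = 2.0, amplitude = 0.4,
                          period = 1.0, contraction_duration = 0.2,
                          expansion_duration = 0.3, n_cycles = 5,
                          fps = 100, noise_sd = 0.01)
sim <- simulate_movie(params, geometry_preset("mini"), seed = 3,
                      pixel_noise_sd = 45)

config <- pipeline_config(um_per_px = 0.25, fps = 100,
                          regions = c("whole", "thirds"), seed = 1)
res <- run_pipeline(sim$frames, config)

print(res$features[, c("region", "number_of_contractions",
                       "contraction_period", "shortening_amplitude",
                       "relaxed_SL_mean", "peak_shortening_velocity")],
      digits = 4)
print(res$qc$flags)
```

prints

```
  region number_of_contractions contraction_period shortening_amplitude
1  whole                      3              0.995               0.3971
2   left                      3              1.000               0.3975
3 center                      3              1.000               0.3989
4  right                      3              0.995               0.3964
  relaxed_SL_mean peak_shortening_velocity
1           2.007                    3.104
2           2.008                    3.121
3           2.005                    3.195
4           2.008                    3.092
          zdisc_flood     count_instability segmentation_failures 
                FALSE                 FALSE                 FALSE 
```

Reading this: of 5 simulated beats, the 3 interior ones are complete
events (the first and last are truncated by the recording edges); the
recovered period (0.995–1.000 s vs true 1.0 s), shortening amplitude
(0.396–0.399 μm vs true 0.4 μm) and resting sarcomere length (2.005–2.008
μm vs true 2.0 μm) match ground truth to ≤1%, per region. The peak
shortening velocity ≈ 3.1 μm/s matches the closed form πA/(2·d_c) =
3.14 μm/s for the raised-cosine descent. No QC flag is raised, so the
movie would enter paired comparisons.

Drug-effect statistics on two feature tables:

```r
paired_comparison(baseline$shortening_amplitude,
                  treated$shortening_amplitude)
# $delta_pct 25, $t_statistic 8.66, $p_value 0.0131, $n 3
```

## Command line

```sh
Rscript -e 'sarcbundle::main_simulate()' --out sim_dir --preset 2dmb --seed 1
Rscript -e 'sarcbundle::main_analyze()'  sim_dir/movie.tif --um-per-px 0.25 \
        --fps 100 --regions whole,thirds --out results_dir
Rscript -e 'sarcbundle::main_compare()'  --baseline a/features.csv \
        --treated b/features.csv --feature shortening_amplitude
```

(equivalently `Rscript inst/scripts/analyze.R ...` from a source
checkout). Movies are multi-page TIFF stacks or directories of per-frame
TIFFs; ND2 must be converted upstream. Config files (`--config`) are JSON
and round-trip the full `pipeline_config` schema.

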