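# qibcdeg

Quantitative image-based cytometry (QIBC) and kinetics for nuclear
protein degradation studies, built around the computations used to find
and characterize cell-cycle-coupled degradation of nuclear cGAS.

High-content microscopy turns every nucleus in a well into a data point:
a DAPI mask defines the nucleus, a dilated ring samples the surrounding
cytoplasm, and background-corrected mean (MFI) and integrated
fluorescence intensities are recorded per cell. `qibcdeg` implements the
full analysis arc on top of that representation:

- **Synthetic data with ground truth** — seeded generators for cell
  populations, rendered multichannel fields (16-bit TIFF), arrayed
  siRNA screen plates, cycloheximide chase time courses and bio-layer
  interferometry (BLI) sensorgrams, each exporting the truth used to
  generate it.
- **Segmentation and features** — Otsu threshold, hole filling and
  distance-transform watershed for nuclei; cytoplasmic ring masks;
  per-image lower-quartile background subtraction.
- **Cell-cycle gating** — DNA content from integrated DAPI with 2N/4N
  peaks fitted by EM (two Gaussians plus a uniform S-phase bridge),
  EdU gating for S phase, a DAPI-MFI (or H3pS10) gate for mitosis, and
  per-phase summaries with ANOVA / Šídák-adjusted contrasts.
- **Screen scoring** — three-anchor plate normalization: with control
  means c₋ (reporter-targeting siRNA), c₀ (negative control) and c₊
  (proteasome inhibitor), a well's score is
  `(x − c₀)/(c₀ − c₋)` below c₀ and `(x − c₀)/(c₊ − c₀)` above, so the
  anchors land at −1, 0, +1; hits deviate from the negative-control
  mean by more than 3 s.d.
- **Decay kinetics** — nearest-centroid nucleus tracking, per-track
  relative MFI, PCNA diffuse/punctate classification for G1→S / S→G2
  timing, and log-linear fits of `N(t) = N₀·e^(−kt)` giving half-lives
  `t½ = ln 2 / k`.
- **Binding kinetics** — global 1:1 Langmuir fits of BLI sensorgrams
  (shared `kon`, `koff`, `Rmax` across concentrations; `Kd = koff/kon`).

## Worked example

Score a simulated 972-gene screen with one planted stabilizer of the
reporter, then fit a sub-micromolar binding interaction:

```r
library(qibcdeg)

design <- screen_design(effect_map = c(gene0042 = 0.45))
scr    <- simulate_screen_plates(design, seed = 7)
wells  <- anchor_normalize(scr$wells)
hits   <- call_hits(wells, k_sd = 3)
head(hits$genes[hits$genes$hit, ], 3)
#>         gene n_wells n_hits_up n_hits_down mean_score  hit direction
#> 1   gene0042       3         3           0 0.47775480 TRUE        up
#> 24  gene0651       3         1           0 0.05472891 TRUE        up
#> 266 gene0366       3         1           0 0.01113632 TRUE        up

sg <- simulate_sensorgrams(kon = 1e5, koff = 3.52e-2,
                           concentrations = c(88, 176, 352, 704, 1408) * 1e-9,
                           noise_sd = 0.002, seed = 7)
fit_1to1(sg)
#> 1:1 Langmuir binding fit (4505 observations)
#>   kon  = 1.001e+05 /M/s
#>   koff = 0.03522 /s
#>   Kd   = 3.518e-07 M (352 nM)
#>   rmax = 0.9998 RU, rss = 0.01779
```

The planted gene tops the ranked list with all three siRNA wells called
in a consistent direction (the two trailing single-well calls are the
expected false positives of a 3-s.d. gate over ~2,900 wells), and the
global fit recovers the planted 352 nM affinity from the noisy
sensorgrams. A chase fit works the same way:

```r
cd <- simulate_chase(chase_truth(rate_k = log(2) / 3, noise_cv = 0.05),
                     seed = 7)
fit_exponential_decay(cd$time_h, cd$value)
#> Exponential decay fit (4 points)
#>   n0        = 105.3 AU
#>   rate k    = 0.2491 / h
#>   half-life = 2.783 h
#>   r^2 (log) = 0.9915
```

Four time points with 5% noise recover the planted 3 h half-life to
within ~10%; the package tests show the median over many replicates is
accurate to well under 1%.

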