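---
title: "Models and methods behind qibcdeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind qibcdeg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the assumptions behind its synthetic-data generator, and the design
choices made where more than one reasonable option existed. It states
no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

# The measurement model

Quantitative image-based cytometry (QIBC) reduces a multichannel field
to one row per nucleus. The nuclear mask comes from the DAPI channel;
a cytoplasmic ring — an annulus starting `gap` px outside the nucleus
and `width` px thick (defaults 1 and 5) — samples cytosolic signal.
Per channel the package records the mean intensity over the mask (MFI),
the integrated intensity (sum; identically MFI × area), and the ring
MFI. The per-image background is the 25th percentile of all pixel
intensities (linear-interpolation percentile over the whole field, not
per object), subtracted from the means and floored at zero. This makes
corrected MFI exactly invariant to adding a constant to every pixel, a
property the tests assert.

The original analyses drew the cell border from a digital
phase-contrast channel; no such channel exists here, so the ring is the
standard dilation-based surrogate. Contested ring pixels between
neighbouring cells go to the nucleus with the nearest centroid, ties to
the lower label, and rings never overlap any nucleus.

## Segmentation

`segment_nuclei()` applies a global Otsu threshold, fills holes, and
splits touching nuclei by a distance-transform watershed
(`ws_tolerance`, default 1, is the minimum basin depth). Components
outside an area window (default 80–5000 px at the synthetic scale) are
dropped, as are border-touching nuclei by default, and labels are
renumbered 1..K. Coordinates are R-native: 1-based matrix indices,
rows = y. On noiseless rendered fields the masks are pixel-exact up to
the thresholded disk boundary; the acceptance checks require per-nucleus
Jaccard ≥ 0.95 against the truth mask and an exact count.

# Cell-cycle gating

DNA content is the integrated DAPI intensity; its log-scale histogram
has a 2N peak (G1), a 4N peak (G2/M), and a plateau between them from
replicating cells. `fit_dna_gates()` fits this structure by EM with two
Gaussian components plus a *uniform bridge* supported on (μ1, μ2),
initialized at the two strongest kernel-density modes. The bridge term
matters: a plain two-Gaussian fit lets S-phase cells drag both means
inward and biases the 4N/2N ratio a few percent low, while the bridge
model keeps the peaks on the summits and reduces to a plain mixture
when no bridge exists. Windows sit at peak ± 2.5 component-sd in log
space; a 4N/2N ratio outside [1.7, 2.3] flags the fit `degraded`, and
an effectively unimodal input duplicates the single peak rather than
erroring. EM non-convergence (rare; monotone likelihood with a 1e-8
stopping tolerance, 200 iterations) falls back to the KDE modes with a
warning. At least 50 cells are required, 200+ recommended.

Phase calls follow the marker logic with S-phase precedence: EdU above
its threshold is S regardless of DNA content (an early-S cell near 2N
is S); otherwise the 2N window gives G1; inside the 4N window, mitosis
is split from G2 by DAPI MFI above its threshold (condensed chromatin
raises the *mean* DAPI signal at roughly constant integrated signal),
overridden by an H3pS10 channel when one is supplied. Everything else
is `unclassified` — reported, excluded from summaries. Both the EdU
threshold (Otsu on log EdU) and the M threshold (Otsu on DAPI MFI
restricted to the 4N window) are histogram-based and therefore
equivariant under rescaling all intensities, so phase calls are
scale-invariant; the Otsu variant used here operates on arbitrary
numeric vectors over 256 bins.

Per-phase summaries report mean, sd and the mean relative to a
reference phase (G1 by default). `condition_contrast()` compares
conditions per phase: ratio of means with a seeded bootstrap CI (2000
resamples by default), a one-way ANOVA p-value, and pairwise Welch
tests adjusted by the Šídák formula `1 − (1 − p)^m` over the pairwise
family — two-sided throughout.

# Screen scoring

Plates carry eight control wells: two negative-control siRNA wells
(anchor 0), two reporter-targeting siRNA wells (anchor −1) and four
proteasome-inhibitor wells (anchor +1). With control means c₋ < c₀ <
c₊, the score of a raw well intensity x is piecewise linear and
continuous at 0:

    score(x) = (x − c₀)/(c₀ − c₋)   if x < c₀
             = (x − c₀)/(c₊ − c₀)   otherwise

Three non-collinear anchor points cannot be satisfied by one linear
map, hence the two slopes. The normalization is exactly invariant to
any positive affine transform of a plate's raw intensities, and maps
the control means themselves to exactly −1/0/+1 — note that the *mean
of the negative-control scores* is not exactly 0 under a kinked map,
because those wells straddle their own anchor; the exactness property
lives at the means.

Two choices here deserve justification:

- **Anchor pooling (`per`)**: anchors are pooled across the experiment
  by default rather than per plate. With only two negative wells per
  plate, per-plate anchors add noise of σ/√2 to every score on the
  plate (σ = well noise) and, worse, couple each negative well to its
  own anchor, so negative-control scores under-disperse relative to
  sample scores by the factor √((n₀−1)/(n₀+1)) and the score null
  acquires non-Gaussian tails. Experiment-wide anchors keep the score
  an affine image of the raw intensity. `per = "plate"` remains
  available for screens with genuine plate-to-plate drift, where the
  bias trade-off reverses.
- **The "3 s.d." scale (`scale_from`)**: hits are wells whose score
  deviates from the *negative-control mean* by strictly more than
  `k_sd` (default 3) standard deviations. The scale is, by default, a
  robust MAD-based s.d. of the *sample-well* scores: in an arrayed
  screen nearly all siRNAs are inert, so the sample MAD estimates the
  null spread precisely (thousands of wells) and robustly (insensitive
  to true hits), whereas the literal s.d. of the few dozen
  negative-control wells is noisy and, under per-plate anchoring,
  systematically deflated — enough to push a nominal 3-s.d. gate to a
  several-percent false-positive rate. `scale_from = "negative"`
  applies the literal reading. With the defaults, the acceptance run
  checks that a null screen of 10,200 wells yields a two-sided hit
  fraction consistent with 2·Φ(−3) ≈ 0.27% and that planted ±6 s.d.
  effects are recovered with ≥ 95% power.

Gene-level calls require `hits_required` (default 1) of a gene's siRNA
wells flagged in a consistent direction. MFI is the gated statistic;
the integrated-intensity score is computed and reported but not gated.
Wells under `min_cells` (default 50) are flagged and excluded from
anchor and scale estimation but kept in reports.

# Decay and binding kinetics

**Tracking.** Nuclei in time-lapse data move little, so linking is
greedy nearest-centroid: candidate (track, detection) pairs are taken
in order of increasing distance (ties by lower track id, then lower
detection label), pairs beyond `max_disp` (default 20 px) are refused,
unmatched detections open tracks, unmatched tracks end. On two-object
crossing paths the tests verify agreement with the exhaustive
minimum-cost assignment.

**Relative MFI.** Each track is normalized to a reference frame
(`relative_mfi[ref] = 1`), the first post-mitotic frame by default —
the caller supplies the anaphase frame when known, otherwise the first
frame of the track is used. Normalizing to a population mean instead
is a one-line alternative the interface deliberately does not hide
behind.

**PCNA patterns.** Replication foci make PCNA punctate in S phase. The
granularity score is `(P99 − median)/median` of in-mask intensities
after Gaussian smoothing (σ = 1 px); crops scoring strictly above 1.0
are punctate. The thresholds are this package's operationalization of
a call originally made by eye, and both are configurable. G1→S is the
first frame opening a run of ≥ `min_run` (default 3) punctate frames;
S→G2 the first frame of the subsequent diffuse run; shorter flickers
are ignored. Frame indices are 1-based.

**Chase fits.** `fit_exponential_decay()` regresses log abundance on
time — closed-form, robust, and exact for a noiseless exponential,
which is the right trade-off for 4-point chase series; a nonlinear
refinement on the natural scale is available via `refine = TRUE`.
Increasing series clamp the rate to 0 (half-life ∞) with a warning
rather than reporting a negative rate.

**BLI fits.** The standard 1:1 Langmuir model is fitted globally
across concentrations with shared kon, koff and Rmax: association
`R(t) = Req·(1 − e^(−(kon·C + koff)t))` with
`Req = Rmax·C/(C + Kd)`, dissociation decaying from the
end-of-association response at rate koff. Fitting is
Levenberg–Marquardt on log parameters from a 3×3 multi-start grid
(kon ∈ 10^{4..6} /M/s, koff ∈ 10^{-3..-1} /s), best residual sum of
squares wins. Rows with negative time are treated as pre-association
baseline and their mean subtracted; no drift term is modelled.
Dissociation-only input fits koff alone and reports kon (hence Kd) as
NA with a warning. Timing defaults mirror the assay: 300 s
association, 600 s dissociation.

# The synthetic-data generator

The generator exists so that every stage can be tested against known
truth; its defaults define the conditions under which the package's
claims are verified.

- **Nuclei** are hard disks on a uniform background with additive
  Gaussian read noise, clipped to 16 bits. No point-spread function,
  no camera noise model beyond Gaussian, no illumination gradient by
  default (a linear `shading` term exists to stress background
  correction). DAPI mean level is constant through interphase and disk
  *area* scales with DNA content, so integrated DAPI tracks genome
  equivalents; mitosis shrinks the radius by 0.7 and raises the mean
  by 1/0.7² (condensed chromatin), which is what makes the DAPI-MFI
  M-gate exercisable. EdU is lognormal-high in S and low elsewhere;
  nuclear cGAS-GFP declines from G1 (500 AU) through S (350) and G2
  (250) to M (200), with a constant cytosolic level (150) painted as a
  concentric disk so rings have something to measure. DNA content is
  2·e^N(0,0.05) in G1, 4·e^N(0,0.05) in G2/M, uniform on (2.1, 3.9) in
  S.
- **Screens** are generated in anchor-score space — true effect plus
  Gaussian well noise, controls around −1/0/+1 — and mapped to raw
  intensities through the inverse of the normalization, so a gene's
  expected score equals its planted effect by construction. Well noise
  defaults to 0.05 anchor units: a well averages ~900 imaged cells, so
  the CV of its mean MFI is a few percent, and the negative-to-
  epoxomicin anchor gap is half the baseline raw level. The default
  raw anchors (120/240/360 AU) are equidistant — reporter knockdown
  roughly halves the baseline well MFI and proteasome inhibition adds
  half — which makes the two normalization slopes coincide and the
  null score distribution exactly Gaussian; with strongly asymmetric
  anchors the kinked map gives the two sides of the null different
  scales, and a single two-sided k-s.d. gate is then only
  approximately calibrated. The well-to-well variance structure of the
  original screen is unknown; these are declared free parameters, not
  estimates of it.
- **Chases** are `N₀·e^(−kt)·(1 + ε)`, ε ~ N(0, cv), on the 0/2/4/6 h
  grid; **sensorgrams** follow the 1:1 model above with additive
  Gaussian noise.

Every generator takes an integer seed and is bit-reproducible; with
all noise at zero, the downstream modules recover generator parameters
exactly (to numerical tolerance), which the tests assert for phases,
screen effects, decay rates and binding constants.

# Problem sizes and numerical conventions

The test suite and acceptance script run at sizes chosen to give tight
statistical checks in seconds: 5,000-cell populations for gating
(fraction recovery to ±0.03, peak ratio to ±0.05), a 10,200-well null
screen for hit-rate calibration (binomial 95% envelope around
2·Φ(−3)), 500 chase replicates (median rate error ≤ 2% at cv 0.05), a
five-point Kd grid from 50 nM to 5 μM (median error ≤ 5% at 1% noise),
and 40-nucleus 900×900 fields for segmentation. Strictness
conventions: hit calling and PCNA classification use strict
inequalities at their thresholds; the Kd–rate identity
`Kd = koff/kon` is exact by construction; watershed ties and ring
ownership ties break to the lower label.

# Limitations

Disks on flat backgrounds do not probe segmentation against textured
chromatin, overlapping cells in 3-D, or debris; passing the
segmentation oracle here shows mask arithmetic and splitting logic are
correct, not that the pipeline is robust to real micrographs.
Cell-cycle gating assumes a bimodal DNA histogram from an unperturbed
cycling population; arrest phenotypes that empty one peak will be
flagged `degraded` rather than gated. The screen model has no spatial
plate effects (no edge effects, no B-score correction — deliberately
out of scope), and the hit rule treats wells as exchangeable.
Tracking has no division handling or lineage reconstruction, and
photobleaching is assumed absorbed by the relative normalization. The
BLI model excludes mass-transport limitation and heterogeneous-ligand
kinetics.
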