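---
title: "Methods: simulating and quantifying tagged psoralen crosslinks on DNA fibers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying tagged psoralen crosslinks on DNA fibers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberglow)
```

## What the package models

The DNA fiber assay spreads lysed-cell DNA on glass so that individual
stretched molecules can be immunostained and measured. In the
experiment this package models, cells are prelabeled with CldU for
24 h (so every fiber is continuously stained end to end), treated with
digoxigenin-tagged trimethylpsoralen (Dig-TMP) and photoactivated with
UVA — either with a lamp, which exposes whole nuclei, or with a
365-nm laser restricted to a rectangular region of interest — then
pulsed with IdU for 1 h to mark ongoing replication. Each Dig-TMP
adduct (mostly interstrand crosslinks, ICLs) is visualized as a single
quantum-dot spot on the fiber.

Three kinds of quantities are measured per experiment: the fraction of
fibers carrying at least one Dig-TMP signal; the signal density per
10³ kb of fiber; and, on fibers with both signals and IdU tracts, the
classification of each replication encounter as single-sided (a tract
abutting one side of the adduct — a fork stalled at the ICL) or
double-sided (tracts on both flanks).

## The generator: model and assumptions

`simulate_fibers()` draws a ground-truth population; everything
downstream can be validated against it.

**Fiber lengths.** No length distribution is published for these
spreads, so the default is a package choice and stays configurable: a
lognormal with mean ≈ 300 kb (sdlog 0.45), truncated by resampling to
30–700 kb. The mean is anchored to the published per-fiber counts: at
the lower dose, roughly 0.7–0.8 signals per fiber were scored at a
density of 2.69 per 10³ kb, which implies fibers of about 300 kb on
average. Truncation by resampling leaves per-kb densities unbiased.
The ceiling keeps every fiber inside the rendered field of view; a
fiber longer than the usable image width raises an explicit error
rather than being clipped silently.

**Adduct placement.** Adducts follow a piecewise-constant-rate Poisson
process along each fiber. Psoralen reacts preferentially with
accessible chromatin, so a single contiguous "accessible" zone covering
30% of the fiber (uniform random offset) reacts at 4× the rate of the
remainder; the two rates are scaled so the length-weighted mean equals
the configured `adduct_rate`. This is the simplest model that produces
clustering without point hotspots, consistent with the observation that
signals do not pile up at discrete sites. Setting `rate_ratio = 1`
recovers the homogeneous process, under which inter-adduct gaps are
exponential with mean 10³/λ kb — a property the test suite checks with
Kolmogorov–Smirnov tests across seeded runs. Each adduct is an ICL with
probability 10/11, matching the 10:1 ICL:monoadduct ratio established
chemically for this compound; the imaging cannot distinguish the two,
so the pipeline counts "signals" and the kind label exists in ground
truth only for validation.

**Dose calibration.** The two treatment concentrations are represented
purely as two density calibrations — 2.69 and 4.48 signals per 10³ kb,
the published per-experiment means — with no dose–response model.

**Replication encounters.** Each adduct independently receives an
adjacent replication event with probability `encounter_fraction`
(default 0.5, a package choice: roughly half of signal-bearing fibers
in the published fields show adjacent replication). The event is
single-sided with probability 0.15, else double-sided, the published
split. Tract lengths are lognormal with mean ≈ 36 kb (a fork moving at
~0.6 kb/min over the 1-h IdU pulse, within the range commonly measured
in fiber assays), truncated to 4–150 kb. Tracts abut the adduct
position exactly; they are clipped to the fiber and truncated so they
never approach a *different* adduct closer than `neighbor_guard_kb`
(3 kb). That guard is what makes ground-truth classification exactly
recover the generator's per-adduct event labels whenever the
classification adjacency tolerance is smaller than the guard. An
adduct too close to a fiber end (or to a neighbor) for a requested side
degrades double→single or single→none and is flagged in ground truth.
Independent "distant" tracts, unlinked to any adduct, are added with
probability 0.2 per fiber and placed at least a guard away from every
adduct.

**Lamp versus laser.** The two photoactivation modes share the same
per-fiber adduct law — the package's encoding of the finding that
adduct distributions barely differ between light sources. Laser mode
differs only in metadata and in that just a configurable fraction of
fibers (default 0.25, representing the harvested region-of-interest
cells) carries adducts at all. The test suite verifies that spacing
distributions from the two modes pass a same-distribution test in at
least 90% of seeded runs.

## Rendering

`render_images()` converts kb to pixels via two constants: the pixel
scale (0.16 µm/pixel, the published value) and the fiber stretching
constant (2.59 kb/µm, the widely used value for conventionally spread
fibers — the source experiment never states one, so it is a recorded
design decision and appears in every output header). Fibers are laid
out in lanes as smooth curves with bounded curvature (a mean-reverting
random-walk heading with a pull toward the lane center), which
guarantees a minimum separation; the CldU channel carries the whole
fiber, the IdU channel only tract arc-segments, and each adduct
deposits a point mass in the quantum-dot channel at its mapped arc
position. All channels are blurred with a Gaussian PSF (σ = 1.2 px),
then background (120 counts), Poisson shot noise and Gaussian read
noise (σ = 6) are added and intensities quantized to 16-bit counts.
Default gains give quantum-dot peaks ≈ 22 background SDs above
background — bright, photostable spots are the point of quantum dots.
Pixel ground truth (fiber paths, spot coordinates) is emitted
alongside for validation.

What the renders deliberately do not emulate: fiber crossings are off
by default (a layout knob exists to create them for testing the
exclusion rule), there is no quantum-dot blinking, no spectral
bleed-through, no uneven illumination, and no debris. Passing tests on
these renders therefore show that the analysis is correct *given* its
detection model, not that it is robust to every real-microscopy
artifact.

## The image analysis

**Tracing.** The CldU channel is lightly smoothed, thresholded at 4
robust (median/MAD) background SDs, morphologically closed, and
skeletonized with Zhang–Suen thinning. Three amendments were needed to
make the textbook algorithm reliable on curvilinear strokes: deletion
candidates are confirmed sequentially against the current image state
(pure parallel deletion disconnects two-pixel diagonal staircases); a
pixel whose only two neighbors are mutually adjacent is treated as a
line tip and never deleted (otherwise staircase ends erode one pixel
per pass without bound); and each iteration ends with a
Hilditch-simple-point cleanup that reduces two-pixel diagonal bands —
which Zhang–Suen cannot thin — to unit width. Short spurs terminating
at branch points are pruned as thinning artifacts. Any component still
containing a branch point (Hilditch crossing number ≥ 3) is a fiber
crossing: it is discarded entirely and counted, matching conservative
manual scoring; nothing is split. Components are ordered into paths by
a double breadth-first search (the graph diameter), smoothed with a
5-px running mean to remove digitization staircase bias, and extended
past both tips along the local tangent up to the half-height crossing
of the ridge intensity — the point where a blurred line end truly
stops — recovering the few pixels thinning retracts. Arc length ×
0.16 µm/px × 2.59 kb/µm is the fiber length in kb; traces under
30 kb are discarded as debris, and traces touching the field border
are flagged `edge_touching` and excluded from statistics (their length
is truncated by the field of view).

**Spot detection and assignment.** Quantum-dot spots are 3×3 local
maxima above background median + 5 robust SDs (SD multiples, not
absolute counts, so the rule survives gain changes), merged within
3 px to the brighter peak, and refined to sub-pixel positions by
intensity-weighted centroids. Each spot is assigned to the trace
minimizing perpendicular distance if that distance is ≤ 3 px — the
package's convention for "on" a fiber, since no published rule
exists — with exact ties discarded and counted rather than guessed;
the arc position of the projection becomes the signal's kb coordinate.

**Tract segmentation.** The IdU intensity profile sampled every 0.5 kb
along each trace is thresholded by Otsu's method per fiber, floored at
the IdU channel's background median + 3 robust SDs — without the floor,
Otsu on a tract-free profile happily splits noise and fabricates
tracts. Supra-threshold runs closer than 1 kb are merged and merged
runs under 5 kb dropped. The operation is idempotent on its own
output.

## Classification

Per signal at position *p*: a tract *end* within ±2 kb marks
replication on the left, a tract *start* within ±2 kb on the right; a
signal lying more than 2 kb inside a tract counts on both sides. Both
sides → `DOUBLE_SIDED`, one → `SINGLE_SIDED`; signals with tracts
elsewhere on the fiber → `TRACT_DISTANT`; then `SIGNAL_NO_TRACT` and
`NO_SIGNAL` complete the five-way partition. A fiber takes the most
advanced state over its signals (DOUBLE > SINGLE > DISTANT), the
most-informative-event rule of visual scoring; per-signal categories
are retained for auditing.

Two choices here deserve their rationale. First, the adjacency window
is symmetric around the signal rather than strictly one-sided: a
detected tract boundary overshoots the true adduct position by a
PSF-sized amount (≈ 1 kb at default calibration), and a one-sided rule
misreads that overshoot as replication past the adduct, flipping true
single-sided events to double-sided; with the symmetric window the
imaging path reproduces ground-truth categories exactly on noise-free
renders. Second, deep embedding counts as double-sided because two
abutting rendered tracts are one contiguous IdU run after blurring —
and because an adduct overtaken by replication on both flanks is
double-sided by definition. The 2-kb default (~5 px) is the package's
quantitative stand-in for "immediately adjacent" visual scoring and is
configurable and reported with results. Signals within the adjacency
tolerance of a fiber end cannot show both sides and are excluded from
encounter proportions as end-censored.

## Statistics

- `chi2_2x2()`: uncorrected chi-squared on a 2×2 table, for
  fibers-with-signal counts between conditions. No continuity
  correction, as a documented convention: for the published counts,
  neither the corrected nor uncorrected variant reproduces the
  published p of 0.114 (both give ≈ 0.17–0.19); the package reports
  its computed value and flags the discrepancy rather than guessing
  the original contingency construction.
- `two_sample_t_summary()`: pooled-variance Student *t* from summary
  statistics, df = n₁+n₂−2. Pooled rather than Welch: with the
  published means/SDs (2.69 ± 0.095 vs 4.48 ± 0.285, n = 3 each)
  pooled gives p ≈ 5×10⁻⁴, consistent with the published "p < 0.001",
  while Welch gives ≈ 6×10⁻³.
- `two_proportion_z()`: the single- and double-sided categories
  partition one sample, so the comparison reduces to a one-sample *z*
  of the double-sided proportion against 0.5. A two-independent-sample
  variant is provided but is not the default.
- `compare_spacing()`: two-sample Kolmogorov–Smirnov plus quartile/mean
  summaries of both spacing distributions.

On pooled published encounter counts (19 single, 118 double) the
proportions are 0.1387/0.8613; per-experiment averaging gives
0.1362/0.8638; the published rounded values are 0.138/0.862. The
pipeline reports pooled values and documents the ≤ 0.003 discrepancy
rather than resolving it. Similarly, the published total fiber counts
"742, 604" conflict with the per-experiment sums (800, 699); pooled
sums are used. No multiple-testing correction is applied anywhere, as
none was applied in the source analysis.

## Numerical and reproducibility choices

All randomness flows from one integer seed through R's default
generator; identical configuration + seed gives bit-identical ground
truth, and `run_pipeline()` writes a manifest with MD5 checksums of
every output. CSVs are comma-separated UTF-8 with kb to three decimals
and a header line recording units and the calibration constants.
Degenerate inputs are explicit: zero fibers is a valid run (stats
skipped with a notice), a flat image yields zero traces with a warning
rather than an error, zero spot detections is a valid outcome, and
configuration errors (negative rates, probabilities outside [0,1],
unknown YAML keys) fail fast with named messages.

## Problem sizes

The shipped tests validate the generator's calibrations on ~10⁴–10⁵
adduct samples, tracing and detection on 1024² fields of ~30 fibers,
and the full image-analysis round trip on 400 fibers (~1.2×10⁵ kb)
across two 2048² fields — sizes at which Poisson sampling error on the
recovered density is ≈ 5–6%, comfortably inside the 10% agreement the
package claims for end-to-end recovery. At these scales the complete
suite runs in a few minutes on one CPU.

## Known limitations

Fiber crossings are discarded, not untangled, so dense fields lose
material; whether the original scoring did the same is unknown — the
exclusion rule is this package's convention. Lengths depend linearly
on the assumed 2.59 kb/µm stretching constant, so densities inherit
any stretching bias of a real spread. The two-zone accessibility model
is deliberately minimal; real chromatin accessibility is continuous
and sequence-dependent. The renderer's noise model is well-behaved
(Poisson + Gaussian); real quantum-dot imaging adds blinking and
antibody background that would lower spot recall below the simulated
values. And the laser mode models only the harvested-cell fiber
mixture, not the nuclear geometry of the irradiated stripe.
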