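---
title: "Quantifying bacterial swimming motility and competitive fitness: models and methods"
author: "swimtracker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacterial swimming motility and competitive fitness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swimtracker)
```

## Scope

Experimental-evolution studies of gut colonization ask whether bacterial
lineages passaged through a host have changed phenotypically: do evolved
isolates swim faster than their ancestor, is a larger fraction of the
population motile, do they outcompete the ancestor inside the host, and do
fluorescent-tag frequencies in serially passaged populations betray
selective sweeps? This package implements the computational side of those
questions as three connected analyses:

1. **Motility** — subpixel particle tracking of swimming bacteria in
   time-lapse movies: spot detection, radial-symmetry localization,
   nearest-neighbor track linking, per-track speeds, motile fractions with
   confidence intervals, and per-flask relative-speed tests.
2. **Competitive fitness** — competitive indices from CFU plate counts of
   two competitors recovered from dissected guts, compared against an
   ancestral control with flask-aware Dunnett contrasts.
3. **Serial passage** — per-passage fluorescent-tag frequencies and a
   simple monotone-change rule for flagging putative sweeps.

Because raw microscopy and plating data are bulky and lab-specific, every
analysis is paired with a synthetic-data generator whose ground truth is
known exactly. The generators are first-class, tested code: they define the
conditions under which the pipeline's statistical behavior is validated.

## The synthetic movie model

`simulateMovie()` emulates bacteria imaged at the bottom interior surface
of a culture flask on an inverted microscope.

**Motion.** Motile cells follow a run-and-tumble walk: a per-cell speed
$v$ drawn once from $\mathcal N(\mu_v, \sigma_v^2)$ truncated at zero, a
heading resampled uniformly at Poisson rate $\lambda$ (`tumbleRate`,
default 1 event/s, a typical run length for flagellated bacteria), and a
displacement of exactly $v\,\Delta t$ per frame. Non-motile cells jiggle by
Brownian motion with diffusion coefficient $D$. Cells reflect at the field
boundary (heading mirrored with the fold), which conserves the cell count
— so track-count assertions against ground truth are exact. The motion
model is deliberately the simplest one with controllable speed; the
contract is only that ground-truth speeds are known, not that the
trajectories are biophysically detailed.

**Default for $D$ (0.02 µm²/s).** The mean apparent speed of a Brownian
walker observed at interval $\Delta t$ is $\sqrt{\pi D/\Delta t}$ — it
*grows* as the frame interval shrinks. At 20 fps, free cytoplasmic-scale
diffusion ($D \sim 0.2$) would give non-motile cells apparent speeds above
3 µm/s, which no operational cutoff could separate from slow swimmers. The
default instead emulates what the assay actually images: non-motile cells
at a flask surface are sedimented or loosely attached and show only a
sub-micrometre jiggle. At $D = 0.02$, the apparent speed is ≈1.1 µm/s,
below the 2 µm/s cutoff — matching the empirical observation that speed
histograms of such movies are bimodal around the cutoff.

**Rendering.** Each cell is an isotropic Gaussian spot of width
`psfSigma` (1.3 px ≈ 0.4 µm at the default 0.325 µm/px — a
diffraction-limited, slightly extended bacterium) with integrated
intensity `spotIntensity` (spec-level brightness is not otherwise
determined by the imaging parameters, so it is an explicit knob), on a
constant background with additive Gaussian read noise; Poisson shot noise
is an optional flag. Additive-Gaussian-only keeps the signal-to-noise
ratio a single interpretable quantity. The rendered spot's integrated
intensity matches the analytic Gaussian integral to well under 1% (the
discrete Gaussian sum and the 4σ truncation each contribute <0.1%).

**Composition.** Exactly `round(nCells * motileFraction)` cells are
motile, rather than a Bernoulli draw per cell. The realized composition
then equals the requested fraction, making the ground truth a sharp oracle
— the binomial sampling the Wilson interval accounts for enters through
which cells are *tracked*, not through the simulation itself.

**What is not emulated.** No chemotaxis (speed, not taxis, is the measured
phenotype), no cell shape or orientation, no focal drift, no
photobleaching, no fluorescence channel crosstalk, no gut spatial
structure. Passing tests therefore show that the pipeline recovers speeds
and fractions from diffraction-limited spots under Gaussian noise and
run-and-tumble motion — not that it is robust to every artifact of real
movies (e.g. dense cell clumps or out-of-focus swimmers).

## Detection

Each frame passes through the sequence *bandpass → threshold →
subpixel localization*.

**Bandpass.** A difference of Gaussians, `bandpassFilter()`, with
`sigmaNoise = 1` px and `sigmaObject = 4` px by default — the standard
particle-tracking convention bracketing the spot scale. Kernels are
truncated at 4σ and renormalized where they overhang the frame edge, so a
constant frame maps to exactly zero everywhere, including borders. The
blur is implemented as separable banded sparse matrix products — several
times faster than FFT filtering at these frame sizes — and is verified in
the tests against an explicit-loop convolution oracle.

**Threshold.** Default is `mean + 4·sd` of each filtered frame, which
adapts to the movie's SNR; an absolute threshold can be supplied instead
(and should be, for noise-only sanity checks, since a pure-noise frame's
4-sd threshold will still pass a handful of smooth noise maxima). Local
maxima closer than `minSeparation = 5` px keep only the brighter peak;
plateau ties resolve to the earlier pixel in column-major order, so
candidate lists are deterministic.

**Radial-symmetry localization.** For a radially symmetric spot, every
image-gradient vector points along a line through the center.
`localizeRadialSymmetry()` computes gradients on the lattice of
pixel-corner midpoints, smooths them with a 3×3 boxcar (zero-padded, as in
the standard formulation — this keeps the estimate exactly equivariant to
integer shifts of compactly supported spots), and solves the 2×2
weighted-least-squares system for the point minimizing the weighted sum of
squared distances to all gradient lines. Weights are $|\nabla I|^2 / d$,
with $d$ the midpoint's distance from the gradient-weighted centroid. On
noiseless Gaussian spots the error is below 0.05 px median and 0.1 px
worst-case over the full subpixel offset range (asserted in the tests), at
a small fraction of the cost of least-squares Gaussian fitting. A flat ROI has no gradient information;
it raises a `localizationUndefined` condition, and `detectStack()` drops
that candidate with a warning. Candidates within half an ROI (default 7×7)
of the border are skipped.

Bright-field movies (dark cells on a light background, used when a strain
cannot be fluorescently tagged) are handled by `invert = TRUE`, which
flips intensities before filtering.

**Coordinates.** The origin is the center of pixel `[1, 1]`; `x`
increases with column, `y` with row; positions are stored in micrometers
as `(index − 1) × pixelSize`; frames are indexed from 1. One convention,
stated once, asserted in tests.

## Tracking

`linkNearestNeighbor()` links consecutive frames greedily,
closest-pair-first, each detection used at most once, links longer than
`maxDisp` forbidden. Greedy mutual-nearest matching is the common meaning
of "nearest-neighbor linking"; the tests bound its difference from the
globally optimal assignment by exhaustive enumeration on 3-particle ×
4-frame instances at realistic geometry (cells tens of micrometers apart
moving ≤0.5 µm/frame), where greedy and optimal agree on >95% of
instances. The default gate of 2 µm at 20 fps is ~1.5× the per-frame
displacement of the fastest plausible swimmer (≈25 µm/s); a rule of thumb
is `1.5 × expected speed × frame interval`. There is no gap closing — a
missed detection terminates a track — and no motion-model prediction.

`filterTracks()` applies the two standard filters in order: discard
tracks shorter than 5 frames; then group surviving tracks whose mean
positions lie within 1.7 µm (the signature of one non-motile cell
repeatedly re-detected as several short tracks) and keep only the longest
per group. Grouping is single-linkage, so chains merge (A–B and B–C within
the radius pull in C even if A–C is not); the pairwise reading of the cull
rule is ambiguous for chains, and single linkage was chosen because it is
deterministic, order-free, and errs toward removing duplicates. Length
ties keep the earlier first frame, then the lower track id. The filter is
idempotent.

## Motility statistics

**Speed** is the mean per-step speed — mean over consecutive frame pairs
of displacement divided by the frame interval — not net displacement over
duration, which systematically underestimates run-and-tumble swimmers.
The choice is explicit in `trackSpeed()` and configurable by computing
something else from `trackPoints()`.

**Motile classification** applies an operational cutoff of 2 µm/s to raw
per-track mean speeds, with no correction for the localization noise
floor; `noiseFloorSpeed()` reports that floor (≈0.3–0.5 µm/s at default
scales) so users can verify it sits well below the cutoff. The motile
fraction's 95% CI is the Wilson score interval (`prop.test`,
no continuity correction): unlike the Wald interval it behaves at
fractions near 0 or 1 with small track counts.

**The counting unit is the track.** After duplicate culling, one track
approximates one bacterium — but only when tracks rarely fragment. On long
movies, fast swimmers repeatedly cross the detection border margin or pass
within the suppression radius of another cell, and each interruption
starts a new track; motile cells are then over-represented in the track
count and the per-track motile fraction is biased upward. This is a
property of the operational definition itself, not of this implementation.
Consequently the package's fraction-recovery validation uses short, sparse
movies (160×160 px, 30 frames, 20 cells) where one track ≈ one cell holds;
the full-length 512×512 px, 600-frame movies are used for speed recovery,
which is insensitive to fragmentation (each fragment estimates the same
per-cell speed). Speed recovery is validated at evolved-like
(8.2 ± 1.2 µm/s) and ancestor-like (5.6 ± 0.5 µm/s) speed distributions at
motile fraction 0.8, three movies per condition.

**Relative speed.** Each flask contributes one ratio (mean mutant speed /
mean ancestor speed, the two strains imaged separately within the same
flask); `relativeSpeedTest()` runs a one-sample, one-tailed t test of the
ratios against 1. Zero-variance ratios (a degenerate but possible input)
return a boundary p-value with a `degenerate` flag rather than an error.

## Competition model and competitive-index statistics

`simulateCompetition()` draws, per flask, a random effect on the
natural-log competitive index ($\mathcal N(0, \sigma_f^2)$), then per gut
a log CI around it ($\mathcal N(\log\mathrm{CI}_\mathrm{true} + b_f,
\sigma_g^2)$), and finally converts to counts: total gut load log-normal
(default median 2000 CFU, a realistic per-gut colonization load),
split binomially at the ratio the gut's CI implies for a 1:1 inoculum;
inoculum triplicates are Poisson around a 1:1 ratio. The two-level design
mirrors how competition assays are replicated (guts nested in flasks) and
makes the true log CI recoverable — the recovery is itself a test.

`competitiveIndex()` implements
$$\mathrm{CI} = \frac{(\mathrm{comp1}:\mathrm{comp2})_\mathrm{gut}}
                     {\overline{(\mathrm{comp1}:\mathrm{comp2})}_\mathrm{inoculum}},$$
with the inoculum ratio the **mean of the per-triplicate ratios** (not the
ratio of summed counts — the phrasing "mean inoculation ratio determined
from the triplicate measurements" fixes this choice). One consequence,
verified in the tests, is that swapping the competitor labels inverts the
CI only up to a small Jensen gap: the mean of ratios of the swapped
triplicates is not exactly the reciprocal of the original mean. A zero gut
count is replaced by 0.5 colonies at the plated dilution (continuity
correction) and flagged `censored` — preserving guts with one-sided
extinction, the strongest outcomes, rather than discarding them; both
counts zero leaves the CI undefined. All displayed CI transforms use log
base 10 (the conventional display scale; configurable by transforming
`ci` directly).

`dunnettVsControl()` is a two-stage analysis: per-flask means of log10 CI
(stage 1) absorb the flask random effect, so flasks are the units of
replication; Dunnett's many-to-one comparison with single-step
multivariate-t adjustment and pooled variance (stage 2, via
**multcomp**) compares each group to the control. With balanced guts per
flask this reproduces the contrast structure of a mixed model with a flask
random effect; under strong imbalance a REML mixed model would weight
flasks differently, and that residual discrepancy is a documented
limitation rather than hidden behavior (a full REML route is out of
scope). Significance stars follow the conventional 0.05/0.01/0.001
thresholds. The test suite estimates the procedure's null familywise
false-positive rate (nominally 5%) and its power to detect a +1 log10
shift with 3 flasks × 10 guts by simulation over seeded replicates.

## Serial-passage model and sweep flagging

`simulatePassages()` alternates deterministic growth with a multinomial
bottleneck. Growth multiplies each tag lineage by `growthFactor` — and by
`growthFactor × (1 + s)` for the lineage carrying a beneficial mutation —
then `bottleneckSize` cells are sampled binomially at the post-growth
frequency. Stochasticity acts only at the transfer, isolating drift at the
step the serial-passage design emphasizes; the growth factor cancels from
frequencies and is kept only for interface completeness. The mutation is
modeled as carried by the whole tagged background from `tMut` onward (the
inference logic of two-tag designs reads a tag's rise as its background
hitchhiking with the sweep), which gives the clean closed form
$\mathrm{odds}_t = \mathrm{odds}_0 (1+s)^{t - t_\mathrm{mut} + 1}$ in the
large-bottleneck limit — verified to within 1% per passage at a bottleneck
of $10^6$. With $s = 0$ the tag frequency is a martingale; over 1000
replicates the mean final frequency sits within Monte-Carlo error of the
founding 0.5.

The default bottleneck of $10^4$ reflects the scale of flask inoculation
in larval-gut passaging (~10³ CFU/ml into ~15 ml); the gut-level founding
population is likely harsher but unquantified, and the parameter is
explicit. Default 20 passages and a 1:1 founding mix match the standard
design.

`tagTrajectorySummary()` flags a putative sweep when a tag's frequency
rises monotonically (non-strictly) by more than 0.30 absolute over a
window of ≥3 consecutive passages with defined frequencies. A passage with
zero total count is undefined and breaks windows — no interpolation. The
0.30/3 defaults are conservative relative to neutral drift at realistic
bottlenecks (flag rate under drift is far below the rate under $s = 0.5$,
a contrast the tests check); both knobs are exposed.

## Numerical choices and degenerate inputs

* Seeds: every generator takes an explicit `seed` and restores the
  caller's RNG state; identical seeds give bit-identical output.
* Validation problem sizes: three 512×512 px, 600-frame movies per speed
  condition; a 3×3 grid (speeds 4/6/8 µm/s × fractions 0.3/0.6/0.9) of 100
  short movies per cell; 250 linking-oracle instances; 100-seed error
  control and 1000-seed neutrality simulations.
* Degenerate inputs are first-class: flat ROIs (condition, candidate
  dropped), single-point tracks (error from `trackSpeed`), zero-variance
  speed ratios (flag), identical flask means (boundary p-values with a
  warning), both-zero gut counts (`NA` with warning), all-degenerate
  inoculum triplicates (error).
* Ties: candidate plateaus (earlier pixel), link distances (then (x, y)
  order), duplicate-cull lengths (earlier first frame, then lower id) —
  all deterministic.

## Known limitations

* Greedy linking can differ from the optimal assignment when two cells
  approach within the gate; identity swaps are not detected.
* The per-track motile fraction is biased upward on long movies by track
  fragmentation (see above); compare fractions only across conditions
  tracked with the same movie geometry.
* The two-stage Dunnett analysis assumes roughly balanced guts per flask.
* The threshold default (`mean + 4·sd`) assumes spots occupy a small
  minority of pixels; dense fields inflate the threshold.
* The original instruments' exact filter kernels, thresholds and linking
  gates are not public; defaults here are field conventions, not claimed
  reproductions of any specific lab's detections.
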