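---
title: "Outline concealment by protruding appendages: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Outline concealment by protruding appendages: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model behind `fringecam`, the
parameters that matter, the numerical choices where the design was genuinely
open, what the synthetic data emulate (and do not), and the package's known
limitations. Every empirical statement here is computed by the test suite or
the `analysis/` scripts; nothing is asserted that the code does not measure.

## The question

An object's outline is one of the strongest cues a visual predator has for
segmenting prey from background. Thin appendages that protrude beyond the
outline — the downy neoptile fringe of a hatchling chick, the setae of a
caterpillar — might conceal that outline by two mechanisms:

1. **Outline diffusion**: the appendages weaken the luminance edge along the
   body contour, so fewer pixels carry a conspicuous contrast.
2. **Luminance transition**: the appendage zone takes on a brightness
   intermediate between body and background, removing the abrupt step.

`fringecam` quantifies both for a simulated observer with receptor-noise
-limited (RNL) achromatic vision.

## The vision model

**Cone catches and luminance.** Images are treated as linear reflectance in
[0, 1] (`to_cone_catch()`; photographs can be linearised with an inverse
2.2-exponent, since camera-specific calibration is out of scope). Luminance
is the mean of the long- and mediumwave catches. Catches are floored at
1/65536 so the logarithms below are always defined.

**Contrast.** The achromatic RNL contrast between catches is
`ΔS = |ln(Qa/Qb)| / ω` with luminance Weber fraction `ω = 0.1`; the
trichromatic form (`delta_s_chromatic()`, Weber fractions 0.05 / 0.07071 /
0.1657) is available and gates the filter on colour images. One ΔS is about
one just-noticeable difference. All logarithms are natural.

**Spatial acuity.** The observer's acuity (cycles per degree) fixes a
minimum resolvable angle `MRA = 1/cpd`; at viewing distance `d` the MRA
footprint on the scene is `d · tan(MRA) · px_per_mm` pixels (3.72 px for
72 cpd at 1300 mm and 11.8 px/mm). Acuity enters as a Gaussian blur of
standard deviation `sigma_per_footprint × footprint`. The published toolbox
this chain emulates does not document its footprint-to-sigma constant, so it
is a single exposed parameter. The package default is **1.0**, selected once
against the published scenario orderings: with constants near 0.5 the blur
cannot mix appendage and background luminance across the ~11 px spacing of
the densest beneficial fringe, and the detectability optimum migrates to
twice the published appendage count. The convolution uses a circular
boundary (FFT), so the image mean is preserved exactly.

**The RNL filter.** Biological early vision removes sub-threshold noise but
keeps — indeed sharpens — discriminable edges. `rnl_filter()` iterates
(default 5 passes) a rank-augmented, threshold-gated smoothing over a disc
kernel (radius 5 px, spatial weights falling linearly to zero over the outer
3 px):

* A pixel whose own sub-threshold cluster (neighbours within 1 ΔS) carries
  at least `min_cluster_frac` of the kernel weight is replaced by that
  cluster's weighted mean — plain edge-preserving smoothing. Neighbours at
  or above threshold never contribute, so suprathreshold boundaries are not
  mixed across.
* A pixel whose own cluster is a minority is a residual level on the flank
  of a blurred suprathreshold boundary. It snaps to the nearer of the two
  dominant extreme clusters (weighted 0.15/0.85 luminance quantiles of the
  kernel), which reconstructs a blurred step back into a step.

Two internal choices deserve comment, because simpler designs demonstrably
fail. A purely gated mean (no snap) freezes the intermediate rings of a
blurred edge — adjacent rings differ by ~2 JND, so no ring ever sees the
plateaus — and the outline never reconstructs; the scenario curves then
invert. A weighted-*median* snap target is a no-op on ramps (monotone
profiles are median root signals). The quantile snap is the smallest change
that actually fulfils the filter's purpose. `min_cluster_frac` defaults to
**0.45**: straight suprathreshold boundaries keep a majority on their own
side (~0.51) and are preserved exactly, while one-to-two-pixel residual
rings snap. The same sweep that fixed the sigma convention fixed this value;
both are ordinary arguments.

## LEIA and the HEI statistic

`leia_stack()` measures, for each in-ROI pixel and each of four orientations
(horizontal, vertical, two diagonals), the luminance ΔS between the two
pixels straddling the focal position at ±1 px (the finest local scale; the
offset is a parameter). Border pixels and out-of-ROI positions are exactly
zero. Post-processing (`postprocess_stack()`) log-transforms the slices,
discards exact-zero positions (the out-of-analysis marker; a genuine in-ROI
ΔS of exactly 0 is discarded with them, a documented conflation kept for
fidelity to the source protocol), clamps negative logs (edge-free areas) to
zero and takes the parallel maximum across orientations.

**HEI pixels.** In every scene analysed, outline pixels form a distinct
high-intensity modal area of the collapsed distribution.
`hei_threshold_from_reference()` finds it with a kernel density estimate:
the antimode (local density minimum) separating the highest-intensity mode
from the rest is the threshold. Numerical choices:

* *Bandwidth*: Sheather–Jones on the nonzero values. The mass clamped at
  exactly zero is a point-mass artefact carrying no shape information, and
  Silverman's sd-based rule spans both clusters of a strongly bimodal
  sample, oversmoothing the valley by an order of magnitude. A floor of
  0.02 × the value range keeps the quantised contrast levels of synthetic
  scenes (a handful of discrete grey-level pairs) from reading as separate
  modes.
* *Mode merging*: adjacent density maxima whose separating valley does not
  dip below half the lower flanking peak are merged, so rasterisation
  ripples do not masquerade as modal areas.
* *Antimode position*: the lower edge of the valley-minimum plateau. In a
  wide empty valley every point separates the modes equally well; the lower
  edge keeps the threshold meaningful as an absolute cut on images whose
  high mode sits below the reference's.

In the proof-of-principle design the share `q` of contour-band pixels above
the antimode is determined once from the zero-appendage reference and reused
as a fixed top-pixel count for every image — the only convention under which
"the same threshold for all images" is well defined. In the paired design
each subject's threshold is an absolute value from its dark-ground
reference crop (`hei_mode = "value"`, the default; `"fraction"` is
selectable, as the printed source protocol is ambiguous between the two
readings).

## The scenario generator

`scenario_spec()` fixes the geometry: disc radius 470 px (printed
circumference 2950 px), appendage length 118 px, thickness 4/8/12 px,
counts 0–512 doubling plus the completely filled stage, transparency 0/25/50
%, two length-heterogeneity profiles, uniform or chessboard (346/86 px)
backgrounds, acuities 72/30/10 cpd. Grey levels are not printed in the
source material; the defaults 0.70 (object) and 0.25 (background) give a
strongly suprathreshold outline (ΔS ≈ 10.3) and are configurable. Rendering
uses hard pixel assignment (no anti-aliasing), so every scene is
bit-reproducible.

Appendages are radial *wedges* whose angular width equals the nominal
thickness at the outline; at the filled stage the wedges tile the circle
exactly. Constant-width strips were implemented and compared: their tip
gaps widen with radius, weakening the re-formation of a boundary at the
appendage tips past the optimum, and the thick-appendage family then loses
its published early optimum. Wedges widen ≤ 25 % at the tip; the analytic
`coverage_fraction()` keeps the nominal line-area law (count × thickness ×
length / annulus area), under which 50 % coverage solves to ~416
appendages. Length-heterogeneity factors are interleaved deterministically
(fractional-rank schedule) rather than randomised, for reproducibility.

## The synthetic paired fixtures

`synth_chick_scene()` emulates the *structure* of the paired-photograph
protocol: a mottled background (band-limited Gaussian noise quantised into
three luminance patches), a textured oval subject clearly lighter than the
ground, a fringe of 2 px strokes protruding 12 % of the canvas side beyond
the outline, outline/feather-boundary masks, a contiguous shadow arc
covering 28 % of the contour band (mirroring the average retained region of
the field protocol), and a reference crop on photographic black (0.02).
Strokes are plumage-coloured, roughly evenly spaced with angular jitter,
0.6–1.0 of the fringe length, and fade from opaque at the base to 25 %
opacity at the tip — downy tips are wispy. The fringe density (0.18 strokes
per perimeter pixel at `fringe_effect = 1`) was calibrated once so that the
fixture effect size mirrors the published field effect (≥ 14/15 subjects
with lower with-fringe mean HEI, mean difference ≈ 0.19); at the 3.7 px
blur the fringe conceals collectively, by raising the luminance just outside
the outline, while each stroke's own side edges *add* edge intensity, so
sparser fringes conceal better than dense collars.

What the fixtures do **not** emulate: real plumage texture and its spatial
correlation with the substrate, UV reflectance, specular highlights,
camera noise, and imperfect masks. Passing fixture tests therefore show the
pipeline's statistical machinery works end to end — not that real chicks
show the effect; that claim needs the deposited field photographs, which the
photograph-directory path of `run_experiment2()` accepts unchanged.

**Null calibration.** A with/without pair at `fringe_effect = 0` is
byte-identical by construction, so the paired test is undefined there
(zero-variance error, by design). The size of the test is instead calibrated
on exchangeable pairs — two independent fringe *realisations* of the same
subject at the same effect size — under which the null of no systematic
difference holds exactly; `exp2_null_rejection_rate()` measures the
rejection rate (5 % nominal).

## Problem sizes

The proof-of-principle runs use the full 1576 px canvases (the published
geometry); one scene takes a few seconds through the compiled filter. The
test suite runs the basic and thickness families (21 full-size scenes), one
low-acuity scene, a 15-subject paired run and a 200-replicate null
calibration on 160 px fixtures. The six-family grid of
`analysis/01_proof_of_principle.R` (77 scenes) takes ~10 minutes on one
CPU.

## Known limitations

* At 10 cpd (blur σ ≈ 27 px) every ±1 px contrast in the filtered image is
  below 1 JND, so all log edge intensities clamp to zero: the low-acuity
  ordering (far less detectable than 72 cpd) is preserved, but the measured
  mean HEI is exactly 0 rather than a reduced positive value. The published
  toolbox apparently rescales images to a fixed pixels-per-MRA before
  filtering, which is outside this package's vision-model contract.
* Appendage transparency shifts the detectability optimum to higher counts
  here only partially: at 50 % transparency the optimum moves from 256 to
  512 appendages, but at 25 % it stays at 256, one doubling earlier than in
  the published analysis (512 and full circle respectively).
* The 8 px thickness family reaches its minimum at 256 appendages here,
  not at the published 128: the ~3.5 px background slivers between 8 px
  appendages at count 256 survive the RNL filter as coherent dark channels
  (their own sub-threshold cluster is a kernel majority), keeping the image
  at weak-to-moderate edge intensity instead of consolidating into a strong
  new outline. The 12 px family does reproduce the published shift.
* The zero-appendage HEI modal share is 1.27 % of the contour band against
  a published 1.59 %: the sharp edge reconstruction required for the
  scenario orderings concentrates the outline's high mode into fewer pixel
  rings. The two goals trade off within this chain.
* Chromatic LEIA, UV channels and non-human cone mappings are out of scope;
  the chain is achromatic throughout.
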