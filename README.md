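# fringecam

Quantifying how thin protruding appendages conceal an object's outline.

Many precocial chicks hatch covered in downy neoptile feathers whose fine
tips protrude beyond the body. `fringecam` asks whether such a fringe makes
the outline harder to detect for a predator whose vision is limited by
photoreceptor noise, and by how much. It is written for visual ecologists
and camouflage researchers who want a scriptable, fully reproducible version
of this analysis: procedural test scenes instead of hand-drawn images, an
explicit achromatic vision model, and edge statistics with open defaults.

## The model

A scene is converted to linear cone catches; luminance is the mean of the
long- and mediumwave channels, `Q = (Q_lw + Q_mw)/2`. Perceptual contrast
between two catches follows the receptor-noise-limited (RNL) model,

    ΔS = | ln(Q_a / Q_b) | / ω,          ω = 0.1 (luminance Weber fraction)

so 1 ΔS is roughly one just-noticeable difference. Spatial acuity (72 cpd
human, 30 cpd corvid, 10 cpd canid; viewing distance 1300 mm) enters as a
Gaussian blur whose width derives from the minimum resolvable angle, and an
iterative edge-preserving RNL filter removes sub-threshold noise while
reconstructing perceptually distinct edges.

Outline detectability is scored with Local Edge Intensity Analysis (LEIA):
at every pixel of a region of interest, the luminance ΔS between the two
pixels straddling it is measured along four orientations; the slices are
log-transformed, negative values clamped to zero, and collapsed by the
parallel maximum. The pixels forming the distinct high-intensity modal area
of that distribution — the HEI (high edge intensity) pixels, located by a
kernel-density antimode — summarise how visible the outline is via their
mean. A complementary Mean Luminance Comparison (MLC) asks whether the
appendage zone forms a luminance transition band halfway between object and
background.

Two study designs are built in:

* **Proof of principle** (`run_experiment1()`): a grey disc (radius 470 px,
  circumference 2950 px) with 0–737 radial appendages (4/8/12 px thick,
  118 px long, optionally transparent or length-heterogeneous) on uniform or
  chessboard backgrounds, seen at three acuities.
* **Paired comparison** (`run_experiment2()`): a subject rendered twice —
  with and without its protruding fringe — inserted into the same
  background, scored on a shadow-excluded contour band, with per-subject HEI
  thresholds from a dark-ground reference crop and a two-sided paired
  t-test across subjects. Subjects are either seeded synthetic fixtures
  (`synth_chick_scene()`) or your own photographs plus masks.

## A worked example

```r
library(fringecam)

r1 <- run_experiment1(families = "basic")
subset(r1$results, select = c(count, mean_hei, coverage, transition_score))
#>   count mean_hei   coverage transition_score
#> 1     0 2.055849 0.00000000       0.21848526
#> 2    32 2.013816 0.03851008       0.19960287
#> 3    64 1.964566 0.07702016       0.18071100
#> 4   128 1.876606 0.15404032       0.14278398
#> 5   256 1.171747 0.30808065       0.06741222
#> 6   512 1.732583 0.61616129       0.08526373
#> 7   737 2.067233 1.00000000       0.21889796
r1$q
#> [1] 0.01268465
```

The zero-appendage disc carries a distinct high-intensity modal area —
1.27 % of the contour band — of mean log edge intensity 2.26, the full
object/background contrast. Adding appendages drags the mean edge intensity
of those HEI pixels down monotonically to its minimum at 256 appendages
(outline diffusion), after which appendages crowd into a new, conspicuous
boundary at their tips and detectability rises again; the completely filled
stage is as detectable as the bare disc. The luminance transition score is
best (closest to 0) near 50 % appendage coverage. The paired fixture
experiment mirrors the photograph protocol:

```r
r2 <- run_experiment2(n_subjects = 15, seed = 1)
r2$comparison
#> Paired comparison of mean HEI edge intensity (without - with)
#>   n = 15 subjects; lower with appendages in 15/15
#>   t = 6.775, df = 14, p = 8.955e-06
#>   mean difference = 0.1902 (95% CI 0.1300 to 0.2504)
```

## Analysis workflow

The `analysis/` scripts re-run the full study and write tables under
`results/`:

```sh
Rscript analysis/01_proof_of_principle.R     # all six scenario families
Rscript analysis/02_paired_fixtures.R 1      # 15 paired subjects + null size
```

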