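---
title: "Swim-path strategy analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Swim-path strategy analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In the Morris water maze a mouse is released at the edge of a circular pool
and must find a hidden escape platform; spatial learning is read off the
search behaviour across a 5-day, 5-trials-per-day protocol. A trial's swim
path can be assigned to one of six exploratory strategy classes, ordered by
a cognitive score: thigmotaxis (wall hugging, 0), scanning (1), circling
(2), focal search (3), rotating (4) and direct swim (5). Thigmotaxis is of
particular interest because it reflects anxiety-like behaviour rather than
spatial memory, inflates escape latency, and — when present early in
training — predicts poor final performance. This package provides the full
analysis chain for that setting: a trajectory simulator that generates
labelled cohorts, a rule-based geometric classifier, a rasterization
pipeline producing the grayscale images a tracker would export, a small
convolutional network for 2-, 3- and 6-class path recognition, and the
cohort-level statistical analyses (stage frequency tables, presence-of-
strategy outcome contrasts, cognitive-score transitions).

## The trajectory simulator

Paths are discrete-time kinematic walks (`dt = 0.1` s, trial cap 120 s, so
up to 1201 samples) with per-step speeds drawn from a normal distribution
(mean 0.117 m/s, sd 0.015 m/s — typical adult-mouse swim speeds; each class
has a speed multiplier, with direct swims the fastest at 1.3). The pool
defaults to radius 0.6 m with a 5 cm platform centred at mid-radius of the
north-east quadrant, and four perimeter release points cycled across
trials. These absolute dimensions are conventional mouse-maze values; all
classifier features are scale-free ratios, so the downstream logic does not
depend on them. A trial terminates when the position enters the platform
disc (escape; latency is the elapsed time) or at the cap (latency 120 s).
Steps that would exit the pool are reflected about the local wall tangent
by folding the radial coordinate at the wall.

Each class has a generative rule built directly from its defining
geometry, chosen so the defining property is guaranteed (or very nearly
so) for every simulated path:

* **Thigmotaxis** — tangential wall following at radius 0.95 R with small
  clamped radial noise (never below 0.905 R), occasional direction
  reversals. The wall annulus (outer 10% of the radius) therefore holds
  the entire path.
* **Scanning** — straight fast segments between waypoints spread across the
  pool; the first waypoints are placed in three distinct quadrants (with
  an angular margin so arrival tolerance cannot leak across a boundary),
  and segments are routed around the platform until that quota is met, so
  at least three quadrants are always visited before an escape can occur.
* **Circling** — an inward spiral from the release point onto a circle of
  radius 0.62–0.8 R, then heading integration at the circle's curvature
  with steering back toward the target radius bounded to half the nominal
  curvature. The bound means the turning direction can never flip, which
  guarantees high turning-sign consistency. (An earlier parametric
  formulation with white radial noise flipped the measured turn sign on
  comparable scales and was abandoned.)
* **Focal search** — linear segments between waypoints confined to one
  closed half-disc (two adjacent quadrants containing the release point);
  a mirror across the bounding diameter enforces the two-quadrant
  constraint exactly.
* **Rotating** — a high-turning-angle walk (turn sd 1.1 rad/step) confined
  to a small patch (radius 0.18 R) just inside the release point, giving a
  small enclosing circle and large mean absolute turning.
* **Direct swim** — per-step homing on the platform with small heading
  noise (sd 0.12 rad), efficiency well above the 0.8 rule threshold.

Non-direct classes may still hit the platform incidentally; the trial then
ends early but keeps its generating label, mirroring the fact that a
human rater labels the overall pattern, not the outcome.

### Cohorts and per-mouse heterogeneity

A cohort is 22 control + 28 lesioned mice by default. Per-(group, stage)
class mixtures default to the early/late frequency tables of such a
50-mouse study; days 1–2 use the early mixture, days 4–5 the late one, and
day 3 — which belongs to neither analysis window — their arithmetic mean.
Labels i.i.d. across trials would, however, make a mouse's early behaviour
uninformative about its day-5 behaviour, so no presence-of-strategy
contrast could emerge. Each mouse therefore receives its own mixture drawn
as `p_mouse ~ Dirichlet(concentration * p_group)`; the expectation is
exactly the group mixture, so cohort-level frequencies still converge to
the specified tables, while strategy use becomes a stable per-animal
trait. The stage-specific draws share one set of underlying uniforms
(comonotonic Gamma quantiles), so a wall-hugging mouse stays wall-hugging
across stages; additionally the thigmotaxis quantile and the direct-swim
quantile are complements of one latent anxiety trait, so wall-prone mice
also escape directly less often — each marginal mixture is unchanged, but
the presence-of-thigmotaxis contrast on day-5 outcomes becomes a property
of the generator rather than an accident of sampling. The concentration
defaults to 15: strong enough that
"mouse with early thigmotaxis" carries real day-5 signal, weak enough
that pooled frequencies stay within ordinary multinomial dispersion
(goodness-of-fit tests at alpha 0.001 on 5000 labels per group pass
comfortably). All randomness derives from one master seed through an
integer-mixing stream splitter, so cohorts are reproducible trial by
trial.

What the generator does **not** emulate: within-trial learning, wall
friction, thermal stress, inter-trial carry-over, or tracker noise. Tests
passing on these cohorts therefore validate the analysis machinery, not
claims about real mice.

## Features and the rule classifier

Nine scale-free summaries per path: wall-annulus occupancy (fraction of
samples with radial position above 0.9 R), distinct quadrant count,
path efficiency (start-to-end chord over path length), turning-sign
consistency (majority fraction of signed turning angles), mean absolute
turning angle per step, minimal-enclosing-circle radius over pool radius
(computed exactly with Welzl's algorithm), mean radial position, latency
and mean speed. Turning angles come from consecutive displacement
vectors; displacements under 1e-6 m are skipped because their heading is
undefined; a path with no measurable turns is assigned consistency 1.

Classification is a fixed-priority decision list — wall occupancy >= 0.8
gives thigmotaxis; efficiency >= 0.8 with escape gives direct swim; a
confined (extent <= 0.5) high-turning (> 0.4 rad/step) path is rotating;
consistent turning (>= 0.75) away from the wall (mean radial <= 0.9) is
circling; at most two quadrants is focal search; anything else is
scanning. The thresholds operationalize the verbal class definitions
("outer 10%", "straight", "circular", "limited area") and are exposed in
`rule_thresholds()`. Priority puts the safety-relevant class
(thigmotaxis) and the unambiguous success (direct swim) first, resolving
mixed-trait paths the way a rater focused on thigmotaxis detection would.
On seeded simulator output the rules recover the generating labels
essentially perfectly (the acceptance suite demands >= 95% overall,
>= 90% per class on 600 paths).

## Rasterization

Trajectories are drawn dark-on-light into a 140 x 120 8-bit raster — the
shape of a tracker's bitmap export — with the pool inscribed at a 2-pixel
margin, x rightward, y downward, pixel centres at half-integers. The
marked pixels are exactly the cells the continuous polyline passes
through (Amanatides–Woo grid traversal, 4-connected). That definition was
chosen over classic 8-connected Bresenham because the set of traversed
cells is algorithm-independent, so an independent dense-sampling oracle
can check it exactly. Renders contain the path only (no pool outline or
platform), giving the network exactly the trajectory signal. For model
input the raster is padded to square with background, downscaled by exact
area averaging (which preserves mean intensity, so thin lines survive
24 x 24), and divided by 255 into [0, 1]. Supported input sizes are
72, 48 and 24.

## The recognition network

Two unpadded convolutions (20 kernels then 50; kernel sides 13/7 for
72 x 72 inputs, 9/5 for 48 x 48, 5/3 for 24 x 24 — scaling that keeps the
convolution ratio fixed), each followed by ReLU and max pooling, then a
500-node fully connected layer with dropout (rate 0.5) and a softmax head
over 2, 3 or 6 classes; cross-entropy loss, Adam (step size 1e-3, betas
0.9/0.999), minibatches of 32, 50 passes over the training data. For
48 x 48 the map sizes run 48 → 40 → 20 → 16 → 8, flattening to 3200.
Two-class recognition is thigmotaxis vs other; three-class adds direct
swim as its own label.

Pooling deserves a note: a stride-1 max pool cannot downsample, yet the
derived flatten widths require halving, so the default pooling is window
2, stride 2; a size-preserving window-2 stride-1 variant (with edge
padding) is available behind `pool_same = TRUE` for readers who want the
literal alternative, and `layer_shapes()` does its arithmetic for both.

The implementation is single-precision C++ (im2col + BLAS GEMM) with its
own Mersenne-Twister stream for initialization (He-scaled), epoch
shuffling and dropout, so training is bit-reproducible for a fixed seed
and thread count. Weight initialization scale and the optimizer defaults
are the commonly published values; all are config-exposed.

## Evaluation protocol

`repeated_holdout()` reshuffles and splits the dataset 80/20 (training
size is the ceiling), trains from scratch and scores the held-out part,
ten times by default; metrics are reported as mean ± SEM across
repetitions, matching the mean ± SEM convention used throughout.
Sensitivity and specificity treat thigmotaxis as the positive class and
are reported for the 2-class task. Confusion counts accumulate across
repetitions; the misclassification matrix divides off-diagonal errors by
the total error count (cells are percentages of all mistakes; diagonals
are not applicable). Splits are by trial image, not by mouse — faithful
to the protocol being reproduced — though mouse-level splitting would be
the more conservative design since trials of one mouse are correlated;
the harness accepts any classifier object, and three analytic stubs
(perfect, majority, uniform) validate the harness itself before any
network run. Wall time is logged but never asserted.

On the default synthetic early-stage dataset (n = 500 at 48 x 48) the
2-class network reaches high accuracy and specificity with non-zero
sensitivity, and 6-class accuracy is reliably below 2-class accuracy —
the ordering, not the magnitudes, is the claim, because synthetic ring-
vs-scribble images are far cleaner than real tracker exports. Real-data
accuracies are not reproducible from simulation and are not asserted
anywhere.

## Statistics

Two-group comparisons use an F test of variance equality at alpha 0.05 to
select the pooled-variance or Welch t test (the gate's alpha is a design
choice; the convention is common in the field's software). Degenerate
zero-variance pairs are reported, not crashed. Multiple groups use
standard one-way ANOVA; for two groups its F equals the square of the
pooled t statistic, which the tests assert to 1e-9. Stage tables print
percentages at one decimal and latencies at one decimal; scores use two
decimals. The early table's latency column is the day-2 per-mouse mean
(mean ± SEM across mice), the late table's is day 5, and day-3 trials
appear in neither stage window. Presence groupings use the at-least-once
rule, so a mouse can belong to several "with" groups; outcome contrasts
compare per-mouse day-5 mean latency and day-5 mean cognitive score.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full study protocol —
a 50-mouse cohort (1250 trials), 500 early-stage images at 48 x 48, 50
epochs, 10 holdout repetitions for both the 2- and 6-class task — sizes
chosen to match the emulated study while keeping a complete run in the
minutes range on one CPU. Smaller configurations (24 x 24, few epochs,
tiny cohorts) are used where a test only exercises plumbing such as
determinism or file round-trips. Ties in max pooling resolve to the first
window element scanned; probability argmax ties resolve to the lowest
class index; the minimal enclosing circle treats collinear triples as
two-point circles; chi-square convergence checks run at alpha 0.001 with
at least 5000 labels per group. Network train/predict calls flush
subnormal floats to zero (restoring the FP state afterwards): once
training converges, squared gradients fall below the single-precision
normal range, where x86 microcode handling would otherwise dominate the
runtime without affecting any meaningful digit.

## Limitations

The simulator's six generators are idealized archetypes: real swim paths
mix strategies within a trial, and a CNN trained on these synthetic
renders will not transfer to real tracker images. The rule classifier is
a reference labeller for synthetic data and a baseline — it is not a
model of the human rater, whose judgement on mixed trials is itself a
known source of label noise. Latency distributions are emergent from the
generators (classes that rarely escape sit at the 120 s cap), so absolute
latencies should not be compared against any real cohort; only the
directions of the contrasts are meaningful.
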