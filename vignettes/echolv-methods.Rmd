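---
title: "Measuring left-ventricular linear dimensions with heatmap keypoint regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring left-ventricular linear dimensions with heatmap keypoint regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(echolv)
```

## The measurement problem

Three linear dimensions summarize left-ventricular (LV) morphology on a
long-axis echocardiographic frame: the interventricular septal thickness
(IVS), the LV internal diameter (LVD) and the free-wall thickness (FW).
A sonographer obtains them by placing four electronic calipers along a
measurement axis crossing the ventricle: the anterior and posterior
borders of the septum, and the anterior and posterior borders of the
free wall. Consecutive pairs of these four keypoints delimit IVS, LVD
and FW; pixel distances are converted to centimetres with the frame's
calibration (cm per pixel, carried per axis).

`echolv` automates the caliper placement as an anatomical-landmark
localization problem, and -- just as importantly -- provides the
statistical framework for judging any automatic (or human) measurer
against a panel of experts, because for this task there is no single
ground truth: trained readers disagree with each other, and an automatic
system should be held to the spread of that disagreement rather than to
one arbitrary reference reading.

## Heatmap regression model

Each keypoint $p_k$ is represented by a spatial confidence map on a
working grid (default $320 \times 320$):

$$H_k(q) = \exp\!\left(-\frac{\lVert q - p_k\rVert^2}{2\sigma^2}\right),
\qquad \sigma = 15\ \text{px at } 320 \times 320,$$

normalized so that the plane maximum is exactly 1 (for sub-pixel $p_k$
the raw render peaks slightly below 1 at the nearest grid point; the
normalization keeps the decoded confidence interpretable and the
amplitude convention consistent). $\sigma$ scales proportionally with
the working grid, so a $128\times128$ configuration uses 6 px. A
keypoint an expert could not place yields an all-zero channel whose
loss weight is 0, so unlabeled points contribute nothing to training.

A fifth channel carries a *pseudo-line*: a unit-amplitude Gaussian
ridge over the polyline joining the four keypoints in anatomical
order. The four calipers of a well-formed measurement are nearly
collinear; regressing this auxiliary channel rewards geometrically
consistent predictions without hard-constraining them. The pseudo-line
is a separate output channel with its own loss term (weight
`pseudo_line_loss_weight`, default 1); it is not burned into the
keypoint channels, which keeps decoding of the four landmark channels
untouched.

The backbone is a compact U-Net: `depth` resolution levels with two
3×3 convolution + ReLU blocks per level, 2×2 max pooling down,
nearest-neighbour upsampling with skip concatenation up, and a linear
1×1 head with 5 output channels. The convolution kernels and their
backpropagation are implemented in RcppArmadillo (`src/convnet.cpp`)
and orchestrated from R; gradients are verified against finite
differences in the test suite. He-normal initialization is used for
hidden layers; the head starts at zero so an untrained network emits
flat heatmaps and every decode falls below the confidence floor.

Training minimizes the masked MSE

$$L = \frac{1}{|\mathcal{C}|}\sum_{c \in \mathcal{C}} w_c\,
  \overline{(H^{pred}_c - H^{tgt}_c)^2},$$

over the unmasked channel set $\mathcal{C}$, with $w_c = 1$ for
keypoint channels and the pseudo-line weight for channel 5. The
optimizer is TAdam -- Adam with a Student-t robust estimate of the
first moment, implemented from its published update rule with
per-tensor degrees of freedom $\nu = d$ -- with plain Adam available
via `train_config(optimizer = "adam")`; results always carry the
optimizer tag. The reference protocol is 200 epochs at initial
learning rate $10^{-3}$, divided by 5 whenever the monitored test loss
fails to improve for 20 consecutive epochs (the schedule is a pure
state machine, unit-tested against hand-simulated traces), with
on-the-fly affine + gamma augmentation applied identically to image
and heatmap targets. The best-test-loss checkpoint is retained.

### Decoding

At inference the image is resized to the working grid (bilinear, with
the exact coordinate contract $x_\text{src} = x_\text{dst} \cdot
w_\text{src}/w_\text{dst}$ on 0-based pixel-centre coordinates), the
network is run, and each keypoint channel is decoded as its global
maximum (ties broken toward the smallest row-major index), refined to
sub-pixel precision as the intensity-weighted centroid of the
*baseline-subtracted* 7×7 window around the peak. The baseline
subtraction matters: with $\sigma = 15$ the Gaussian is nearly flat
across a 7-pixel window, and a plain centroid collapses toward the
peak pixel, losing the sub-pixel information; subtracting the window
minimum restores it (worst-case round-trip error ≈ 0.3 px, verified
over 1000 random sub-pixel placements in the acceptance suite).
Decoded working coordinates map back to native pixels by the inverse
of the resize scaling. Peaks below `confidence_floor` (default 0.1)
are reported as missing rather than guessed.

### Caliper measurements

`derive_measurements()` computes IVS, LVD, FW as full Euclidean
distances between consecutive keypoints, applying the per-axis spacing
to the coordinate deltas before the norm, so anisotropic calibration
(including the anisotropy created by resizing a non-square frame) is
exact. Distances are deliberately *not* projections onto a common
axis; instead `check_geometry()` flags suspect configurations --
`OUT_OF_ORDER` when the projections onto the total-least-squares line
are not monotone in anatomical order, `NON_COLLINEAR` when the maximum
perpendicular deviation exceeds $\tan(15^\circ)$ times the projected
span. The 15° default is permissive enough for the site-to-site
variation seen among real readers yet flags the "diagonal path across
the ventricle" failure mode; flags are advisory, since human readers
are themselves not constrained to a line.

## The synthetic phantom

Real long-axis frames cannot ship with the package, so the entire
pipeline is exercised on phantoms that emulate exactly the features
the method relies on: two bright near-parallel wall bands
perpendicular to a measurement axis, lying on the midline of a
fan-shaped scan sector over a darker blood pool, with multiplicative
speckle (`img * (1 + s(R - E[R]))`, $R$ Rayleigh -- the simplest
ultrasound-like texture) and a gamma curve. Ground-truth keypoints are
the intersections of the axis with the band edges, so the generated
thicknesses are exact by construction.

Cohort defaults were fixed once, from typical canine long-axis values:
frames span 6.4 cm (0.02 cm/px at 320 px, 0.05 cm/px at 128 px), IVS
and FW uniform on 0.5--1.0 cm, LVD on 1.8--3.0 cm, axis within ±4.6°
of vertical, mild speckle (0.10--0.20), gamma 0.9--1.1; two frames
(labelled ED and ES) per synthetic study, mirroring a validation set
in which every study contributes one end-diastolic and one
end-systolic frame. The measurement axis stays on the sector midline
because the longitudinal measurement site must be recoverable from
visible structure -- a band is translation-invariant along its length,
so a phantom with a randomly displaced invisible axis would make the
localization task ill-posed. All randomness flows from one seed via
counter-based per-frame substreams, so cohorts are reproducible
regardless of generation order.

What the phantom does *not* model: point-spread convolution,
attenuation, anatomical clutter (papillary muscles, valve apparatus),
view foreshortening, and real inter-patient texture variation.
Passing phantom tests therefore demonstrates the correctness of the
pipeline's machinery -- encoding, optimization, decoding, calibration,
statistics -- not clinical-grade performance on real images.

### The simulated reader panel

`rater_model()` emulates the structure of a multi-reader study: 13
raters × 2 blinded repeats (26 labels per frame). Its noise geometry
mirrors how real readers disagree: small *transverse* noise along the
measurement axis (default SD 2 px -- readers agree on where a wall
edge is), larger *longitudinal* noise along the walls (default SD
8 px -- readers disagree on where along the wall to measure), plus a
per-rater fixed longitudinal bias (SD 4 px) representing readers who
systematically choose more apical or basal sites, held constant across
repeats and frames. Transverse bias is assumed zero. With transverse
noise only, the thickness of a wall measured from two independently
displaced endpoints disperses with SD $\sqrt{2}\,\sigma_t\,\Delta x$
cm; the acceptance suite checks the simulated panel against this
closed form to 15% over 50 frames × 26 labels.

## Consensus validation framework

For each frame × site, the *consensus* is the arithmetic mean of all
expert labels (repeats count as independent labels). Each label's
signed deviation from its frame's consensus is pooled across frames
per phase × site; the pooled deviations have mean exactly zero by
construction (asserted to 1e-9 -- the "Mean 0.00" column of a reader
study table is structural, not empirical), and their SD -- equal here
to the RMS -- indexes expert dispersion. A candidate measurer (the
network, or any single rater being audited) contributes one deviation
per frame; whether the candidate's deviations are *larger* than the
experts' is tested with the Levene/Brown-Forsythe statistic

$$W = \frac{N-k}{k-1}\,
  \frac{\sum_i n_i(\bar Z_i - \bar Z)^2}{\sum_{ij}(Z_{ij}-\bar Z_i)^2},
\qquad Z_{ij} = |Y_{ij} - \tilde Y_i|,$$

with median centering by default (mean centering gives the classic
test; the choice is recorded in the output metadata), and the
candidate's mean bias with the ordinary paired t-test against the
per-frame consensus. The dispersion comparison pools all expert
deviations (≈ 26 × n frames) against the n candidate deviations;
group sizes are printed in the summary for transparency, since
dispersion p-values depend on this pooling convention. Degenerate
inputs (zero spread of the centered scores, zero-variance differences)
are reported as explicit flags or errors, never silently coerced to a
number.

`build_summary()` emits one row per phase × site with expert and
candidate deviation mean/SD/median, the Levene statistic and p, the
bias and its p, and all group sizes -- the machine twin of a
two-phase, three-site reader-study summary table. Frames lacking a
candidate value are listed in an exclusion report.

## Numerical and design choices

* **Coordinates** are 0-based with the origin at the centre of the
  top-left pixel, x rightward (columns), y downward (rows), stored at
  native resolution; the working/native mapping is the exact linear
  scaling above, so encode→decode→rescale round-trips to machine
  precision at identity scale.
* **Dataset splitting** defaults to study level (all frames of a scan
  on one side) to prevent leakage of near-duplicate frames; a
  frame-level mode exists for datasets of independent frames, taking
  `floor(fraction × n)` frames.
* **Targets are rendered, never resized.** Heatmaps are generated
  directly at working resolution, avoiding interpolation attenuation
  of peaks; only images pass through the bilinear resize.
* **Tie-breaking** at equal heatmap maxima is the smallest row-major
  index -- deterministic and documented.
* **Scaled-down study sizes.** The test and acceptance runs use a
  depth-2, 8-channel U-Net at 128×128 (64×64 for the quickest unit
  tests) trained on 200 phantoms for 10 epochs with 50 held-out
  evaluation phantoms, and reader-panel simulations of 10--50 frames.
  For these short runs the configuration is Adam, batch size 2,
  learning rate 5e-3, heatmap SD 4 px, pseudo-line weight 0.25, no
  augmentation. Each departure from the long-protocol defaults has a
  specific reason in the 10-epoch regime: TAdam's robust damping of
  the first moment -- an asset over a 200-epoch schedule on noisy real
  data -- slows the first few hundred updates; the pseudo-line
  channel, whose ridge support is far larger than a keypoint peak,
  otherwise dominates the 5-channel loss average early and starves the
  keypoint channels; sharper targets separate the two edges of a thin
  wall; and augmentation (a regularizer for small real datasets) is
  unnecessary on clean, abundant phantoms. These choices are fixed in
  the scripts and reported with the optimizer tag.
* **Config files** for the command-line interface are YAML with strict
  unknown-key rejection, so a typo in a scientific parameter is an
  error, not a silently ignored default. Every artifact-producing run
  writes a resolved-config copy and version stamp into its output
  directory, making each run reproducible from its own record.
* **Model storage** is plain text (one CSV per weight tensor plus a
  YAML header), human-inspectable and diff-able.

## Known limitations

* The phantom's simplicity means phantom-trained models say nothing
  about real-image performance; the package's claim is that the
  *machinery* is correct and that a real dataset can be dropped in
  through the same JSON-lines/PNG interfaces.
* Single-device CPU training only; the compact backbone trains tiny
  configurations in minutes but is not sized for 320×320 production
  training, which would want a GPU framework.
* One output peak per channel: multi-candidate tracking (e.g. both
  ends of a foreshortened wall) is out of scope.
* The dispersion p-values of a reader study depend on the pooling
  convention for group sizes; with a different convention the same
  data give different p-values, which is why the summary prints its
  group sizes rather than claiming a canonical test.
* ED/ES frame selection, DICOM ingestion and video tracking are out of
  scope; frames and phase labels are inputs.
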