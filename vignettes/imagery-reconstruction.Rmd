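---
title: "Reconstructing imagined letters from simulated retinotopic cortex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing imagined letters from simulated retinotopic cortex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfrecon)
```

## The problem

Early visual cortex is retinotopically organised: each voxel responds to a
restricted region of the visual field, well described by an isotropic 2-D
Gaussian population receptive field (pRF) with centre $(x_0, y_0)$ and size
$\sigma$, where $\sigma$ grows roughly linearly with eccentricity.  If
visual mental imagery re-uses this topographic code, the spatial pattern of
voxel activity evoked by *imagining* a letter should resemble the pattern
evoked by *seeing* it — closely enough that the visual field can be
reconstructed from imagery activity and the imagined letter recognised.

`prfrecon` implements that entire analysis as a testable pipeline, together
with a synthetic-cortex generator that plays the role of the scanner: it
produces voxel populations with known ground truth and BOLD-like responses
to bar-mapping, letter-perception and letter-imagery runs.  Everything
downstream — pRF fitting, encoding analysis, visual-field reconstruction,
autoencoder denoising, decoding with permutation inference — operates only
on the simulated (or user-supplied) voxel-by-volume matrices, never on the
ground truth.

## Forward model and simulation

A stimulus is a binary image on a calibrated raster (default
$150 \times 150$ pixels spanning 10°; letters H, T, S, C fill an 8°×8°
guide box with 1° margin).  A voxel's neural drive at each volume is the
inner product between its pRF profile and the stimulus frame; drives are
convolved with a canonical double-gamma HRF (peak 6 s, undershoot 16 s,
ratio 1/6, sampled at TR = 3 s), white Gaussian noise is added, and each
voxel's series is z-scored.  The session layout mirrors the study design
the package targets: one bar-mapping run (1.33°-wide bar, 12 steps × 4
orientations × 6 repetitions, randomized step order, 3 s per step), one
perception run (8 trials per letter, 6 s stimulation), and four imagery
runs of 32 balanced trials (8 per letter, 6 s imagery phase, rests
alternating 9/12 s).

Imagery has no agreed generative model, so the generator adopts the
simplest account consistent with the phenomenon it emulates: the imagery
drive is `imagery_gain` × the perceptual drive (default 0.5) with inflated
noise (`imagery_noise_sd`, default 2 vs 1 for perception).  Gain 0 is a
useful negative control: imagery runs then carry pure noise and decoding
must fall back to chance.  The generator makes no attempt to model
physiological noise, temporal autocorrelation, motion, inter-subject
variability in imagery vividness, or voxel sampling inhomogeneities —
synthetic subjects differ only through seeds and the gain/noise settings.
Passing tests therefore demonstrate the *correctness of the analysis
machinery* and the *internal consistency* of the method, not its
performance on real 7T data.

## pRF fitting

`fit_prf()` is a grid search: candidate locations lie on a polar grid of
100 angles × 100 eccentricities whose density decays exponentially with
eccentricity,
$e_k = e_{\max}\,\frac{\exp(d\,k/100) - 1}{\exp(d) - 1}$ (decay $d = 3$ by
default; as $d \to 0$ the spacing approaches uniform), and each location is
paired with the ten size–eccentricity slopes $0.1, 0.2, \dots, 1.0$, giving
100 000 candidate models per voxel.  Candidate sizes are
$\sigma = \max(\text{slope} \times \text{ecc}, 0.1°)$; the floor keeps the
Gaussian well-defined at fixation, at the price of making the slope
non-identifiable where slope × ecc falls below it (closed-loop recovery is
therefore assessed on identifiable ground truth).  Goodness of fit is the
Pearson correlation between predicted and observed series — amplitude-free,
so the unknown gain between drive and z-scored signal drops out.  Ties
break deterministically toward the smallest eccentricity, then the smallest
slope.  Voxels enter later stages only if their fit score reaches
`selection_threshold` (default 0.2, configurable; the retained count is
recorded because it strongly predicts downstream quality).

## Reconstruction

The encoding matrix $W$ (voxels × pixels) holds each selected voxel's
Gaussian profile at the pixel centres, scaled to unit row sum.  The visual
field is recovered from a pattern $y$ by minimising

$$E(x) = \lVert y - W x \rVert^2 + \lambda\, x^\top D x,$$

where $D$ is the diagonal *outdegree* matrix — the column mass of $W$,
i.e. how much total encoding weight each pixel projects to cortex — so the
penalty is weakest where cortex samples the field most densely (a cortical
magnification correction).  The minimiser is
$x = (W^\top W + \lambda D)^{-1} W^\top y$.  Two numerical choices matter:

* **Penalty weight.**  The balance between $W^\top W$ and $D$ depends
  entirely on the amplitude convention chosen for $W$, which the inverse
  formulation itself leaves open.  `projection_matrix()` therefore defaults
  to the trace-balancing weight
  $\lambda = \operatorname{tr}(W^\top W) / \operatorname{tr}(D)$, which
  makes reconstructions invariant to any global rescaling of $W$ and puts
  the data-fit and penalty terms on a common scale.  With unit-row-sum
  profiles and no such balancing, the penalty dominates by roughly three
  orders of magnitude and reconstructions collapse to heavily smoothed
  back-projections.  An explicit `lambda` argument restores any other
  reading.
* **Solving.**  $p = n_\text{pixels}$ far exceeds $v = n_\text{voxels}$, so
  the $p \times p$ normal matrix is never formed; the projection is applied
  through the Woodbury identity with one $v \times v$ Cholesky
  factorisation, and pixels covered by no pRF receive an epsilon floor
  ($10^{-6} \times \max D$) that keeps the system positive definite while
  shrinking those unconstrained pixels to zero.

Reconstruction quality is scored at two levels: the Pearson correlation
between a reconstruction and its binary letter (first level; Fisher z for
averaging), and the correlation between the 6 pairwise similarities of the
letters and the 6 pairwise similarities of their reconstructions (second
level), which asks whether the *pattern* of shape relationships survives.

## Denoising autoencoder

Imagery patterns are noisy, attenuated copies of perceptual ones, so a
denoiser trained purely on perception can act as an attractor network for
imagery.  The autoencoder has one hidden layer of
$k = \lfloor 0.1\,v \rfloor$ units, tied weights
($W_d = W_e^\top$, enforced structurally — the decoder matrix is never
stored), rectifier hidden units (a logistic variant is available since both
appear in descriptions of this architecture; neither is asserted as
canonical), and a linear output layer.  Training minimises the mean squared
distance between clean targets and restorations of corrupted inputs using
Adam (learning rate $10^{-5}$, batch 100, 2000 steps), where the training
set is the four average perceptual patterns plus four all-zero patterns
(the zero attractor prevents signal-free inputs from being restored to an
arbitrary letter).  Each step resamples the eight items with replacement
and corrupts them afresh with $\mathcal N(0, \sigma^2)$ noise,
$\sigma = 12$ in z-units — far above the unit-scale patterns, which forces
the network to learn pattern-shaped filters rather than copy its input;
values in $[8, 14]$ behave equivalently.

One numerical choice is load-bearing: **initialisation scale**.  Weights
start at $\mathcal N(0, 0.01^2)$.  Because corrupted inputs have SD 12,
larger initial weights make the early restorations (and the loss) explode
under the fixed learning-rate schedule; at small scale the same schedule
reliably reaches the attractor regime.  Training aborts with diagnostics if
the loss ever becomes non-finite.

## Classification and inference

The classifier stacks a four-unit softmax head on the *frozen* encoder
(multinomial logistic regression on hidden representations; cross-entropy,
Adam, learning rate $10^{-4}$, batch 96, 250 steps, zero-initialised head —
the problem is convex, so training is deterministic).  Evaluation is
leave-one-run-out over the four imagery runs: 96 training patterns, 32 test
patterns per fold.  Significance comes from a permutation null: the
training labels (test labels intact) are scrambled, the full
cross-validation repeated, and the observed mean accuracy compared to the
95th percentile (nearest-rank) of 1000 null accuracies.  With four balanced
classes the null centres on 25%.  Internally all permutations are trained
jointly as one block-structured softmax — identical mathematics, one pass
of matrix algebra.

## Problem sizes

The package's own test suite and acceptance script run at desk scale,
chosen to preserve every structural invariant of the design while keeping a
full run affordable on a laptop: populations of 80–500 voxels for
simulation-heavy properties (2000 for the noiseless closed-loop fidelity
check), rasters of 32–150 px, the full 100 000-candidate search grid for
recovery checks, 200-permutation smoke nulls in tests and the full 1000 in
the acceptance script.  Trial bookkeeping (4 × 32 imagery trials, 8
perception trials per letter) is never scaled down, since the counts are
part of the method's contract.

## Known limitations

* The synthetic generator's simplifications (white noise, shared HRF, no
  scanner artefacts) mean quantitative agreement with real-data correlation
  tables is out of scope; qualitative orderings (e.g. coarse letters
  reconstruct better than fine ones, denoising pulls single trials toward
  perception-level quality) are the meaningful checks.
* The mixed-model analyses relating reconstruction quality to questionnaire
  scores have no synthetic counterpart; the encoding contrast is reduced to
  per-subject OLS plus an across-subject one-sample t test on the
  (3, −1, −1, −1) contrast, Bonferroni-corrected for the 4-letter × 3-ROI
  family (α/12 = 0.0042).
* The slope of the pRF size relation is non-identifiable below the sigma
  floor, and location recovery degrades gracefully (not catastrophically)
  for pRFs much smaller than a bar step.
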