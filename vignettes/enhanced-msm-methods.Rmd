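---
title: "Speed-invariant gait recognition with the enhanced mutual subspace method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speed-invariant gait recognition with the enhanced mutual subspace method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emsm)
```

## The problem

Gait is a behavioural biometric: people can be identified at a distance from
the way they walk, using only binary silhouette sequences extracted from
video. The classical feature, the gait energy image (GEI, the per-pixel mean
of one cycle of silhouettes), is accurate when the enrolment and query
conditions match, but walking-speed changes alter pitch and stride and with
them the GEI, so identification degrades exactly when it is most needed.

This package implements a subspace remedy. A set of silhouette images of one
person is modelled not as one average image but as a low-dimensional linear
subspace of image space; identification compares the *subspaces* of the
enrolled person (gallery) and of the query (probe). Speed mostly moves images
*within* a person's subspace (the GEI is essentially its first principal
direction; the following directions carry the motion), so subspace-to-
subspace comparison is far less speed-sensitive than image-to-image
comparison.

## The model

**MSM.** For gallery class $c$, frames are vectorized to $x_{c,n}$ and the
class subspace is spanned by the leading eigenvectors of the autocorrelation
matrix
$\Gamma_c = \frac{1}{N_c}\sum_n x_{c,n} x_{c,n}^\top$
(no mean subtraction; `fit_subspace()` computes it through the thin SVD of
the sample matrix). The probe sequence gets its own subspace the same way.
The similarity between gallery subspace $\Phi$ (first $d^G$ columns) and
probe subspace $\Psi$ (first $d^P$ columns) is the set of squared cosines of
their canonical angles: the eigenvalues of $Z = M M^\top$ with
$M = \Phi^\top \Psi$, computed in `canonical_similarities()` as squared
singular values of $M$ — identical algebra, better conditioning. Similarity
$s(r, d^G, d^P)$ denotes the $r$-th largest. The coefficient rows returned
alongside reproduce the canonical vectors
$v_r = \sum_d \omega(r,d)\,\psi_d$, and
$\langle v^G_r, v^P_r\rangle^2 = s(r)$ — a relation the test suite asserts.

**2D-PCA.** The covariance of vectorized $A \times B$ frames is
$(AB)^2$-sized and cannot be estimated from a few dozen frames. 2D-PCA
instead forms the $B \times B$ image covariance
$S = \frac{1}{N}\sum_n (I_n-\mu)^\top(I_n-\mu)$ and keeps its top $K$
eigenvectors $\eta_1 \dots \eta_K$ (`fit_image_basis()`). Every frame is
projected to the $A \times K$ matrix $\Xi = [I\eta_1, \dots, I\eta_K]$
(`project_image()`); projected matrices are flattened column-major and fed to
MSM. Two deliberate asymmetries follow the method's definition exactly:
the covariance is mean-centred but projection applies to the raw frame $I$
(a `center_projection`-style variant was considered and rejected to keep the
projection formula as defined); and probe frames are projected with the
basis of the *gallery class under comparison*, so the probe subspace is
recomputed per class — the per-class features are the point, not a bug.

**Rotation bank.** 2D-PCA is a block PCA with horizontal scan lines; rotating
the image by $\theta$ and reapplying it is equivalent to scanning the
original with rotated lines, which captures obliquely oriented biometric
structure (limb segment lengths, arm positions). `rotate_frame()` zero-pads
to the fixed square of side $\lceil\sqrt{A^2+B^2}\rceil$ and rotates about
the centre with nearest-neighbour interpolation, preserving binarity and
giving every angle the same output geometry. The default bank is
$\theta \in \{-20^\circ, -18^\circ, \dots, 20^\circ\}$; coarse wings out to
$\pm 90^\circ$ are available (`build_rotation_grid()`) but contribute little
and are off by default.

**Boosted fusion.** Every parameter combination
$(r, d^G, d^P, \theta)$ defines a weak classifier
$h = \arg\max_c s_c(r, d^G, d^P, \theta)$. AdaBoost (`fit_boost()`) selects
combinations sequentially: round $t$ picks the minimum weighted error
$\epsilon_t$, assigns confidence
$\alpha_t = \tfrac12\ln\frac{1-\epsilon_t}{\epsilon_t}$, and reweights
training probes by $e^{\mp\alpha_t}$ with renormalization. The strong
classifier is the $\alpha$-weighted vote
$H = \arg\max_c \sum_t \alpha_t [h_t = c]$.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| canvas | 64 × 44 px | normalized silhouette size |
| $\Theta$, $\Delta\theta$ | 20°, 2° | rotation bank half-range and step |
| $K$ | 16 | 2D-PCA dimension (performance is flat for roughly 9–21) |
| $d^G, d^P$ axes | 10..50 step 10 | subspace dimensionalities searched by boosting |
| $R$ | 18, capped | canonical angles; capped at the smallest axis value (see below) |
| $T$ | 30 | boosting rounds; convergence is typically seen in well under 15 |

Since $Z$ has rank at most $\min(d^G, d^P)$, canonical angles beyond the
smallest axis value do not exist; `emsm_control()` therefore caps the
effective $R$ (18 requested, 10 effective on the default axes) rather than
produce undefined entries. Where rank-capping of a *subspace* (degenerate
data) leaves fewer angles than requested, the missing similarities are
reported as 0 — the limiting "no correlated direction" value — so tensors
stay complete; on the default synthetic conditions (60 frames, dims ≤ 50)
this path is never taken.

## Numerical choices

* Eigenvector signs are fixed (largest-magnitude component positive) so all
  outputs are deterministic and snapshot-stable.
* Subspace dimensions requested beyond the numerical rank (singular values
  below $10^{-10}$ of the largest) are capped with a warning.
* $\alpha_t$ diverges at $\epsilon_t = 0$, and perfect weak classifiers do
  occur on separable data; $\epsilon$ is clamped to
  $[\tfrac{1}{2N}, 1-\tfrac{1}{2N}]$ before the log, which preserves the
  ordering of classifiers and keeps the vote finite. Clamping is reported via
  a message. Boosting stops early if no weak classifier beats chance
  ($\min\epsilon \ge 0.5$), where $\alpha$ would turn non-positive.
* Ties — in the weak argmax, in boosting's classifier selection, and in the
  strong vote — are broken deterministically (lowest class identifier, or
  earliest grid position with $r$ varying fastest and $\theta$ slowest).
* The autocorrelation form of the class matrix is printed in some
  descriptions of MSM as a double sum over both sample indices, which is
  algebraically rank one; `fit_subspace()` implements the standard
  autocorrelation and keeps the rank-one variant behind
  `printed_double_sum = TRUE` for auditability.
* The ROC threshold set is the midpoints between consecutive sorted unique
  scores plus $\pm\infty$; the EER interpolates the FAR/FRR staircase in
  curve space (not threshold space), which makes it exactly invariant under
  monotone score transforms.

## The synthetic walker

No external gait dataset is required: `walker_subject()`,
`render_sequence()` and `make_benchmark()` generate articulated 2D
side-view walkers whose *identity* is a tuple of body proportions (leg
length, torso height/width, head radius, arm length, limb thickness, drawn
uniformly from fixed ranges) and whose *style* varies with a speed
parameter: stride amplitude $0.25 + 0.20\,s$ rad, cadence $0.03 + 0.02\,s$
cycles/frame, arm swing $0.15 + 0.10\,s$ rad. Legs move in antiphase as
thick segments from the hip; arms in antiphase to their ipsilateral legs;
frames are height-normalized (`normalize_silhouette()`: bounding box scaled
to the canvas height, re-binarized at 0.5, horizontally centred) and
optionally corrupted by i.i.d. pixel flips. Flips are applied after
normalization: flipping first would scatter foreground across the raw
canvas and the bounding-box crop would no longer be defined by the body.

Two fixed asymmetries are built in deliberately. Far-side limbs are drawn
slightly shorter and thinner (self-occlusion in a side view), and the
forward step is slightly deeper than the backward one (step-length
asymmetry, as in real gait). Without them the silhouette sequence would be
exactly invariant under a half-cycle shift and the gait *cycle* would be
unobservable: `estimate_gait_cycle()` tracks the foreground width of the
lower (leg) half of each frame — counting columns with at least two
foreground pixels, so isolated flipped pixels cannot stretch the measured
leg spread — and returns the dominant peak lag of its autocorrelation, using
the unbiased ($1/(n-k)$) normalization because the biased estimator damps
the full-cycle lag in favour of the half-cycle one.

What the generator does *not* emulate: real silhouette extraction artefacts
(holes, shadows, boundary jitter — noise here is i.i.d. flips only), 3D
articulation and knees/feet, clothing and carrying variation, view changes.
Passing tests therefore demonstrate the correctness of the machinery and its
speed-robustness on idealized gait, not field performance on real video.

Sequences are not truncated to one gait cycle before subspace modelling:
subspace estimates only improve with more frames and MSM needs no cycle
alignment. `estimate_gait_cycle()` and `truncate_to_cycle()` are provided
for one-cycle evaluation protocols, and `compute_gei()` for the GEI
baseline.

## Problem sizes used in the shipped experiments

The package's own experiments (test suite and `scripts/acceptance.R`) use a
10-subject benchmark with one 60-frame gallery sequence per subject at speed
1.0, boosting trained on 10 probes at speed 1.3 and evaluated on 10 probes
at speed 1.6 with flip noise 0.02 — about three gait cycles per sequence, a
scale at which the subspace spectra are stable and a full fit runs in a few
minutes on one core. Smaller fixtures (3–4 subjects, reduced rotation banks)
exercise the identities and reductions: the $\theta = 0$ slice of the bank
equals the rotation-free path bit for bit, with or without gallery-model
caching, and disabling 2D-PCA ($K = \mathrm{NULL}$) with a $\{0\}$ grid
reproduces classic vectorized MSM to $10^{-8}$.

## Known limitations

* The rotation bank is in-plane only; out-of-plane view change is out of
  scope.
* The divided-areas MSM variant and Random-Forest fusion are not
  implemented.
* `spec_sens_sweep()` reports both the conventional sensitivity
  $TP/(TP+FN)$ and the false-negative rate $FN/(FN+TP)$, explicitly
  labelled, because the latter is occasionally mislabelled "sensitivity" in
  the screening literature; users should pick the column they mean.
* With a single training speed, boosting tends to select one dominant
  parameter combination repeatedly (its training error is already zero);
  the fused classifier then inherits that combination's behaviour. This
  mirrors how the method behaves on separable training sets generally.
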