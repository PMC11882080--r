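---
title: "Inferring the cellular microenvironment from actin-wave videos: models and methods"
author: "actinwave package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the cellular microenvironment from actin-wave videos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinwave)
```

## The scientific problem

Giant electrofused *Dictyostelium discoideum* cells display travelling waves
of actin polymerization on their cortex. The shape and motion of these waves
respond to the cell's physical microenvironment: on nano-ridged substrates
(1.6 um pitch) the waves become quasi-one-dimensional bands guided along the
ridges (esotaxis), while on flat substrates they stay two-dimensional; a DC
electric field superimposes a coherent drift on the wave features
(electrotaxis). `actinwave` asks the inverse question: given only
fluorescence time-lapse videos of the waves, can the microenvironment — the
nano-topography type and the field state — be inferred?

Three feature families feed a linear support-vector machine (SVM):

* **Dictionary features** (static, per frame). Sparse coding of image
  patches against a learned dictionary; the per-frame descriptor is the
  total absolute activation of each atom.
* **Scattering features** (static, per frame). First-order Morlet wavelet
  scattering coefficients, a fixed multi-scale, multi-orientation texture
  descriptor.
* **Optical-flow features** (dynamic, per video). Shi-Tomasi corners
  tracked by pyramidal Lucas-Kanade flow, summarised by the mean corner
  velocity.

Static features resolve the topography (in the absence of the field);
resolving the field state requires the dynamic features. The package
reproduces this full pipeline and validates it end-to-end on a synthetic
video generator, because the original microscopy videos are not publicly
archived.

## Sparse dictionary learning

Patches are vectorised into columns of a data matrix $X \in
\mathbb{R}^{d\times N}$ ($d = p^2$, default $p = 20$) and factorised as $X
\approx DS$ by minimising, per patch,

$$\mathcal{L}(s_i) = \tfrac12\lVert x_i - D s_i\rVert_2^2
  + \lambda \lVert s_i\rVert_1, \qquad D_j^{\top} D_j = 1 ,$$

with $\lambda = 1$ and $M = 100$ atoms at study scale. The unit-norm
constraint prevents the trivial escape of shrinking $S$ by inflating $D$.
Optimisation alternates exactly the two convex subproblems:

* **Coding step** — cyclic coordinate descent with soft-thresholding
  (tolerance $10^{-6}$ on the largest coordinate update, at most 1000
  sweeps; ties at zero break toward zero). Codes are warm-started from the
  previous epoch, which makes the full-data objective provably
  non-increasing at every half-step — a property the test suite asserts at
  $10^{-10}$ relative tolerance.
* **Dictionary step** — block coordinate descent over atoms. With $A =
  SS^{\top}$ and $B = XS^{\top}$ the constrained minimiser for atom $j$ at
  fixed codes is the normalised residual correlation
  $D_j \propto B_j - DA_j + D_j A_{jj}$, i.e. renormalisation after every
  column update is the exact solution, not a projection heuristic.

Patches have their scalar mean subtracted before encoding (standard for
patch dictionaries; the mean is restored on reconstruction; configurable
off). Initial atoms are a seeded random sample of the patches; mini-batches
(default 15 patches, as in the study) use one fixed shuffle drawn from the
seed.

Atoms are then ranked by the leave-one-atom-out reconstruction error
$e_j = \sum_i \lVert x_i - (D s_i)_{-j}\rVert^2$ **at fixed codes** — the
formula implies codes computed once with the full dictionary, and we follow
it literally; the reduced dictionary (default: top 30 of 100) re-encodes
patches for features and reconstruction. Removing an atom can never reduce
the error at fixed codes, and an unused atom scores exactly the baseline;
both are asserted in tests. Per-frame features use *all* overlapping
patches, $v_k = \sum_i \lvert s_{i,k}\rvert$; training uses 300 random
patches per frame.

## First-order Morlet scattering

The zeroth- and first-order scattering coefficients of a frame $I$ are

$$S_0(I) = I * \phi, \qquad
  S_1^{(j,\ell)}(I) = \lvert I * \psi_{j,\ell}\rvert * \phi ,$$

subsampled by $2^J$, giving $1 + JL$ maps of $(M/2^J)^2$ pixels — 49 maps of
$32\times32$ for $M = 512$, $J = 4$, $L = 12$. The mother wavelet is a
zero-mean-corrected complex Morlet
$\psi(u) = \alpha\,(e^{i\xi\cdot u} - \beta)\,e^{-\lVert u\rVert^2/2\sigma^2}$
with $\beta$ computed *per discrete filter* so the sampled sum is exactly
zero. Dilation by $2^{j-1}$ halves the central frequency per scale (asserted
by an FFT peak-locating test); orientations sit on
$\theta_\ell = 90^\circ - (\ell-1)\,180^\circ/L$.

Numerical constants — $\xi = 3\pi/4$, $\sigma_0 = 0.8$ px, envelope slant
$4/L$ — follow common scattering-package conventions and are exposed as
arguments; exact numeric parity with any particular reference
implementation is not a goal. Two conventions deserve note:

* $\theta_\ell$ labels the orientation of the filter's *stripes* (the wave
  vector is perpendicular), so horizontal ridge-guided bands excite the
  $\theta \approx 0$ filters. This matches the interpretation of the angular
  weight plots, where ridged-surface evidence concentrates in
  $[15^\circ, -15^\circ]$.
* With $L = 12$ the grid $90^\circ, 75^\circ, \dots, -75^\circ$ spans only
  down to $-75^\circ$; the description "angles between 90 and -90 degrees"
  double-counts the endpoint, since coefficients are invariant under
  rotation by $\pi$. We implement the 12 distinct angles.

Convolutions are periodic FFT products; smaller frames are reflect-padded
to the transform size; subsampling is average pooling after the low-pass
($\sigma_\phi = 0.8\cdot 2^{J-1}$). Because the per-frame feature
$v_\alpha = \sum_{ij} X_\alpha(i,j)$ sums whole maps, circular translations
leave it exactly invariant; genuine translations of content inside the
frame change it by well under the 5 % band asserted in the tests. Map-level
translation sensitivity decreases with $J$, which the property suite
checks. Second-order coefficients are out of scope.

## Corner tracking and optical flow

Corners are pixels where the windowed structure tensor
$M = \sum_w \nabla I\,\nabla I^{\top}$ has two large eigenvalues; the
Shi-Tomasi score is $R = \min(\lambda_1, \lambda_2)$. We use
central-difference gradients and a uniform box window (the tensor window is
symmetrised to an odd size, default $10 \to 11$ px; a box rather than a
Gaussian keeps the brute-force oracle in the tests exact). Detection keeps
pixels with $R \ge \alpha\,R_{\max}$ (default $\alpha = 0.2$), sorts by
score and greedily suppresses lower-scoring corners within
$\ell_{\min} = 7$ px, returning at most $N_c = 300$ corners.

Tracking solves, per corner and frame pair, the $2\times2$ normal equations
of the window-summed brightness-constancy residual (31 px window centred on
the point), iteratively (at most 30 iterations, step tolerance 0.01 px),
coarse-to-fine over a Gaussian pyramid (sigma 1 blur, 2x decimation, 3
levels above full resolution). A trajectory dies — permanently — when its
window leaves the frame, the window tensor's smallest eigenvalue falls
below $10^{-4}$ per window pixel, or the iteration fails to converge.
Corners are detected on the first frame only, and the surviving set shrinks
monotonically.

The per-(sub)video descriptor pools every step of every alive trajectory:
$\bar v_x, \bar v_y$ are the means of the per-step displacements and
$\bar v = \sqrt{\bar v_x^2 + \bar v_y^2}$ — the magnitude *of the mean*, so
zero-mean wandering gives $\bar v \approx 0$ even when the mean speed is
large. Pooling weights trajectories by their number of alive steps; a
per-trajectory-mean option is provided since the original averaging
convention is not fully specified. Sub-videos are consecutive $n$-frame
segments from frame 0, plus the final $n$ frames when the length is not
divisible by $n$ (a 95-frame video at $n = 60$ gives frames [0, 60) and
[35, 95)); videos shorter than $n$ are used whole.

## Linear SVM and leakage-safe evaluation

Each track feeds a linear SVM $f(v) = w\cdot v + b$ trained by minimising
$C\sum_i \max(0, 1 - y_i f(v_i))^2 + P(w)$ with $P$ either
$\lVert w\rVert_1$ or $\tfrac12\lVert w\rVert_2^2$ (intercept unpenalised),
the squared-hinge/penalty convention of the solver the study used. The
settings per track are fixed: L1 with $C = 1000$ (dictionary), L1 with
$C = 5000$ (scattering), L2 with $C = 10$ (flow). Features enter raw — the
weights are then directly interpretable on the feature scale — and classes
are unweighted. The optimiser is L-BFGS-B from a zero start (L1 via the
positive/negative weight split with box constraints, which yields exact
zeros); it is deterministic, and on separable toys agrees in direction with
an independent SVM implementation to $\cos > 0.99$.

Splits operate on whole videos, never frames: class-wise partition into
three groups (each group tested once; e.g. 5 ridged videos split 2/2/1, 12
flat 4/4/4) for the frame tracks, and repeated random 2:1 splits for the
flow track. Rotation-augmented copies carry their source id and are forced
onto the same side of every split. Frame-level predictions
$\operatorname{sign} f$ are aggregated to video labels by majority voting;
exact ties break by the sign of the video's mean score (logged in the
report). Confusion matrices put true classes on rows.

## The synthetic generator: what it emulates, and what not

`genRidgedVideo()` renders bright bands with the 7.6 px spacing implied by
the 1.6 um ridge pitch at 0.21 um/px, inside a soft-edged, lobed cell mask;
band intensity is modulated along the bands so that the quasi-1D texture
still contains trackable corners. `genFlatVideo()` renders isotropic
annular wavefronts expanding from a few sources, plus persistent speckle
puncta that move rigidly with the cell — without a persistent component all
image structure would be travelling wavefronts and no stable features would
exist to track. Motion is a per-video drift (field on) plus a Gaussian
random walk of the cell centre (wander sigma 0.3 px/frame); field-off
videos always have zero drift.

Design choices worth recording:

* **Wave motion is periodic, not secular.** Band phase sloshes
  sinusoidally (amplitude half a band period over a 20-frame cycle) and
  ring re-nucleation shares the same period. A steadily advancing phase
  would add a spurious net texture velocity and make the imposed drift
  unrecoverable; with periodic internal dynamics, only drift and wander
  move the texture on average, so phase correlation at a one-cycle lag and
  corner tracking both recover the drift to better than 0.1 px/frame.
* **Field response is heterogeneous.** In `genDataset()` each field-on
  video draws its drift magnitude from a Gamma distribution (shape 3, mean
  0.5 px/frame, leftward) and a response lag uniform on [0, 50] frames
  before the drift sets in, emulating the observed variability and latency
  of electrotactic responses. This heterogeneity is what makes short
  sub-videos genuinely harder to classify than long ones — segments that
  fall before a cell's response onset look field-off — reproducing the
  qualitative accuracy-versus-$n$ shape of the study.
* **Framing follows the cell.** Drifting cells start offset by half their
  total transit so they stay in the field of view, as an experimenter
  would frame them.
* **Noise is additive Gaussian** (sigma 0.03), not Poisson — adequate for
  the texture statistics exercised here. "Unfused cell" distractor blobs
  are available but off by default.

The generator is deterministic per seed, byte for byte. What it does *not*
emulate: reaction–diffusion wave dynamics, optics (PSF, shot noise),
photobleaching, wave nucleation statistics, or the spatial intermittency of
real actin waves. Passing the synthetic suite therefore demonstrates that
the pipeline's machinery is correct and that the features separate the
encoded phenomenology; it does not certify the real-data accuracies, which
depend on unreleased microscopy videos.

## Problem sizes, tolerances and degenerate inputs

The test suite and acceptance script run the full pipeline at reduced
scale, chosen so every stage is still exercised across several videos per
class: 64 px frames with 12 px patches and a 32-atom dictionary reduced to
16 for the static tracks (6 + 6 no-field videos of 8 frames), and 96 px,
100-frame videos (five per environment) with 50 corners for the flow track.
Geometry checks (49 filters, 32x32 maps) run at the full 512 px. The
drift-recovery statistic uses 60-frame videos and a 20-frame correlation
lag; phase-correlation whitening is regularised at 1 % of the spectral
maximum because exact whitening is badly biased on smooth noise-free
images.

Degenerate inputs are defined errors, not crashes: empty stacks, mixed
frame sizes, patches larger than the frame, fewer patches than atoms,
single-class training data, track sets without steps, sub-video lengths
below 2. An empty corner set is a legitimate result of a high quality
threshold. Dictionary atoms with zero residual correlation keep their
previous value rather than dividing by zero; lasso ties at zero break
toward zero.

## Known limitations

* Numeric parity with the original pipeline's feature values is not
  attainable from the publication (unstated Morlet constants, solver
  internals, epoch counts) and is not claimed; all quantitative assertions
  are about self-contained arithmetic, oracle equivalences, and synthetic
  recovery.
* The L1-penalised SVM objective is not strictly convex; different solvers
  can return different weight vectors of equal loss. Tests therefore
  assert accuracies, sparsity patterns and decision directions, not weight
  values.
* Rotation handling assumes square frames and 90-degree multiples;
  arbitrary-angle augmentation would require interpolation and is out of
  scope.
* The flow summary assumes corner identity is preserved by tracking;
  re-detection or re-seeding mid-video is deliberately not implemented.
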