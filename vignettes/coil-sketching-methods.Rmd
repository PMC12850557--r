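---
title: "Coil-sketched reconstruction of respiratory-resolved lung MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coil-sketched reconstruction of respiratory-resolved lung MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The reconstruction problem

Free-breathing lung MRI acquires non-Cartesian (stack-of-spirals) k-space
continuously while the diaphragm moves. Retrospectively, every readout is
assigned to one of $R$ respiratory states, and the respiratory-resolved image
stack $x \in \mathbb{C}^{R \times J}$ ($J$ voxels per state) is recovered by
solving

$$
x^\star=\arg\min_x \tfrac{1}{2}\,\bigl\lVert P^{1/2}(FSx-k)\bigr\rVert_2^2+g(x),
$$

where $k$ is the sorted multicoil data ($C$ coils, $K_r$ samples per state),
$S$ the coil sensitivities, $F$ the non-uniform Fourier encoding evaluated by
NUFFT, $P$ a diagonal k-space preconditioner, and $g$ a regularizer. The
data-consistency term is block-diagonal over respiratory states, so 4D
reconstruction is a coupled series of 3D (or, in this package's test mode, 2D)
problems tied together only by $g$.

Every forward/adjoint pair in the package is an *exact* adjoint pair by
construction (the gridding weights are real and shared), so inner-product
identities hold to machine precision; the NUFFT's *approximation* accuracy
relative to an exact DFT is set by its Kaiser-Bessel kernel (oversampling 2,
width 8, Beatty beta), around $10^{-7}$ relative.

## Regularizers

* `tv` — $\lambda\lVert Gx\rVert_1$ with $G$ the spatio-temporal first
  differences. The phase axis is differenced circularly by default because
  breathing is cyclic; spatial axes use zero-boundary forward differences.
* `lr` — $\lambda\lVert x\rVert_*$, the nuclear norm of the $R \times J$
  Casorati matrix. Its prox is exact singular-value soft-thresholding.
* `mocolr` — $\lambda\lVert Mx\rVert_*$ with $M$ the linear operator warping
  all states onto a reference. Its proximal update is the forward-only sweep
  described below.
* `cgsense` — Tikhonov $\lambda\lVert x\rVert_2^2$, solved with CG.

## Forward-only motion-compensated low-rank update

Optical-flow motion fields are not diffeomorphic: composing forward and
inverse warps accumulates error over iterations. The proximal update here
never inverts a field. For each reference state in turn, all states are
warped *onto* that reference, the aligned Casorati matrix is soft-thresholded
in its singular values, and only the reference row of the result is kept.
One sweep over references updates every state, at the cost of $R$ times more
registrations, each of which is cheap at these problem sizes. When all
fields are zero (a static stack) the sweep collapses exactly to the nuclear
prox, which the tests assert.

Motion fields are estimated once, from the warm-start image after the
initial compressed iterations, and cached (`moco_refresh` can force
re-estimation every so many outer iterations). Registration uses multi-scale
Horn-Schunck optical flow on magnitude images (Gaussian pyramid, incremental
warping, Jacobi relaxation). The flow hyperparameters are this package's
own: smoothness weight `alpha = 0.5` on unit-normalized intensities, 3 warp
updates of 60 Jacobi iterations per level, and at least 3 pyramid levels.
They were chosen so that a known rigid translation is recovered to a
fraction of a voxel and the phantom's analytic fields to well under a voxel
RMS; they are deliberately on the smooth side because lung parenchyma is
nearly homogeneous and the flow must interpolate between the diaphragm edge
and vessel texture.

## Coil sketching

The expensive term in every iteration is $A^HAx$ with $A = P^{1/2}FS$. Coil
sketching replaces $A$ inside the inner loop by a sketched operator
$A_{S_t}$ built from $C_S \ll C$ random coil combinations, while anchoring
each outer iteration $t$ with one full-operator gradient at the anchor
$x_t$:

$$
\nabla f_{S_t}(x)=A_{S_t}^HA_{S_t}(x-x_t)+\bigl[A^HA x_t-A^Hy\bigr].
$$

This anchored form is pinned down by two exact identities that the test
suite enforces: at $x = x_t$ the sketched gradient
equals the full gradient for *any* sketch, and under the identity sketch it
equals the full gradient everywhere. The anchor term is computed once per
outer iteration with coil batching (batch size $C_S$), which is what caps
peak memory in the full-scale setting.

Sketches keep virtual coil 1 (the highest-energy coil after SVD reordering)
verbatim; the remaining $C_S-1$ rows are independent Rademacher $\pm 1$
combinations of coils $2..C$ scaled by $1/\sqrt{C_S-1}$, so
$\mathbb{E}[S_t^HS_t]$ is the identity on the non-kept coils. The phrase
"randomly selected" could alternatively mean subset selection; the mixing
interpretation is implemented as the default because a random *combination*
of coils is what makes the sketch an unbiased dimension reduction, and pure
selection remains available (`mode = "select"`). A realized Rademacher
sketch can have operator norm above 1 even when $\lVert A\rVert = 1$, so
each sketched block estimates $\lVert A_{S_t}^HA_{S_t}\rVert$ with a few
power iterations and scales the inner step by its inverse; CG needs no such
control.

The schedule follows the reference settings: 5 initial iterations on the
top-$C_S$ SVD-compressed coils (warm start, no anchor term — the initial
phase is a plain compressed reconstruction), then 6 outer iterations of 5
inner iterations each, a fresh sketch per outer iteration drawn from a
per-iteration sub-seed. The conventional reconstruction is the same driver
with the full operator throughout, so the degenerate sketch $C_S = C$ with
identity sketches reproduces its trace to float tolerance. The long
convergence reference uses 199 outer iterations (1000 total as counted by
this schedule); the desk-scale experiment harness uses a 200-iteration
reference and records that count in its report.

## Toeplitz embedding

$F^HPF$ is a convolution, so $A^HAx$ can be evaluated without any k-space
interpolation: zero-pad $S_cx_r$ onto a $2\times$ grid, multiply by a
precomputed frequency-domain kernel, inverse FFT, crop, and combine with
$\bar S_c$. The kernel is the adjoint NUFFT of the preconditioner weights
onto the $2\times$ grid; $2\times$ (per axis) is the exact linear-convolution
embedding and is independent of the $1.33\times$ reconstruction-matrix
padding. Because the kernel depends only on the trajectory and weights —
never on the coils — the same per-state kernels serve the full, compressed,
and sketched operators, and enabling it changes the final images by far
less than $10^{-3}$ NRMSE on the test instances.

## Preconditioning and normalization

The single-channel k-space preconditioner is the Frobenius-optimal diagonal
for $FF^H$ computed from the trajectory's point-spread function:
$p_i = \psi(0)\,/\,\sum_j\lvert\psi(\kappa_i-\kappa_j)\rvert^2$, where
$\psi$ is the Fourier transform of the unit image mask; the correlation sum
is evaluated with two NUFFTs on a $2\times$ grid. On a fully-sampled
Cartesian trajectory the weights are constant, and on spirals the
preconditioned single-channel spectrum is verifiably better conditioned
than the raw one. A Pipe-Menon density-compensation fallback sits behind
`precond = "dcf"`. After preconditioning, the largest eigenvalue of $A^HA$
is estimated by the power method (tolerance $10^{-7}$ on the Rayleigh
quotient) and folded into the weights so the spectrum lies in $[0, 1]$ and
unit steps are stable; $P^{1/2}$ multiplies both the operator and the data,
consistently.

## Solvers

* `cg` — conjugate gradient on the (possibly sketched) normal equations;
  quadratic regularizers only.
* `fista` — accelerated proximal gradient with momentum restart on objective
  increase; TV uses an inner Chambolle dual prox.
* `pdhg` — Chambolle-Pock with the *regularizer* dualized ($K$ = finite
  differences for TV, identity otherwise, dual prox via Moreau) and the
  smooth data term handled inside the primal update by `pdhg_inner = 4`
  gradient steps on the proximal subproblem. Placing the data term in the
  primal (rather than dualizing it) is this package's choice where the
  splitting placement was not specified; the $\lambda = 0$ cross-checks
  against CG cover it.

The objective trace always evaluates the data term with the *full* operator,
never the sketched one, so convergence curves of all arms are comparable.

# The synthetic study

No raw patient data are available, so the package ships a seeded analytic
phantom and acquisition simulator that together stand in for the study
conditions; every generator is a pure function of its spec and seed.

* **Phantom.** A torso ellipse (intensity 1), two lungs at a parenchyma
  level of 0.35, zero-intensity cysts, bright vessel-like inclusions, and a
  low-order polynomial phase map (so complex-valued code paths are
  exercised without destabilizing magnitude-based registration). Breathing
  is an SI translation plus uniform SI stretch of each lung about its fixed
  apex, with the diaphragm displaced by
  $a\sin(2\pi p/R)$ voxels; parenchyma intensity scales inversely with the
  stretch, so total lung signal is conserved across states (within ~2%
  rasterization error) — the density behaviour that makes respiratory-
  resolved lung MRI useful. The motion is analytic, so ground-truth
  displacement fields are exact, which is what registration and MoCo tests
  compare against.
* **Acquisition.** Golden-angle (~222.4922°) Archimedean spiral interleaves
  (397 per kz at full scale; desk-scale tests use fewer), TR 8.3 ms,
  readout 5.4 ms, an SI navigator sampled every 120 ms, 4-s breathing
  period, complex Gaussian noise. The navigator waveform is a sinusoid plus
  noise — its shape is not specified by the reference pipeline and is this
  package's choice. The generating respiratory phase is defined as the
  analytic-signal phase of that waveform, so the retrospective Hilbert-
  phase binning can be scored against the generating schedule (the
  agreement requirement is 95% at zero navigator noise).
* **Binning.** Equal-width phase bins on $[-\pi,\pi)$; whole readouts are
  assigned using their start time (navigator cadence is much coarser than a
  readout). Equal-width versus equal-count binning was left open by the
  reference pipeline; equal-width is implemented and documented as the
  convention, with a sign flip available for the inhale/exhale convention.
* **What the generator does not emulate:** T2*/UTE decay, off-resonance,
  slab profiles, gradient-trajectory errors, bulk motion, or realistic coil
  noise correlation (pre-whitening is still exercised with synthetic
  correlated noise). Passing tests therefore demonstrate the *numerics* of
  the pipeline — operator correctness, solver equivalences, sketching and
  Toeplitz behaviour, binning and registration recovery — not clinical
  image quality.

## Desk-scale problem sizes

The shipped test and acceptance instances are chosen so the full pipeline
runs in seconds to a few minutes on one CPU: a $32\times32$ grid with 6
coils and 3 respiratory states (about 92k spiral samples over three
breathing cycles) for the reconstruction arms, a $24\times24$, 4-coil,
2-state instance for replica loops, and a $48\times48$, 6-state phantom for
registration. 2D+time is a first-class mode — every operator is
dimension-agnostic over $d\in\{2,3\}$ and the 3D paths are exercised by the
operator tests — because the full 3D acquisition scale is a GPU-class
workload by design.

## Sensitivity maps

Maps are estimated once from phase-pooled data (the reference pipeline also
estimates a single map set): samples near the k-space centre are gridded
onto a 2-fold downscaled grid, calibration kernels are harvested by SVD of
the block-Hankel calibration matrix (defaults: calibration width 16,
kernel 4, null-space threshold 0.02 — named but unparameterized in the
reference, so set here as configurable defaults), per-voxel eigenvectors
give unit-norm maps masked at 95% of the peak eigenvalue, and the result is
Fourier-upscaled to the full grid, phase-referenced to coil 1, with
root-sum-of-squares clamped to 1. On the synthetic fixture the estimated
magnitudes agree with the (RSS-normalized) truth to ~4.5% RMS in the
high-signal region, and reconstructions with estimated versus true maps
differ by ~1% NRMSE.

## Numerical conventions and edge cases

* Coordinates are in grid units, each axis in $[-N/2, N/2)$, DC at the
  centred voxel $\lfloor N/2\rfloor$; out-of-box coordinates are an error,
  not a wrap.
* The $1.33\times$ reconstruction padding enlarges the FOV at fixed
  resolution: the grid grows to the next even size and coordinates scale by
  the actual ratio.
* Empty respiratory bins, constant navigators, stale sketch anchors,
  non-finite motion fields, and non-finite exports are all named errors
  rather than silent degradation.
* HDF5 containers are written with object-time tracking disabled and NIfTI
  exports uncompressed, so identical inputs produce byte-identical files —
  the determinism the CLI tests assert.

## Known limitations

The MoCo-LR sweep is a prox-like mapping, not provably the prox of a single
penalty $g$ (whether the per-reference sweep corresponds to one is an open
question); its reported objective uses alignment to state 1 as a fixed
reporting convention. Horn-Schunck flow underestimates displacement in
texture-free regions and the analytic fields are discontinuous at the lung
boundary, so field-recovery guarantees are stated inside the lung mask.
The pseudo-replica SNR of iterative, regularized arms depends on the
(common) iteration budget; only ratios between arms at matched budgets are
meaningful. GPU kernels, vendor raw formats, trajectory correction, and
diffeomorphic registration are out of scope.
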