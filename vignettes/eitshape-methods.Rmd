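---
title: "Implicit shape reconstruction for EIT: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implicit shape reconstruction for EIT: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Electrical impedance tomography (EIT) drives small currents through
electrodes on the boundary of a body and records the resulting boundary
voltages; the governing model is the elliptic equation
$\nabla\cdot(\sigma\nabla u)=0$ on the domain $\Omega$ with Neumann data (the
injected current) on $\partial\Omega$ and the grounding condition
$\int_{\partial\Omega}u=0$. Recovering the interior conductivity $\sigma$
from boundary data is severely ill posed. `eitshape` targets the *shape*
version of the problem: the background conductivity is known (unit), and the
task is to decide, for any point $p$ of the domain, whether $p$ lies in the
homogeneous background or inside an anomaly. The package implements the full
simulation-to-inversion chain on the unit disk with $L=16$ point electrodes:

* a P1 finite-element forward solver under the adjacent source–sink
  protocol, producing the $L(L-3) = 208$-entry measurement vector $m$, the
  discrete Neumann-to-Dirichlet (NtD) matrix $\Lambda_\sigma$, and the exact
  adjoint Jacobian $\partial m/\partial\sigma$;
* random circular-anomaly phantom and dataset generation with stratified
  labelled point clouds and Gaussian measurement noise;
* an implicit (coordinate-based) classifier: a measurement encoder, a point
  encoder and a decoder built from fully connected residual blocks, trained
  with ADAM on cross-entropy to predict anomaly membership of arbitrary
  continuous points;
* a monotonicity-test baseline that probes small balls for inclusion in the
  anomalous region via positive semi-definiteness of NtD differences; and
* iteratively regularized Gauss–Newton (IRGN) conductivity reconstruction in
  standard, shape-constrained and piecewise-constant modes.

## Forward model and discretization

The disk is meshed by placing nodes on concentric rings (outer-ring count
rounded to a multiple of $L$ so the electrode angles $2\pi k/L$ fall exactly
on nodes) and Delaunay-triangulating them. Interior rings carry a $10^{-4}$
deterministic radial ripple: exactly co-circular rings are a degenerate
input for Delaunay codes, and the ripple removes the degeneracy without
measurably moving any node. Two stock refinements are used: the *training
mesh* $h=0.08$ (856 triangles) for data generation and evaluation, and a
*fine mesh* $h=0.035$ (5048 triangles) for super-resolution experiments.
Several structural checks (total area $\to\pi$, conforming edges, one
boundary edge per boundary triangle) are enforced in the test suite.

Conductivity is piecewise constant per triangle (P0), potentials are P1. The
pure-Neumann stiffness system is grounded by a Lagrange multiplier enforcing
zero mean over the boundary nodes, which matches the continuous grounding
condition and keeps the augmented system symmetric; pinning a single node
instead would ground the system asymmetrically and condition the solve on an
arbitrary node choice. Electrodes are ideal points: each injection puts
$\pm 1$ units of current on the two drive nodes. One sparse LU factorization
per conductivity serves all 16 drive patterns, the 15 NtD basis solves and
the 16 adjoint solves of the Jacobian.

Two conventions deserve a note:

* **Pair orientation.** Electrodes are numbered counterclockwise and the
  "right-hand neighbour" of electrode $k$ is $k+1 \bmod L$; a measurement is
  $u(e_k)-u(e_{k+1})$ for every adjacent pair containing neither drive
  electrode. Under this orientation every recorded difference is negative
  (the potential rises monotonically from sink around to source), which is
  physically immaterial but matters for the noise scale below.
* **Analytic validation.** For the homogeneous disk the boundary potential
  of a two-point injection is the logarithmic pair potential
  $u(x)=\tfrac{1}{\pi}\left(\ln|x-b|-\ln|x-a|\right)$ up to a constant. The
  validation compares FEM and analytic boundary values *away from a fixed
  0.2 rad arc around each drive point*: the analytic solution is singular at
  the drives and nodal FEM values there do not converge pointwise, so a
  fixed exclusion zone (about half an electrode spacing, mirroring the
  protocol's own exclusion of drive-adjacent pairs) is the quantity that
  converges cleanly — observed relative $L^2$ errors are $\approx 7\cdot
  10^{-4}$ at $h=0.08$ and $\approx 1.6\cdot10^{-4}$ at $h=0.04$.

## Phantoms, labels, noise

A phantom is up to four circular inclusions over unit background. The
generator draws radii $\sim U(0.1, 0.35)$, centres uniform over the sub-disk
where the circle fits with margin $0.05$, and conductivities log-uniform on
$[0.2, 5]$ with the dead zone $(0.8, 1.25)$ excluded. The source study
states only "random radius and conductivities"; these ranges are the
package's fixed convention, chosen so inclusions span conductive and
resistive contrasts while the dead zone guarantees that "anomaly" is
well defined against the unit background. Overlapping circles are allowed;
a point is anomalous iff it lies strictly inside any circle, and
rasterization onto a mesh assigns a triangle the conductivity of the last
circle (in list order) containing its centroid.

Training labels come from the continuous membership rule, never from the
rasterized field — the same separation the evaluation uses, so no inverse
crime couples the classifier to the mesh. Point clouds are stratified:
exactly half the points uniform over the background region, half uniform
over the anomaly region (by direct per-circle sampling with union-coverage
rejection, which stays cheap for small inclusions).

Measurement noise at level $\delta\%$ adds i.i.d. Gaussians of standard
deviation $\max(|m|)\cdot\delta/100$. The printed formula in the source
protocol reads "$N(0,\max(m))\cdot\delta/100$" and leaves open whether the
maximum is over signed entries; under this package's pair orientation all
entries of $m$ are negative, so the signed maximum would give a degenerate
(negative or near-zero) scale and the magnitude maximum is the only
consistent reading. Noise is always drawn fresh — per epoch during training,
once per validation pass with a logged seed during evaluation — and never
stored with a dataset record.

## The implicit classifier

All hidden widths are multiples of a single integer `scale` (default 2).
The measure encoder maps the 208-vector through six residual blocks
($208 \to 128s \to 128s \to 128s \to 64s \to 64s \to 64s$); the point
encoder maps a normalized point through two blocks ($d \to 32s \to 64s$);
the decoder takes the elementwise *sum* of the two embeddings through two
blocks ($64s \to 32s \to 2$) and a stabilized softmax. Classification is
"background iff the background probability strictly exceeds the anomaly
probability", so exact ties go to anomaly. A residual block here is
Linear($in\to out$) + LeakyReLU + Linear($out\to out$), with an identity
shortcut when $in=out$ and a single linear shortcut otherwise, and a final
LeakyReLU after the addition; the source figure shows the two shortcut
variants but not the internal layer count, and two linear layers is the
minimal standard unit.

**Initialization.** Weights start uniform with fan-in scaling
($U(\pm 1/\sqrt{fan_{in}})$) from a recorded seed, and the default training
path then applies a *standardization-folded* correction to the first
measure-encoder block (`init_params_standardized()`): the block is
re-parameterized so the network effectively sees the training measurements
centred by their mean and scaled by their mean cross-record standard
deviation. The transform is folded into the block's weights, so the function
class is untouched — this is a data-dependent initialization in the LSUV
family, not an architecture change. It matters because the global 0–1
min–max normalization leaves the informative cross-experiment signal as a
small ripple on a large common offset; a generic init then produces
measurement embeddings that are nearly constant across experiments, and the
optimizer spends a large share of the step budget at the unconditional
optimum of the loss — the value reached by ignoring the measurements
entirely — before conditioning begins. The folded initialization removes
that warm-up; the test suite's capacity check (ten phantoms, 300 optimizer
steps) verifies that training lands far below the unconditional optimum.
Plain uniform initialization remains available via
`train_implicit(..., init = "uniform")`.

Measurements are normalized to $[0,1]$ by a *single global* min–max fitted
on the training split only (the protocol says "the maximum–minimum",
singular); points are mapped per coordinate from $[-1,1]$ to $[0,1]$.
Normalization is affine and never clips, so out-of-range validation values
map outside $[0,1]$.

The implicit structure is what makes evaluation cheap: the measurement
embedding is computed once per experiment and reused for every query point,
so a full-mesh prediction costs one measure-encoder pass plus one
point-encoder/decoder pass per triangle centroid. The package asserts that
this amortized path is bit-identical to evaluating each point separately.

## Training procedure

Per epoch the training records are shuffled into batches of 64; for every
record a *fresh* stratified cloud is drawn and *fresh* measurement noise at
the training level (0.1% by default) is added; one ADAM step is taken per
batch on the mean cross-entropy over all point predictions, with the anomaly
probability clamped to $[10^{-7}, 1-10^{-7}]$. Every ten epochs the ADAM
moment estimates are reset and the learning rate is multiplied by $2/3$
(starting from $5\cdot10^{-4}$), i.e. $lr(e) = 5\cdot10^{-4}(2/3)^{\lfloor
e/10\rfloor}$; "resetting the optimizer" is read as re-initializing the
moments while keeping the parameters, because the protocol couples the reset
to the learning-rate change. The best-validation-accuracy parameters (at 0%
validation noise, one logged noise seed per pass) are returned together with
the full history.

The reference protocol trains for 1000 epochs on 16,384 phantoms with
1024-point clouds. Desk-scale runs in this package shrink the *sizes*, never
the protocol, and apply one scaling rule to the schedule: at the reference
composition, "decay every 10 epochs" means decay every 2,560 optimizer steps
(batch 64), so scaled-down datasets keep the *steps per decay stage* rather
than the epochs per stage (`scaled_decay_interval()`; it reduces to exactly
10 epochs at the reference size). Without this rule a dataset scaled down by
a factor $f$ decays $f$ times faster per optimizer step than the reference
protocol and the learning rate collapses before conditioning on the
measurements develops. Desk-scale accuracy tracks the optimizer-step
budget, not the epoch count alone; the suite and acceptance-script runs
state their sizes inline (512 train / 48 validation phantoms, 90 epochs,
256-point clouds) and report the accuracy those budgets actually attain.

What the synthetic generator does *not* emulate: real electrode contact
impedance (ideal point electrodes only), non-circular anomaly shapes,
spatially varying backgrounds, correlated or non-Gaussian measurement noise,
and 3-D geometry (the point encoder accepts $d=3$ at the type level but all
experiments are 2-D). Passing tests therefore demonstrate the method under
the simulation assumptions, not tank-data performance.

## Monotonicity baseline

For conductivities $\sigma_1\le\sigma_2$ the NtD operators satisfy
$\Lambda_{\sigma_1}\succeq\Lambda_{\sigma_2}$. The baseline probes a
hexagonal grid of small balls (spacing 0.1, radius 0.1, kept inside radius
0.95): for a conductive anomaly, a ball $B$ is flagged iff
$\Lambda_{1+c\,\mathbf 1_B}-\Lambda_{\text{measured}}$ is positive
semi-definite; resistive anomalies use the mirrored difference, and the
default "both" direction flags a ball if either test passes. Test contrasts
are $+1$ (conductive) and $-0.5$ (resistive) — the theory wants a contrast
below the true one, which is not known, so these sit inside the generator's
dead-zone-to-extreme range. Ball NtD operators are precomputed once per
(mesh, grid, contrast). PSD is decided on the smallest eigenvalue with
relative tolerance $10^{-10}$ at zero noise; the test's extreme noise
sensitivity is the point of the comparison — at 1% measurement-scale noise
the flag set is empty, and the package reproduces exactly that.

## IRGN reconstruction

All three modes iterate
$\theta_{k+1} = \theta_k + (J^\top J+\alpha_k I)^{-1}\left(J^\top(m_{obs} -
F(\sigma_k)) - \alpha_k\theta_k\right)$ in a reduced parameterization
$\sigma = base + P\theta$, with $J$ the adjoint Jacobian restricted by $P$,
a Tikhonov term anchored at the initial (background) guess, and box
projection onto $[0.05, 20]$ after each step. `standard` uses $P=I$ (every
triangle free); `constrained` restricts $P$ to the flagged triangles of a
predicted mask, freezing the rest at background; `piecewise` has one scalar
per edge-connected mask component. The schedule is
$\alpha_k=\alpha_0\cdot0.8^{k-1}$ with
$\alpha_0=\max(10^{-3}\|J^\top r_0\|_\infty,\;10^{-9}\max\mathrm{diag}(J^\top J))$
over at most 20 iterations, stopping early when the relative residual
improvement falls below $10^{-4}$; the floor term keeps the normal equations
well posed when the data are exactly consistent with the initial guess
(zero-residual fixed point). These hyperparameters are the package's own:
the source defers all IRGN details to its reference literature, which is why
absolute error values are not reproduction targets — only the *ordering*
(constrained $\le$ standard on noisy data) is. Reconstruction error is the
element-area-weighted norm
$\|\hat\sigma-\sigma\|=\sqrt{\sum_T |T|\,(\hat\sigma_T-\sigma_T)^2}$.

## Numerical choices and degenerate inputs

* Solver residuals: the grounded sparse LU gives relative residuals at
  machine level; NtD symmetry holds to $10^{-12}$ and is re-symmetrized
  before eigendecomposition.
* Rasterizing a phantom whose circles are thinner than a triangle can
  produce an empty mask; constrained/piecewise IRGN warn and return the
  background field.
* `classify` maps exact probability ties to anomaly (strict inequality for
  background).
* Component adjacency is shared-edge, not shared-vertex, so two inclusions
  touching at a point stay separate parameters.
* All randomness flows from explicit seeds: datasets store one seed per
  record and regenerate bit-identically; training is deterministic given its
  master seed; every noisy evaluation logs its noise seed.

## Known limitations

The classifier assumes the known unit background that the generator
enforces; accuracy degrades for inclusions close to the dead zone or the
boundary margin. The monotonicity baseline is only meaningful at zero noise
and its resolution is bounded by the ball grid. The IRGN linearization uses
the full dense Jacobian, which is comfortable at the mesh sizes shipped here
(hundreds to thousands of triangles) but would need matrix-free treatment on
finer meshes. Desk-scale training accuracy is limited by the optimizer-step
budget and remains below the full-scale reference accuracy (≈ 0.978 at
16,384 phantoms × 1000 epochs); the acceptance script reports the accuracy
its own scaled run attains, and larger budgets move it upward monotonically
in our experience with this implementation.
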