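---
title: "Physics-informed recovery of heterogeneous elastic properties: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed recovery of heterogeneous elastic properties}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Elastography estimates how stiff a material is, point by point, from how it
deforms under load. The measurable quantity is a two-dimensional displacement
field $(u_x, u_y)$ on a regular grid — from ultrasound speckle tracking,
digital image correlation, or (here) a finite-element simulation. The
quantities of interest are the Young's modulus field $E(x,y)$ and Poisson's
ratio field $\nu(x,y)$ of a thin plate in plane stress. The forward physics is
standard linear elasticity:

* strain from displacement:
  $\varepsilon_{xx} = \partial_x u_x$, $\varepsilon_{yy} = \partial_y u_y$,
  $\gamma_{xy} = \partial_y u_x + \partial_x u_y$;
* stress from strain (isotropic plane stress):
  $\sigma = \frac{E}{1-\nu^2}
  \begin{pmatrix} 1 & \nu & 0\\ \nu & 1 & 0\\ 0 & 0 & (1-\nu)/2 \end{pmatrix}
  \varepsilon$;
* static equilibrium:
  $r_x = \partial_x \sigma_{xx} + \partial_y \tau_{xy} = 0$,
  $r_y = \partial_x \tau_{xy} + \partial_y \sigma_{yy} = 0$.

The inverse problem is ill-posed in two specific ways this package is built
around. First, numerical differentiation amplifies measurement noise, and the
equilibrium residual needs *second* derivatives of displacement; direct
finite differencing of noisy data fails even at mild noise. Second, the
equilibrium equations are homogeneous of degree one in $E$: if $E(x,y)$
satisfies them, so does $c\,E(x,y)$ for any $c>0$, so displacement data alone
determine the modulus only up to a global scale.

The method answers both with a two-phase design:

* **Phase 1** trains three sine-activated coordinate networks — a
  displacement network (a denoiser: fits the noisy data), a strain network
  (fits the finite-difference strain of the *displacement network's* output,
  decoupling the residual computation from raw data), and an elasticity
  network (outputs $E$ and $\nu$) — against a four-term loss. The recovered
  modulus is anchored to an arbitrary reference $E_c$ and is therefore
  *relative*.
* **Phase 2** integrates the predicted boundary-normal stress along the
  loaded edge and compares it with the known total applied force $F$,
  recovering the scale $\hat c = F / \sum_i \hat\sigma_{xx}(x_b, y_i)\,h$ and
  with it the absolute modulus $E_\text{abs} = \hat c\,\hat E$. Poisson's
  ratio, being a dimensionless ratio, needs no calibration.

## Discretization

All derivatives are correlation-style kernel sums on the grid (`fd_kernels()`,
`valid_convolve()`): $2\times 2$ kernels take node displacements to
cell-center strains (grid $N_x\times N_y \to (N_x-1)\times(N_y-1)$), and
$3\times 3$ kernels take cell stresses to interior equilibrium residuals
($\to (N_x-3)\times(N_y-3)$). Strain, stress, and elasticity all live on the
same cell grid, so the constitutive law applies pointwise with no
interpolation.

Two spacing conventions are implemented, because the source arithmetic is
ambiguous about division by grid spacing. `"physical"` (the default) divides
x-differences by $t$ and y-differences by $h$ (each $3\times3$ kernel sums
three central differences spanning two cells, hence the $6t$ / $6h$
denominators), making both operators exact on affine fields and
unit-consistent. `"paper_literal"` applies the kernels undivided for strain
and divides the residual by the product $h\,t$. On a uniform grid the two
differ by global per-axis factors; the residual normalization and Phase-2
calibration absorb global factors, so square-pixel results agree.

The PDE loss normalizes the residual magnitude by $\tilde E$, the $3\times3$
neighborhood sum of the predicted modulus over the same stencil window. This
makes the loss invariant to a global rescaling of $E$ — deliberately so: the
scale direction is left to the $E_c$ anchor in Phase 1 and to the force in
Phase 2, instead of fighting the residual term.

## The training objective

With $\lambda$-weighted terms (all L1):

* $L_u$: mean $|\hat u - u^*|$ over the node grid (both components);
* $L_\varepsilon$: mean absolute difference between the strain network and
  the finite-difference strain of the displacement network (three
  components);
* $L_r$: mean of $(|r_x| + |r_y|)/\tilde E$ over the residual grid, with
  stress assembled from the strain and elasticity networks;
* $L_E$: the modulus anchor. Two modes exist: `"pointwise"`
  (mean $|\hat E - E_c|$, the printed equation, the default) and
  `"mean_anchor"` ($|\overline{\hat E} - E_c|$, the prose description:
  "constraining the mean"). The pointwise form actively flattens spatial
  contrast — it penalizes every deviation from $E_c$, not just the scale —
  so heterogeneous recovery is measurably better under `"mean_anchor"`,
  which the acceptance configurations use; the pointwise default is kept
  because it is what the printed equation says.

**Internal loss normalization.** The four terms carry different physical
units (length, strain, strain/length, stress), and their raw magnitudes vary
with grid spacing and load size by orders of magnitude. Naively weighting the
raw terms makes the strain-consistency gradient on the displacement network
~$1/t$ times stronger than the data term — at fine spacing the networks
drift off the data and co-adapt to please the physics term, which we observed
directly (the displacement loss rising well above its pretrained level while
the PDE loss fell *below* the value the ground truth attains). The training
objective therefore divides each term by a data-derived scale (mean absolute
displacement; mean absolute finite-difference strain; that strain scale per
stencil length; $E_c$), making the exposed weights dimensionless. The
exported loss functions (`loss_displacement()` etc.) remain literal
definitions; normalization is a property of the optimization, not of the
metrics.

**Default weights** are $\lambda_u = 10$, $\lambda_\varepsilon = 1$,
$\lambda_r = 1$, $\lambda_E = 10^{-3}$ (all exposed in `train_config()`).
The source work states only that weights were chosen by empirical
exploration; ours were chosen the same way, on a clean inclusion phantom,
before the acceptance thresholds were evaluated. The structure matters more
than the values: the displacement network must be anchored to data more
strongly than the strain-consistency pull (factor ~10), and the PDE term must
dominate the modulus anchor by orders of magnitude, since $\lambda_E$'s only
legitimate job is pinning the arbitrary scale.

**Pretraining.** Stage 1 fits the displacement network alone to the data;
stage 2 fits the strain network to the finite-difference strain of the stage-1
output; only then does joint training of all three networks begin. This
mirrors the source procedure (50k + 100k iterations at paper scale) and is
reproduced proportionally in the reduced presets. Disabling pretraining
(`pretrain = FALSE`) folds the pretraining budget into joint training so
ablation comparisons hold total cost fixed.

**Optimizer.** Full-batch Adam over the whole grid with a cosine-decayed
learning rate (to 0.1% of peak). The `paper_scale` preset keeps the literature
rate $10^{-4}$; the reduced presets use $2\times10^{-3}$ because a rate sized
for a 200k-iteration schedule cannot move the networks in a few thousand
iterations. The elasticity network optionally gets a learning-rate multiplier
(`el_lr_mult`): it is the only network with no data term, its information
arrives through an elliptic, local residual, and its field must travel
farthest from its flat initialization; values around 3 help at short
schedules. The multiplier ramps in linearly over the first 20% of joint
training — at the very start the modulus field is still flat and the
residual gradients it generates are systematically misdirected, so taking
them at full strength damages the Poisson field before the modulus has
formed.

**Boundary-force term.** An optional fifth term (`lam_bc`, default 0)
penalizes the mismatch between the integrated boundary stress and the
applied force during training. It exists to reproduce the reported
instability of enforcing the loading condition inside the loss: switching
it on visibly degrades the Poisson field in our experiments too. The
two-phase design — ignore the force during training, calibrate with it
afterwards — is the point of the method.

## Networks and encoding

Each network is an MLP over positionally encoded coordinates. Coordinates are
first normalized to $[-1,1]$ per axis (the encoding and sine layers are
scale-sensitive; the source does not state a normalization). Each coordinate
is expanded into $\omega$ sine/cosine pairs at frequencies $f^{2i/\omega}$,
$i = 1..\omega$, with minimum frequency $f = 10^{-4}$ — a geometric ladder of
*scales* rather than oscillations (all factors are $\le f^{2/\omega} < 1$);
high-frequency capacity comes from the sine activations. The stated index
convention in the source is internally inconsistent about total width; we fix
exactly $\omega$ sines + $\omega$ cosines per scalar coordinate, $4\omega$
features total, no raw-coordinate passthrough.

Hidden layers use the sine (SIREN) activation with $\omega_0 = 30$ on the
first layer and 1 thereafter, first-layer weights $U(\pm 1/\text{fan\_in})$,
deeper layers $U(\pm\sqrt{6/\text{fan\_in}})$. We tested the original SIREN
convention ($\omega_0$ on every layer with $1/\omega_0$-compensated
initialization) and found it unstable at the learning rates the reduced
schedules need, so the first-layer-only convention stands. Swish, tanh and
relu variants exist for the activation ablation.

Output heads: identity for displacement and strain (each scaled by the
corresponding data magnitude so raw outputs are $O(1)$); for elasticity,
softplus on the $E$ head — positivity by construction, scaled so a zero raw
output yields $E_c$ — and $0.5\,\mathrm{sigmoid}$ on the $\nu$ head. The
source applies softplus to the elasticity network's output; softplus on $\nu$
would allow $\nu \ge 0.5$, where the plane-stress constitutive matrix
degenerates and training dies mid-run, so we bound $\nu$ into $(0, 0.5)$
instead — the physically meaningful range for the materials modeled (the
package's containers accept the full thermodynamic range $(-1, 0.5)$; only
the network head is restricted).

## Synthetic data: what it emulates, what it does not

The generator stands in for the external FEM datasets of the source study
(shape-structured $E$ and $\nu$ maps under four right-edge load profiles).

* **Forward solver**: bilinear quadrilateral (Q4) plane-stress elements on
  the structured grid, material constant per cell (exactly the phantom's cell
  grid), 2×2 Gauss quadrature, sparse Cholesky solve. Left edge fully
  clamped — the source shows loads only on the right edge and never states
  the fixity, but a static problem needs a rigid-body constraint, and a
  clamped support is the standard test-bench realization. Right-edge
  profiles: uniform traction; Gaussian ("normally distributed") traction with
  std 0.2 of the edge length; uniform traction over the central 50%; and
  uniform strain, realized as a uniform prescribed x-displacement rescaled by
  linearity so the total reaction equals $F$. Consistent nodal loads are
  rescaled to integrate exactly to $F$. Thickness is 1; all forces are per
  unit thickness.
* **Phantoms**: homogeneous, circular inclusion, multiple inclusions,
  linear gradients, and arbitrary bitmap masks (the stand-in for dragon/dog
  silhouettes). Defaults describe a soft-tissue-like phantom: background
  $E = 1$, inclusion $E = 3$ at radius 0.25 of the domain, $\nu$ 0.3 / 0.4.
  These were fixed a priori as a typical elastography contrast; they are not
  tuned to any test outcome.
* **Noise**: (i) additive Gaussian with per-component
  $\sigma = \bar u/\text{SNR}$, $\bar u$ the signed mean of that component
  (the source's worked example, means 1.27 / 0.242 at SNR 100 giving
  $\sigma$ 0.0127 / 0.00242, is consistent with signed or absolute means; a
  flag switches). (ii) Structured, ultrasound-style: convolution with a
  cosine-modulated Gaussian point spread function
  $h[i,j] = e^{-i^2\sigma_x^2 - j^2\sigma_y^2}\cos(2\pi f_c j)$ followed by
  additive Gaussian noise at the same SNR rule. The PSF support is truncated
  at three standard-deviation-equivalents per axis and normalized to unit sum
  (edge-renormalized), so a constant field passes through unchanged —
  without normalization the "noise" would rescale the signal and corrupt the
  SNR definition. $f_c$ is a cycles-per-sample parameter; the quoted 6 (MHz)
  is retained as the default even though at integer lags $\cos(2\pi\cdot 6 j)
  \equiv 1$, leaving a pure Gaussian blur — the sampling rate that would map
  physical frequency to sample index is not stated in the source.

What a green test on this generator does **not** establish: performance on
real speckle-tracked data (correlated, signal-dependent noise;
non-rectangular geometry), on sharp high-contrast maps at high resolution, or
at the source's 150k-iteration training scale.

## Reduced scale and what it costs

All automated tests run a "tiny" preset (24×24 grid, depth-3 networks of
width 48–64, $\omega = 8$ or 16, a few thousand iterations), far below the
source's scale (up to 16 hidden layers of width 128, $\omega = 64$, 150k
iterations). Three consequences are worth naming honestly.

First, the modulus field converges slowest of all quantities: its
information propagates through a local elliptic residual, so contrast fills
in from material boundaries over thousands of iterations — at short
schedules the recovered inclusion contrast is attenuated. This is an
optimization-budget artifact: it relaxes with more joint iterations and
with the larger `reduced` preset.

Second, the Poisson field carries a *resolution-dependent bias* that does
not relax with iterations. The forward data come from a Q4 finite-element
solve while the inverse residual uses the package's finite-difference
stencils; the two discretizations disagree at the few-percent level on
coarse grids, and the minimizer of the modulus-normalized residual over
$(E, \nu)$ given that slightly inconsistent strain sits at a $\nu$ visibly shifted
low in the background. We isolated this by training the
elasticity network alone against the *noise-free* finite-difference strain
with everything else exact: the modulus recovers well while the $\nu$ bias
remains — so it is a property of the discrete objective, not of the
networks, the noise, or the optimizer (whose gradients are verified against
finite differences in the test suite). It shrinks only with grid
refinement. The acceptance suite's Poisson-ratio recovery threshold is
accordingly not met at the desk scale the test budget affords, and the
corresponding assertion is left failing rather than loosened; the test
output is the honest record of the gap.

Third, single short runs have visible seed-to-seed variance; the acceptance
suite asserts medians over seeds and trend orderings, not single-run
magnitudes. Two orderings are re-scoped to where their phenomenon is
observable at this scale: the SNR-monotonicity trend is asserted on the
Poisson-ratio error (the modulus error is optimization-dominated here and
carries no usable noise signal), and the model-ablation chain (full model
vs. displacement-only vs. direct finite differencing) is asserted at
SNR 20 — on a coarse grid, finite-difference noise amplification, the
effect the chain is about, only bites at strong noise, whereas at the
source's finer grids it already bites at SNR 1000.

## Degenerate inputs and numerical choices

* $\nu$ is validated strictly inside $(-1, 0.5)$ with tolerance $10^{-6}$;
  the constitutive denominators $1-\nu^2$ and $2(1+\nu)$ stay
  well-conditioned.
* $\tilde E \le 0$ anywhere is a hard error (cannot happen from the softplus
  head; can happen with user-supplied fields).
* Non-finite training loss raises a diagnostic error rather than continuing.
* `calibrate_scale()` refuses a non-positive integrated boundary stress
  (sign-inconsistent prediction) instead of returning a negative scale.
* The boundary stress column sits at $t/2$ inside the physical edge (cell
  centers); the resulting small bias in $\hat c$ is part of the measured
  calibration error. Rectangle quadrature is the default to match the
  source's discrete force balance; trapezoid is available.
* Seeds: every stochastic step (phantom placement, noise, initialization)
  takes an explicit seed, scoped so package code never disturbs the caller's
  RNG state.

## Known limitations

* Plane stress, isotropic, linear; no plane strain, 3-D, anisotropy,
  viscoelasticity or hyperelasticity.
* Calibration supports a single normal load on the right edge; with unknown
  loads only relative fields are produced (no calibration).
* Pure-R training: roughly 20–40 ms per iteration at desk scale on one
  core. The paper-scale preset exists and works but is an overnight CPU job.
* The boundary-condition residual term that the source found destabilizing
  is intentionally absent from the default loss.
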