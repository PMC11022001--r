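---
title: "Inverse identification of aneurysm wall constants from luminal volumetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverse identification of aneurysm wall constants from luminal volumetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneufit)
```

## The problem

A saccular aneurysm deforms measurably when a known flow stimulus is
injected against its wall through a catheter while the deformation is
imaged at sub-millimetre resolution. If the wall obeys an isotropic
incompressible Fung-type hyperelastic law with strain energy

$$W(I_1) = \frac{a}{b}\left(e^{\frac{b}{2}(I_1-3)}-1\right),$$

then the luminal volume change $\Delta V$ between the unstimulated (C1)
and stimulated (C2) acquisitions carries information about the material
constants $a$ (kPa, stiffness scale) and $b$ (dimensionless strain
stiffening). The package identifies $(a, b)$ by matching an
image-measured $\Delta V_{exp}$ against forward-model predictions
$\Delta V_{num}(a, b)$, and from the identified constants quantifies the
wall stress state (mean first principal Cauchy stress and mean applied
pressure at the systole peak) as input to an eventual rupture criterion.

## The forward model and its assumptions

The full problem is a one-way fluid-structure interaction on a
subject-specific geometry. This package deliberately replaces that with a
desk-scale reduced-order model whose every step is closed-form checkable:

* **Geometry.** The sac is an ideal sphere of reference radius $R_0$
  (taken from the diastolic C1 image; baseline inflation from the truly
  unloaded state is absorbed into $R_0$) and uniform wall thickness $H$
  (default 430 um, mid-range of reported arterial values).
* **Load.** The transmural pressure is the arterial outlet pressure plus
  the stagnation pressure of the catheter jet,
  $P(t) = p_{out}(t) + \tfrac12 \rho\, v_{jet}(t)^2$, with $v_{jet}$ the
  stimulus flow rate divided by the catheter lumen area (inner diameter
  1.68 mm). Distributing the jet load uniformly is this package's own
  approximation; nothing finer is defensible without the 3D flow field.
  The catheter body is treated as rigid and motionless.
* **Mechanics.** Spherical-membrane equilibrium under equibiaxial stretch
  $\lambda$: Laplace's law $P = 2\sigma h/r$ with $r = R_0\lambda$,
  incompressible thinning $h = H\lambda^{-2}$, and
  $\sigma(\lambda) = (\lambda/2)\,d\hat W/d\lambda$ for
  $\hat W(\lambda) = W(2\lambda^2+\lambda^{-4})$. The solver brackets the
  first root above $\lambda = 1$ (the stable ascending branch) and
  reports the limit pressure when a non-monotone pressure-stretch curve
  is exceeded — relevant only for weak strain stiffening, since at
  $b \approx 16$ the curve is monotone over any physiologic range.
  At the default geometry $H/R_0 \approx 0.22$, beyond the usual
  thin-wall comfort zone; the solver warns (the warning is expected and
  deliberate) and the membrane algebra is still applied, consistently,
  on both the synthesis and identification sides.

Units are SI internally (Pa, m, s); interfaces use kPa, mm and
ml min$^{-1}$ as is conventional in this literature.

## Loading conditions

The cardiac waveform is a half-sine-squared systolic bump over a
diastolic baseline for the inlet velocity (peak 0.35 m/s), with the
outlet pressure following the same shape between 5732 and 13865 Pa
(43-104 mmHg). The stimulus is a trapezoidal pulse at 150/170/190
ml/min held for 3 s; the stimulated image is acquired 2 s after pulse
onset, well inside the plateau.

Two timing quantities are deliberately explicit because the animal's
heart is too fast to gate the scanner:

* **Heart rate** is not part of the imaging protocol; the default is 240
  beats/min (typical for an anesthetized New Zealand white rabbit),
  giving a 0.25 s cycle so the scanned offsets (below) cover a
  meaningful phase range. It is a configuration value, not a constant.
* **Acquisition phase.** The cardiac phase of the stimulated acquisition
  $t_2$ defaults to end-systole. The baseline instant is
  $t_1 = (\mathrm{phase}(t_2) - \Delta t) \bmod T$ for the unknown offset
  $\Delta t \in \{0.01, \dots, 0.07\}$ s. With $t_2$ at end-systole all
  seven candidate offsets sample distinct pressures on the systolic
  flank; placing $t_2$ at the systole peak instead would park
  $\Delta t \ge 0.05$ on the flat diastolic baseline, making those
  offsets mutually indistinguishable in principle, not just in practice.
  $\Delta V$ can be negative when the baseline lands nearer the pressure
  peak than the stimulated instant; only its consistency across flow
  rates matters to the identification.

## The inverse engine

For each candidate $\Delta t$, the forward model is evaluated on a sweep
of 51 $(a, b)$ couples (default: a 17 x 3 tensor grid over
$[85, 645]\,\mathrm{kPa} \times [14.4, 17.6]$, corners included; a seeded
latin-hypercube layout is also available) and a quadratic response
surface

$$\Delta V_{num}(a,b) = \alpha_1 a^2 + \alpha_2 b^2 + \alpha_3 a +
\alpha_4 b + \alpha_5 ab + \alpha_6$$

is fitted by least squares. Because $a$ and $b$ differ by more than an
order of magnitude in scale, the regression runs in affine-normalized
coordinates; the scaling is stored with the surface so evaluation is
bit-reproducible, and the coefficients are also reported in raw units.
The cost $FC(a,b) = |\Delta V_{num}(a,b) - \Delta V_{exp}|$ is minimized
over the box by multi-start local optimization (verified in the tests
against an iterated dense-grid brute-force scan), and the $\Delta t$
whose minimized cost is lowest is selected.

Three design points deserve justification:

* **Per-load non-uniqueness.** Matching a single scalar $\Delta V_{exp}$
  over a 2-D box generically leaves a whole zero-cost level curve. In
  per-load mode ties (costs below $10^{-9}$ mm$^3$) are broken by taking
  the zero-level point closest, in normalized coordinates, to the
  literature anchor for unruptured aneurysms ($a = 353.6$ kPa,
  $b = 16.7$), and the tie-break is flagged in the result. The
  statistically identifiable default is **joint mode**: the three flow
  rates share one $(a, b)$ and one $\Delta t$, giving three constraints
  for two unknowns.
* **Sharpening.** The wide-box quadratic is a biased metamodel of the
  strongly nonlinear $\Delta V(a,b)$ (its maximum residual, reported
  with every fit, reaches a large fraction of the signal at the box
  edges). In joint mode the engine therefore re-sweeps and refits on a
  local sub-box around the first estimate, then finishes with a direct
  derivative-free minimization of the exact forward-model cost. This is
  surrogate-based optimization with exact re-evaluation — affordable
  here precisely because the reduced-order forward model costs
  microseconds where the original finite-element solve cost hours. The
  top three $\Delta t$ candidates are sharpened and the lowest exact
  cost wins.
* **Identifiability of $b$.** At small wall strains the exponent is
  nearly unidentifiable: a shift of $b$ by $\pm 0.5$ can be compensated
  by a fraction-of-a-percent change in $a$ while moving the exact-model
  joint residual by only $\sim 10^{-5}$ mm$^3$. The exact-cost polish is
  what resolves $b$; any identification from volumes measured with
  realistic noise should quote $b$ with corresponding caution. This is a
  property of volume-based inverse identification, not of this
  implementation.

Extrapolation outside the sampled box is refused by default; the surface
is only trusted where it was fitted, and an identified cost below the
surface's own residual bound is flagged as not to be over-read.

## The synthetic study

No imaging data are deposited, so the package synthesizes its own study:
a parent vessel (cylinder, radius 1.5 mm, length 12 mm) carrying a
spherical sac (radius 2 mm, neck 1.2 mm) voxelized at 0.25 mm with
center sampling, the C2 sac inflated by the package's own forward model
at known ground-truth $(a^*, b^*)$ and $\Delta t^*$. A seeded noise
model flips a fraction of boundary-shell voxels. The default material
truth (a = 300 kPa, b = 16.2) sits in the range identified in vivo for
this animal model, and the resulting volume changes (tenths of a mm$^3$
to ~1 mm$^3$ on a ~30 mm$^3$ sac) match the published experimental
magnitudes.

What the phantom does *not* emulate: scanner physics and contrast
transport, segmentation errors beyond boundary-voxel noise, anatomic
tortuosity and neck geometry, and — most importantly — spatially
heterogeneous wall properties (a homogeneous $(a,b)$ is assumed
throughout, as in the original procedure). Passing closed-loop tests
therefore demonstrates the correctness and identifiability of the
*procedure* under its own model, not the accuracy of the reduced-order
model against a real wall.

One honest consequence of the imaging resolution is surfaced rather than
hidden: the stimulus deforms the sac radius by far less than a voxel, so
the voxel-count volume change of a 0.25 mm mask pair is
quantization-limited (a single voxel is 0.0156 mm$^3$, and surface
quantization noise is larger than the signal). The volumetry module
measures it anyway — with overlay registration, world-frame cut-plane
delimitation, and both voxel and mesh estimators as mutual controls —
but the identification demonstration consumes the forward-sourced
$\Delta V$, exactly as the closed-loop validation prescribes. Real
studies face the same limit and resolve it with sub-voxel/partial-volume
segmentation, which is out of scope here.

## Volumetry choices

* **Two volume estimators.** Voxel counting (centers on the aneurysm
  side of the cut plane) is the direct image-domain measurement and the
  default; the enclosed volume of the watertight voxel-boundary surface
  mesh, clipped by the same plane, is the control. Their agreement on
  phantoms (within a few percent; exactly equal for the unclipped lumen
  by construction) bounds the surface-extraction error. No marching-cubes
  smoothing is applied: the voxel-boundary mesh is exact with respect to
  the mask, and smooth parametric meshes (icosphere, capped cylinder)
  are provided where a staircase surface would bias areas — wall
  offsetting and area measurements.
* **Registration metric.** The rigid overlay maximizes overlap of the
  masks restricted to the parent artery, with the aneurysm explicitly
  excluded so its deformation cannot bias the alignment. Initialization
  is by artery centroids; refinement is Nelder-Mead on the mean
  trilinearly interpolated baseline occupancy at the transformed lumen
  points (continuous in the transform, unlike binary Dice). A
  post-registration artery Dice below 0.5 is a hard failure.
* **Cut-plane persistence.** The delimitation plane is defined once in
  world coordinates, serialized as JSON, and applied to both
  acquisitions after overlay, so the same aneurysm volume is extracted
  on the experimental and numerical sides.
* **Conventions.** World coordinates in mm, right-handed, identity
  orientation; voxel centers define membership (half-open); the aneurysm
  side is positive signed distance. Surfaces aligned exactly with
  voxel-center planes are the measure-zero worst case of center
  sampling, so phantoms in tests are posed off-lattice.

## Numerical choices

* Membrane equilibrium roots are bracketed by multiplicative marching in
  $\lambda$ (factor 1.05) and solved by Brent's method at machine
  tolerance; the Laplace residual of a converged state is checked to
  $10^{-8}$ relative in the tests.
* The quadratic fit uses a rank-checked QR solve; a rank-deficient
  design (fewer than six informative couples) is an error, and the
  six-point minimal grid design includes axis midpoints precisely so the
  pure quadratic terms stay identifiable.
* Cost minimization runs multi-start L-BFGS-B on the squared cost, then
  polishes on $\sqrt{FC}$ — conical rather than quartically flat near a
  zero-touching minimum, which locates the minimizer several orders of
  magnitude more precisely.
* Determinism: all stochastic steps (noise model, latin-hypercube
  layout, seeded validation sweeps) restore the caller's RNG state; a
  pipeline rerun with the same configuration is bit-identical, and the
  run manifest checksums every artifact.

## Problem sizes

The shipped tests and the acceptance script run the full procedure at
the study's native sizes — 51-couple sweeps, seven-point $\Delta t$
grids, 0.25 mm phantoms of roughly $60^3$ voxels — with ten seeded
ground truths for the closed-loop property; the end-to-end pipeline
demonstration uses the same sizes. These match the published study
design, which is small by construction (51 finite-element runs per
configuration were the paper-side bottleneck; the reduced-order model
removes it).

## Known limitations

* The spherical-membrane forward model preserves the *structure* of the
  inverse problem (a scalar $\Delta V$ per load, monotone in $a$) but
  not subject-specific geometry; identified constants from real images
  would inherit its bias. The geometry-faithful 3D solve is explicitly
  out of scope.
* Homogeneous wall properties and uniform thickness; no multi-layer or
  anisotropic laws.
* No non-rigid registration; the parent artery is assumed rigid between
  acquisitions.
* The stress-to-pressure ratio reported per condition is a provisional
  rupture-criterion ingredient and is labelled as such; the proper
  combination of stress components is an open question.
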