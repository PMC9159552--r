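---
title: "Linear viscoelasticity of the 2D vertex model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear viscoelasticity of the 2D vertex model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertexrheo)
```

## The model

`vertexrheo` simulates the linear rheology of a confluent epithelial
monolayer described by the 2D vertex model. The tissue is a polygonal tiling
of a periodic box; the degrees of freedom are the vertex positions
$\mathbf r_i$ (three-fold junction points). The energy is quadratic in each
cell's area and perimeter deviations,

$$E = \sum_C \left[\tfrac{K}{2}(A_C - A_0)^2 +
      \tfrac{\Gamma}{2}(P_C - P_0)^2\right],$$

with identical constants for all cells. Energies are measured in $K A_0^2$,
stresses in $K A_0$, lengths in $\sqrt{A_0}$. The stiffness ratio is fixed at
$\Gamma/(K A_0) = 0.289$; the single control parameter is the target shape
index $p_0 = P_0/\sqrt{A_0}$, which drives a solid-fluid transition at
$p_c = \sqrt{8\sqrt 3} \approx 3.7224$ for the honeycomb lattice and near
$3.93$ for disordered tilings.

Vertices obey overdamped dynamics against substrate friction,
$\gamma\,\dot{\mathbf r}_i = \mathbf F_i = -\nabla_{\mathbf r_i}E$, which
sets the time unit $t^* = \gamma/(K A_0)$. Substrate friction is the only
dissipation channel: there is no thermal noise and no internal (cortical)
viscosity, so the package is not a model of unsupported epithelia.

The tissue stress is the area-weighted average of per-cell stresses
$\hat\sigma_C = -\Pi_C\hat I + \frac{1}{2A_C}\sum_{e\in C}\mathbf T_e\otimes
\mathbf l_e$ with $\Pi_C = -K(A_C - A_0)$ and the junction tension
$\mathbf T_e = \partial E/\partial \mathbf l_e$. Because a junction belongs
to two cells, its tension carries *both* incident cells' perimeter terms,
$\Gamma[(P_{C_1}-P_0) + (P_{C_2}-P_0)]\,\hat{\mathbf l}_e$. With this
convention the tissue stress equals the strain derivative of the energy
density exactly; the test suite verifies
$\sigma_{xy} = A_\text{box}^{-1}\,\partial E/\partial\varepsilon$ to 1e-4
on generic configurations. A per-cell-only tension would fail this identity
by a factor of about two, and would be inconsistent with the affine
high-frequency shear modulus below.

## Tilings

Two generators play the role of synthetic data; their defaults are the study
conditions and are not tuned.

* `hex_tiling(nx)` builds the honeycomb ground state with `nx` columns and
  `ny = nx` rounded up to even rows (so `nx = 15` gives the 240-cell system
  used for almost all runs), in the orientation with two vertical junctions
  per cell. That orientation matters: the pre-deformation boundary
  $p_c(a)$ below is derived for a uniaxial stretch along $x$ in exactly this
  orientation.
* `disordered_tiling(n, L)` places `n = 200` seed points in a periodic
  square of side `L = 15` by random sequential addition and tessellates
  them with a periodic Voronoi construction (half-plane clipping against
  perpendicular bisectors of the 3x3 periodic images — an exact construction
  for well-separated seeds; no external geometry library is used). The
  preferred area is $A_0 = L^2/n$. The RSA exclusion distance is not part of
  the published protocol; the default $d_\text{min} = 0.5\sqrt{L^2/n}$ is
  low enough that RSA always saturates at this density and high enough to
  avoid sliver cells.

Meshes store one canonical copy of each vertex plus per-incidence wrap
offsets $(m_1, m_2)$, so every polygon reconstructs contiguously as
$\mathbf r_i + m_1\mathbf a_1 + m_2\mathbf a_2$ even while the box deforms.
This is equivalent to a minimum-image convention for cells smaller than half
the box and stays unambiguous under large box deformations.

What the generators do **not** emulate: real epithelia have heterogeneous
cell properties, curved junctions, higher-coordination vertices, division
and extrusion. Passing tests show that the *model's* rheology is reproduced,
not that real tissue behaves this way.

## Relaxation and T1 handling

Energy minimization uses FIRE (inertial quench with velocity mixing;
$\alpha_0 = 0.1$, $f_\text{inc} = 1.1$, $f_\text{dec} = 0.5$,
$f_\alpha = 0.99$, $N_\text{min} = 5$, $dt_0 = 0.01\,t^*$,
$dt_\text{max} = 0.1\,t^*$). Convergence requires the relative energy change
to stay below `rel_tol` (default $10^{-12}$) for five consecutive
iterations *and* a residual force below `f_tol` (default $10^{-8}$); the
energy rule alone can fire spuriously right after a FIRE velocity reset,
when the step size collapses. Because fluid-phase minima sit at $E \to 0$
(degenerate ground states), the relative criterion uses an absolute energy
floor of $10^{-12} N_c K A_0^2$.

T1 neighbour exchanges are allowed throughout. A junction shorter than
`l_t1` between two three-fold vertices is flipped: the new junction is
placed perpendicularly through the midpoint with length `l_new = 1.5 l_t1`.
During oscillatory probing the threshold is `l_t1 = 0.01 sqrt(A0)`; at the
amplitudes used ($\varepsilon_0 = 10^{-7}$) flips essentially never fire.
During minimization of disordered tilings the landscape genuinely crosses
T1s, and a junction near a marginal (four-fold) configuration can flip back
and forth indefinitely. `fire_minimize()` therefore flips one junction per
event, limits each junction to two flips, and afterwards lets that junction
shrink freely (force-flipping only if it collapses to numerical zero);
the ensemble scans use a smaller minimization threshold
`l_t1 = 0.002 sqrt(A0)` so that legitimately short equilibrium junctions do
not trigger spurious flips. These guards only affect degenerate cases; the
relaxed states they produce are verified against the Hessian (no negative
eigenvalues beyond numerical noise).

## Oscillatory probing and moduli

The probe is an affine deformation $\hat F(t)$ with
$\varepsilon(t) = \varepsilon_0\sin(\omega_0 t)$, applied as simple shear
or biaxially. Each time step applies the *incremental* map
$\hat F(t_{n+1})\hat F(t_n)^{-1}$ to all vertices and the box (preserving
accumulated non-affine relaxation — the only ordering compatible with a
fluid that flows at low frequency), followed by one forward-Euler step of
the overdamped dynamics. The time step is $0.00866\,t^*$ for
$\omega_0 t^* < 29.02$ and $0.000866\,t^*$ above, reduced where necessary so
that 25 samples per cycle land on integer steps. Stress is measured after
the relaxation sub-step.

The stress and strain channels are cut into blocks of three driving cycles
and transformed with a rectangle rule at the 75 block samples. Identical
treatment of both channels makes the quadrature bias cancel exactly in the
ratio $G^*(\omega_0) = \tilde\tau(\omega_0)/\tilde\varepsilon(\omega_0)$
for pure $\omega_0$ content; on the discrete grid a pure sine recovers its
amplitude exactly, and content at integer harmonics is rejected exactly. We
use the $e^{-i\omega t}$ kernel so that the loss modulus is $+\mathrm{Im}$
of the ratio (the opposite kernel yields the complex conjugate; the stated
positive-dissipation convention fixes the sign). The DC component (residual
prestress) is orthogonal to the probe frequency and is not subtracted.

Steady state is declared when consecutive block amplitudes agree to
`steady_rel_tol` (default $10^{-3}$) twice in a row, so the earliest accept
is block 3; runs are capped at 40 blocks and unconverged points are flagged,
never silently kept. Linearity was verified: moduli at
$\varepsilon_0 = 10^{-7}$ and $10^{-6}$ agree to better than $10^{-3}$, and
stress amplitudes ($\sim 10^{-7} K A_0$) sit far above double-precision
noise.

## Constitutive fits

`fit_viscoelastic()` fits a spring-dashpot model to a measured curve and
returns a classed object with the usual modelling methods. Internally every
model is a generalized Maxwell form — `n` Maxwell arms $(E_k, \eta_k)$ in
parallel, optionally with a parallel spring — so the standard linear solid
(one arm + spring) and the Burgers model (two arms, no spring) are exact
special cases and the nesting identities hold by construction. The
objective is joint least squares on $\log G'$ and $\log G''$ (equal
weights, points below $10^{-12} K A_0$ excluded) because the moduli span
decades; positivity is enforced by log-parameterization;
Levenberg-Marquardt steps run from five perturbed asymptote-based starts
(the near-critical Burgers objective is flat). Arms are reported in
decreasing order of relaxation time, which removes the permutation
degeneracy and makes "arm 1" the slow arm whose constants jump at the
transition.

Analytic limits used for cross-validation:

* quasistatic shear: $G'(\omega\to 0) = K A_0 (1 - \alpha^2)$ with $\alpha$
  the uniform rescaling that cancels the residual hydrostatic stress of the
  lattice. An exact elimination of the internal modes against the Hessian
  (computed independently in the tests) agrees with this expression to
  better than 1% throughout the solid phase and exactly at the transition.
* affine (high-frequency) shear: $G'(\omega\to\infty) =
  3\sqrt3\,\Gamma(1 - p_0/p_c)$; for a uniaxially pre-deformed lattice the
  modulus is computed as the numeric second strain derivative of the
  single-cell energy density (step $10^{-5}$), which reproduces the closed
  form at $a = 1$ to eight digits.
* affine bulk: $B = 2KA_0 + 12^{1/4}\,\Gamma p_0$, with $12^{1/4} = p_c/2$;
  the coefficient is pinned by the hexagon-dilation derivative of the
  hydrostatic stress and by the simulated frequency-independent $B'$
  (agreement to $10^{-4}$).
* pre-deformation boundary: $p_c(a) = \sqrt{8\sqrt3}\,
  (1 + \sqrt{1 + 3a^2})/3$, the zero of the pre-deformed affine modulus; it
  matches the Hessian stability boundary to $10^{-3}$ in the tests.

## Stability analysis

`hessian_spectrum()` assembles the analytic Hessian (per-cell rank-one
gradient outer products plus the constant area curvature and per-junction
perimeter curvature) and classifies states: two rigid translations are
always exact null vectors; additional zero modes mark the fluid; negative
modes mark saddles. The lowest non-translational eigenvalue is read off
after shifting the exact translation null space upward, which avoids any
ambiguity between translations and a closing gap near the transition.

The zero tolerance is $10^{-10} K A_0$ for exact lattice states (the labels
are insensitive over $10^{-12}$–$10^{-8}$). For FIRE-relaxed disordered
states the flat directions of the degenerate minimum carry curvature noise
of order $10^{-9}$ (the minimum is reached only to machine precision), so
the ensemble scans use $10^{-8} K A_0$ — still two decades below the
smallest genuine solid eigenvalue near the onset. The disordered critical
point is defined operationally as the median over seeds of the smallest
grid $p_0$ (step 0.01) whose relaxed state carries nontrivial zero modes;
per-seed onsets are located by bisection on the grid, relying on
monotonicity of floppiness in $p_0$.

## Problem sizes and numerical choices

Desk-scale defaults reproduce the study's headline numbers with the
published system sizes (240-cell honeycomb; ten 200-cell disordered
tilings) over reduced frequency windows: five log-spaced points per decade
and two to three decades per regime instead of the full seven-decade span.
Solid shear sweeps centre their seven-point grid on the predicted crossover
$E_1/\eta_\text{ref}$ with $\eta_\text{ref} = 0.05\,\gamma$ — the dashpot
constant is set by the friction scale and is nearly independent of $p_0$,
so a single reference value keeps every sweep inside its crossover region.
The intermediate-frequency loss exponent of disordered ensembles
($\approx 0.73$) is out of desk scale: it needs large ensembles and long
low-frequency runs; the estimator (`loss_exponent()`) and the configuration
path are provided and validated on synthetic power laws instead.

Known limitations: only substrate friction (no internal dissipation, no
noise); linear response only (amplitudes are infinitesimal; no shear-driven
rigidity or plasticity); scalar, homogeneous cell parameters; junction
tensions are straight lines. The fitting module assumes positive moduli
spanning the crossover; curves near the disordered transition genuinely
need more relaxation times than SLS/Burgers provide, which shows up as a
monotone residual decrease with added Maxwell arms rather than as a failed
fit.
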