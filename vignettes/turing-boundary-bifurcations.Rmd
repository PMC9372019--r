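---
title: "Boundary conditions and the shape of the Turing bifurcation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boundary conditions and the shape of the Turing bifurcation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turingbc)
```

## The model

`turingbc` analyses two-species reaction-diffusion systems

$$
u_t = \frac{D_u}{L^2} u_{xx} + f(u,v), \qquad
v_t = \frac{D_v}{L^2} v_{xx} + g(u,v),
$$

posed on a nondimensional unit interval.  The domain scale $L$ multiplies
the diffusion term only, so increasing $L$ is equivalent to enlarging the
physical domain; it is the bifurcation parameter throughout.  The kinetics
must admit a homogeneous steady state $(u_s, v_s)$ that is stable to
spatially uniform perturbations but destabilized by diffusion — the
classical Turing scenario.  Two boundary conditions are treated, and they
are the whole point of the package:

* **Dirichlet** (used here in the specific sense of *pinned at the
  steady state*): $u = u_s$, $v = v_s$ at both ends, domain
  $[-1/2, 1/2]$.  Near onset the solution is even, so the natural basis is
  the odd cosines $\cos((2n+1)\pi x)$.
* **Neumann** (zero flux): $u_x = v_x = 0$ at both ends, domain $[0, 1]$,
  basis $\cos(n\pi x)$.

Linear analysis cannot tell these cases apart: the first unstable mode is
$\cos(\pi x)$ in both, at the same critical scale
$$
L_c^2 = \frac{2 D_u D_v \pi^2}
{(D_u g_v + f_u D_v) + \sqrt{(D_u g_v + f_u D_v)^2 - 4 D_u D_v \det J}}.
$$
The difference appears at second order in the weakly nonlinear expansion,
and it is structural: with pinned boundaries the square of the critical
mode, $\cos^2(\pi x)$, is *resonant* (its odd-cosine expansion contains
$\cos(\pi x)$ with coefficient $8/3\pi$), so a quadratic solvability
condition exists and the bifurcation is **transcritical**; with zero-flux
boundaries $\cos^2(\pi x) = (1+\cos 2\pi x)/2$ is orthogonal to the
critical mode, the quadratic term is non-secular, and the bifurcation is
the familiar **pitchfork** obtained at third order.

## The multiple-scales machinery

The expansion is $u = u_s + \epsilon U_1 + \epsilon^2 U_2 + \epsilon^3
U_3$, $L = L_c + \epsilon L_1 + \epsilon^2 L_2$, with slow times
$t_1 = \epsilon t$, $t_2 = \epsilon^2 t$.  At each order the singular
critical-mode operator $\mathcal L = (1/L_c^2) D \partial_x^2 + J$ must be
solvable; projecting the forcing onto the adjoint kernel (the Fredholm
alternative) yields the amplitude equations.  The package mechanizes this
as linear algebra:

* kernel and adjoint vectors of the $2\times2$ critical matrix
  $M = J - (\pi^2/L_c^2)\,\mathrm{diag}(D_u, D_v)$, normalized to unit
  v-component (`kernel_vectors()`);
* second-order fields by mode-wise $2\times2$ solves
  (`solve_second_order()`): under Dirichlet conditions an odd-cosine
  series driven by the cubically decaying Fourier coefficients of
  $\cos^2(\pi x)$ (truncated, see below); under Neumann conditions exactly
  a constant mode and a $\cos(2\pi x)$ mode;
* third-order secular projections assembling the transcritical
  coefficients $p_1 \dots p_5$ of
  $$
  \tfrac{1}{\epsilon}\dot a =
  \left(p_1(L_1+\epsilon L_2) - p_3\epsilon L_1^2\right) a
  + (p_2 - p_4 \epsilon L_1) a^2 - \epsilon p_5 a^3
  $$
  and the pitchfork coefficients of
  $\dot a = \mathrm{lin}\,L_2 a - \mathrm{cub}\,a^3$.

Rather than transcribing closed-form coefficient formulas, every
per-mode system is solved numerically; the procedure is fully determined
by the expansion, and the closed forms would add nothing but
transcription risk.  Coefficients are reported with the bookkeeping
$\epsilon$ stripped, and displayed rounded to two decimals.

### Sign convention

The kernel vector is defined only up to scale.  We fix the v-component to
1 and then flip the overall sign exactly when that makes the quadratic
coefficient $p_2$ positive, so the transcritical equation always appears
in the canonical orientation (trivial branch stable below onset, the
$a>0$ sub-branch subcritical).  All physical predictions are invariant
under this choice.

### Gauge freedom at second order

The critical-mode component of $U_2$ is determined only up to a multiple
of the kernel vector — a genuine gauge freedom of the expansion.  The
resummed physics (steady branch shapes, $p_1$, $p_2$, $p_3$, $p_5$) is
gauge-invariant; the mixed coefficient $p_4$ is not, so quoting it
requires naming the gauge.  The package's default (`gauge = "vcomp"`)
zeroes the *v-component* of the critical-mode coefficient, in both the
$aL_1$ and $a^2$ sectors; `"ucomp"` and `"kernel"` (zero component along
the kernel direction) are available for comparison, and the test suite
asserts that only $p_4$ moves between them.  The `"vcomp"` choice is the
natural one when the amplitude is read off the inhibitor field and gives
the conventional printed form of the third-order equation for the
Schnakenberg example.

### The pitchfork cubic and its three contributions

Under Neumann conditions the cubic coefficient collects three terms: the
mean-mode cross term $B(U_1, c_0)$, the second-harmonic cross term
$\tfrac12 B(U_1, c_2\cos 2\pi x)$, and the cubic Taylor term
$\tfrac18\,T$.  `neumann_cubic_coefficients()` reports the breakdown
alongside the total because the second-harmonic term is easy to lose in
hand derivations — $\cos(\pi x)\cos(2\pi x)$ does contain
$\tfrac12\cos(\pi x)$ — and dropping it changes the Schnakenberg value by
roughly 30%.  The package includes the term, and validates the total
against an independent oracle: the converged pattern amplitude of the
full nonlinear PDE near onset must obey
$A^2 = \mathrm{lin}\,(L - L_c)/\mathrm{cub}$, and the test suite checks
the measured branch slope against the computed cubic to 2%.  This cross
check is the reason the breakdown is exposed; there is no gauge freedom
in the Neumann cubic (kernel multiples of the critical mode project to
zero), so the simulation is decisive.

## Numerical choices

* **Steady states and derivatives.**  Damped Newton with the symbolic
  Jacobian; residual tolerance $10^{-12}$.  All 18 kinetic partial
  derivatives up to third order are produced by symbolic differentiation
  (`stats::D`), with central finite differences as a fallback
  (step $\mathrm{eps}^{1/(k+2)}$ for order $k$, scaled by the base
  point).  Positivity of steady states is enforced as an error by
  default, relaxable to a warning — nonnegative concentrations are a
  modelling convenience, not a mathematical requirement.
* **Fourier truncation.**  The Dirichlet second-order series keeps
  $N = 128$ odd modes by default.  Because the forcing coefficients decay
  cubically and the mode matrices grow quadratically, the retained
  coefficients decay like the fifth power of the mode number;
  `dirichlet_cubic_coefficients()` recomputes at $2N$ and errors if any
  coefficient moves by more than $10^{-6}$ relative.
* **Simulation.**  Method of lines, second-order central differences on a
  uniform grid (default 256 nodes; the examples and tests use 64–202),
  Dirichlet rows eliminated against the pinned values, Neumann closure by
  ghost-node reflection.  Time stepping by the stiff solver in
  `deSolve` (`lsodes`), relative tolerance $10^{-8}$, absolute
  $10^{-10}$.  Random initial data are pointwise uniform,
  $|(u_s,v_s) + \mathcal U(-\sigma,\sigma)|$, hence non-smooth; the
  parabolic flow smooths them after a short transient, which is the
  standard practice for this kind of study.  For the sign-selected
  polynomial perturbations only the activator is perturbed and the
  inhibitor starts at $v_s$ — the inhibitor's initial shape is not
  constrained by the construction, and starting it at rest is the
  neutral choice.  Slow domain growth uses $L(t) = L_0(1 + t/100)$
  inside the diffusion prefactor only; the dilution term that exact
  uniform growth would add is neglected, which is valid precisely in the
  slow-growth regime the schedule describes.
* **Continuation.**  Pseudo-arclength with exact tangents from the
  bordered Jacobian (secant tangents stall at folds through catastrophic
  cancellation), damped bordered Newton, adaptive step
  ($ds_0 = 10^{-3}$, capped at $5\times10^{-3}$ near events and relaxed
  when traversing long smooth segments), state weighted by $1/\sqrt{2n}$
  in the arclength metric so diagrams are resolution-independent.
  Default 200 interior nodes.  Stability comes from the rightmost
  eigenvalues of the dense linearization.  Newton accepts iterates
  stalled at the round-off floor of the discrete residual (max norm
  below $10^{-8}$) when the nominal $10^{-10}$ cannot be reached — the
  $1/h^2$ Laplacian scale bounds the attainable residual from below.
  Bifurcations are located by bisection in $L$ (tolerance $10^{-4}$),
  folds by a local quadratic fit of $L(s)$.
* **Branch switching.**  At a simple bifurcation the corrector is seeded
  with $y \pm \delta\phi$ along the critical eigenvector, with the
  eigenvector sign canonicalized by its projection on $\cos(\pi x)$ so
  that the two signs mean "pattern above" and "pattern below" the steady
  state.  For a transcritical point the two signs live on opposite sides
  of $L_c$ (the $a>0$ state exists below onset), so the parameter offset
  must be chosen accordingly; for a pitchfork both exist above onset and
  form an exact mirror pair under $x \mapsto 1-x$.

## What the worked example shows

For the Schnakenberg kinetics ($f = 1 - 2u + u^2v$, $g = 3 - u^2v$,
$D_u = 10^{-3}$, $D_v = 10^{-1}$, steady state $(2, 3/4)$) the package
computes $L_c \approx 0.107$, an unstable window $[k_-, \pi]$ with
$k_- \approx 1.02$ at onset, kernel ratios $\Lambda \approx -30.3$,
$\eta \approx 22.7$, and the amplitude equations printed in the README.
Continuation then shows the two faces of the same kinetics: under
Dirichlet conditions a transcritical point whose unstable sub-branch
folds near $L \approx 0.03$ into stable large-amplitude "bat ear"
boundary-peak states (activator maxima near 50 at the fold, relaxing
to about 20), while the small-amplitude supercritical branch is stable
only on a short corridor ending near $L \approx 0.33$; under Neumann
conditions a supercritical pitchfork whose mirrored branches continue
into the classical peak-splitting cascade on a growing domain.

```{r, eval = FALSE}
amp <- amplitude_equations(schnakenberg())
amp$dirichlet
amp$neumann
```

## Scope and limitations

* Exactly two species, one spatial dimension, constant coefficients, one
  unstable wavelength at onset.  Mode-interaction and multi-wavelength
  phenomena are outside the expansion's validity.
* The amplitude equations are local: their quantitative range in
  $L - L_c$ is small (the cubic transcritical truncation even
  manufactures a spurious fold above onset, exposed by
  `predicted_branch(..., order = "cubic")` and visible when overlaid on
  continuation data).  Global statements come from the continuation and
  simulation modules, not from the normal forms.
* Only steady bifurcations are classified; oscillatory (Hopf) instability
  tracking is not implemented, and eigenvalues are used for stability
  signs only.
* Connected branches only: the continuation follows what it can reach by
  switching at detected simple bifurcations.  Disconnected branches would
  need deflation-style techniques.
* Robin (mixed) boundary conditions, curved or two-dimensional domains,
  non-uniform growth and cross-diffusion are out of scope.
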