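---
title: "Methods: desk-scale flow-diverter design optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale flow-diverter design optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fdstent` couples a parametric braided-stent generator, a 2-D pulsatile
non-Newtonian flow solver, wall-shear-stress (WSS) reward functions and
a single-step reinforcement-learning agent into one optimization loop.
This vignette records the models, the tunable parameters, and the
design decisions taken where more than one reasonable choice existed.
No empirical claim is made here beyond what the test suite and the
acceptance script themselves compute.

## Stent generator

Wires are wrapped around a toroidal envelope parametrized by the
azimuth $\theta$ and centerline arc length $s$:
$$\big((r(s)\cos\theta + R)\cos(s/R),\,(r(s)\cos\theta + R)\sin(s/R),\,
r(s)\sin\theta\big),$$
with a slowly varying minor radius
$r(s) = r_{prox}(1 - s/l) + r_{dist}\,s/l$ (the affine fit is rejected
when the end radii differ by more than 50 % of their mean).  A design
is four per-quadrant wire counts $n_j \in \{3..7\}$ plus a winding
factor $k \in \{20,25,30,35\}$; from each of the $\sum n_j$ start
positions (centers of equal azimuthal sub-intervals per quadrant,
quadrant 1 spanning $[0^\circ, 90^\circ)$ on the upper-outer side) two
wires are braided, one per handedness, so the total count is
$2\sum n_j \in [24, 56]$ and the design space has $5^4 \times 4 = 2500$
members.

**Winding-factor mapping.** No analytic definition of $k$ is given in
terms of the geometry, so the generator uses
$\theta(s) = \theta_0 \pm 2\pi k s / L_{ref}$ with a single calibration
constant: $L_{ref}$ is fixed so that $k=25$ produces a braiding angle
of $75^\circ$ at a 1.75 mm minor radius
($L_{ref} = 2\pi \cdot 25 \cdot 1.75/\tan 37.5^\circ \approx 358$ mm).
With this one constant, $k \in \{20..35\}$ spans roughly
$63^\circ$–$94^\circ$, matching the nominal $65^\circ$–$95^\circ$
range of the design family.  The braiding angle is *measured* from
finite-difference tangents of the generated polylines (twice the
average angle between the wire tangent and the local axial direction),
which agrees with the closed form $2\arctan(r\,|d\theta/ds|)$ to
$0.1^\circ$ on slender constant-radius envelopes.

**Braiding is geometric interleaving only**: all wires lie exactly on
the envelope surface, with no radial over/under weave offsets — those
are far below the resolution of the flow model.

**Porosity and pore density** are estimated on the pre-deployment
cylinder with a planar rhombic unit-cell model: two wire families at
$\pm\beta/2$ from the axis, same-family perpendicular spacing
$p = (2\pi R_c/N)\cos(\beta/2)$, per-family coverage $f = d/p$ (wire
diameter $d = 120\,\mu$m by default — wire radius 60 µm), wire-free
fraction $(1-f)^2$ (the crossing-overlap correction is exactly $f^2$
per cell) and pore count $\sin\beta/p^2$ per unit area.  Per-quadrant
values restrict the census to each quadrant's $n_j$; the global figure
is the quadrant mean.  A Monte-Carlo rasterization of the unrolled
cylinder confirms the closed form to well under 1 %.  The reference
cylinder radius is not uniquely determined by the nominal porosity and
pore-density figures simultaneously under this cell model; the package
defaults to $R_c = 1.75$ mm and treats the pore-density scale as
indicative only.

## 2-D hemodynamics environment

The patient-scale 3-D pipeline (image-based lumen, anisotropic
adaptation, 32-core runs) is deliberately replaced by a desk-scale
2-D fixture: a straight parent channel (width $H = 4$ mm, length
24 mm) with a circular sac (radius 2.2 mm) attached to the upper wall
through a 3 mm neck.  A *wide-neck* sac was chosen: flow diverters
target wide-neck aneurysms, and a wide neck gives the fixture a
pre-stent sac circulation strong enough that the porosity response of
the stented runs is resolved well above the numerical noise floor.
All operator definitions (incompressible Navier–Stokes, Carreau–Yasuda
viscosity, WSS with the Weissenberg–Rabinowitsch prefactor, parabolic
pulsatile inflow, residual-based stabilization) carry over unchanged;
this dimension reduction is the central deliberate deviation from the
patient-scale setting and is what makes every claim testable in
minutes on one CPU.

The mesh is a structured, wall-graded triangulation of the channel
conforming to a transfinite mesh of the sac segment (the sac region is
convex, so the chord-to-arc blend is fold-free); boundary edges are
tagged `inlet`, `outlet`, `wall`, `sac_wall`.  The intra-saccular mask
$\delta_{sac}$ consists of the arc nodes strictly above the neck line.

**Discretization.** Equal-order P1/P1 elements with SUPG/PSPG and
grad-div stabilization; semi-implicit first-order time stepping
(convection advected by, and viscosity evaluated at, the previous
step), $\tau_M = \big((2/\Delta t)^2 + (2|a|/h)^2 + (4\nu/h^2)^2 +
\sigma_e^2\big)^{-1/2}$ per element and $\tau_C = h^2/\tau_M$, both
with configurable prefactors.  The stabilization residual is corrected
by subtracting the lumped $L^2$ projection of the coarse-scale
residual (orthogonal-subscale correction): without it the PSPG
consistency error drains about 1 % of the mass flux along the channel,
which is exactly the order of the Poiseuille and mass-conservation
bands the solver is held to; with it both are satisfied to machine
precision on the fixtures.  Time step 0.02 s (40 steps per 0.8 s
cycle); two cardiac cycles from an end-diastolic start with the first
tenth of the first cycle ramped to avoid an impulsive start; the first
cycle is burn-in and all WSS statistics use the second.  Linear
systems are solved by sparse direct LU with an explicit residual check
against the configured $10^{-6}$ tolerance (a direct factorization is
more robust at these sizes than an iterative Krylov solve, and the
tolerance contract is still enforced verbatim).

**Inflow.** The 2-D analogue of a volumetric rate $Q$ (ml/s) treats
the channel as a unit-depth slab of thickness $H$: 2-D flux
$q = Q/H$, parabolic profile with peak $1.5\,q/H$, rescaled so the
trapezoid integral over the inlet nodes equals $q$ exactly.  The
synthetic one-period pulse is
$q(u) = q_{dia} + (q_{sys}-q_{dia})\sin^p(\pi u)$ with $p$ solved so
the cycle mean matches $q_{mean}$; it starts at the end-diastolic
minimum and peaks at mid-cycle.  (A two-harmonic form cannot pin the
minimum, maximum and mean simultaneously without overshooting the
extrema; the $\sin^p$ family can, exactly.)  Defaults: period 0.8 s,
2.5/4.0/7.5 ml/s diastole/mean/systole — mean velocity 0.25 m/s in
the 4 mm channel, a physiological internal-carotid scale.

**Stent immersion.** The deployed stent is a thin shell hugging the
vessel wall.  In a 2-D depth slab, every wire within a near-wall
out-of-plane band obstructs the planar flow, so the deployment maps a
design to per-station *effective* discs: at axial stations spaced
0.25 mm, the wires whose azimuth falls in the band (half-width 0.4 of
the tube radius) facing the neck (or the opposite wall) are counted,
and the local depth-averaged metal fraction
$f = n_{band}\, d/(b \cos(\beta/2))$ becomes the disc's *solidity*.
An earlier implementation sectioned the wire set with literal planes;
the discrete crossing census made neck coverage non-monotone in the
design (sampling noise), whereas the band census is smooth and grows
with wire count and winding factor exactly as the nominal metal
coverage does.  The plane-sectioning operator is retained (and tested)
for geometric use.

**Penalization.** Nodes inside fully solid discs get hard Brinkman
drag ($\sigma = 10^8\,\mathrm{s}^{-1}$, at least six orders above the
fixture's convective rate $U/H$, driving obstacle velocities below
$10^{-3}$ of the inlet peak).  Partial solidity $f$ maps to a finite
Ergun-type porous-screen drag
$\sigma_{scr} = 150\,\nu_\infty f^2/((1-f)^3 d^2)$: with a strictly
binary indicator any sub-grid wire would seal its whole mesh cell and
the porosity ladder would saturate into noise; the graded drag is what
lets denser braids divert measurably more flow.  The indicator is
smoothed one element layer by a conservative diffusion pass (a
max-dilation pass was rejected for inflating the blocked area).

## WSS statistics and rewards

Per sac-wall edge, the adjacent element's velocity gradient gives the
shear rate $\dot\gamma = (2\,\varepsilon\!:\!\varepsilon)^{1/2}$, the
Carreau–Yasuda viscosity $\mu(\dot\gamma)$, and
$\mathrm{WSS} = \tfrac{3n+1}{4n}\mu\dot\gamma$ (stored in Pa,
reported in dyne/cm², $\times 10$).  SAWSS is the length-weighted
spatial mean over the sac edges; TAWSS the per-node mean over the
evaluation (second) cycle; MWSS the maximum of SAWSS over that cycle.
The global reward is $r = -|\mathrm{MWSS} - \mathrm{MWSS}_0/2|$; the
banded local variant integrates $(\mathrm{WSS}-\mathrm{WSS}_{inf})$
below, $0$ inside and $(\mathrm{WSS}_{sup}-\mathrm{WSS})$ above the
band over the sac surface.

## Single-step PPO agent

The policy is state-independent: a constant input is mapped through
two hidden tanh layers of 4 units to the mean of a 5-D normal
distribution with diagonal covariance; the log standard deviations are
free trainable parameters starting at $\log 0.5$ (large initial spread
in raw $[-1,1]$ units for exploration).  Raw actions are clipped to
$[-1,1]^5$ and binned — five equal sub-intervals onto $\{3..7\}$ per
wire-count coordinate, four onto $\{20,25,30,35\}$ for the winding
factor, upper bins right-closed, interior edge ties rounding down.
Each episode evaluates 8 environments; advantages are the whitened
rewards (population standard deviation; a zero-spread batch yields
zero advantages and no update); the clipped surrogate
$\min(\rho A, \mathrm{clip}(\rho, 1\pm0.3)A)$ is ascended with Adam at
$5\times10^{-3}$ for 32 epochs of shuffled size-2 minibatches, ratios
taken against the pre-update policy.  The discount is 1 — one
interaction per episode, no critic, no bootstrapping.  Failed
environment evaluations are dropped from the batch rather than
penalized.  Convergence is flagged when one mapped design is sampled
by a majority of all actions over a trailing 10-episode window.  All
sampling, shuffling and initialization run off a single seed;
identical seeds give bit-identical runs.

## Surrogate environment

For agent validation and brute-force enumeration a fast surrogate
replaces the flow solve: $\widehat{\mathrm{MWSS}} = \mathrm{MWSS}_0
\,(P/100)^{2.5}$ with $P$ the global unit-cell porosity of the uniform
structure with the same total wire count and winding factor.  Two
properties make this the faithful stand-in for the 2-D environment:
the slab reduction responds to *total* metal coverage (the band census
counts all wires), and its damping is strong enough that every design
overshoots the half-setpoint — under exponent 2.5 the surrogate shares
both, so its optimum (the most porous design) has the same character
as the flow environment's.  An earlier surrogate with
per-quadrant-weighted porosity and an interior setpoint was discarded:
it concentrated the top designs in a reward shell thinner than any
stochastic optimizer resolves in a 100-episode budget, which tests the
landscape, not the agent.

## Benchmarks

Rosenbrock (2-D/5-D) and Branin are minimized by the agent (as
maximization of negative cost, actions mapped affinely onto the box,
initial policy mean at the shared start) against a
$(\mu,\lambda)$-ES (intermediate recombination, comma selection,
log-normal step-size self-adaptation, $\mu = \lceil\lambda/2\rceil$)
and a standard CMA-ES, all with 5 individuals per iteration, identical
seeds and starting points, and exactly the stated budgets (50
evaluations for Branin = 10 iterations × 5; the Rosenbrock harness
uses the iterations × parallelism product as the budget).  Exact
$(\mu,\lambda)$ settings and step-size rules for the reference
implementations are not published; standard textbook defaults are
used.  Best-so-far traces per evaluation are averaged over 10 seeded
runs.

## Problem sizes and numerical choices

Default fixture: ~3000 nodes (edge 0.35 mm, 3× neck refinement, 3×
wall grading), 40 steps/cycle, 2 cycles — about half a minute per
design evaluation; the test suite's solver-level properties run on a
coarser ~1200-node variant, and the Poiseuille verification uses a
wall-graded plain channel.  Degenerate inputs are rejected early
(non-positive lengths, neck wider than the sac, fewer than two
waveform samples, out-of-range actions); tie-breaks are documented at
the operator (bin edges round down; the brute-force table breaks
reward ties by enumeration order).

## Limitations

The 2-D slab is a model of a model: it preserves the operators and the
qualitative porosity response, but absolute WSS levels, jet velocities
and reduction percentages are not comparable to patient-scale 3-D
values, and out-of-plane swirl, vessel curvature, wall compliance and
deployment mechanics are absent.  Passing tests therefore certify the
numerics (Poiseuille recovery, conservation, settling, refinement
robustness), the monotone flow-diversion response, and the agent
mechanics — not clinical hemodynamics.  Pore-density figures are
nominal pre-deployment values under one cell model.  The agent's
convergence is to the design it predominantly samples; on razor-sharp
reward landscapes (noted above) single-step PPO converges to
near-optimal, not provably optimal, designs.
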