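---
title: "Engineering azeotropy in patchy-particle mixtures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Engineering azeotropy in patchy-particle mixtures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(azeopatch)
```

# The problem

Multicomponent self-assembly designs pay a thermodynamic price: every new
species adds a degree of freedom, and a demixing transition can strand the
assembly at a composition different from that of the target structure.  An
*azeotrope* removes that risk: at an azeotropic composition the coexisting
phases have the same composition as the parent mixture, so the system
condenses and crystallises like an effective one-component fluid.

`azeopatch` implements the full tool-chain for *designing* azeotropy into
patchy-particle mixtures:

1. **Design rules** on the color-compatibility matrix that force all
   unbonded-patch probabilities equal (azeotropy), with checkers, a
   rule-satisfying matrix generator, and the reduced scalar mass-balance
   equation.
2. **Wertheim first-order perturbation theory** for the mixture free
   energy, the common-tangent construction of coexistence at fixed (T, P),
   and an azeotrope locator.
3. **Isochoric thermodynamics**: binodal tracing by ODE integration in
   pressure and critical-point location from the Hessian of the Helmholtz
   energy density.
4. A **Kern–Frenkel Monte Carlo engine** (NVT + Gibbs ensemble with
   aggregation-volume-bias moves) that checks the theory in simulation on
   the N2c8s2 cubic-diamond binary mixture.

Reduced units are used throughout: lengths in the hard-core diameter
$\sigma$, energies in the square-well depth $\epsilon$, $k_B = 1$, pressure
in $\epsilon/\sigma^3$.

# Models

## Kern–Frenkel patchy particles

A particle is a hard sphere of diameter $\sigma$ decorated with $N_p$ patch
unit vectors.  Two particles at centre distance $r \in [\sigma,
\sigma+\delta]$ gain energy $-\epsilon$ when some color-compatible patch
pair is mutually aligned: the cosine of the angle between each patch vector
and the centre-to-centre line must be at least $\cos\theta_{max}$,
simultaneously for both partners.  The working point of the diamond design
is $\delta = 0.2$, $\cos\theta_{max} = 0.98$ — narrow patches chosen
because small angular widths favour crystallisation over glassy arrest.
With this aperture two patches can never bind the same partner patch
simultaneously, and a patch cannot hold two bonds (a second particle in the
same cone would overlap the first), so the one-bond-per-patch condition of
the theory is enforced geometrically; `total_energy()` additionally reports
`max_patch_use` so any violation would surface in the analysis.

The bonding volume — the pose-space volume (position × normalised
orientation measure) over which a compatible pair stays bonded — has the
closed form
$$V_b = \frac{\pi}{3}\left[(\sigma+\delta)^3 - \sigma^3\right]
        (1 - \cos\theta_{max})^2,$$
the spherical-shell volume times the squared cone fraction
$(1-\cos\theta_{max})/2$.  A pose-sampling Monte Carlo oracle in the test
suite confirms the expression across a grid of $(\delta, \cos\theta_{max})$.

## Law of mass action and the design rules

The probability $X_\alpha^{(i)}$ that patch $\alpha$ of species $i$ is
unbonded satisfies
$$X_\alpha^{(i)} = \Big[1 + \rho \sum_j x^{(j)}
  \sum_{\gamma\in\Gamma(j)} \Upsilon_{\alpha\gamma} \Delta\,
  X_\gamma^{(j)}\Big]^{-1},$$
with $\Upsilon$ the symmetric 0/1 interaction matrix over patch colors and
$\Delta$ the bond integral.  Azeotropy follows whenever the design forces
all $X_\alpha^{(i)}$ equal, because the bonding free energy then collapses
to that of a one-component fluid.  Three sufficient rules are implemented:

* **Bond exclusivity** — every patch has exactly one partner among all
  patches; azeotrope at the equimolar composition $1/N_s$.  The common $X$
  solves $\frac{\rho\Delta}{N_s} X^2 + X - 1 = 0$ (with $m$ partners per
  patch the weight becomes $m/N_s$).
* **Bond multiplicity** (binary) — patches bonding into species 2 are
  exclusive, patches bonding into species 1 have $n$ partners there;
  azeotrope at $x = (1/(n{+}1), n/(n{+}1))$ and weight $n/(n+1)$.
* **Fully connected** — every patch has exactly one partner on *every*
  species; the weight is 1 and the mixture is azeotropic at every
  composition.

In all cases the reduced equation is quadratic with a single root in
$(0,1]$; `solve_azeotropic_x()` asserts this and the test suite
cross-checks it against the full $N_s \times N_p$ solver to $10^{-10}$ on
randomized rule-satisfying matrices.

`generate_rule_matrix()` builds such matrices constructively (random
matchings; per-species-pair bijections; an $n$-regular graph plus hub
construction for multiplicity) and verifies them with the checkers before
returning.  For the multiplicity rule the generator also requires at least
one inter-species bond: the patch-level counts alone admit degenerate
solutions that split into two non-interacting one-component systems (a
complete graph inside one species plus a matching inside the other), which
are not mixture designs in any useful sense.  With this requirement the
1:3 ratio on four tetrahedral patches is infeasible — each species-2 hub
needs three exclusive species-1 partners, leaving a single species-1 color
that cannot reach degree three — matching the known impossibility of that
ratio.

## The N2c8s2 design

The minimal two-species cubic-diamond design uses four tetrahedral patches
per species and eight colors, two of them self-complementary.  The package
encodes it as the pair set
$$(1,1),\;(2,2),\;(5,6),\;(3,7),\;(4,8),$$
with colors 1–4 on species 1 and 5–8 on species 2.  This is the unique
structure (up to relabelling) compatible with all of the design's defining
properties: one 1 per row (exclusivity), trace 2, chain-forming pure
components (each species keeps exactly two intra-species bondable patches —
two self-complementary colors on species 1, one complementary pair on
species 2), and a fully bonded periodic cubic-diamond decoration.  A
derivation in terms of orientation parities shows that placing the two
self-complementary colors on different species cannot decorate the diamond
lattice consistently, which forces the arrangement above.

The matching lattice decoration slices the cubic-diamond crystal into
slabs of width $a/2$ along $x$ that cycle through four
(species, orientation) forms with period $2a$; `build_diamond_seed()`
constructs it (the cell count along $x$ must therefore be even) and the
energy routine verifies full valence 4 at $-2\epsilon$ per particle before
the fixture is returned.  The hexagonal (wurtzite) seed is built
geometrically and is deliberately paired with a permissive single-color
mixture: the N2c8s2 matrix frustrates that lattice, and the detector test
should isolate the *geometric* (dihedral) distinction rather than the
color frustration.

## Wertheim free energy

Per particle, in units of $k_BT$:
$$\beta f = \underbrace{\ln \rho\sigma^3 + \textstyle\sum_i x^{(i)}\ln
x^{(i)} - 1}_{ideal} + \underbrace{\frac{\phi(4-3\phi)}{(1-\phi)^2}}_{CS}
+ \underbrace{\sum_i x^{(i)} \sum_{\alpha\in\Gamma(i)}
\left(\ln X_\alpha^{(i)} - \tfrac{X_\alpha^{(i)}}{2} +
\tfrac12\right)}_{bonding}.$$
The thermal volume is set to $\sigma^3$ for every species: it only shifts
$g$ by a composition-linear term and cannot move coexistence.  The bond
integral uses the contact expansion of the hard-sphere radial distribution
function,
$$\Delta = V_b\,(e^{\beta\epsilon}-1)\,\langle g_{HS}\rangle,\qquad
g_{HS}(r) \approx \frac{1-\phi/2}{(1-\phi)^3} -
\frac{9\phi(1+\phi)}{2(1-\phi)^3}\,(r-\sigma),$$
volume-averaged over the well shell; the expansion order (0 = contact
value, 1 = linear, the default) is an argument of `bond_integral()`.  An
independent quadrature oracle in the tests guards the transcription.

Pressure is computed analytically, $P = T\rho^2 \partial_\rho (\beta f)$,
with $\mathrm{d}X/\mathrm{d}\rho$ from implicit differentiation of the
mass-balance system (including $\Delta(\rho)$); the isochoric module
recovers the same number through $P = -\Psi + \sum_i \rho_i\mu_i$ with
finite-difference $\mu_i$, a deliberate dual route asserted to $10^{-7}$.

# Numerical methods

**Mass balance.**  Damped fixed-point iteration (damping 0.5, start
$X = 1$) to a loose tolerance, then Newton, to residual $10^{-13}$.  The
damped map alone is marginally stable at strong bonding ($|f'| \to 1-X$);
the Newton polish makes the solve robust and fast everywhere the package
operates ($\beta\epsilon$ up to $\sim 20$).

**Gibbs free energy at fixed (T, P, x).**  Minima of $g(\rho) = T\beta f +
P/\rho$ are located as up-crossing roots of $P(\rho) = P$ on a logarithmic
density grid over $[10^{-9}, 1.1]$ and refined by bisection to machine
precision.  All minima are reported so two-phase structure stays visible.

**Common tangent.**  $g(x)$ is sampled on a grid (default $\Delta x =
0.005$), concave gaps are found on the lower convex hull, and the pair is
refined by Newton iteration on equal slope and equal intercept.  Density
roots are warm-started walking outward from the window centre — a minimum
can disappear across a spinodal but never appears from nothing in that
direction, which keeps the scan both fast and safe.

**Azeotrope location.**  For a negative azeotrope the composition gap
closes at the pressure minimum of the lens.  `azeotrope_point()` bisects
in pressure between a single-phase and a two-phase state, shrinking the
composition window and the grid spacing with the measured gap (spacing
$\approx$ gap/15) so the detector resolution always tracks the gap.  The
gap closes very steeply in pressure (roughly as $\sqrt{P - P_{az}}$ with a
small prefactor), which is why a fixed-resolution scan would stall.  Near
the azeotrope the two-phase region consists of two mirror lobes meeting at
$(x_{az}, P_{az})$; the locator converges on one lobe and reports the
midpoint of the closing pair, which the design symmetry pins at
$x = 1/2$ to well below the $10^{-3}$ assertion.

**Isochoric tracing.**  With $\Psi(\boldsymbol\rho)$ as potential, the
isothermal coexistence ODE system is
$\mathrm{d}\boldsymbol\rho'/\mathrm{d}P = H'^{-1} v$,
$\mathrm{d}\boldsymbol\rho''/\mathrm{d}P = H''^{-1} v$, where $v$ solves
$\boldsymbol\rho'\cdot v = \boldsymbol\rho''\cdot v = 1$ (the matrix
becomes singular exactly at an azeotrope, where the integration naturally
stalls).  Integration is step-doubling RK4 with relative tolerance
$10^{-6}$; every accepted step is Newton-projected back onto the equal-P,
equal-$\mu$ manifold to prevent drift.  The ideal part of $\Psi$ is
analytic; the excess part is differentiated by Richardson-extrapolated
central differences with per-component steps
$\max(0.01\rho_i, 10^{-9})$ — the floor matters for dilute phases, where
the ideal contribution dominates the Hessian anyway.  Termination: end of
range, step collapse, or the Hessian determinant falling to $10^{-4}$ of
its starting magnitude (approach to a critical point).

**Critical points.**  `find_critical_point()` locates a sign change of
$\det H$ on a density segment and polishes the two conditions $\det H = 0$,
$u\cdot\nabla\det H = 0$ ($u$ the vanishing eigenvector) by Newton;
`critical_temperature_at_x()` brackets in temperature the point where the
minimum of $\det H$ along a fixed-composition ray touches zero.  On the
N2c8s2 design the critical temperature decreases monotonically from the
azeotropic composition toward both pure components, which have no
liquid–gas transition at all (pure species keep only two bondable patches
and aggregate into chains).

# Monte Carlo engine

The sampler (compiled code) implements per sweep $N$ attempted moves with
the default mix 80% rototranslation (maximum displacement $0.1\sigma$,
maximum rotation 0.1 rad), 10% AVB bind, 10% AVB release; the Gibbs
ensemble adds one volume move (uniform in $\ln V$, half-width 0.1) and
$N/10$ transfer attempts per sweep.  Cell lists accelerate the energy when
the box holds at least three cells per dimension; smaller boxes fall back
to all pairs.  A single 64-bit Mersenne Twister seeded from the user's
seed makes runs bit-reproducible; seeds are recorded in run metadata.

**AVB moves.**  The bind move picks a target $j$, then a particle $k$
uniformly among those not bonded to $j$, then a compatible patch pair
uniformly among the $n_{pairs}$ combinations for the two species, and
finally a pose uniform in that patch's bonding volume (cone-restricted
shell position; orientation with the partner patch in the return cone and
uniform spin).  The release move sends a bonded neighbour to a uniform
pose in the box, rejecting proposals that land bonded again.  Writing the
proposal densities out gives
$$\mathrm{acc}_B = e^{-\beta\Delta U}\,
  \frac{M_{out}(s)\, n_{pairs} V_b}{N_j(s')\,V},\qquad
  \mathrm{acc}_U = e^{-\beta\Delta U}\,
  \frac{N_j(s)\, V}{M_{out}(s')\, n_{pairs} V_b},$$
with $N_j$ the bonded-neighbour count of the target and $M_{out} = N-1-
N_j$.  The large ratio $V/V_b$ is what makes bond breaking acceptably
probable at $\beta\epsilon \gtrsim 12$.  Correctness is pinned by two
oracles: an arithmetic detailed-balance identity (to $10^{-12}$) and the
exact two-particle partition function
$p_{bond} = V_b e^{\beta\epsilon} / (V - V_{core} - V_b +
V_b e^{\beta\epsilon})$, matched within statistical error at three
temperatures.

**Gibbs-ensemble practice.**  Volume moves that would shrink a box below
$2(\sigma+\delta)$ are rejected (the minimum-image convention would break);
transfers preserve species identity and pick the particle uniformly in the
source box.  Production runs discard the first 20% and report
block-averaged densities and compositions (10 blocks), with the dilute and
dense branch identified per sample by density.  Coexistence runs start
with one box dilute and one box dense and pre-bonded by a short NVT run —
the standard initialisation: a randomly oriented dense box is effectively
a hot hard-sphere fluid and would transiently evaporate before the bond
network forms.

**Problem sizes.**  The package's validation runs use $N = 128$–$192$
particles and $10^5$–$10^6$ sweeps.  At these sizes the two branches
separate cleanly and the dilute branch reaches its equilibrium density,
but the dense branch continues to densify slowly (its block averages are
still drifting upward when the runs end) and holds only a few tens of
particles, so branch compositions carry sampling errors of a few percent.
These are desk-scale choices for a fast, deterministic test suite; all
run lengths and sizes are arguments, and production studies should scale
them up along with the system size.

**Crystal detection.**  A particle is cubic-diamond-like when it has four
bonds and every bond to its neighbourhood is staggered: all dihedral
angles $k$–$i$–$j$–$l$ across a bond satisfy $\cos 3\theta < 0$ (staggered
minima at 60°/180°/300° give $-1$, eclipsed at 0°/120°/240° give $+1$).
This bond-network dihedral classifier substitutes for full local
bond-order analysis; it is validated against constructed cubic and
hexagonal seeds (fractions exactly 1 and 0) and is not claimed equivalent
to bond-order methods on disordered configurations.

# What the generators emulate — and what they do not

`random_gas()` produces ideal-gas-like starting states (uniform positions
with hard-core rejection, uniform orientations, largest-remainder species
counts); it does not emulate equilibrated fluid structure at high packing
(insertion fails above $\phi \approx 0.45$).  `build_diamond_seed()`
produces perfect zero-temperature lattices; thermalised crystals have
vibrational disorder the detector tolerates only through the sign (not the
magnitude) of $\cos 3\theta$.  `generate_rule_matrix()` spans the rule
classes the checkers know; it does not search for matrices that assemble a
*given* target structure, which is a satisfiability problem outside this
package's scope.  Passing tests on these fixtures therefore validate the
algorithms and their bookkeeping, not the behaviour of any experimental
system.

# Known limitations

* Equal bond strengths throughout ($\Delta_{\alpha\gamma} \in \{0,
  \Delta\}$); mixed strengths would generalise the rules but are not
  implemented.
* All species share one diameter and one patch count; first-order theory
  only (no rings/loops, no bond cooperativity).
* The samplers require cubic boxes; the R-side analysis (bond graph,
  crystal fraction) accepts orthorhombic boxes for lattice fixtures.
* Desk-scale Gibbs runs under-estimate the dense-branch density (slow
  densification); the dilute branch and both compositions are the
  quantitatively meaningful observables at these sizes.
* Spontaneous nucleation at production scale (hundreds to thousands of
  particles over $10^8$ or more sweeps) is out of scope for the test
  suite; the crystal-growth check seeds a small crystallite and verifies
  growth and species balance instead.
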