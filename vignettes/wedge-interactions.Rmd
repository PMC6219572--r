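---
title: "Bilayer-mediated interactions between amphipathic protein wedges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bilayer-mediated interactions between amphipathic protein wedges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4.2)
library(wedgelat)
```

## The model

Amphipathic helices such as the N-terminal H0 helices of N-BAR proteins
(amphiphysin, endophilin) insert partially into one leaflet of a lipid
bilayer and act as "wedges": they locally compress the hydrophobic thickness
of the leaflet they sit in and tilt its surface.  Because leaflet
deformations cost elastic energy and relax over a characteristic length of
about a nanometre, two nearby wedges share (or frustrate) each other's
deformation fields, which produces an effective membrane-mediated
interaction between them.

`wedgelat` implements a minimal continuum model of this effect.  The upper
(wedge-containing) leaflet is described by two scalar fields: the leaflet
height $h^+(x, y)$ and the leaflet thickness deformation $u^+(x, y)$; the
lower leaflet is taken to be undeformed.  The elastic energy is

$$
G = \frac{1}{2}\!\int\! \mathrm{d}x\,\mathrm{d}y\,
\Big\{ K_b\big[(\nabla^2 h^+)^2 - (\nabla^2 h^+)(\nabla^2 u^+)
       + \tfrac12 (\nabla^2 u^+)^2\big]
 + \frac{K_t}{2}\Big(\frac{u^+}{a}\Big)^{\!2} + \tau\,\frac{u^+}{a}
 + \tau\big[(\nabla h^+)^2 - \nabla h^+\!\cdot\!\nabla u^+
       + \tfrac12 (\nabla u^+)^2\big] \Big\},
$$

with bending rigidity $K_b$, thickness deformation modulus $K_t$,
unperturbed monolayer hydrophobic thickness $a$ and membrane tension
$\tau$.  The defaults, $K_b = 20\,k_BT$, $K_t = 60\,k_BT/\mathrm{nm}^2$,
$a = 2\,\mathrm{nm}$, are standard values for phospholipid bilayers.  The
constant energy density $-\tau^2/4K_t$ of the tension-relaxed state is
subtracted throughout; it cancels in every interaction quantity.

A wedge imposes three contact conditions at the bilayer–wedge interface:
the leaflet thickness deformation equals the immersion depth, $u^+ = U$
($U \approx 0$ for the shallow state of H0, $U \approx -0.9$ nm for the deep
state); the contact slope of $u^+$ along the outward normal is $0$; and the
contact slope of $h^+$ is $-\tan 9^\circ$, the wedge half-opening suggested
by the helical wheel of H0.  The wedge cross-section is mirror symmetric,
so the same slopes apply on both sides.

## The analytic 1D solution

For two long parallel wedges the only relevant coordinate is the
perpendicular distance $r$; with the axis-to-axis separation $d$ and wedge
radius $r_0$ the bilayer region between the wedges spans
$r \in [-(d/2 - r_0),\, +(d/2 - r_0)]$.  The Euler–Lagrange equations of
the energy decouple in the shifted thickness variable
$\bar u^+ = u^+ + \tau a / K_t$:

* $\bar u^+$ is a combination of four exponentials
  $e^{\pm\sqrt{\nu^\pm} r}$ with
  $\nu^\pm = \tfrac12 \big[\lambda_t^{-2} \pm
  (\lambda_t^{-4} - \lambda_s^{-4})^{1/2}\big]$, where
  $\lambda_t = (K_b/\tau)^{1/2}$ and
  $\lambda_s = (K_b a^2 / 8 K_t)^{1/4}$;
* $h^+ = \bar u^+/2 + w$ with $K_b\, w'''' = \tau\, w''$.

At zero tension $\nu^\pm = \pm i/2\lambda_s^2$ are purely imaginary
conjugates, so the thickness field decays over $2\lambda_s \approx 1.28$ nm
with an oscillatory profile; this oscillation is what creates a *favorable*
interaction window at intermediate separations.  Instead of switching to a
dedicated basis at $\tau = 0$ (the textbook $\{1, r, e^{\pm r/\lambda_t}\}$
basis of the $w$-equation degenerates there) the solver uses the
limit-stable basis
$\{1,\, r,\, \lambda_t^2(\cosh(r/\lambda_t) - 1),\,
\lambda_t^3(\sinh(r/\lambda_t) - r/\lambda_t)\}$, which tends smoothly to
$\{1, r, r^2/2, r^3/6\}$ as $\tau \to 0$ and is well conditioned for every
$\tau \ge 0$.  Exponentials are anchored at the nearest wedge edge so that
their magnitude never exceeds one on the span.  Coefficients are complex;
conjugate pairing keeps the fields real to machine precision.

Six boundary conditions (three per wedge edge) plus the $h^+$ reference
level fix seven of the eight coefficients; the eighth degree of freedom is
the relative height of the two wedges, over which the energy — an exact
quadratic — is minimised analytically ("zero vertical force").  The
on-shell energy is evaluated from the total-derivative (boundary-term) form
of the functional, and independently by adaptive quadrature of the energy
density; the two agree to $10^{-6}\,k_BT$ on arbitrary parameter draws,
which is one of the package's standing property tests.

The interaction potential is
$G_\mathrm{int}(d) = G(d) - \lim_{d' \to \infty} G(d')$, with the reference
computed in closed form as the summed energies of the two isolated
semi-infinite exterior profiles, never by large-$d$ extrapolation.

```{r curve}
bp <- bilayer_params()
deep <- wedge_params(U = -0.9)
ic <- interaction_curve(bp, deep, deep, d_grid = seq(1.3, 8, by = 0.02))
plot(ic, main = "Deep immersion state, zero tension")
dimerization_energy(bp, deep)[c("energy", "d_star")]
```

### Useful closed forms

Two special cases make independent oracles:

* **Shallow state.** With $U = 0$ and zero thickness slope the thickness
  sector vanishes identically and the interaction is a pure
  bending-frustration term of the mirrored contact slopes:
  $G_\mathrm{int}(d) = K_b L \tan^2 9^\circ / (d/2 - r_0)$ *exactly* at
  $\tau = 0$.  This algebraic $1/d$ repulsion, not an exponential decay, is
  also the far-field tail of every interaction curve with the default
  contact slopes — the "unfavorable interactions at large separations" of
  the deep state.  At $d = 40$ nm it is still $\approx 0.08\,k_BT$.
* **Small tension.** The isolated-wedge reference acquires a tension tail
  of energy $L \tan^2 9^\circ \sqrt{K_b \tau}/2$ per side, so
  $G_\mathrm{int}(\tau)$ approaches its tensionless limit with a
  $\sqrt{\tau}$ cusp rather than analytically.  A consequence worth knowing:
  the dimerization energy *rises* by a few hundredths of $k_BT$ at very
  small tensions ($\tau \lesssim 0.1\,k_BT/\mathrm{nm}^2$, where the pair
  "hides" two reference tails) before the dominant thickness-sector
  weakening takes over; for tensions in the experimentally visible range
  ($\tau \gtrsim 0.2\,k_BT/\mathrm{nm}^2$) dimerization weakens
  monotonically, with shifts below $1\,k_BT$ up to
  $\tau \approx 1\,k_BT/\mathrm{nm}^2$, and the shallow state is far less
  tension-sensitive than the deep state.

With the default parameters the solver gives a critical immersion depth
$U_c \approx -0.40$ nm separating net-repulsive from net-attractive wedge
pairs, an optimal deep-state separation $d^\ast \approx 1.78$ nm with a
dimerization gain of $\approx 12.8\,k_BT$ per H0 dimer, and a favorable
window $1.34 \lesssim d \lesssim 3.9$ nm.  The window endpoints are set by
the phase of the thickness oscillation ($\pi \cdot 2\lambda_s \approx 4$ nm
from the well to the next sign change), so they scale directly with
$\lambda_s$.

## The 2D thickness solver

For arbitrary in-plane arrangements the package minimises the energy with
the height field pinned flat ($h^+ = 0$) over a regular grid around
stadium-shaped wedge footprints (a rectangle of length $L - 2r_0$ capped by
semicircles of radius $r_0$).  The imposed immersion is $U$ along the
straight sides and tapers to zero towards the cap centers; the taper is
linear in arc length, the minimal smooth choice.  Working in $\bar u^+$
makes the discrete energy a pure positive-semidefinite quadratic form (a
13-point bilaplacian stencil plus a spring term), so the field is the
unique solution of one sparse SPD system.

Numerical choices that matter:

* **Clamped contact.** The footprint interior is held at the immersion
  profile and the curvature energy also counts the ring of footprint cells
  adjacent to the membrane; this penalises any slope jump across the
  staircase boundary and reproduces the zero contact slope.  A mid-length
  transect of a long footprint matches the analytic 1D $h^+$-pinned
  profile to about 3% in the field and well under 10% in energy per unit
  length.
* **Staircase caveat.** The rasterised footprint boundary carries a
  non-convergent corner energy, so *absolute* field energies are
  discretisation-dependent.  All physical quantities are interaction
  energies — joint energy minus isolated references computed on the same
  lattice alignment — in which the corner contributions cancel;
  interaction energies change by about 2% on halving the grid spacing.
* **Patch.** The patch edge is clamped to the relaxed state; by default it
  sits 10 decay lengths from the footprints.
* **Sub-cell gaps.** Poses whose outline gap is below one grid cell cannot
  be resolved and are recorded as hardcore.

Pair-potential tables are built on a non-uniform pose grid
(offset $\Delta x, \Delta y$ in the first wedge's frame, relative
orientation $\Delta\theta$ with period $\pi$), exploiting the stadium's two
mirror symmetries.  Lookups interpolate multilinearly, return zero beyond
the tabulated range, and test the hardcore exactly from the capsule
geometry, never by interpolation.

## Self-assembly Monte Carlo

N-BAR proteins are rigid bodies: a crescent scaffold (capsule arc of 10 nm
span) with one H0 footprint at each tip, directed along the tip tangents.
Inter-protein energies are the tabulated H0–H0 interactions (four terms per
protein pair, averaged over the two lookup frames so the pair energy is
exactly symmetric) plus hardcore sterics from capsule–capsule distances,
and optionally a scaffold–scaffold pair potential
$\varepsilon[(r_m/r)^{12} - 2 (r_m/r)^6(1 - |2\theta_1 - \pi|/2\pi -
|2\theta_2 - \pi|/2\pi)]$ with $\varepsilon = 10\,k_BT$, $r_m = 10$ nm,
minimised by two scaffolds facing side-by-side at $r_m$.

A Monte Carlo step performs one displacement trial ($\delta r = 0.1$ nm)
and one rotation trial ($\delta\theta = 1^\circ$) per protein in a freshly
shuffled order; trials are accepted by the Metropolis rule with the
temperature in units of room temperature.  Annealing holds $T = 2$ for the
hot phase and then cools linearly to $T = 0$; the full-scale protocol is
$10^7 + 5\times 10^6$ steps, while the package's tests use
$10^5 + 5\times 10^4$ steps with 16 proteins in a 60 nm periodic box,
which already assembles tip-to-tail chains of antiparallel H0 dimers in a
few tens of seconds.  Annealing locates low-energy configurations; it does
not sample thermodynamic ensembles.

Two geometric defaults were genuinely open and deserve their rationale:

* **Tip tangent angle (60°).**  The scaffold arc is strongly curved, with
  tip tangents at 60° to the chord, matching the roughly third-of-a-circle
  crescents of N-BAR scaffolds.
* **H0 position (center 0.9 nm beyond the tip).**  The helix lies partly
  alongside the scaffold tip, as in N-BAR structures where H0 emerges at
  the distal ends of the scaffold.  This placement also controls which
  H0-dimer architecture the scaffold potential favours: pairing on the
  *inner* helix sides pulls the partner scaffold to (or inside) $r_m$,
  where the $r^{-12}$ wall penalises it, while *outer*-side pairing keeps
  the scaffolds near the shallow part of the potential.  With H0 far beyond
  the tips the discrimination reverses sign — the inner arrangement then
  parks the partner scaffold in the attractive region — so the observed
  outer-side selectivity is a genuine function of how close the helices
  sit to the scaffold ends.  With the defaults, annealing without the
  scaffold term produces both architectures, and adding it makes
  outer-side dimers dominate.

## Conformational statistics of the switch

A pair of proteins carries conformation variables $s_{1,2} \in \{0, 1\}$
(shallow/deep) with single-protein bias
$G_\mathrm{non} = (s_1 + s_2)\,\varepsilon_d$ and the separation-dependent
interaction from the 1D solver (face-on, isotropic in the axis-to-axis
distance $r$; the mixed state uses the asymmetric-pair solution with the
same contact slopes on both wedges).  Sampling the separation at surface
concentration $c$ gives the Boltzmann weights

$$
z(s_1, s_2) = e^{-G_\mathrm{non}}
\Big[1 + c\,\pi\!\int_{2 r_0}^{r_c}\! \big(e^{-G_\mathrm{int}(r)} - 1\big)\, r\,
\mathrm{d}r\Big],
\qquad
P_d = \frac{z(1,1)}{z(0,0) + 2 z(0,1) + z(1,1)}.
$$

The radial integral is split at the potential minimum (the deep-state Mayer
function peaks at $e^{12.8} \approx 4 \times 10^5$ there) and evaluated
adaptively to $10^{-6}$ relative tolerance.  In the dilute limit
$P_d \to 1/(1 + e^{\varepsilon_d})^2$; because the deep-state integral is
$\sim 10^6\,\mathrm{nm}^2$, "dilute" here means
$c \lesssim 10^{-8}\,\mathrm{nm}^{-2}$.  The expansion breaks down when
$1 + cI$ turns non-positive for the repulsive states, at
$c \approx 3\times10^{-3}\,\mathrm{nm}^{-2}$ with default parameters;
higher concentrations raise a range error (or `NA` grid cells in the phase
diagram).  Two consequences of the algebraic $1/d$ tail of the repulsion:
the spatial integrals retain a small sensitivity to the cutoff $r_c$
(moving it from 40 to 80 nm shifts $P_d$ at the $10^{-3}$ level at
moderate $c$, not $10^{-4}$), and the shallow-state integral is itself a
few hundred $\mathrm{nm}^2$ negative.

```{r phase, fig.height = 4.6}
cm <- conformational_model(epsilon_d = 0)
pd <- phase_diagram(cm)
plot(pd, main = expression(P[d] ~ "with" ~ P[d] == 1/2 ~ "contour"))
```

$P_d$ grows monotonically with $c$ for every $\varepsilon_d$, and for
$\varepsilon_d > 0$ there is a threshold concentration at which
$P_d = 1/2$: the concerted switch of the pair into the deep state.

## What the tests do and do not show

The test suite checks the analytic solver against independent quadrature,
closed forms and its own symmetry/scaling invariants; the 2D solver against
the 1D limit and pairwise additivity; the Monte Carlo module against
locality, periodicity, rigid-motion invariance, determinism and hand-built
dimer/chain configurations; and the statistical-mechanics layer against
closed-form limits and monotonicity.  Everything runs at desk scale (grids
of $\sim 10^4$ cells, $1.5\times10^5$ Monte Carlo steps, 10 seeds), sizes
chosen so that the whole suite completes in minutes while still exhibiting
chain self-assembly.  What passing tests do *not* show: the model has no
lipid tilt degrees of freedom, treats the lower leaflet as rigid, uses a
flat reference membrane, fixes $h^+ = 0$ in two dimensions, and the
annealed configurations are low-energy states, not a thermal ensemble —
conclusions about real membranes inherit those assumptions.

## Known limitations

* The favorable-window endpoints and the optimal separation inherit the
  thickness-decay length $\lambda_s = (K_b a^2/8K_t)^{1/4} \approx 0.64$ nm;
  quantities that depend on the oscillation phase are sensitive to it.
* Absolute 2D field energies carry staircase-corner contributions; only
  interaction differences are physical (see above).
* The scaffold geometry of the Monte Carlo module is a two-dimensional
  cartoon with configurable dimensions; architecture-selection results
  depend on it and the defaults are documented choices, not measurements.
* The conformational-switch layer is a pair theory; it says nothing about
  three-body effects or the absolute concentration scale of experiments.
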