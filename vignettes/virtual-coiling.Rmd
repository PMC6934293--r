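---
title: "Virtual coil embolization: models, numerics and design choices"
author: "coildeploy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual coil embolization: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`coildeploy` simulates the endovascular treatment of intracranial
aneurysms with detachable platinum coils.  This vignette is the package's
account of the science it implements: the mechanical model of the coil,
the virtual manufacturing of its pre-shape, the explicit dynamics of the
three mechanical steps of coiling, the cross-section metrics used to
quantify deployed coil distributions, and the design choices made where
the problem left the design genuinely open.

## 1. The coil as a multiscale structure

An embolic coil has three structural scales:

* **primary**: a platinum-alloy stock wire of diameter $D_1$
  (0.0381 mm for the bare platinum coils modeled here);
* **secondary**: that wire tightly wound into a helical, spring-like
  tube of outer diameter $D_2$ (0.2921 mm);
* **tertiary**: the helical tube heat-set around a shaped mandrel into a
  3D "pre-shape" of envelope diameter $D_3$ (millimetres), which the
  coil tries to recover after release — its shape memory.

Resolving the primary wire in a deployment simulation is hopeless (a
10 cm coil has ~2600 wire loops), so the secondary structure is modeled
as a chain of tubular Timoshenko beam elements whose *section and
moduli are chosen so the beam has the rigidity of the helical spring it
replaces*.

### Spring rigidities

For a helical spring of wire diameter $D_1$, coil diameter $D_2$,
$n$ wire loops and length $l$, with wire moduli $E_w, G_w$:

$$D_{compressive} = \frac{G_w D_1^4 \, l}{8 n D_2^3}, \qquad
  D_{shearing} = \frac{E_w D_1^4 \, l}{8 n D_2^3}, \qquad
  D_{flexural} = \frac{E_w G_w D_1^4 \, l}{16 n D_2 (2 G_w + E_w)}.$$

Under tight winding, adjacent wire loops touch, so $l = n D_1$
(`loops_from_length()`).  The equivalent beam moduli come from equating
beam rigidity to spring rigidity:

$$E_b A_b = D_{compressive}, \qquad
  \lambda G_b A_b = D_{shearing}, \qquad
  E_b I_b = D_{flexural},$$

with $A_b$, $I_b$ the beam section area and second moment and $\lambda$
the Timoshenko shear shape correction factor.

### The section-convention problem

The axial and flexural equations overdetermine $E_b$ for any fixed
section, and no single tubular section convention reproduces both
published equivalent moduli of the bare platinum coil
($E_b = 1.52\times10^{-3}$ GPa, $G_b = 1.85\times10^{-3}$ GPa)
simultaneously.  The package therefore keeps the convention explicit
(`beam_section()` supports `ANNULUS_OUTER_D2`, `ANNULUS_AROUND_D2`,
`SOLID_D2`) and ships a calibrated default:

* $E_b$ from the **flexural** equation with an annulus of wall $D_1$
  *around* $D_2$ (`ANNULUS_AROUND_D2`), which lands within 1% of the
  published value.  Flexure governs the looping of a deployed coil,
  which is why the flexural calibration is primary.
* $G_b$ from the shear equation with a **solid** $D_2$ disc and
  $\lambda = 0.75$, within 0.5% of the published value.

All three candidate moduli are recorded in the returned
`equivalent_material`, so any other convention is one configuration away.

```{r}
library(coildeploy)
coil_beam_properties(D1 = 0.0381, D2 = 0.2921, l = 100)
```

The resulting beams are about five orders of magnitude softer than
platinum wire ($\log_{10}(E_w/E_b) \approx 5.2$), which is the essential
difference between simulating a coil as a spring-equivalent structure
and simulating it as a stiff platinum rod.

### Effective density

The explicit solver needs mass.  No density is published for the
equivalent beam, so the package conserves mass per unit coil length:
the wound wire contributes
$\rho_w \frac{\pi}{4} D_1^2 \cdot \pi (D_2 - D_1)/D_1$ per mm of coil
(0.512 mg/mm for platinum), and `effective_density()` divides by the
beam section area.  Quasi-static results are insensitive to this choice;
it matters only for the stable time step and settling times.

## 2. Virtual manufacturing of the pre-shape

Real pre-shapes are imprinted by winding the secondary tube around a
mandrel: a main cylinder of diameter $D_3 - 1.5$ mm carrying cross-axis
cylinders of diameter $D_3$.  `build_mandrel()` implements exactly this
rule; the *number, spacing and azimuths* of the cross cylinders and the
winding path are not published (commercial designs are proprietary), so
they are free parameters with one documented default
(`default_winding_pattern()`): a main-axis helix that, at each cross
cylinder, ends its turn exactly at the stub azimuth, rides over the
protruding stub in a half-wrap at one axial station, and resumes the
climb above it, with pitch at least $D_2$ so the inflated coil cannot
interpenetrate.  A *full* encircling wrap is not used: its entry and
exit must cross the band of wrap passes on the stub surface, which
provably brings the inflated tube within less than $D_2$ of itself.

Winding is computed analytically — helix and half-wrap segments on the
cylinders joined by short in-plane diagonals and cylindrical-coordinate
ramps (the physical wire likewise bridges through air between
cylinders) — rather than by constrained-spline projection in a CAD
kernel.  The junctions are tangent-continuous except at the two stub
corners, where the wire turns sharply; the self-clearance invariant
(minimum distance between well-separated centerline stretches at least
$D_2$) is verified across mandrel sizes 2.5–10 mm.  This keeps the geometry reproducible to the bit
(`wind_on_mandrel()` is deterministic) and dependency-free.  The wound
curve is truncated to the coil length and discretized at element length
$h$ (default $h = D_2 \approx 0.29$ mm; the tests and the reduced
protocol use $h = 0.5$ mm for speed).

A spherical-spiral family (`parametric_preshape()`) stands in for purely
mathematical pre-shapes as an A/B baseline.  It is this package's own
baseline: a spiral on the $D_3$ sphere whose winding rate is solved so
the arc length equals the coil length.  It is *not* a reproduction of
any published parametric coil equations.

## 3. Vascular geometry

Synthetic aneurysm cases (`make_synthetic_aneurysm()`) replace patient
imaging so the full pipeline is testable: a spherical sac on a straight
or planar-arc tube (sidewall) or on a symmetric bifurcation (terminal),
with the orifice contour computed analytically as the sac/vessel
intersection curve and an analytic centerline.  Each case carries both
implicit solids (exact containment queries) and triangulated surfaces:
icospheres for the sac, swept tubes for the vessel, and a watertight
union extracted from the implicit function by marching tetrahedra with
topological orientation.  Containment is tested two ways — generalized
winding number and ray-crossing parity — which agree on random points.

The delivery catheter is a swept tube around the centerline with inner
radius $D_2$ (twice the coil radius), truncated at the orifice,
proximally extended by a straight segment of one coil length, and
carrying a conical entry funnel (below).  The centerline must be no
shorter than the longest coil, and its curvature radius must exceed the
tube radius; both are hard errors.

## 4. Explicit dynamics

The solver integrates a chain of **corotational Timoshenko** elements
with the central-difference rule and lumped masses.  Each node carries a
position and a unit-quaternion frame; element strains are the material
frame components of the stretched/sheared chord
($\Gamma = R_e^\top d / L_0$) and the relative-rotation curvature
($\kappa = 2\,\mathrm{vec}(q_i^{-1} q_j)/L_0$), measured *relative to
the rest strains of the pre-shape* — that offset is the coil's shape
memory.  Elastic constants are $E_b A_b$, $\lambda G_b A_b$ (transverse
shear), $E_b I_b$ and $G_b J$ with $J = 2 I_b$.  The formulation was
chosen because the element family (Timoshenko) is given but the exact
formulation is not; corotational strain measures with one-point
integration are the standard, shear-locking-free choice for explicit
codes in the large-rotation / small-strain regime.  Verification:

* cantilever tip deflection within 2% (0.02% observed at 50 elements)
  of $FL^3/3EI + FL/\lambda G A$;
* exact trajectories under constant acceleration (the first velocity
  update is a half kick from the integer-time initial condition);
* bounded oscillator energy over $10^4$ steps;
* momentum conservation to $10^{-8}$ without external forces.

**Damping.** Rayleigh damping with $\alpha = 1\,\mathrm{s}^{-1}$ and
$\beta = 10^{-6}\,\mathrm{s}$ (the published calibration) is the
default.  $\beta$ is applied at element level to the strain rates
(a $\beta K \dot u$ surrogate that never assembles $K$).  Penalty
contacts additionally carry a viscous normal damper at 20% of critical —
standard explicit-contact practice to suppress chatter; all damping
flows into the dissipation ledger.

**Time step.** `stable_dt()` bounds the step by the axial/shear wave
transit $2c/h$, the rotational frequency of the lumped rotary inertia,
and the contact-spring frequency (with a factor covering several
simultaneous contacts on one node), reduced by the standard Rayleigh
factor $\sqrt{1+\xi^2} - \xi$.

**Contact.** Rigid triangulated barriers (aneurysm wall, neck cover) use
nearest-triangle penalty contact with elastic Coulomb friction
(tangential anchor springs capped at $\mu N$): $\mu = 0.6$ against the
vessel wall, $0.2$ coil-to-coil, $0$ against the catheter, following the
published friction coefficients.  Penalty stiffness is not published;
the default $k_n = 10 E_b A_b / D_2$ keeps static penetration at a small
percent of $D_2$ and is configurable.  The catheter is enforced as an
*analytic* swept-tube wall (two-sided thin shell) — the catheter is
defined as a tube around a centerline, so triangulating it for contact
would only add noise.  Nodes inside the catheter are shielded from mesh
barriers: the physical tube wall separates them from the vessel.

**Energy ledger.** Work and dissipation are accumulated with
midpoint-velocity products, which closes the discrete central-difference
balance: external work = kinetic + elastic strain + contact-spring
energy + dissipation to within 1% over the packaging simulation.  The
rotational elastic torques are first-order consistent with the strain
energy (mean-quaternion and lever-arm derivatives are approximated), so
under violent free rotation — far outside the quasi-static regime the
deployment protocol operates in — ledger closure loosens to a few
percent while dissipation remains monotone.

## 5. The three mechanical steps

1. **Packaging** pulls the distal coil node along the catheter
   centerline with a quintic smooth-step displacement (zero velocity and
   acceleration at both ends) of amplitude equal to the coil length.
   The pre-shape ball cannot jump into a 0.29 mm tube, so a conical
   entry funnel (slope 0.3, one-sided, with the true cone-normal
   reaction) is prepended, the coil starts at the funnel mouth, and the
   pull is topped up in short increments until every node is inside the
   $D_2$-radius tube.  The funnel is a packaging aid of this
   implementation; the tested contract is containment plus arc-length
   preservation within 1%.
2. **Advancement** pushes the proximal node by the catheter centerline
   arc length, bringing the distal tip to the orifice.  Through a
   straight catheter this is a near-rigid translation (final strain
   energy within 5% of packaged); through a curved catheter the coil
   additionally stores bending energy — the strict inequality that
   motivates modeling this step at all.
3. **Deployment** pushes the proximal node until the coil is fully
   released.  The sac surface is a keep-inside barrier, and a one-sided
   neck cover spans the orifice as the balloon/stent surrogate,
   preventing herniation into the parent artery.  The cover is an
   annulus with a central opening of about three coil radii through
   which the catheter passes — a full cover would crush the nodes still
   inside the tube between two rigid surfaces.  After the push the end
   is released and the coil settles freely; herniated nodes (inside the
   vessel, outside the sac) are a flagged failure, never silent.

Between steps the state settles under damping until kinetic energy is
below $10^{-3}$ of strain energy.  Step durations default to a drive
speed of 0.4 mm/ms, keeping kinetic energy well below strain energy
during driving (a quasi-static surrogate); durations are configuration,
as none are published.

The strain-energy ordering — packaged $\approx$ advanced-straight <
advanced-curved, and deployment *releases* energy (pre-shape recovery) —
is asserted in the test suite on the reduced case.  A deliberate
limitation: at the default drive speed a tightly curved catheter leaves
some transient axial compression in the advanced state, so
curved-advancement energies should be read as ordering, not as converged
quasi-static values.

**Ensembles.** Deployment variability is represented by rotating the
pre-shape coaxially about the catheter axis in 40° increments before
packaging — nine runs per case over a full turn; θ = 0° and θ = 360° are
bit-identical, and all nine final configurations differ.  Multi-coil
plans run the three steps sequentially per coil, with earlier coils left
in the sac as fully deformable contact bodies (chains combined into one
model with explicit element connectivity).

## 6. Quantifying coil distributions

Five cross-section planes, 1 mm apart and perpendicular to the
dome-to-neck axis (the first 1 mm below the dome apex), emulate the
physical sectioning of epoxy-embedded phantoms; a 5 mm sac admits only
four such planes, and the reduced tests use four.  Each section is
rasterized by capsule–plane intersection (a pixel is coil if its centre
lies within $D_2/2$ of any centerline segment) at resolution $D_2/8
\approx 0.037$ mm/pixel; the sac outline of the *first* section is the
analysis mask for all five, as in the physical protocol.

* **Coil density** $CD$ = black pixels inside the mask / mask pixels.
* **Lacunarity** $L$: gliding-box algorithm — for box size $r$, slide an
  $r\times r$ window over every position inside the mask bounding box,
  $\Lambda(r) = \sigma^2/\mu^2 + 1$ of the box masses, and $L$ is the
  arithmetic mean of $\Lambda(r)$ over $r \in \{2, 4, 8, \dots\}$ up to
  45% of the bounding box.  The box series, single grid orientation and
  aggregation are declared defaults (the reference tool's settings are
  not published) and are configurable.  The implementation is verified
  against exhaustive enumeration on all small images.

Aneurysm-averaged $(CD, L)$ points are standardized per phantom to mean
0, standard deviation 1 (sample estimator; with only two points this
yields $\pm 1/\sqrt 2$, not $\pm 1$), and compared by Euclidean distance
$d = \sqrt{\Delta CD^2 + \Delta L^2}$, summarized as $d_{Min}$,
$d_{Max}$ (extremes over the nine virtual points) and $d_{Avg}$
(distance to the *centroid* of the nine — which can be smaller than
$d_{Min}$).  `compare_groups()` applies Shapiro–Wilk normality tests,
Levene's test, and a Student's t-test with equal variances when Levene
does not reject, at the 0.05 threshold.

## 7. What the synthetic data does and does not show

The synthetic generator produces idealized spherical-sac aneurysms with
analytic centerlines, and the reduced protocol deploys a single
5 mm × 20 mm coil at $h = 0.5$ mm.  This exercises every stage of the
pipeline — winding, packaging through a funnel, advancement energy
storage, release, containment, sectioning, metrics — under conditions
where the expected behaviour is provable.  It does **not** show that
deployed configurations match physical deployments in patient-specific
geometry: real sacs are non-spherical, necks are irregular, catheters
move during delivery, and clinical packing uses multiple long coils at
much higher packing density (a single reduced coil reaches $CD \approx
0.02$ per section versus ~0.2–0.3 clinically).  Statistics on Euclidean
distances between simulated ensembles and physical experiments require
physical cross-section images, which are outside this package's scope.

## 8. Numerical choices and degenerate inputs

* Problem sizes: the test suite and worked examples use the reduced coil
  (40 elements), icospheres at subdivision 2–3 for contact, and
  marching-tetrahedra grids of 36–56 points per axis — sizes chosen so a
  full nine-run ensemble completes in minutes on one core.
* Zero-length elements, non-increasing centerlines, degenerate annuli,
  sub-1.5 mm mandrels, overlapping cross cylinders, too-coarse raster
  resolutions and empty masks are all explicit errors.
* An all-white section defines $L = 1$ (logged convention).
* Quaternions are renormalized every step; adjacent-frame sign
  consistency is enforced at assembly and maintained by continuity.
* Determinism: the solver contains no random number generation; a seed
  only enters through user-level initial-condition choices, so identical
  inputs give bit-identical trajectories.

## 9. Known limitations

* Stretch-resistant fibers, hydrogel coatings, plasticity and
  temperature-dependent shape memory are not modeled.
* The vessel wall is rigid; there is no blood flow and no gravity.
* Coil detachment mechanics and catheter kickback are not modeled; the
  driven end follows the centerline exactly while driven.
* The funnel-based packaging is an idealization of manufacturer
  packaging; only the packaged state, not the packaging transient, is
  meaningful.
* Friction uses elastic-anchor Coulomb sticking against meshes but
  regularized (velocity-smoothed) Coulomb for coil-coil contact, so
  very slow coil-on-coil creep is slightly over-damped.
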