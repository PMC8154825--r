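---
title: "Methods: strain-adaptive bone remodelling with piezoelectric coupling"
author: "piezobone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: strain-adaptive bone remodelling with piezoelectric coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model implemented by `piezobone`, the numerical
choices behind it, the synthetic geometries used to exercise it, and the
limits of what the test suite can and cannot show about real bone.

## The model

Bone is treated as an isotropic linear-elastic continuum in a 2-D
plane-strain slice of the proximal femur.  The elastic modulus depends on
the apparent density $\rho$ (g/cm$^3$) through the power law

$$E(\rho) = M\rho^{\gamma},$$

and the density itself evolves under the strain-energy-density (SED)
stimulus

$$\frac{d\rho}{dt} = B\left(\frac{U}{\rho} - S_r\right),
\qquad U = \tfrac{1}{2}\,\sigma : \varepsilon,
\qquad \rho_a \le \rho \le \rho_b .$$

Density grows where the SED per unit density exceeds the reference
stimulus $S_r$ and resorbs (disuse) where it falls short.  There is no
lazy zone and no saturation of the density-change rate: both are known
extensions of this law, deliberately absent here, which is why the
dynamics react strongly (and without a dead-band) to over- and
under-loading.

The coupled variant adds the piezoelectric behaviour of bone matrix with
hexagonal symmetry: stress acquires a converse-effect term
$-\alpha(\rho)\,\mathcal{E}^{*}\mathbf{E}$ and the electric displacement is
$\mathbf{D} = \alpha(\rho)\,\mathcal{E}\varepsilon +
\alpha(\rho)\,\beta\mathbf{E}$ with $\mathbf{E} = -\nabla\varphi$ and
$\alpha(\rho) = \rho^{\gamma}$.  Mechanics and electrostatics are solved
together as one quasi-static saddle system each step.

### Parameters (defaults, `material_params()`)

| parameter | meaning | default | unit |
|---|---|---|---|
| `rho_min`, `rho_max` | resorbed / cortical density bounds | 0.010, 1.740 | g/cm^3 |
| `S_r` | reference stimulus | 0.004 | J/g |
| `B` | remodelling rate constant | 1 | (g cm^-3)^2 (MPa day)^-1 |
| `M`, `gamma` | modulus power law | 3790, 3 | MPa/(cm^3/g)^gamma, -- |
| `k` | Poisson's ratio (density-independent) | 0.3 | -- |
| `plate_E`, `plate_k` | side-plate elasticity | 17000, 0.3 | MPa, -- |
| `e31`, `e33`, `e15` | piezoelectric coefficients | 1.50765e-9, 1.87209e-9, 3.57643e-9 | C/mm^2 |
| `e14` | out-of-plane shear coupling | 0 (inert in 2-D) | C/mm^2 |
| `beta11`, `beta33` | permittivities | 88.54e-12, 106.248e-12 | F/mm |

Units are mm--N--MPa--day--V--C with densities in g/cm$^3$.  Since
1 MPa = 1 J/cm$^3$, the ratio $U/\rho$ carries J/g and is directly
comparable with `S_r`.  The tensor values are used on this scale as given.

### The plane reduction

The material 3-axis (poling, the femur's longitudinal direction) is mapped
to the global vertical axis of the model and the 1-axis to the horizontal;
the out-of-plane direction is the 2-axis.  Under plane-strain kinematics
the `e14` entries couple only out-of-plane shear and vanish identically
(asserted against the full 3-D contraction in the tests, including with a
deliberately nonzero `e14`).  The surviving coupling is

$$D_x = \alpha\, e_{15}\gamma_{xy}, \qquad
  D_y = \alpha\,(e_{31}\varepsilon_{xx} + e_{33}\varepsilon_{yy}),$$

with permittivity $\alpha\,\mathrm{diag}(\beta_{11}, \beta_{33})$.

### The Lamé convention

`lame_coefficients()` implements $\lambda = kE/(1-k^2)$ exactly as the
remodelling literature this model follows writes it, not the standard 3-D
$kE/((1+k)(1-2k))$ (a `lame_convention = "standard"` switch exists).  This
is not a cosmetic choice: with this $\lambda$, a plane model under uniaxial
in-plane stress obeys $\varepsilon = \sigma/E$ *exactly*, which is what
makes the closed-form bar equilibrium

$$\rho^* = \left(\frac{\sigma^2}{2 M S_r}\right)^{1/(\gamma+1)}$$

($\approx 0.738$ g/cm$^3$ at $\sigma = 3$ MPa) an exact oracle for the FEM
pipeline rather than an approximation.

## Discretisation and solver

* **Elements.** 3-node linear triangles for both displacement and
  potential (constant strain and field per element).  This pairs naturally
  with the elementwise-constant density of the rate law: element SED is
  evaluated at the centroid strain and feeds the element's own density.
* **Assembly.** Because $k$ is density-independent, $C(\rho) =
  E(\rho)\,C_1$ and all coupled blocks scale elementwise by $\rho^\gamma$.
  The sparse pattern, Dirichlet reduction and triplet-to-slot aggregation
  map are therefore built once per run; each time step only rescales the
  numeric values and refactorises.  Stiffness is reassembled every step
  (no lagging).
* **Linear solves.** One sparse LU factorisation per step of the
  unsymmetric saddle system $[K_{uu}, K_{u\varphi}; -K_{u\varphi}^T,
  K_{\varphi\varphi}]$.  The blocks differ by ~19 orders of magnitude
  (MPa·mm stiffness vs F/mm permittivity), so the matrix is symmetrically
  equilibrated by its diagonal before factorisation; without this the LU
  condition check rejects the system.  Load cases within a step share one
  factorisation (multi-column right-hand side).
* **Dirichlet conditions** are applied by exact row/column elimination
  with value substitution, not penalties — required for the patch tests to
  be exact to machine precision.
* **Time integration.** Forward (explicit) Euler with $\Delta t = 0.1$
  day by default, density clamped to $[\rho_a, \rho_b]$ after every step.
  Euler is first-order and conditionally stable; at the default step the
  bar fixture's day-300 field changes by $< 10^{-6}$ RMS when the step is
  halved (measured by the acceptance script).
* **Load-case combination.** The three gait load cases act "per day"; the
  stimulus of a step is the arithmetic mean of the per-case SED fields,
  which equals the time average of a sequential within-day application
  under quasi-statics.  A `combiner = "sum"` option exists for sensitivity
  runs.
* **Tractions.** Joint and abductor loads are consistent nodal loads of a
  parabolic traction profile along the named boundary arc (zero magnitude
  at the arc ends), integrated exactly with 2-point Gauss per edge and
  normalised so the resultant equals the prescribed force to machine
  precision.  Angles are measured from the global vertical; `"down"`
  (head) and `"up"` (trochanter) senses oppose each other.
* **Stimulus with coupling.** The SED uses the full constitutive stress,
  including the converse-effect term (`stimulus = "full_stress"`).  Note
  that this makes the charge-only SED sign-indefinite: the pure
  inverse-piezoelectric "deposition" picture corresponds to
  `stimulus = "mechanical_only"`, which is what the mechanism test uses
  (see below).

## Scheduling

Phase 1 (days 0 to `t_remodel`, default 300) applies all load cases every
iteration.  Phase 2 (to `t_end`, default 400 when enabled) models reduced
physical activity: loads act only on every `reduced_activity_every`-th day
(default 3), while a therapeutic surface charge $q_N$ (default
$2\times10^{-9}$ C/mm$^2$) acts on the trochanter arc every iteration when
stimulation is enabled.  On no-load days with stimulation the coupled
system is still solved with the charge alone and its SED enters the
stimulus; without stimulation those days are pure disuse.  On load days
the charge and the tractions act together, so their strain fields
interfere (the cross term in the SED can locally outweigh the tiny
charge-only SED).  All three gait cases are applied on phase-2 load days,
mirroring phase 1.  The stimulation charge acts from the first phase-2
step.

With the printed sign of the charge term, a positive $q_N$ produces a
positive potential near the charged arc (the literature this model follows
reports the same magnitude with negative sign, i.e. the opposite
charge-term convention); the run trace records both potential extremes.

## Synthetic geometries

`generate_bar_mesh()` builds structured vertical bars (poling axis along
the length) used by every analytic oracle: uniaxial stress states, the
open-circuit piezoelectric bar
($\varphi_{tip} = (e_{33}/\beta_{33})\,\varepsilon L$, $\approx 1.762$ V
at $\varepsilon = 10^{-3}$, $L = 100$ mm), patch tests, cantilever
refinement, Betti reciprocity.

`generate_femur2d()` builds a stylised proximal-femur-like contour: a
shaft whose medullary gap is closed by a separate `SIDE_PLATE` region
(joined to the femur only along the lateral P--R and medial Q--S node
chains, thickness 0.1 mm vs 1 mm, non-remodelling, electrically passive
with vacuum-scale permittivity so the potential problem stays well-posed),
a metaphyseal flare, a trochanter bump, and a circular femoral head capped
by the head arc.  The two published landmark distances are generator
constraints satisfied exactly: $|PQ| = 66.59$ mm and $|RS| = 34.10$ mm.
The grid is a Coons patch between the resection plane, the head arc and
height-parametrised lateral/medial contour splines; the region above the
shaft is untangled by Laplacian smoothing of the interior grid (boundaries
and the P--Q interface row held fixed), and each structured quad is split
along the diagonal that maximises the minimum triangle area.  The
generator is fully deterministic; regeneration is bit-identical.  Load
segments subtend a fixed 60° of the 120° head arc by default
(config-overridable), since no footprint is published.

What the stand-in does *not* emulate: the CT-derived contour, cortical
thickness variation, any anatomical detail beyond the two published
dimensions, and the real structure's load-spreading.  Its arcs are shorter
and its domain smaller than a real proximal femur, so the Table-2 gait
loads drive most of the section towards the cortical bound during phase 1
(average density near 1.73 g/cm$^3$ by day 300 at default resolution
(1948 elements; 1416 femur, 532 side-plate), computed by the acceptance
script).  Tests on this fixture therefore assert *invariants* — bounds,
finiteness, determinism, Euler convergence, energy identities — not
density-map realism; the published density maps, the 176-point RMS of
0.218 g/cm$^3$ and the −45 V figure depend on the unpublished CT geometry
and node selections and are not reproducible from a stand-in.

## Verification strategy

* Closed forms: bar equilibrium density, open-circuit tip potential,
  uniaxial SED, Clapeyron's theorem (total strain energy = half external
  work to 1e-8).
* Exactness: patch tests to 1e-10 (heterogeneous density with every node
  prescribed — with interior nodes a constant-strain field is no longer
  the FEM solution when the modulus varies elementwise — and uniform
  density with interior nodes).
* Independent oracles: dense energy-based element/global assembly,
  fine-step integration of the exact remodelling ODE, 3-D tensor
  contraction for the plane reduction, loop recomputation of the
  validation metrics.
* Structure: coupling-block transpose relation assembled through two
  independent routes (mechanical and electric weak forms), discrete Betti
  reciprocity $f\cdot u(q) = -q\cdot\varphi(f)$, node-renumbering
  invariance, bit-identical reruns.

One stated property is knowingly not met and the corresponding test is
left failing rather than weakened: from $\rho_0 = 1.4$ g/cm$^3$ the bar
cannot reach the $10^{-3}$ band around $\rho^*$ by day 300 — the exact
rate law itself (independent `deSolve` integration) only reaches
$\approx 0.7511$ by then, because disuse resorption is capped near
$B\,S_r = 0.004$ g/(cm$^3$·day); the FEM trajectory matches the exact
dynamics to $4\times10^{-5}$.  About 600 days are needed, and the
opposite-extremes sweep test uses that horizon.

The electrically driven deposition mechanism is tested in a clean window:
no mechanical loads, `mechanical_only` stimulus, and an amplified charge
($2\times10^{-4}$ C/mm$^2$) so the effect rises above the floating-point
noise of two separately solved trajectories.  There the density difference
is strictly nonnegative and concentrated at the charged arc.  At the
physiological charge the effect on density is far below $10^{-6}$
g/cm$^3$ — consistent with the very small stimulation-induced differences
this model class reports — and the test asserts exactly that.

## Degenerate inputs and tie-breaks

Zero-area triangles raise a degenerate-element error; clockwise triangles
are repaired on read with a warning.  Boundary chains reconstructed from
loose MSH line elements start at the smallest-id endpoint (deterministic).
Negative Hounsfield units clamp to zero ash density before conversion
(config-overridable); apparent densities above $\rho_b$ are reported as-is
in validation, which compares measurements rather than simulation state.
Validation sampling uses the containing element's constant density, not
nodal interpolation.  Duplicate-coordinate detection is per region because
the side-plate intentionally overlays the shaft in-plane.

## Problem sizes

Default test and acceptance sizes, chosen as the package's own working
scale: bar oracles use 32--80 element bars over 300 days at
$\Delta t = 0.1$; the femur runs use the default-resolution fixture
(1948 elements) for 300 days at $\Delta t = 0.1$, plus a 100-day coupled
continuation with and without stimulation; the cantilever refinement pair
uses 1152 vs 4608 elements.

## Known limitations

2-D plane strain only; no surface (external) remodelling; no streaming
potential or poroelastic fluid flow; isotropic elasticity; explicit Euler
(first-order, conditionally stable); the stylised femur is a topological
stand-in, not an anatomical model; the inverse-piezoelectric effect on
density at physiological charge is orders of magnitude below the density
scale, so therapeutic-stimulation conclusions from this model rest on the
potential fields, not on density shifts.
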