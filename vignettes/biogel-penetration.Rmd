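---
title: "Modelling particle penetration into bio-gels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling particle penetration into bio-gels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelpen)
```

## The physical picture

Mucus layers, biofilm matrices and similar bio-gels are polymer networks
holding 90–99% liquid. Whether a particle — a drug carrier, a virus, a
pollutant — gets through such a gel is, to first order, a competition
between the particle's size and the spacing of the network's chains, and,
when the particle is pushed, between the applied force and the entropic
elasticity and bond strengths of those chains. `gelpen` implements a
microscopically motivated, entropy-based description of both regimes.

Each chain between two cross-links is treated as a freely jointed chain
of `n` rigid units of length `l`. Swelling by a volumetric factor `J`
dilates the random-walk end-to-end distance to
\(R = J^{1/3}\sqrt{n}\,l\). A chain stretched by \(\lambda\) relative to
\(R\) carries the entropic tension
\(f l / k_b T = \beta(\lambda\kappa)\), where
\(\kappa = J^{1/3}/\sqrt{n}\) and \(\beta\) is the inverse Langevin
function, evaluated with the rational approximant
\(\beta(x) = x(3-x^2)/(1-x^2)\). The approximant — not an exact numeric
inversion — is part of the model definition here; the exact inversion
exists in the test suite as an oracle and agrees within 5% over
\(x \in [0, 0.9]\).

Key modelling assumptions, inherited throughout the package: penetration
is quasi-static (no viscoelasticity, no rate effects); the particle is
rigid; its influence is local (only the 4 contact chains and their 12
nearest neighbours respond, and particle concentrations are dilute); and
particle–gel chemistry (mucoadhesion, charge) is outside the model.

## Spontaneous penetration and gel characterization

A sphere of diameter \(2\rho\) meeting a locally `m`-coordinated mesh
passes without force iff \(R > 2\rho\tan(\pi/m)\) — strict inequality,
with a \(10^{-9}\) relative guard so that exact-boundary inputs land on
the "no" side rather than being decided by floating-point error in
\(\tan(\pi/m)\). For an ellipsoid (semi-axes \(\rho,\rho,\xi\rho\))
entering through its short axis on a quadrilateral mesh, the long axis
must clear the cell: \(R > 2\xi\rho\).

`characterize_gels()` inverts this: from the average diameter of
particles observed to penetrate a gel spontaneously it computes
\(R = \bar d \tan(\pi/m)\) for each assumed coordination (`m = 3`
triangular, `m = 4` quadrilateral), reports `R` to two significant
figures — the precision that particle-sizing data supports — and derives
\(n = (R_{rep}/(J^{1/3} l))^2\), rounded to the nearest integer, **from
the reported (rounded) `R`**. Deriving `n` from the unrounded `R` would
pretend to more precision than the input has, and the reported/derived
pair would be mutually inconsistent for a reader who recomputes one from
the other. The rounding order matters at the unit level in `n` and was
fixed by that consistency argument.

Defaults for the bundled mucus observations: liquid content
`cl = 0.95` and repeat-unit length `l = 18` nm, the midpoint of the
16–20 nm range reported for mucin. `R` itself is independent of `l`, so
only `n` is sensitive to this choice. For the two biofilm rows only
ranges are available (`cl` 87–99%, `l` 0.07–1.5 nm); range cells resolve
to their midpoint by default, which makes the biofilm `R` values solid
(they depend only on the diameters) but the biofilm `n` values
indicative only — published repeat-unit counts for these systems imply
unstated point values near \(J^{1/3} l \approx 1.2\) nm, so the package
does not claim to reproduce them. One further convention: a triangular
reading of the finest biofilm data can produce `R` below one swollen
repeat unit; `n` is then clamped to 1 with a `sub_monomer` warning rather
than reported as 0.

## Forced penetration

When the particle does not fit, pushing it in stretches the 4 contact
chains. Tangency of the deformed cell (side \(\lambda R\)) to the
particle's cross-section at the network plane gives the sink relation

\[ y/\rho = 1 - \sqrt{1 - \lambda^2\eta^2}, \qquad
   \eta = \frac{R}{\rho\sqrt{2(\xi^2+1)}}, \]

so full penetration occurs at \(\lambda = 1/\eta\). The test suite
verifies this relation to \(10^{-10}\) against an explicit tangency
construction (tangent square for spheres; for ellipsoids, a numeric
solve of the tangent-line condition for the rhombus of vertex angle
\(\gamma = 2\arctan(1/\xi)\) against the in-plane ellipse).

Neighbouring chains rotate, without stretching, into trapezoids of base
angle \(\alpha = \arccos((\lambda-1)/2)\): 90° at rest, 0° at the
collapse stretch \(\lambda = 3\). Beyond collapse, rotation is exhausted
and the 12 neighbour chains must stretch. Three choices here were
genuinely open and are worth recording:

* **Neighbour stretch after collapse.** Only the *fact* that 12 chains
  stretch is given by the geometry. We impose series compatibility on the
  collapsed trapezoid — the near side \(\lambda R\) equals the far side
  plus two legs, all three stretching equally — which gives
  \(\lambda_{nb} = \lambda/3\), continuous (\(\lambda_{nb}=1\)) at
  \(\lambda = 3\). Any alternative sharing rule would either break
  continuity or require information the model does not carry.
* **Averaging denominator.** The reported average chain force divides by
  all 16 local chains in both regimes:
  \(\langle f \rangle = [4\beta(\kappa\lambda) +
  12\beta(\kappa\lambda_{nb})]/16\). Pre-collapse the neighbours sit at
  the constant reference tension \(\beta(\kappa)\), so only the contact
  chains contribute \(\lambda\)-dependence — and at \(\lambda=3\) the
  slope jumps *up* by \((12/16)(\kappa/3)\beta'(\kappa)\), the stiffening
  kink. Dividing by the number of *stretching* chains instead would
  produce a downward discontinuity at collapse, which is unphysical for a
  quasi-static process.
* **Reference baseline.** Whether published force–sink curves subtract
  the reference-state tension \(\beta(\kappa)\) is not decidable from
  their axes; rather than guess, `average_chain_force()` and
  `simulate_penetration()` expose `subtract_reference` (default `FALSE`).

Cross-links feel the vector sum of the four adjoining tensions. With the
two stretched chains at vertex angle \(\gamma\) (tension
\(f=\beta(\kappa\lambda)\)) and each adjacent trapezoid leg (tension
\(f_{leg}\): \(\beta(\kappa)\) pre-collapse, \(\beta(\kappa\lambda/3)\)
after) pulling \(\cos\alpha\) along its own chain axis and \(-\sin\alpha\)
along the other, the resultants close to

\[ f^{CL}_1 = 2\cos(\gamma/2)\,\big|f + f_{leg}(\cos\alpha-\sin\alpha)\big|,
   \qquad f^{CL}_2 = 2\sin(\gamma/2)\,\big|\cdot\big|, \]

so \(f^{CL}_1/f^{CL}_2 = \cot(\gamma/2) = \xi\) identically, both vanish
in the reference state (the equilibrium check that validates the vector
construction), and a sphere gives
\(\sqrt2\,|f + f_{leg}(\cos\alpha-\sin\alpha)|\) at every vertex. The
closed forms are tested to \(10^{-10}\) against an explicit 2-D vector
summation. Because the elongated particle concentrates load
(\(2\cos(\gamma/2) > \sqrt2\) for \(\xi>1\)), cross-link 1 of an
ellipsoid is loaded harder than a sphere's cross-link at every common
state — by the constant factor 1.34 at \(\xi = 3\).

**Damage.** A chain ruptures when \(f > f_{rup}\); a cross-link
dissociates when \(f^{CL}_1 > f_{dis}\) (site 1 is always critical). If
both thresholds are crossed in the same sweep step, the larger *relative*
exceedance wins; an exact tie goes to cross-link dissociation, the more
probable mechanism in physically cross-linked gels such as mucin, and the
tie-break is configurable for covalently cross-linked systems. Thresholds
are dimensionless (\(f l/k_b T\)) and `Inf` disables a mechanism.

**The sweep.** `simulate_penetration()` marches \(\lambda\) uniformly
(default 400 steps) from 1 to \(\min(1/\eta,\ \lambda_{max}(1-10^{-6}))\),
where \(\lambda_{max} = 1/\kappa\) is the extensibility limit; the
\(10^{-6}\) guard keeps the last state off the entropic singularity, and
stretches within \(10^{-9}\) of full extension raise an error anywhere in
the package. A uniform \(\lambda\) grid (rather than uniform sink) keeps
force increments smooth through the collapse kink. The sweep is
deterministic; it stops at the first damage event. Outcomes partition as:
\(\eta \ge 1\) spontaneous (empty trajectory); damage event; elastic
penetration on reaching \(\lambda = 1/\eta\); otherwise jammed
(extensibility exhausted, no damage — only possible for large \(\kappa\),
since any finite threshold is crossed before the singularity). The
boundary case \(\eta = 1/3\) is exact: penetration completes at the
collapse stretch, so no stiffened state is ever visited, while
\(\eta < 1/3\) produces stiffened states before penetration.

## The synthetic-data generator

`generate_fixtures()` emulates the *inputs* of the characterization
pipeline: observation tables whose rows are built around a drawn true
mesh size (3–1000 nm, log-uniform, spanning biofilm-fine to mucus-coarse),
liquid contents 85–99%, repeat units 20–100× below the mesh, with
particle diameters placed deliberately on either side of the fit
criterion, plus forced-penetration configurations covering the regime
corners (\(\eta\) near 1, \(\eta < 1/3\), \(\kappa\) near the
extensibility limit, a finite dissociation threshold). It is seeded and
byte-reproducible. What it does *not* emulate: measurement noise and
size polydispersity, gel heterogeneity and anisotropy, and
particle–chain chemistry. Passing tests on these fixtures therefore
demonstrate internal consistency of the pipeline, not agreement with any
particular real gel; agreement with real data is exercised separately by
the bundled literature table.

## Numerical conventions and problem sizes

Angles are degrees at every interface and radians internally. Forces are
dimensionless throughout; `force_si()` converts with
\(k_b = 1.380649\times10^{-23}\) J/K at a default 310 K. Algebraic
inverses (liquid content ↔ swelling, sink ↔ stretch, angle ↔ stretch)
round-trip to \(10^{-10}\)–\(10^{-12}\) and are tested at that level.
The test suite runs its oracle comparisons on grids of a few hundred
points (e.g. 13 stretches × 3 aspect ratios × 3 extensibilities for the
vector-sum check; 400-step sweeps for trajectory properties), which keeps
the full suite under a few seconds on one CPU while covering every branch
of the regime classification.

## Known limitations

* Quasi-static only: no viscoelastic relaxation, loading-rate or
  frequency dependence — a real cough is not quasi-static.
* The forced-penetration lattice is locally quadrilateral; triangular
  forced penetration is not modelled (the spontaneous criterion covers
  both coordinations).
* Ellipsoids enter through the short axis with the long axis along the
  cell diagonal; other orientations change the kinematics qualitatively
  and are not implemented.
* The bulk resistance of the network and the constitutive link from
  chain forces to the external force on the particle are deliberately
  not modelled; the package reports chain-level and cross-link-level
  forces, which is where the damage criteria live.
* Initial sink is defined by the \(\lambda = 1\) state of the sink
  relation; a weight-balance initial condition would need the bulk model
  above.
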