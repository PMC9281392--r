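---
title: "Molecular dynamics with the symmetry group as an input"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecular dynamics with the symmetry group as an input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symdyn)
```

## The model

Ordinary molecular dynamics essentially never visits configurations with
crystallographic point-group symmetry: symmetric arrangements form a
measure-zero subset of phase space. `symdyn` turns the symmetry group into a
*constraint* of the dynamics instead of hoping for it as an outcome.

A configuration of $N$ particles is symmetric under a wallpaper or space
group $G$ when applying any group element to all particles reproduces the
same point set. If that holds at $t = 0$ (and no particle is accidentally
fixed by a non-identity element), the particles partition into $N/|G| = n$
group orbits, and the full configuration is a deterministic function of one
representative per orbit — the *asymmetric unit*. Keeping the symmetry at
all times is a holonomic constraint, and the asymmetric-unit coordinates are
exactly the generalized coordinates of the constrained system. So the
integrator advances only the $n$ asymmetric-unit particles; the remaining
$N - n$ symmetry mates, and all lattice images, are *ghost particles*:
re-derived from the asymmetric unit through the group's affine operators in
fractional coordinates immediately before every force evaluation, and never
integrated.

Because the Lennard-Jones potential is invariant under rotations, mirrors
and permutations, the forces are group-equivariant: the force a ghost would
feel is the transformed force of its representative. The per-cell potential
can therefore be computed with an outer loop over the asymmetric unit only,
weighting each particle by its orbit multiplicity,
$$U_\text{cell} = \tfrac12 \sum_{i \in \text{asym}} w_i \sum_{j \ne i} u(r_{ij}),$$
where $j$ runs over every explicit particle (orbit mates, lattice images,
and the particle's own images — the last matter once the cell shrinks below
the cutoff). For a symmetric configuration with a sufficient image shell
this equals the brute-force sum over all unit-cell pairs plus half of every
cell–image interaction; the equality is tested to $10^{-10}$ for all 17
wallpaper groups, and the constrained trajectory is tested to agree with an
unconstrained full-cell trajectory from the same symmetric start to
$10^{-8}$ over 100 steps — the central correctness property of the method.

## Group data

All 17 wallpaper groups and space groups 1, 2 and 127 ship as plain-text
operator tables (`inst/extdata/groups/`): generator triplets in the standard
coordinate notation (`"-y, x-y"`), the tabulated general-position
multiplicity, the Bravais class, and Wyckoff sites as coordinate
expressions (`"x, 0"`). At load time the element list is generated as the
closure of the generators and validated against the tabulated multiplicity,
so a transcription error in a generator cannot load silently. Centred
groups (cm, cmm) include the centring translation as a group element and
use the conventional rectangular cell.

Two derived objects are computed from the tables rather than transcribed:

* **The asymmetric-unit region.** A wrapped fractional point is taken to be
  in the fundamental domain iff it is the lexicographically smallest member
  of its own orbit. This is a valid fundamental domain for any group, with
  no per-group inequality tables to get wrong, and sampling is exact:
  draw uniformly in the cell and replace the point by its canonical orbit
  representative.
* **Wyckoff orbits.** A site is stored only as its projector $P$ (the
  idempotent affine map onto the site). The coset operators that generate
  the reduced orbit, the site multiplicity, and the stabilizer order are
  found at load time by applying every group element to a generic site
  point.

## Wyckoff constraints

A particle assigned to a Wyckoff site must satisfy
$\sigma(q) = q - Pq = 0$, with $P$ acting in fractional coordinates and the
residual mapped to Cartesian through the current box (so the constraint is
exact under constant-pressure box changes; the Jacobian is rebuilt whenever
the box moves). Because $\sigma$ is affine, the end-of-step Lagrange
multiplier is a single linear solve in the pseudo-inverted Gram matrix of
the constant Jacobian — exact in one iteration, no SHAKE-style loop. Two
details matter in practice:

* the fractional residual is wrapped to the nearest integer, so the
  constraint targets the nearest lattice copy of the site and commutes with
  cell wrapping (the correction can legitimately land on the far cell face,
  fractional coordinate exactly 1, and is re-wrapped);
* after each position correction and each velocity update, the velocity
  component normal to the site is removed, so constrained particles do not
  accumulate kinetic energy in directions they cannot move. The
  temperature uses $\mathrm{dof} = D\,n - \sum_c \mathrm{removed}_c$.

## Integration and ghost refresh

NVE uses velocity Verlet; NVT uses the BAOAB Langevin splitting with O-step
decay $e^{-\gamma\,\Delta t}$ and noise scale
$\sqrt{T(1 - e^{-2\gamma \Delta t})/m}$; with $\gamma = 0$ BAOAB reduces to
velocity Verlet exactly. Defaults are $\Delta t = 0.005\,\tau$ and
$\gamma = 0.1$ in reduced Lennard-Jones units
($\tau = \sqrt{m\sigma^2/\varepsilon}$). Ghost positions are re-derived
before every force evaluation; asymmetric-unit positions are wrapped back
into the root cell after every position update, which keeps the
self-exclusion bookkeeping of the pair loop exact.

Two numerical choices deserve a note:

* **Cut-and-shift.** The pair potential is truncated at $r_c = 3.5\,\sigma$
  (no tail correction) and, by default, shifted by $u(r_c)$ so the energy is
  continuous at the cutoff. The shift changes no force and no trajectory;
  without it, every pair crossing the cutoff steps the bookkept energy by
  $|u(r_c)| \approx 2.2\times10^{-3}\varepsilon$ (times the orbit weight),
  and those jumps — not the integrator — dominate any conservation
  measurement. `lj_params(shift = FALSE)` restores the bare form.
* **What "drift" means.** A symplectic integrator's energy error at
  $\Delta t = 0.005$ contains a bounded, reversible oscillation of order
  $(\omega\,\Delta t)^2$ that peaks during close encounters; it is visible
  in the instantaneous trace but reverts after each encounter. The
  conservation figure of merit is therefore the *secular* drift: the
  least-squares linear trend of the total energy across the run,
  normalized by $\max(|E_0|, KE_0)$ — the total energy alone can sit
  arbitrarily close to zero by kinetic/potential cancellation at gas-like
  densities. `run_conservation()` reports both the secular drift and the
  maximum instantaneous excursion. At the standard conditions
  ($\rho = 0.2$, $T_0 = 0.5$, 5000 steps) the secular drift is of order
  $10^{-4}$ for all tested groups.

Starting configurations are rejection-sampled in the fundamental domain
with a minimum Cartesian pair separation of $1.0\,\sigma$ after expansion
(pair energies at or below zero), so a start is thermally consistent with
its target temperature rather than beginning partway up the repulsive wall.

## Constant pressure on a Bravais class

A space group tiles space only if the cell belongs to its Bravais class, so
box moves live in an unconstrained "working" box $B'$ that is pushed
through a class projector before use: cubic boxes become $a\,I$ with $a$
the mean of the three vector lengths, tetragonal boxes keep $a = b$, 2D
hexagonal boxes keep $|v_1| = |v_2|$ at $120^\circ$, and so on. Averaging
the constrained-equal quantities makes the projector continuous and
idempotent. Pressure enters only through the Metropolis rule for box
moves — no virial is ever computed, since a virial over the asymmetric unit
alone is not meaningful. Proposals are symmetric in $\ln V$ (plus one
log-scaled free lattice parameter for classes with more than one, plus an
additive shear step for oblique/triclinic), and acceptance uses
$$\min\{1, \exp(-[\Delta U + P\,\Delta V - (N{+}1)\,T \ln(V'/V)]/T)\},$$
the standard pairing for $\ln V$ proposals, under which the sampled density
satisfies $\langle N/V \rangle = P/T$ exactly for an ideal gas — the
package's analytic end-to-end check (it passes within 3 standard errors).

Periodic wrapping plays no dynamical role under NPT: all interactions go
through the explicit image shell (default radius 2, i.e. $3^{2D}$ images),
whose radius adapts automatically if the cell shrinks below what the cutoff
requires. Two guards keep the shell finite: the adaptive radius floors at
the configured value instead of ratcheting upward permanently, and
proposals whose cell would have a face-to-face height below
$0.4\,V^{1/D}$ are rejected — nothing in the ensemble penalises
near-degenerate *representations* of the same lattice, so an unclamped
shear performs a random walk toward cells needing unboundedly many images.
The clamp does not touch the volume marginal.

## The structure screen

`run_atlas_job()` reproduces the three-stage metastability screen at
configurable scale: (1) constrained NPT compression at $P = 0.25$,
$T = 0.1$; (2) constrained NVT equilibration at $T = 0.05$ — the result is
the proposed crystal for that group; (3) the cell is expanded, every
particle becomes real, the box is frozen, and 5000 unconstrained NVE steps
track the RMSD from the stage-3 start. A flat trace marks the structure
metastable; statuses are `diverged` (any stage blew up), `low_density`
(NPT ended at number density $\le 0.5$), `unstable` (RMSD rise
$> 0.5\,\sigma$), else `stable`.

Choices made where the protocol was open:

* RMSD uses nearest-image displacements in the frozen stage-3 box and no
  rotational fitting. The expanded cell's net momentum is zeroed once at
  stage-3 start (standard before NVE production); without this the trace
  measures centre-of-mass drift of order $\sqrt{T/N}\,t$ and classifies
  even a perfect crystal as unstable.
* The four cell sizes per group are $\{1,2,3,4\}\times|G|$ general
  positions, plus one job per bundled Wyckoff site; the enumeration is the
  package's own.
* Default reduced stage lengths are 50k/10k/5k steps (the last matching the
  screen's published length; the first two are 1/20 and 1/10 scale,
  overridable to full scale from the command line). The default starting
  density is 0.4 — below any plausible crystal density, and comfortably
  above the screen's 0.5 low-density failure threshold after compression.
* Hexagonal order is quantified by the bond-orientational parameter
  $\psi_6$ over nearest neighbours (with periodic images): 1 for a perfect
  triangular lattice, $\approx 0$ for square packing, small for a fluid.
  At reduced scale the symmetry-free (p1) job relaxes to $\psi_6 > 0.95$.

## What the tests do and do not show

The test fixtures are generated by the package itself (random symmetric
gases, ideal gases, small crystals), so passing tests demonstrate the
*mechanics* — orbit algebra, constraint exactness, oracle equivalence,
ensemble sanity — at desk scale. They do not reproduce the full
258-structure screen, million-step NPT relaxations, or any claim about
which wallpaper groups possess metastable Lennard-Jones crystals beyond the
p1 hexagonal case; runs at those scales use the same code paths but longer
schedules. Known limitations: a single Lennard-Jones species only; brute-
force pair loops (no neighbour lists), appropriate for desk-scale cells;
net linear momentum of the *constrained* dynamics is reported, not
corrected; and the 3D group library is a small named subset, not the full
230.
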