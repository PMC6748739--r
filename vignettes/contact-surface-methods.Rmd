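---
title: "Direct contact surface areas by occluder-group sampling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Direct contact surface areas by occluder-group sampling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactarea)
```

## The model

Every atom $A$ is represented by its solvent-expanded sphere of radius
$R_A = r_A + r_p$, where $r_A$ is the van der Waals radius and $r_p$ the
probe radius (1.4 Å by default, the effective radius of a water
molecule). A fixed lattice of $N$ near-equidistant unit directions is
scaled onto each expanded sphere; each point represents the same solid
angle $4\pi/N$, hence an area $(4\pi/N)R_A^2$ on atom $A$.

The classical Shrake–Rupley estimate discards every point that falls
inside a neighbouring expanded sphere and reports the remaining area as
SASA. This package keeps the buried points and records, for each one, the
*occluder group*: the exact set of neighbouring atoms whose expanded
spheres contain it. A point may be inside several neighbours at once, and
that is precisely the information the ΔSASA approximation throws away.
From the table of distinct groups and their point counts everything else
follows:

* $\mathrm{SASA}(A)$ — accessible points × point area;
* $\mathrm{CSA}(A,B) = \sum_{G \ni B} \frac{n_G}{|G|}\,\frac{4\pi}{N}R_A^2$
  — every group patch is divided evenly among its members, so surface
  shared by several occluders is attributed fractionally and never
  double-counted;
* $\mathrm{BSA}$ — column sums of the contact matrix over a selection
  (for intermolecular runs, the partner object's atoms);
* the ΔSASA approximation (`delta_sasa_csa()`) — SASA of each object in
  isolation minus its SASA in the complex, for comparison with the direct
  calculation.

Because each buried point contributes weight exactly 1 split across its
group, the counting identity
$\mathrm{SASA}(A) + \sum_B \mathrm{CSA}(A,B) = \frac{4\pi}{N} R_A^2 \cdot N$
holds *exactly* in point arithmetic; the test suite checks it at relative
tolerance $10^{-9}$, which only allows for floating-point summation error.

The contact matrix is asymmetric by construction: row $A$ measures area on
$A$'s expanded sphere, and the two atoms of a pair have different radii
and different crowding. Residue-level matrices are exact block sums of the
atom-level matrix, so totals are preserved to machine precision.

### Modes of operation

* **Mode 0** — SASA only.
* **Mode 1** — intermolecular matrices under *all-atom* occlusion: a point
  of atom $A$ buried by both a same-object neighbour and a partner atom
  splits its weight between them. This keeps the conservation identity
  intact and reads the interface the way a solvent probe would see it.
* **Modes 2/3** — intramolecular residue/atom contact maps (all-atom
  occlusion, no object mask).
* **Mode 4** — *cross-object-only* occlusion: each object's points are
  classified against the other objects' atoms only, so a contact surface
  is counted whether or not it is solvent accessible. For a ligand at the
  bottom of a deep cavity, mode 1 attributes part of the pocket's surface
  to the pocket's own atoms, while mode 4 credits the full patch to the
  ligand.

The distinction matters exactly where atoms of one object shield each
other above the partner's surface. On the shipped buried-cage system
(`make_buried_cage()`) the mode-4 ligand contact total is ~2.7× the
mode-1 total — both are reported by `scripts/acceptance.R`. Which scope
the intermolecular BSA column sums should use was an open design choice;
this package sums over the partner object's columns of whichever matrix
the mode produced, so mode-1 BSA is the solvent-consistent reading and
mode-4 BSA the cavity-tolerant one.

## Parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| probe radius | 1.4 | Å | effective water radius; configurable (`--probe`) |
| lattice points $N$ | 2000 | – | two-sphere CSA within 1% of the analytic cap (see below); ~0.057 Å² per point on a typical heavy atom |
| PDB radii | united-atom, NACCESS-style | Å | hydrogens implicit; trigonal C 1.76, tetrahedral C 1.87, N 1.65, O 1.40, S 1.85 |
| Mol2 radii | SYBYL-typed, Chimera-style | Å | fine-grained typing for small molecules; hydrogens explicit |
| waters | excluded | – | solvent is modelled by the probe, not by crystallographic waters |
| hydrogens | dropped for PDB, kept for Mol2 | – | matches the radius-table conventions |

Both radius tables ship as versioned plain-text files
(`inst/extdata/radii/`) and can be replaced wholesale via
`radii_table(path = ...)` or `--radii`. The numeric values are transcribed
from the published united-atom and SYBYL-typed sets the tables are named
after; unknown keys fall back first to an element-level entry, then to a
global 1.70 Å fallback with a warning.

## Numerical choices

* **Lattice.** Golden-section (Fibonacci) spiral: deterministic, any
  count, no RNG, nearest-neighbour chord ratio measured ≤ 1.15 for all
  tested counts (the suite asserts ≤ 2). The spiral's height ladder is
  mirror-symmetric about the equator, so caps cut perpendicular to the
  z axis are sampled with exactly balanced counts; the mirror-pair fixture
  exploits this and measures a CSA difference of exactly zero.
* **Burial tie-break.** A point at distance exactly equal to an occluder's
  expanded radius counts as buried (closed inequality) — stable and
  conservative. Exactly tangent spheres are *not* neighbours (strict pair
  cutoff), so tangency contributes zero contact, matching the analytic
  limit.
* **Neighbour search.** Uniform grid with cell edge twice the largest
  expanded radius; verified against an $O(n^2)$ brute-force oracle on
  random clusters. Exactly coincident centres are kept, with a warning,
  and occlude each other like any pair.
* **Alternate locations.** Highest occupancy wins, first record on ties;
  multi-model PDB files use model 1 with a warning.
* **Group identity.** Canonical keys are the sorted serial numbers of the
  occluders, making group tables and all downstream output deterministic;
  two identical invocations produce byte-identical TSV files.
* **TSV precision.** Four decimals — far below sampling granularity,
  keeps files diffable.

### What "1% of the analytic cap" can mean under point sampling

The only closed-form oracle for the engine is the two-sphere cap area.
At $N = 2000$ the lattice-versus-cap-boundary discrepancy is up to about
6 points regardless of cap size, so the *relative* error of a sampled cap
is bounded below by granularity: a 1% claim is testable only for caps of
at least ~600 points (≈ 30 Å² on a typical atom). The oracle grid in the
acceptance suite therefore uses substantial overlaps — five radii × three
radii × centre distances at 0.20/0.30/0.40 of the expanded-radii sum, 45
geometries, worst measured error 0.85% — while tangency and engulfment
are asserted exactly (zero and full-sphere area), and a separate property
test covers arbitrary random geometries with a granularity-scaled bound
(sampled CSA never exceeds the analytic cap by more than 6 point areas).
Shrinking granularity is also why the grid-worst error decreases with
$N$ over 250→4000, which the suite checks allowing 1.5× noise between
consecutive counts.

## The synthetic fixtures

All tests run on generated systems with analytically known properties —
no structure downloads:

* `make_two_spheres()` — the cap oracle;
* `make_fig1_triple()` — occluder groups {B}, {C}, {B,C} on one atom;
  CSA(A,B) must equal the {B} patch plus half the shared patch,
  recomputed from the raw group table;
* `make_mirror_pair()` — exact sampling symmetry;
* `make_crowding_pair()` — a collinear A···B–C arrangement in which C's
  surface facing A is already buried by B within the isolated dimer, so
  ΔSASA must fall strictly below the direct CSA total (measured: ~10%
  below on this three-atom system);
* `make_buried_cage()` — a fully buried ligand (SASA exactly 0) inside an
  icosahedral cage, separating mode-1 from mode-4 semantics;
* `make_random_cluster()` — seeded uniform clusters with radii drawn from
  the shipped united-atom table, for conservation, aggregation,
  determinism and neighbour-index properties.

These fixtures are geometric, not biochemical: they exercise every code
path and every counting identity of the engine, but they do not reproduce
the packing density, bonded geometry or chemical composition of real
macromolecules. Passing them demonstrates the correctness of the
algorithm and its bookkeeping, not biological insight; on real complexes
the *size* of the ΔSASA underestimate, for example, depends on interface
crowding and will differ from the three-atom fixture's ~10%.

Problem sizes used by the default suite and the acceptance script —
50-atom clusters at five seeds for conservation, 45 oracle geometries,
24–30-atom clusters for mode and aggregation identities — were chosen as
the smallest systems that exercise dense multi-atom occlusion; the whole
suite runs in well under a minute.

## Known limitations

* Sampled, not analytic, areas: accuracy is granularity-limited at
  $O(1/N)$ per patch; raise `--points` for tighter tolerances.
* United-atom PDB radii assume hydrogens are implicit; structures with
  explicit hydrogens should use `--include-hydrogens` with a matching
  custom table, or Mol2 input.
* Object auto-detection classifies by residue name only; exotic residues
  land in the ligand class and may need an explicit `--chains` selection.
* mmCIF and trajectory formats are out of scope; convert externally and
  feed one PDB per snapshot for batch use.
* Occupancy-weighted ensembles are not modelled: one altloc is kept per
  atom.
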