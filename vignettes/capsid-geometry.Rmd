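---
title: "Caspar–Klug lattices, split hexamers and the divisibility-by-three theorem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Caspar–Klug lattices, split hexamers and the divisibility-by-three theorem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsidlattice)
```

## The scientific question

Icosahedral capsids are built from pentamers and hexamers of a major
capsid protein (MCP). The 12 pentamers always sit on the global 5-fold
axes, but the 10 three-fold and 15 two-fold axes of the icosahedron may or
may not pass through a hexamer center, depending on the architecture. This
matters biologically: hexamers with full 6-fold symmetry are compatible
with any axis, but *split* hexamers — two half-hexamers separated by a
chasm along the hexamer's internal 2-fold line and bridged by an accessory
protein dimer — and the skewed hexamers of procapsids retain only 2-fold
symmetry. A 2-fold-symmetric hexamer centered on a global 3-fold axis
would be a symmetry mismatch, so the architectures that can use split/skew
hexamers *everywhere* are exactly those whose lattice places no hexamer on
a 3-fold axis.

The package constructs the Caspar–Klug lattice explicitly, classifies
every capsomer against the 31 global symmetry axes, and establishes:

> a hexamer is centered on a true 3-fold axis ⇔ 3 | T,

by two deliberately independent routes (exact integer lattice arithmetic,
and brute-force 3D geometry), for every distinct triangulation number up
to 300.

## Lattice arithmetic

A step `(h, k)` on the hexagonal lattice (basis vectors 60° apart) joins
two nearby pentamers; its triangulation number is `T = h² + hk + k²`. The
twelve point-group images of a step (six 60° rotations and their mirrors)
all describe the same architecture; `canonicalize_step()` picks the unique
image with `h ≥ k ≥ 0`. A chiral capsid and its enantiomer therefore share
one canonical step — surveys count architectures per `T`, not per
handedness, and `build_capsid(handedness =)` selects the mirror form
explicitly. A `T` realized by inequivalent steps (first at `T = 49`, by
`(7, 0)` and `(5, 3)`) is still one survey row.

When `3 | T` the face centroid is itself a lattice point, reached from a
pentamer by the sublattice steps

```
(hH, kH) = ((h − k)/3, (h + 2k)/3),
```

which are integers exactly when `h ≡ k (mod 3)`; an exhaustive check of
residues (run in the test suite over all canonical steps with `T ≤ 300`)
shows this congruence is equivalent to `3 | T`. The inverse transformation
implemented is

```
(h, k) = (2 hH + kH, kH − hH),
```

one of six symmetry-equivalent forms, chosen because it satisfies
`T(h, k) = 3 · T(hH, kH)` identically — direct algebraic expansion gives
`(2hH + kH)² + (2hH + kH)(kH − hH) + (kH − hH)² = 3(hH² + hH·kH + kH²)`.
A superficially simpler form that is sometimes quoted, `(hH + kH, kH − hH)`,
does *not* satisfy this identity unless `hH = 0` (for `(hH, kH) = (1, 1)` it
gives `T(2, 0) = 4` instead of `9`) and is therefore not used; the test
suite pins the implemented form against a 2D geometric oracle that locates
the face centroid in cartesian coordinates.

## Explicit 3D construction

`build_capsid()` uses a **faceted** embedding: the hexagonal net is laid on
the 20 flat faces of a regular icosahedron (vertices at normalized cyclic
permutations of `(0, ±1, ±φ)`, which puts 2-fold axes on the coordinate
axes). On flat faces all symmetry coincidences are exact up to floating
rounding, which is what makes a brute-force geometric oracle trustworthy;
spherical projection would only change rendering, not topology, and is
deliberately omitted.

Face membership of a lattice point is decided in exact integer arithmetic:
in a face whose corners are pentamers, the point `(i, j)` has scaled
barycentric coordinates `pa = i(h + k) + jk` and `pb = jh − ik`, integers
between 0 and `T`. Sites shared between faces are deduplicated by an exact
combinatorial key — the vertex index for corners, or (icosahedron edge,
reduced fraction along that edge) for edge sites — so no distance
tolerance enters the construction at any `T`. The same integer coordinates
drive `facet_mesh()`, which triangulates each face by incremental point
insertion with exact orientation tests and glues faces through the shared
keys into a closed, outward-wound 2-manifold (Euler characteristic 2,
`20T` triangles).

## Two classification routes

`classify_sites()` assigns each capsomer the highest-order global axis
within `tol × radius` of its center:

* **geometric route** — point-to-axis distances against all 31 axes,
  computed from the perpendicular component `p − (p·u)u` (the
  difference-of-squares form loses ~6 digits to cancellation at this
  radius and is avoided);
* **exact lattice route** — recorded at construction: vertex corner
  (pentamer, 5-fold), face centroid (`pa = pb = T/3`, exists iff
  `h ≡ k mod 3`), edge midpoint (fraction 1/2, exists iff `h` and `k` are
  both even).

The two routes must agree site by site; the test suite treats any
disagreement as a failure, not a warning, since their agreement *is* the
verification of the theorem. With the default `tol = 1e-6` (relative to
the radius) the separation is comfortable: genuine on-axis sites land
within `10⁻¹²` of an axis, off-axis sites no closer than `10⁻²` of the
radius for all `T ≤ 300`.

Orbit sizes pin the counts: hexamers on 3-fold axes number exactly 20
(10 axes × 2 antipodal face piercings) when `3 | T`, else 0; hexamers on
2-fold axes number exactly 30 (one per edge) when `h` and `k` are both
even, else 0; all remaining hexamer counts are multiples of the free orbit
size 60. The survey reports the exact global-axis count (20); hexamers at
local quasi-3-fold positions are not classified — the package decides
compatibility against *global* symmetry only, and does not attempt to
construct a consistent orientation field for the 2-fold hexamer tiles.

## Stoichiometry and packing

`protein_census()` implements `60T` MCPs in 12 pentamers and `10(T − 1)`
hexamers. With `portal = TRUE` one pentameric vertex is replaced by the
portal complex, removing five MCPs (`60T − 5`; 415 for `T = 7`) — the
portal itself is counted as one unit, not as MCPs, matching the standard
tailed-phage architecture. Accessory-protein stoichiometry is a parameter
(copies per hexamer) rather than a per-phage constant; 2 per hexamer
models the chasm-bridging dimer of split-hexamer capsids. Genome density
uses a spherical interior of the stated internal diameter — no better
shape information is available at this level of description — so the
density ratio of two capsids with equal diameters reduces to their
genome-length ratio (for 70.5 vs 64.5 kb at 63 nm: +9.30 %).

Minor-protein trimer accounting is out of scope: no counting rule derives
those copy numbers from `T` alone.

## Parameters, defaults, and degenerate inputs

| parameter | default | meaning |
|---|---|---|
| `radius` | 300 (length units; Å in PDB output) | centroid-to-vertex distance; 300 ≈ a 60 nm capsid, the tailed-phage scale |
| `handedness` | `"laevo"` | `(h, k)` counted counter-clockwise seen from outside; `"dextro"` is the mirror through `x = 0` |
| `tol` | `1e-6` | relative on-axis tolerance, see above |
| `accessory_per_hexamer` | 0 (2 for split-hexamer capsids) | accessory protein copies per hexamer |

Degenerate and invalid inputs are rejected with classed conditions: the
zero step `(0, 0)`, non-T integers (2, 5, 6, …) in `protein_census()` and
`predict_centered_hexamer()`, `centroid_steps()` on `3 ∤ T`, non-positive
tolerances, radii, genome lengths and diameters. `T = 1` (no hexamers) is
a valid capsid: it appears in survey tables but is excluded from both the
centered and the all-skew summary counts, which is why the `T ≤ 52` survey
reads "8 of 20" and "12 of 20" over the 20 hexamer-bearing architectures.

## Problem sizes and limitations

The survey and theorem verification default to desk scale: `T ≤ 52`
(21 architectures, under a second) for the survey reproduced in the
README, and `T ≤ 300` (93 architectures, a few seconds) for the
brute-force theorem check in the test suite — the bound at which the
per-capsid site count (`10T + 2`) still keeps the full 60-rotation
invariance checks cheap. `facet_mesh()` is quadratic per face in the
number of lattice points and is intended for rendering-sized `T` (tens),
not for the survey bound.

What the in-silico verification does **not** show: it says nothing about
protein chemistry — whether a particular MCP can actually adopt the split
conformation, or whether an accessory protein exists to stabilize it —
only about which architectures are symmetry-compatible with all-2-fold
hexamers. Capsids are treated as strictly isometric icosahedra; prolate or
otherwise elongated shells have no `(h, k)` description here, and deposited
experimental structures are neither downloaded nor parsed.
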