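# capsidlattice

Tools for the geometry of icosahedral virus capsids built on the
Caspar–Klug construction: which capsid architectures *must* contain a
hexamer sitting on a global 3-fold symmetry axis, and which can instead be
built entirely from split or skew hexamers — hexamers that retain only
2-fold symmetry, as in tailed-phage procapsids and in mature capsids whose
hexamer halves are bridged by an accessory ("cement") protein across a
2-fold chasm.

The package is aimed at structural virologists and phage biologists who
want to reason about capsomer symmetry, protein stoichiometry and genome
packing without touching cryo-EM data: everything here is exact lattice
arithmetic and explicit 3D geometry.

## The mathematics in brief

An icosahedral capsid is classified by its triangulation number

> T(h, k) = h² + hk + k²,

where (h, k) are the integer steps on a hexagonal lattice joining two
nearby pentamers. A T-capsid contains 60T major capsid proteins (MCPs) in
12 pentamers (at the icosahedron vertices) and 10(T − 1) hexamers. The
central result the package implements and verifies by brute force:

> **A capsid has a hexamer centered on a true (global) 3-fold axis if and
> only if T is a multiple of three.** Equivalently, a capsid can be formed
> with all split/skew (2-fold) hexamers iff 3 ∤ T.

For 3 | T the hexamer on the 3-fold axis sits at a face centroid, reached
from a pentamer by sublattice steps (h_H, k_H) with T = 3 (h_H² +
h_H·k_H + k_H²); conversely (h, k) = (2h_H + k_H, k_H − h_H) triples any
T-number. The verification never trusts the arithmetic: capsids are built
explicitly in 3D and every hexamer center is tested against the 10 global
3-fold axes by point-to-axis distance.

## Worked example

```r
library(capsidlattice)

rep52 <- survey(52)                # the classic HK97-fold size range
attr(rep52, "summary")[c("n_capsids_with_hexamers", "n_centered", "n_all_skew")]
#> $n_capsids_with_hexamers
#> [1] 20
#> $n_centered
#> [1] 8
#> $n_all_skew
#> [1] 12
attr(rep52, "summary")$centered_t
#> [1]  3  9 12 21 27 36 39 48
```

Of the 20 hexamer-bearing architectures with T ≤ 52, eight (the multiples
of three) require a 6-fold-symmetric hexamer on each global 3-fold axis;
the other twelve — including the T = 7 capsids of many tailed phages — can
be built from split/skew hexamers throughout.

```r
cap <- build_capsid(c(2, 2), radius = 300)   # T = 12, ~60 nm capsid
cap
#> <capsid_lattice> T = 12 (h = 2, k = 2), laevo, radius 300
#>   122 capsomers: 12 pentamers + 110 hexamers
cls <- classify_sites(cap)
sum(cls$type == "hexamer" & cls$on_axis_order == 3)   # hexamers on 3-fold axes
#> [1] 20

protein_census(7, portal = TRUE, accessory_per_hexamer = 2)
#> <protein_census> T = 7 (portal at one vertex): 415 MCPs in 11 pentamers
#>   + 60 hexamers; 120 accessory proteins (2 per hexamer)

density_ratio(capsid_payload(70.5, 63), capsid_payload(64.5, 63))
#> [1] 9.302326
```

The last line compares two T = 7 phages with the same 63 nm internal
diameter but different genome lengths: the larger genome packs ~9.3 % more
densely.

A command-line interface is installed under `exec/`:

```sh
capsidlattice survey --tmax 52 --csv report.csv --json report.json
capsidlattice build --h 2 --k 2 --pdb t12.pdb --obj t12.obj --cxc t12.cxc
capsidlattice counts --t 7 --portal --accessory-per-hexamer 2
capsidlattice verify-theorem --tmax 300
```

`build` writes one pseudo-atom per capsomer center (B-factor encodes the
symmetry class) so the lattice can be inspected in any molecular viewer.

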