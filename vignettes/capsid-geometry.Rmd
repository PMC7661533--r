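---
title: "Measuring icosahedral capsids: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring icosahedral capsids: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icocapsid)
```

# The problem

Icosahedral viruses of the picorna-like superfamily package a single-stranded
RNA genome inside a protein shell built from 60 copies of an asymmetric unit
(AU) — here three jelly-roll subunits, so the lattice is T=1 with a pseudo-T=3
appearance. Comparative questions about such capsids are geometric: how large
is the internal cavity, how much volume does each genome nucleotide get, how
much surface do the subunits bury against one another, which subunits sit on
which symmetry axes, and how far apart are symmetry-related residues that
latch neighbouring pentamers together. `icocapsid` implements that tool chain
from atomic coordinates alone, with a synthetic-capsid generator so each
measurement is validated against closed-form ground truth rather than against
any particular deposition.

# The symmetry machinery

The proper icosahedral rotation group I has order 60 (identity, 15 two-folds,
10 three-fold axes contributing 20 rotations, 6 five-fold axes contributing
24). We generate it by numerical closure from three generators — a two-fold
about z, the cyclic coordinate permutation (a three-fold about (1,1,1)), and
a five-fold about the icosahedron vertex direction (0, 1, φ) with φ the
golden ratio — in the "I222" orientation: three mutually perpendicular
two-folds on x, y, z, the frame in which icosahedral cryoEM maps are commonly
deposited. The construction is validated at build time: orthogonality and
determinant to 1e-9, group order exactly 60, and the test suite checks
closure of all 3600 pairwise products at 1e-6 plus the axis census
(15, 10, 6). When an input file carries a full 60-operator biological
assembly record (BIOMT or `_pdbx_struct_oper_list`), the pipeline prefers the
file's own operators, because distances to symmetry mates must be measured in
the deposition's own symmetry frame; generated operators are the fallback.

Symmetry-mate distances (e.g. the CB–CB separation of the two-fold-related
surface helices that flank a capsid two-fold) are reported as the *minimum*
over the requested axis class. Publications rarely state which particular
two-fold was used; the minimum is the only convention that is well-defined
without that information, and for an atom near one specific two-fold it
coincides with the intended measurement.

# Shell geometry

The radial profile is simply the histogram of atom distances from the capsid
centre (the centroid of the expanded particle, which equals the origin when
the symmetry frame is correct; a deviation > 1 Å triggers a warning). The
**inner radius** is the 0.5th percentile of radial distances and the outer
the 99.5th, rather than the extrema: cryoEM models often have a few N- or
C-terminal residues hanging into the cavity or sticking outward, and the
percentile estimate is robust to them while recovering the exact boundary of
an ideal uniform shell to well under 1 Å. Both percentiles are parameters
and are echoed into every report row.

The **inner volume** is the sphere of the measured inner diameter,
V = (π/6)d³, reported in 10³ nm³. This is demonstrably the convention behind
published capsid comparison tables — the tabulated volumes equal (π/6)d³ of
the tabulated diameters in every row we checked — so it is the default, with
a genuinely independent estimator attached as a cross-check:

The **voxel cavity volume** discretises space on a cubic grid (default 2 Å),
marks voxels within `atom_radius` of any atom as solid, flood-fills the void
component containing the centre (6-connected), and then dilates the cavity
by `atom_radius`. The dilation step deserves a note: the raw flood-filled
void stops one atom radius short of the atom centres, while diameters read
off atomic positions (and hence the sphere model) measure to the centres.
Dilating by the same radius used for solidity makes the two definitions
commensurable; on an ideal shell with atom centres at r = 100 Å the method
recovers (4/3)π(100 Å)³ to better than 1%. If the fill reaches the grid
boundary, the shell leaks at this atom radius and the result is flagged
rather than trusted. Convergence is checked by halving the voxel (< 2%
change on the ideal fixture).

**Volume per nucleotide** divides the inner volume by the genome length plus
a 200 nt poly-A allowance. The allowance is applied by the pipeline to the
raw genome length — never pre-baked into inputs — so report rows are
comparable by construction. Report rounding matches the comparative-table
convention (diameters/volumes 1 decimal, volume per nucleotide 2); unrounded
values are kept alongside because the second decimal of volume-per-nucleotide
only reproduces from the unrounded volume.

The printed shell-thickness figures in the published table we model this
pipeline on are mutually inconsistent with the printed diameters; we
therefore report the operational thickness (outer − inner percentile radius)
and treat no printed thickness as a validation surface.

# Surface areas

SASA is a native Shrake–Rupley implementation: each atom's sphere of radius
(vdW + probe) is sampled at `n_points` (default 960) positions from a
deterministic Fibonacci spiral — not random points, so results are
bit-reproducible — and a point is accessible when outside every neighbour's
inflated sphere. Neighbour search uses a cell list, keeping full capsids
(10⁵–10⁶ atoms) tractable. The radii table is a single published protein set
(C 1.70, N 1.55, O 1.52, S 1.80, P 1.80 Å), shipped as data and overridable;
absolute buried areas are convention-dependent, so cross-structure
comparisons should hold the table fixed, and orderings rather than absolute
magnitudes are the robust statistic. Validation: an isolated atom reproduces
4π(r+p)² to < 1%, and a two-atom system reproduces the spherical-cap closed
form to < 2% down to near-tangency (where one quadrature point,
4π(r+p)²/960 ≈ 0.13 Å², is the resolution floor).

Buried surface area is (SASA_A + SASA_B − SASA_AB)/2. The two-slab fixture
used to validate planar interfaces ships a closed form that includes, besides
the slab face area, the probe-scale rim terms (the arc of the edge
half-cylinders of the upper slab that falls inside the lower slab's inflated
surface, and the lateral burial margin on the lower slab). The naive
"buried area ≈ face area" intuition is only the large-slab limit — at an
affordable 30 Å slab the rim contributes ~50% — and the implementation
matches the full closed form to < 1%.

`capsid_buried_area` enumerates the symmetry copies in contact with copy 0
(any atom pair within 5 Å), computes the AU–copy BSA per unique interface,
and reports either the per-AU neighbour sum or the whole-particle total
(sum × 60/2, each interface being shared by two AUs). Both modes are
labelled in the output because published per-capsid buried-area figures do
not always state their normalisation.

# Sequence bookkeeping

Polyprotein cleavage uses the convention that "cleaved at position s" cuts
the bond *after* residue s — the only convention under which a 931-residue
polyprotein cut at 264 and 515 partitions into 264/251/416, matching the
mature-protein accounting of the system this package was built around.
Masses are average (not monoisotopic) residue masses plus one water;
published subunit masses in kDa are sanity context, not a validation target,
when the underlying sequence is not distributed with the structure. Basic
residues (Arg/Lys/His) are mapped to the inner surface through their charged
terminal side-chain atom (NZ/CZ/NE2, CB fallback for unmodelled side chains),
with radial position and nearest-axis annotation, since RNA-contacting
clusters of basic residues concentrate near specific axis classes.

# The synthetic generator: what it does and does not emulate

`make_shell_capsid` states a world: one AU of carbon pseudo-atoms confined to
a single fundamental wedge of the sphere (canonicalised by maximising the
dot product with a fixed generic direction, which picks exactly one point
per group orbit), radii uniform in [inner, outer], three chains, seeded and
reproducible, with a minimum-distance guard against an atom clashing with
its own images at wedge boundaries. Expansion therefore yields an *exactly*
icosahedral shell whose true inner/outer radii are known by construction —
the ground truth every geometry operation is tested against. The dense mode
(`surface_coverage`) lays concentric spiral layers instead, spaced ~2.5 Å,
which is what the flood-fill needs to see a watertight shell.

What it does not emulate: real secondary structure, sequence, side-chain
chemistry, B-factors, the corrugated capsid surface of a real virus, or RNA
density. A green fixture test therefore establishes the *correctness of the
measurement machinery* (the geometry, quadrature, group theory and
plumbing), not the biological accuracy of any particular published number;
measurements on deposited models additionally depend on the deposition's own
modelling choices (missing termini, altlocs, radii conventions). Default
sizes (inner 100 Å, shell 30 Å, 500 atoms per AU → 30,000-atom particles)
are in the range of small RNA virus capsids and keep the full suite under
half a minute.

# Numerical choices

* Tolerances: orthogonality/determinant 1e-9, group closure and operator
  matching 1e-6, PDB coordinate round-trip 1e-3 Å — each fixed once in an
  internal constant record.
* Percentile estimator: R's default quantile type 7; with 30,000 atoms the
  difference between types is far below the ±2 Å fixture tolerance.
* Axis directions are sign-normalised (positive z, then x, then y) so axis
  tables are deterministic.
* Altloc handling keeps the highest-occupancy conformer; geometry needs one
  position per atom.
* Degenerate inputs: empty selections are values, not errors; an AU whose
  images it never touches gives a buried area of exactly 0; a solid seed
  voxel (no cavity) is a flagged zero, not an error.
* Contact cutoff 4.0 Å heavy-atom default; cryoEM models carry no hydrogens.

# Known limitations

* The mmCIF reader covers the `atom_site` loop and `_pdbx_struct_oper_list`
  as written by this package and by common depositions; exotic dialects
  (multi-model loops, anisotropic records) are out of scope.
* No quasi-equivalence handling beyond labelling: T > 1 lattices expand
  correctly under I but the per-subunit bookkeeping assumes one AU.
* Buried-area magnitudes depend on the radii table and probe; only
  orderings across structures computed under identical settings should be
  interpreted.
* The voxel estimator needs a watertight shell at the chosen atom radius;
  sparse models must use the sphere model (the default).
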