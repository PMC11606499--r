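---
title: "Methods: lattice models, interface classification, and geometry measures"
author: "bmcshell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice models, interface classification, and geometry measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmcshell)
```

## The model

Bacterial microcompartment shells — here, the polyhedral protein shells
of the alpha-carboxysome — are built from hexameric and pentameric
capsomeres arranged on Caspar–Klug lattices. An icosahedral shell is
indexed by two non-negative integers $(h, k)$, the steps separating
adjacent pentamers on the underlying hexagonal lattice. Its
triangulation number is

$$T = h^2 + hk + k^2,$$

and a closed icosahedral shell then carries exactly 12 pentamers and
$10(T-1)$ hexamers. Prolate (five-fold elongated) shells add body
indices $(h', k')$ for the steps separating pentamers across the
tubular midsection, with elongation number

$$Q = hh' + hk' + kk' \ge T$$

and hexamer count $10(T-1) + 5(Q-T)$. These two formulas are the
closed-form core of the package; everything else measures how real or
synthetic models realise them.

A lattice with $k = 0$ or $h = k$ is achiral (superimposable on its
mirror image); all other index pairs give chiral lattices whose
enantiomer is $(k, h)$.

## Lattice construction

`build_lattice()` realises the classic net construction: hexagonal
lattice points are collected inside a triangle with corners $(0, 0)$,
$(h, k)$ and the 60-degree rotation of $(h, k)$, and the triangle is
mapped affinely onto each of the 20 faces of an icosahedron with edge
$\sqrt{T} \times s$, where $s$ is the capsomere spacing (default 65
angstroms, chosen so the faceted $T = 9$ shell spans roughly 37 nm
across its vertices — the size scale of the midi-shell forms). Shared
edge and vertex points are deduplicated; sites coinciding with the 12
polyhedron vertices are pentamers.

The canonical embedding is the *faceted* polyhedron, not a spherized
projection: bend then concentrates at inter-facet edges and at
pentamer vertices, while hexamer–hexamer interfaces interior to one
facet are exactly flat. This mirrors the experimental observation that
pentamer-proximal interfaces are bent and structurally conserved while
facet-internal interfaces are nearly planar. A `spherize` option
projects sites onto the circumscribed sphere for comparison, giving
curvature (nonzero bend) at every interface.

For prolate bodies the two pentagonal caps are regular icosahedral
caps, and the ten mid-band triangles — one edge equal to the cap edge,
slant edges given by the body vector and its complement — are embedded
with a five-fold screw: the two pentamer rings are offset by an
azimuthal angle and an axial rise solved from the slant lengths. Not
every $(h', k')$ with $Q \ge T$ admits this embedding (strongly sheared
bodies have no real axial rise); such requests fail with an explicit
error. Because nothing in the construction pins down $(h', k')$ for a
given $Q$, the package defaults to collinear elongation — for the
$T = 9$, $Q = 12$ form, $(h', k') = (4, 0)$ — and accepts any valid
pair. Note that with $(h, k) = (3, 0)$ only multiples of 3 are
reachable as $Q$; intermediate values are not expressible on this
lattice.

Adjacency connects sites closer than $1.2\,s$: on ideal lattices first
neighbours sit at $\le s$ and second neighbours at $\ge 1.5\,s$ even
across folds, so the rule has a wide margin; the factor is exposed for
unusual geometries.

## Symmetry detection and interface classes

Interface classes are orbits of adjacency edges under the point group
of the site set. Rather than assuming a group, the package recovers it
numerically (`detect_point_symmetry`): a candidate orthogonal operation
is fixed by the images of three independent reference sites, candidates
are pruned by conserved invariants (site kind, distance from the
centre, pairwise distances), and an operation is accepted only if it
permutes the entire site set kind-preservingly. On icosahedral
lattices this yields the 60 proper rotations, plus 60 improper
operations when and only when the lattice is achiral; on prolate
lattices it yields the dihedral screw group. The same machinery runs
on segmented capsomere centroids, so classification of a measured
model never borrows information from the generator.

Mirror merging (using improper operations) defaults to on for achiral
lattices and off for chiral ones. Whether the published interface
counts used mirror merging is not stated anywhere we could find; this
single consistent rule reproduces both printed extremes — 4 classes
for $T = 9$ and 10 for $T = 19$ — and is therefore adopted as the
package default, flagged in every classification result.

Classes are ordered pentamer-involving first, then hexamer–hexamer by
decreasing orbit size, ties broken by the lexicographically smallest
representative edge; site indices are 0-based internally only in the
C-like loops and always reported 1-based.

The asymmetric unit of an icosahedral lattice is reported as one
representative site per rotation orbit with occupancy (orbit size)/60:
$T = 19$ gives three whole hexamers and one pentamer subunit (12/60 of
a pentamer = 1/5, reported as one subunit), $T = 16$ gives 2.5 hexamer
equivalents.

## Bend and twist angles

Each capsomere is reduced to its least-squares plane (smallest
principal component of all subunit points — using every point, not
just centroids, for noise robustness), oriented outward from the shell
centroid. For adjacent capsomeres A and B:

* **bend** $\alpha = \angle(\mathbf{n}_A, \mathbf{n}_B)$, computed in
  the `atan2` form, which is stable where `acos` would amplify
  rounding near parallel normals;
* **twist** $\beta$: B's subunit-direction phase after rotating its
  plane onto A's about the interface axis
  $\mathbf{n}_A \times \mathbf{n}_B$, minus A's phase, both measured
  against the interface direction and folded into the joint cyclic
  fundamental domain ($360/\mathrm{lcm}(n_A, n_B)$ degrees, reported
  in $[0, \mathrm{period}/2]$). Phases are circular means of order
  $n$, so they are independent of subunit labelling.

The published definition of the two angles lives in supplementary
material we do not have; the decomposition above is the natural
"vertical/horizontal" split, it reproduces the printed zero twist for
pentamer–hexamer interfaces on achiral lattices, and an alternative
reference (the capsomere symmetry axis instead of the interface axis)
differs only by which projection defines the phases — the interface
axis was chosen because it makes the two-capsomere fixture exactly
self-consistent.

Two geometric facts discovered while validating are worth recording.
First, on faceted embeddings a hexamer pair straddling a facet edge
carries a small (< 4 degree) nonzero twist even though the underlying
lattice is "untwisted": projecting the two hexagonal vertex stars onto
their tilted fitted planes distorts the phases by slightly different
amounts. Second, chiral lattices ($T = 13$, $T = 19$) have an
intrinsic nonzero pentamer–hexamer twist (1.8–4 degrees) under *any*
symmetry-covariant capsomere orientation, because no mirror passes
through their interfaces; the experimentally reported zero twist for
those shells reflects relaxation of real subunits, which idealized
rigid lattices cannot and should not reproduce. The tests therefore
assert exact zero twist only where symmetry forces it (achiral
pentamer–hexamer classes and constructed fixtures) and assert
class-constancy (dispersion below $10^{-6}$ degrees) everywhere.

Superposition RMSD between capsomeres uses the Kabsch algorithm
restricted to proper rotations (proteins are chiral), minimised over
the 5 or 6 cyclic subunit correspondences only — no reflections.

Shell diameter offers three conventions: twice the maximal or minimal
centroid radius (circumsphere/insphere), and `diagonal_average`, which
emulates the micrograph procedure of drawing three diagonals through
the centre at 60-degree increments in a projection plane and averaging
their extents. The projection is random but seeded (default seed 42)
so reports are reproducible; on a sphere of capsomeres all conventions
agree to within 1%.

## The synthetic generator and what it does (not) emulate

`generate_shell()` places a pseudo-atomic capsomere template — 5 or 6
wedge-shaped subunits of 7 points each, one chain per subunit — on
every lattice site, oriented along the circular-mean phase of the
site's neighbour directions. That orientation commutes with every
lattice symmetry, which is what makes per-class angle dispersion zero
to machine precision on ideal shells and lets the generation manifest
(capsomere membership, kinds, interface classes, true bend/twist per
edge) act as ground truth for the whole downstream pipeline. Isotropic
Gaussian coordinate noise is optional; above 10% of the capsomere
spacing the generator warns, above 25% it refuses (adjacency would be
ambiguous). One seeded stream per artifact makes output bit-identical
under a fixed seed.

The generator emulates geometry only: subunit wedges carry no
side-chain chemistry, so contact detection is exercised on small
all-atom micro-fixtures built in code, and `interface_report()`
explicitly refuses pseudo-atomic shells. Passing the synthetic round
trips therefore demonstrates the correctness of segmentation,
classification and angle machinery — not that any particular
experimental shell has these exact angles, which would require the
deposited models.

Synthetic linkers plant `[IV][TS]G` anchor motifs at known positions
in a random 20-letter background; accidental matches elsewhere are
removed by rejection resampling of background residues (never touching
planted positions), so the manifest is exactly the truth. Matches of
this pattern can never overlap each other (a match position constrains
the next two residues out of the pattern), but consecutive repeats are
common and all matches are reported without greedy consumption.

## Segmentation

Chains are grouped into capsomeres by a two-level rule: a tight
heavy-atom contact graph (default 5 angstroms) plus centroid linkage
at $1.4\times$ the median nearest-neighbour chain-centroid distance.
The median estimates the intra-capsomere subunit spacing (adjacent
subunits are each other's nearest neighbours); the factor keeps the
rule below inter-capsomere spacings while tolerating coordinate noise
that breaks individual atom contacts — pseudo-atomic subunits are
sparse, so at 5% spacing noise single contacts routinely exceed any
fixed cutoff while centroids move only by $\sigma/\sqrt{7}$.
Components larger than six subunits (a whole shell fused through
dense inter-capsomere contacts, the failure mode of single-cutoff
clustering on real assemblies) are re-split using the centroid links
alone. Components of 5 or 6 subunits become pentamers/hexamers;
anything else is labelled `unknown` and kept.

## Contact chemistry and surface areas

Hydrogen bonds are N/O–N/O heavy-atom pairs across groups within 3.5
angstroms (pairs under 2.0 angstroms are excluded as covalent-range);
salt bridges are Asp/Glu carboxylate oxygens within 4.0 angstroms of
Arg/Lys — and, configurably, His — nitrogens. No angular term is
applied: published interface descriptions for these shells report
contacts by residue pair without geometric criteria, and the cutoffs
are arguments everywhere. The production neighbour search bins atoms
on a grid at the cutoff length and is exactly equivalent to quadratic
enumeration (tested against it on a thousand random configurations).

Solvent-accessible surface area is Shrake–Rupley sampling on a
deterministic golden-spiral point set (default 960 points per atom,
probe 1.4 angstroms) over Bondi van der Waals radii; the radii table
name is carried in every result. Buried area is
$\mathrm{SASA}(A) + \mathrm{SASA}(B) - \mathrm{SASA}(A \cup B)$,
reported both total and halved, because published "contact areas" do
not always state which convention they use; the convention string is
part of the result rather than a silent choice.

## Problem sizes and numerical choices

The test suite and analysis scripts work at the native sizes of the
five studied shell forms (92–192 capsomeres, up to 1152 chains and
~8000 pseudo-atoms for $T = 19$), which a laptop handles in seconds
per shell. Tolerances: site deduplication and symmetry detection use
$10^{-6}$ of the capsomere spacing on ideal geometry; class-dispersion
assertions use $10^{-6}$ degrees; Monte-Carlo assertions (plane-fit
tilt, RMSD under noise, angle recovery) use the analytic expectation
with 20% slack over 50–100 seeds. Degenerate inputs are rejected
early: $h = k = 0$ lattices, $Q < T$ bodies, collinear point sets for
plane fits, mismatched point counts for superposition, non-positive
probes.

## Known limitations

* No energetics: the package describes lattice geometry and does not
  predict which $T$ a biological system selects, nor model curvature
  elasticity.
* Idealized rigid capsomeres: measured angle values on synthetic
  shells are properties of the faceted embedding, not predictions of
  experimental angles (see the twist discussion above).
* Contact chemistry is distance-only; no hydrogen placement, pKa, or
  energy scoring.
* Prolate construction is validated on achiral and small chiral
  bodies; exotic high-shear bodies may have no embedding and are
  refused rather than approximated.
* The scaffold protein's real sequence is not bundled (it is not
  printed in the source material); motif analyses on real linkers
  require a user-supplied FASTA.
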