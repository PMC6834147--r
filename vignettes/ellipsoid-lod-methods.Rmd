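---
title: "Ellipsoidal LOD abstraction of molecular surfaces: methods and design"
author: "EllipsoidLOD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ellipsoidal LOD abstraction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EllipsoidLOD)
```

# The problem

A van der Waals rendering of a protein draws one sphere per atom. Past a few
tens of thousands of atoms most of those spheres project to less than a
pixel, yet they still cost intersection tests and destroy the Goodsell-style
readability of the overall shape. The classic answer is a level-of-detail
(LOD) hierarchy: cluster atoms into nested groups, bound each group by a
simple solid, and draw groups instead of atoms once they are far enough
away. Two choices dominate the quality of the result: *how atoms are
grouped*, and *what solid bounds a group*. This package implements a
specific pair of answers — residue-restricted clustering under a
volume-based metric, and minimum-volume enclosing ellipsoids — together with
the distance-driven selection rule and a CPU renderer that makes every stage
testable.

# Residue-restricted hierarchical clustering

`buildClusterTree()` agglomerates bottom-up in two phases. In phase 1 only
clusters belonging to the same residue may merge, until every residue is a
single cluster; phase 2 then agglomerates the residue clusters to a single
root. The restriction is enforced structurally (the two phases cannot
interleave), not heuristically. It exists for biological, not geometric,
reasons: residues are the chemically meaningful unit of a protein chain, so
every abstraction band either subdivides residues or groups whole residues,
never a mixture that straddles a residue boundary. A side effect is that
chemically identical residues produce identical subtree shapes, so symmetric
parts of a molecule placed in the same distance band automatically receive
the same representation.

Every merge creates exactly one internal node, so n atoms give 2n − 1 nodes.
Nodes carry one of five levels — ATOM (leaves), RESIDUE_INTERIOR (proper
sub-residue clusters), RESIDUE (exactly one whole residue), RESIDUE_LINK
(several whole residues) and MOLECULE (the root). A residue containing a
single atom keeps its leaf at ATOM level with a residue-root flag, which
preserves the 2n − 1 count; a molecule with a single residue labels its root
MOLECULE.

## The volume-based distance metric

The dissimilarity between two atoms is the volume of the smallest sphere
enclosing both vdW spheres: if one contains the other that is the larger
sphere; otherwise the radius is (d + r₁ + r₂)/2. Between clusters we use the
unweighted average of this quantity over all leaf-atom pairs (UPGMA),
maintained incrementally with the Lance–Williams average-linkage update and
verified in the tests against a naive implementation that recomputes the
full matrix at every step. Minimizing enclosing *volume* rather than
center-to-center distance is what keeps the hierarchy tight: each merge is
the one that inflates the new cluster's bounding volume least.

Ties in the dissimilarity are broken toward the candidate pair whose
(min id, max id) is lexicographically smallest, so the tree is a pure
function of the input molecule. During clustering, each internal node's
bounding sphere is the pairwise enclosing sphere of its children's spheres —
monotone and cheap, which the merge loop needs; the *exact* minimal
enclosing spheres used for rendering are recomputed later by
`annotateTree()`.

# Bounding volumes

`annotateTree()` gives every internal node two bounds.

**Exact minimal enclosing sphere** of the member atom spheres, found by
minimizing the convex function max_i(‖c − cᵢ‖ + rᵢ): a Bâdoiu–Clarkson
averaging warm start from the centroid followed by a Nelder–Mead polish with
machine-precision relative tolerance. The suite checks the result against a
dense multi-start oracle at 10⁻⁶ relative radius.

**Minimum-volume enclosing ellipsoid** (MVEE). The solver is the
Khachiyan/Kumar-style first-order ascent on the dual D-optimal design
problem with the stopping rule max_i qᵢᵀX⁻¹qᵢ ≤ (1+ε)(d+1). This yields two
guarantees used directly as test assertions: all input points lie inside the
(1+ε)-inflated ellipsoid, and the volume is within (1+ε)³ of the true
minimum (checked against an independent penalty-method convex optimizer).
The ellipsoid is returned in center/axes/semi-axes form; the quadric matrix
A = V diag(λ⁻²) Vᵀ is available via `quadricMatrix()`. Axis signs are
canonicalized (largest component positive) so results are bit-reproducible.

Ellipsoids are fitted to *surface samples*, not to the exact union of balls:

* RESIDUE_INTERIOR and RESIDUE nodes sample every member atom sphere with a
  k-point Fibonacci lattice;
* RESIDUE_LINK and MOLECULE nodes sample the MVEE surfaces of their two
  children.

The cascade means high-level ellipsoids only ever look at the previous
level's bound, which is what keeps annotation cost linear in the tree rather
than quadratic in atoms, at the price of inheriting the children's
inflation. "Previous level" is read tree-locally as the node's two children
— the only definition that does not depend on any particular camera.

## Parameters and numerical choices

* `pointsPerSurface` k = 32 (per sphere/ellipsoid surface). Enough that the
  between-sample bulge of a vdW sphere is small relative to atom spacing;
  annotation cost grows linearly in k.
* `tolerance` ε = 10⁻³: volume within 0.3% of optimal; inflation guarantee
  (1+ε).
* `maxIterations` 10⁴ caps the Frank–Wolfe loop; typical inputs converge in
  tens to hundreds of iterations.
* Rank-deficient sample sets cannot occur for a real atom cluster (k ≥ 4
  surface points of a ball span 3-space) but are guarded: six axis-aligned
  points at ±10⁻⁶ Å are added and the fit retried; semi-axes are floored at
  10⁻⁶ Å.

Because the Fibonacci lattice is axis-fixed, rotating a molecule does not
rotate the sample clouds exactly, so MVEEs are rotation-equivariant only up
to sampling resolution — at k = 128 the semi-axes agree within a few
percent, as the property test documents. Exact equivariance would require a
rotation-covariant sampling scheme; we prefer the deterministic lattice.

# LOD selection

`selectDisplayList()` walks the tree from the root. A node C with subtree
height D (edges to its deepest leaf) at distance *dis* from the camera is
emitted when D ≤ (dis − inival)/interval; leaves are emitted when reached;
otherwise both children are visited. The threshold is compared as a real
number — no flooring — and may be negative, in which case only leaves
qualify. *dis* is measured to each cluster's own center (MVEE center in
ellipsoid mode, minimal-sphere center in sphere mode), so a single frame
mixes abstraction bands: near residues stay atomistic while far ones
collapse.

Defaults are inival = 100 Å and interval = 20 Å: a protein a few tens of Å
across shows full vdW detail when the camera is nearer than 100 Å, and loses
one hierarchy level per additional 20 Å. The emitted frontier always
partitions the atom set (a traversal invariant, tested for every pose), and
moving the camera radially outward never lengthens the display list.
`vdw` mode bypasses the predicate and emits all leaves.

# Rendering

The renderer reimplements GPU glyph ray casting as deterministic CPU code so
the whole image pipeline is unit-testable.

* **Camera**: right-handed pinhole, pixel (0,0) top-left, rays through pixel
  centers; vertical FOV in degrees.
* **Sphere glyphs**: standard smallest-positive-root quadratic; outward
  radial normal (also for interior origins).
* **Ellipsoid glyphs**: the ray is translated by −c and rotated by Vᵀ into
  glyph space, where the quadric is x²/a² + y²/b² + z²/c² = 1; the
  glyph-space normal (x/a², y/b², z/c²) is rotated back. Rotation preserves
  length, so the glyph-space t is the eye-space depth directly; the
  equal-axis case reproduces the sphere path to machine precision.
* **Agent geometry**: the concentric sphere of radius λ₁ bounds each glyph.
  On the GPU this sphere is the proxy rasterized by the vertex stage; here
  it becomes a conservative screen-space rectangle (`screenBound()`) that
  restricts the per-glyph pixel loop — same role, fully testable (a
  brute-force full-frame scan verifies no hit pixel ever falls outside).
* **Depth buffer** stores the eye-space ray parameter t in Å rather than
  normalized device depth; the silhouette threshold and all oracles then
  work in physical units.
* **Shading**: Lambert with ambient floor 0.2, clamped; `constant` mode
  returns the albedo unchanged (used for flat outline comparisons). The
  default light is a headlight (from the surface toward the camera);
  a fixed `lightDirection` can be set instead.
* **Silhouettes**: a pixel is marked when the maximum absolute depth
  difference to its 8 neighbors exceeds threshold·(1 + scale·depth)
  (defaults 1 Å and 0.01/Å). Foreground pixels adjacent to the background
  always exceed the threshold, so object outlines are always closed;
  background pixels and out-of-frame neighbors are never marked.
* **SSAO**: per foreground pixel, 16 cosine-weighted offsets (deterministic
  Park–Miller sequence seeded by `ssaoSeed`) inside the normal-oriented
  hemisphere of radius 3 Å are projected to the screen; a sample counts as
  occluded when the stored depth there is nearer than the sample point,
  within a 2×radius range check and a 2.5% bias against self-occlusion.
  Occlusion is the occluded fraction; colors are darkened by (1 −
  occlusion).
* **Colors**: a per-level palette by default; `colorMode = "residue"`
  cycles a 20-color palette per residue for per-amino-acid images.

Image output is 8-bit PNG (via the png package) or binary P6 PPM quantized
by round-half-up on 255·value; both are byte-reproducible.

# Synthetic molecules

`generateSyntheticMolecule()` is the package's test substrate and demo
input. Residue centers follow a helix (radius 6 Å, 0.6 rad and 2 Å rise per
residue, ~4.1 Å between consecutive centers — the scale of a real peptide
backbone); atoms scatter isotropically around their center with σ = 1 Å, so
residues are spatially coherent blobs whose spacing exceeds their spread.
Elements are drawn C/N/O/S with protein-like frequencies, giving Bondi radii
between 1.52 and 1.80 Å. Generation is bit-deterministic for a fixed seed
and restores the caller's RNG state.

What it does *not* emulate: covalent bond lengths and angles, secondary
structure, side-chain packing, or the residue-size distribution of real
proteins. Tests passing on these chains therefore establish the geometric
and algorithmic properties (counts, partitions, containment, monotonicity,
determinism) — not that any particular real protein looks good at a given
parameter setting. For real inputs, `readPDB()` accepts standard PDB files
(model 1, altLoc blank/"A", waters excluded, HETATM behind a flag, Bondi
radii with a 1.5 Å default).

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run at desk scale: trees up to
1000 atoms (250 × 4), MVEE point sets of 8–40 points, renders at 64–512 px,
brute-force render oracles at 64×64. These sizes were chosen so every
invariant is exercised across all five node levels while the whole suite
stays interactive to run.

# Known limitations

* Tree construction is O(n²) memory in the atom-pair VDM matrix; fine for
  desk-scale molecules, not for million-atom scenes.
* MVEEs bound sampled surface points, so a bound can miss surface between
  samples; increase `pointsPerSurface` where exactness matters.
* The renderer is an offline software implementation — correctness and
  reproducibility over speed; no frustum culling, deferred shading or
  temporal reuse.
* Level transitions are hard switches between bands; no geometric morphing
  between a cluster and its children.
* Conformational change invalidates the tree; there is no incremental
  update, rebuild instead.
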