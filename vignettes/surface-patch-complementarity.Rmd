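---
title: "Surface-patch complementarity: models, parameters and design notes"
author: "surfcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-patch complementarity: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(surfcomp)
```

## The model

`surfcomp` scores how well a small molecule's surface complements a protein
binding pocket without posing the ligand.  Both sides are decomposed into
overlapping **surface patches**; each patch is summarized by
rotation-invariant descriptors; an assignment problem decides which pocket
patch corresponds to which ligand patch; and the quality of that
correspondence, together with a size term, becomes the complementarity
score.  The pipeline assumes rigid input conformers — ligand flexibility is
handled upstream by scoring many conformers per ligand and keeping the best
few.

### Surfaces

The molecular surface is the $\rho = 1$ isosurface of a sum of atomic
Gaussians, $\rho(x) = \sum_i \exp(-\kappa\,(|x-x_i|^2 - r_i^2)/r_i^2)$ with
$\kappa = 2.3$, so an isolated atom's surface sits at its van der Waals
radius.  Surface points are placed on grid edges that straddle the iso
level; two points are graph-adjacent when their host edges share a grid
cube, which supports geodesic (shortest-path) distances along the surface.
Each point also carries an outward normal (the descending density gradient)
and an area weight (its grid face projected through the normal), so total
surface area is a by-product.  This Gaussian-isosurface construction is
parameter-light and smooth; when a Poisson–Boltzmann solver is available its
OpenDX output can be imported instead and interpolated onto the surface
(`assign_electrostatics(mode = "from_grid")`), keeping the published
workflow available.  The built-in electrostatics is a distance-screened
Coulomb model, $\phi(x) = \sum_i 332.06\,q_i\,e^{-d_i/\lambda}/(\varepsilon
d_i)$ kcal/mol/e with $\varepsilon = 80$ and $\lambda = 8$ Å — a cheap
stand-in for solvent screening whose *sign structure* is what the
descriptors mostly consume.

Grid spacings default to 0.6 Å for proteins and 0.4 Å for ligands: a 5 Å
patch must contain enough points (dozens to hundreds) to voxelize stably,
and ligands are small enough that the finer grid is affordable.

### Pocket, seeds, patches

The pocket is the protein surface region hit by rays cast from the bound
ligand's mass center (1000 directions on a Fibonacci sphere, 12 Å range,
first hit per ray, perpendicular tolerance 1.2 × grid spacing), dilated by
one graph ring to close pinholes between rays.  Seed points are surface
points nearest heavy atoms within 3.5 Å of the surface, visited in
ascending atom-to-surface distance (ties by atom serial, so runs are
deterministic), and accepted only if at least 3.0 Å from every previous
seed.  A patch is the connected region within 5.0 Å *geodesic* distance of
its seed; reading the patch radius geodesically guarantees the stated
connectedness by construction (a Euclidean-ball variant is available behind
`segment_patches(euclidean = TRUE)`).  Patches may overlap; no ownership
partition is imposed.

### Descriptors

Each patch is centered on its point centroid and scaled so its farthest
point lies at radius 0.7 of the unit ball (the standard safety margin that
keeps the function inside the basis' support), voxelized on a 64³ grid, and
expanded in the Zernike–Canterakis basis up to order $n_{\max} = 15$.  The
per-$(n,l)$ norms $F_{nl} = \sqrt{\sum_m |\Omega_{nlm}|^2}$ are invariant
under rotation; order 15 gives 72 shape invariants and $72 + 72$ invariants
for the positive part and the magnitude of the negative part of the surface
potential — splitting at $\phi = 0$ keeps both channels non-negative while
preserving field strength, rather than binarizing the sign.

Three numerical choices matter here:

* **Radial basis.**  The radial polynomials are generated from the
  closed-form Canterakis coefficients and are orthonormal under the $r^2$
  weight up to ~1e-7 (asserted in the test suite); moments are computed by
  direct summation over occupied voxels, which is exact for the voxelized
  function and fast because patches occupy a few thousand voxels.
* **Anti-aliased voxelization.**  By default each point splats its value
  over its 8 neighbouring voxels with trilinear weights.  Hard
  nearest-voxel binning leaves a grid-orientation fingerprint in the
  descriptors (median rotational deviation ~3 % at 64³); splatting reduces
  it to ~0.1 %, so descriptor differences reflect geometry, not the
  lattice.  `voxelize_patch()` retains the plain nearest-voxel semantics
  for inspection and interchange; `patch_descriptor(method = "nearest")`
  reproduces it.
* **Size normalization.**  Each channel is divided by its own $F_{00}$
  (when positive), so `pdist` compares shape rather than size; molecular
  size enters the total score separately through the patch-count term.
  Disable with `normalize = FALSE` to keep absolute magnitudes.

### Matching and scoring

The patch-pair distance is $w_1\,\mathrm{pdist} + w_2\,\mathrm{appd} +
w_3\,\mathrm{grpd}$: descriptor distance (fixed channel weights
0.717/0.283), Euclidean distance between 40-bin geodesic position
histograms (bin width 1 Å; unreachable pairs are capped at 40 Å with a
warning), and the geodesic relative-position difference against the pairs
matched so far.  Assignments are solved with a forward ε-scaling auction on
integer-scaled costs (scale 1e6; ε from half the largest cost down by
factors of 5 until below $1/(n+1)$, which is optimal for the scaled
integers — verified against exhaustive enumeration in the tests).
Rectangular problems are padded with zero-cost dummy rows, which leaves the
restricted optimum unchanged.  Because `grpd` depends on the matching
itself, `match_patches()` iterates: an auction without the `grpd` term
(there are no prior pairs yet), then re-auctions with the full cost using
the previous round's pairs as context, until the pair set is stable (at
most 5 rounds).  A strictly sequential greedy variant
(`mode = "sequential"`) grows the matching one cheapest-pair at a time and
is kept for comparison; on the synthetic benchmarks the two modes perform
similarly and the iterated re-auction is the default.  Ties in cost resolve
deterministically (lowest indices).  Every patch of the smaller side is
matched, so $N = \min(n_A, n_B)$.

The conformer-level total is $w_1\,\mathrm{avgZd} + w_2\,\mathrm{avgGrpd} +
w_3\,\mathrm{pocketSd}$ with trained defaults (0.8, 0.0, 0.1); lower is
better.  `avgZd` is the plain mean of pair descriptor distances (an
optional coverage penalty $\times n_A/N$ exists behind a flag, for pockets
much larger than their ligands); `avgGrpd` averages
$|G2_A(a_i,a_j) - G2_B(b_i,b_j)|$ over all couples of matched pairs;
`pocketSd` is $|n_A - n_B|/\max(n_A, n_B)$, a symmetric relative
patch-count difference bounded by 1.  The legacy pocket-comparison variant
(`totalscore_ps`, fixed weights 0.06/0.14/0.8 with Euclidean-distance `rdp`
and descriptor-only matching) is provided for binding-ligand prediction
workflows, together with a per-ligand-type `pocket_score` in which each of
the top $k = 20$ ranked conformers contributes a linearly decreasing reward
$k - i + 1$ to its ligand type, normalized by the type's conformer count —
a prose-faithful reading of the published ranking reward, isolated in one
small function for easy replacement.  Library ranking averages each
ligand's ten best conformer totals.

## Synthetic benchmarks: what they do and do not show

Everything is tested against generated fixtures
(`make_complementary_pair()`, `make_screening_set()`), which are pure
functions of a seed.  A fixture complex is an ellipsoid-confined
self-avoiding walk of C/N/O pseudo-atoms (default 20 heavy atoms — a
typical drug-like ligand size) surrounded by a wall of pseudo-atoms placed
along each direction at a ~2 Å gap from the ligand's own Gaussian
isosurface, with an opening on one side.  The wall therefore *tracks* the
ligand's shape, producing a genuinely complementary groove, and the
ellipsoidal confinement breaks rotational symmetry so that a ground-truth
patch correspondence exists; a spherical cavity admits no well-defined
correspondence and any matcher degenerates to chance on it.  Dipolar
charges (wall positive, ligand negative) exercise both electrostatic
channels.  Screening actives are positional jitters of the cavity-filling
ligand (3 conformers each); decoys are re-grown chains with the same atom
count and charge pattern (similar size, different topology), one conformer
each.

These toys emulate the *geometry* of complementarity, not chemistry: there
are no protons, no realistic charge distributions, no conformational
strain, and the surfaces are smoother and the systems far smaller than real
complexes.  Passing the synthetic benchmarks shows the machinery is
internally correct — descriptors invariant, assignments optimal,
complementary partners rank above topological decoys, native contacts
recovered well above chance — not that any particular enrichment level will
transfer to real screening sets.  Two scale effects are worth noting when
comparing against full-size benchmarks: a toy pocket spans a few patch
diameters, so a 5 Å contact cutoff is proportionally looser and the
random-pairing baseline correspondingly higher than on real complexes; and
the surfaces' smoothness leaves the descriptor term with little
*localization* signal, so the geometric terms carry most of the matching on
fixtures.  Consistent with that, grid-optimizing the distance weights on
the fixtures (the same protocol that produced the published weights on a
real benchmark) selects a heavily geodesic-weighted triple, and the
native-contact evaluation in the acceptance suite uses the weights it
optimizes on a training subset of the fixtures rather than transplanting
numbers trained on protein crystal structures onto toy geometry.

Problem sizes in the shipped benchmarks — 20 complexes for contact
recovery, 20 libraries of 5 actives + 45 decoys (one conformer per decoy,
three per active) for screening, 50 rotations for invariance, 200 instances
for auction optimality — keep a full run in the tens of minutes on one
core while leaving the statistics stable.

## Degenerate inputs and edge behaviour

Patches with fewer than 3 points, all-identical points, or empty voxel sets
raise errors or warnings rather than silent zeros; infinite geodesics
(disconnected surface components) are capped at the APP histogram range
with a warning; `avgGrpd`/`rdp` return 0 with a warning for single-pair
matchings; rectangular cost matrices must be oriented rows ≤ columns
(callers transpose); an empty ray-cast pocket or a seedless surface is an
error naming the cause.  Auction costs are rounded at 1e-6, so "zero" costs
in tests are asserted at that quantum.

## Known limitations

* The screened-Coulomb surface potential is not a Poisson–Boltzmann
  solution; for quantitative electrostatics import an APBS grid.
* Patch counts on the two sides enter `appd` as raw histogram counts, so
  pockets much larger than their ligands shift that term; the trained
  weights absorb this on real data, but extreme size mismatches dilute it.
* The matcher returns one deterministic matching; near-degenerate
  geometries (quasi-symmetric pockets) have rival registrations whose
  scores differ less than the descriptor noise, and no uncertainty is
  reported.
* Conformer generation, protonation and partial-charge assignment are out
  of scope; inputs are consumed as given (PQR/MOL2/SDF carry charges and
  bonds where available).
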