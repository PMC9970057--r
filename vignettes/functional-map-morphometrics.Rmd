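---
title: "Landmark-free morphometrics with functional maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-free morphometrics with functional maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fmorph)
```

## The problem

Classical geometric morphometrics quantifies bone shape through landmark
configurations placed by an expert and aligned by Procrustes analysis. The
landmarks limit what variation can be captured and introduce observer
effects. `fmorph` instead treats every specimen as a whole triangular
surface mesh and estimates *functional correspondences* between specimens:
instead of matching points, it matches the spaces of functions defined on
the surfaces. All downstream shape statistics are then derived from the
correspondences, with no landmarks in the loop.

The pipeline is:

1. **Preprocess** — read meshes, optionally resample to a common vertex
   count, rescale each specimen to unit surface area (removing size), and,
   if specimens arrive in arbitrary poses, rigidly prealign them.
2. **Spectral basis** — discretise the Laplace–Beltrami operator (LBO) of
   each surface with the cotangent scheme and a lumped barycentric mass
   matrix, and keep the `k` smallest eigenpairs. The eigenfunctions
   generalise the Fourier basis to curved surfaces and are invariant to
   rigid motion and to isometric bending.
3. **Descriptors** — compute pointwise, isometry-invariant descriptors on
   each mesh. The default is the Wave Kernel Signature (WKS); a small
   pointwise network over the same spectral inputs can be *learned*
   unsupervised instead (Siamese training with a structural loss).
4. **Functional maps** — for each ordered pair of shapes, estimate the
   `k x k` matrix `C` that best transports descriptor coefficients from
   one eigenbasis to the other, with a Laplacian-commutativity regulariser.
   Point-to-point (P2P) maps are recovered by exact nearest neighbours in
   the spectral embedding.
5. **Consistent refinement** — refine all maps of the collection jointly
   with the Limit Shape / Consistent ZoomOut iteration: estimate a latent
   "mean" functional space for the whole collection, re-extract P2P maps
   in the shared latent coordinates, re-express them as functional maps at
   a higher spectral resolution, and repeat from `k = 20` up to `k = 70`.
6. **Shape variables** — from each specimen's latent map `Y_i`, compute
   two shape-difference operators relative to the limit shape: an
   area-based operator `t(Y_i) Y_i` and a conformal (angle-based) operator
   `pinv(Lambda0) t(Y_i) Lambda_i Y_i`. Flattened, these are the latent
   shape-space differences (LSSDs) — the package's analogue of Procrustes
   shape variables.
7. **Statistics** — PCA of the LSSDs at a 95% cumulative-variance cutoff,
   distance-matrix correlations between representations, cross-validated
   group classification (multinomial logistic, LDA, naive Bayes; K-means
   as the unsupervised reference), weighted distinctive functions that
   localise between-group differences on the surface, and a
   landmark-transfer protocol for validation against known ground truth.

## Model assumptions

* Surfaces are **closed, edge-manifold triangular meshes**. Boundary
  handling is not implemented; bones and all fixtures are watertight.
* Specimens in a collection are **near-isometric deformations** of a
  common anatomy: features present in one specimen exist (possibly at a
  different size) in the others. Functional maps can only be as good as
  this assumption — structures with no counterpart on the other shape
  have no well-defined correspondence.
* Size is a nuisance parameter and is removed by unit-area rescaling; all
  distances reported downstream (e.g. landmark-transfer errors) are in
  unit-area mesh units.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k_final` | 70 | spectral truncation of the final maps; 70 eigenfunctions retain fine detail at desk scale while keeping `C` small |
| `k_init`, `step` | 20, 5 | refinement schedule; starting low lets the coarse structure lock in before detail is added |
| `n_wks` | 100 | WKS energy channels; `wks()` uses up to 200 eigenfunctions when available |
| `sigma_scale` | 7 | WKS Gaussian width in units of the energy-grid step (the common literature choice) |
| `alpha` | 1e-2 | weight of the Laplacian-commutativity term in `estimate_fmap()` |
| `var_threshold` | 0.95 | cumulative variance retained by `pca_scores()` |
| `folds` | 11 | cross-validation folds in `classify_groups()` |
| `m` | 10 | eigencomponents of the difference operator used by `distinctive_functions()` |
| learning rate, batch | 1e-3, 1 | ADAM settings of the unsupervised training loop |
| loss weights | 1e3, 1e3, 1, 1e5 | bijectivity, orthogonality, Laplacian- and descriptor-commutativity weights, following the reference Siamese implementation |

**On `alpha`.** The commutativity penalty compares eigenvalue gaps, whose
raw magnitude grows like `k^2` and depends on mesh scale. `estimate_fmap()`
therefore normalises the eigenvalues by their joint maximum inside the
penalty, making `alpha` dimensionless and transferable across meshes and
truncations. With that parameterisation the data term dominates by roughly
two orders of magnitude at the default `alpha = 1e-2`; on the synthetic
collections this value roughly halves the refined correspondence error
relative to `1e-3` while leaving self-maps exact, and it is the default
everywhere.

## Numerical choices

* **Mass lumping.** The mass matrix is diagonal (one third of the incident
  triangle area per vertex). This keeps projections and P2P recovery
  cheap; a full Galerkin mass matrix would change eigenvalues at the
  discretisation-error level, well below the truncation error at `k = 70`.
* **Cotangent clamping.** Scanned meshes contain slivers; cotangents are
  clamped at `|cot| <= 1e4` and the clamp count is reported.
* **Eigen-solvers.** Small meshes use a dense symmetric solver on the
  mass-normalised operator; larger ones use ARPACK in shift-invert mode
  through `igraph::arpack()` with a sparse Cholesky factor, retried with a
  larger Krylov subspace on non-convergence. Eigenfunction signs are fixed
  (largest-magnitude entry positive). Eigenvalue ties (sphere multiplets)
  are left in solver order; no tested quantity depends on the rotation
  within an eigenspace.
* **Exact nearest neighbours.** P2P recovery and the latent-coordinate
  search use blocked dense distance evaluation — exact, ties to the lowest
  index — so oracle tests can require exact index agreement.
* **Coverage.** The bijective coverage of a P2P map is reported as the
  fraction of source vertices whose target is claimed by no other source
  vertex (unique-preimage reading); the alternative image reading
  `|unique(T)|/n` is attached as an attribute.
* **Limit shape.** The consistent latent basis comes from the smallest
  eigenvectors of the block consistency matrix of all pairwise maps,
  stacked and normalised so `sum_i t(Y_i) Y_i = N I`, then canonicalised
  by diagonalising the average pulled-back Laplacian; its eigenvalues are
  the latent spectrum `Lambda0`. For a collection of copies of one shape
  this reproduces that shape's eigenvalues exactly.
* **Conformal operator at the zero mode.** `Lambda0`'s first entry is the
  zero-frequency (constant) mode, which carries no Dirichlet energy; its
  distortion ratio is defined as 1 and the corresponding row of `D_conf`
  is an identity row, so exactly isometric shapes yield `D_conf = I`.
  `D_conf` is stored symmetrised.
* **Standardisation.** In combined LSSD matrices, columns that are
  constant to within numerical noise are mapped to zero rather than
  amplified.
* **Descriptor-commutativity term.** During training, the `E4` operators
  are built for a seeded subsample of descriptor channels per pair (15 by
  default), as in the reference Siamese implementation; the subsample is a
  deterministic function of the pair so the epoch loss is a deterministic
  function of the parameters.

## The synthetic-data generator

No real bone scans ship with the package; `make_collection()` generates
seeded collections that stand in for them with *exact* ground truth:

* One template: an ellipsoid with distinct semi-axes (no continuous
  symmetry) carrying a fixed, asymmetric two-bump "anatomy" shared by
  every specimen — the analogue of homologous features on real bones, and
  what breaks the residual discrete symmetries that would otherwise make
  correspondence ill-posed.
* Group structure mirrors comparative samples: every specimen carries a
  weak bump (height 0.06) at each of the group patches, and group `g`
  enlarges the bump at its own patch by a staggered amount
  (0.12, 0.19, 0.26, ...). Features therefore differ in *size*, never in
  *existence*, and no two groups' enlargements are interchangeable.
  A shared smooth group warp (0.05), a per-specimen idiosyncratic warp
  (0.02) and vertex noise (0.001) complete the deformation model.
* All specimens share the template's connectivity, so the ground-truth
  bijection between any two is the identity permutation and every
  correspondence error is measurable exactly. Five landmarks are placed at
  well-separated template vertices more than 3.5 patch radii away from
  every group patch — as an expert would, on stable shared anatomy.

What the generator does **not** emulate: independent remeshing and varying
triangulation (a `deform_with_known_map()` of a resampled copy provides a
harder variant, at the price of approximate ground truth), scanning holes
and topological noise, allometry, and realistic bone shape statistics.
Passing tests on these fixtures demonstrates the correctness of the
machinery and its behaviour under controlled near-isometric variation —
not performance on any particular real dataset.

## Problem sizes used by the test-suite and the acceptance script

Fixture resolutions are chosen at desk scale: 642-vertex meshes
(subdivision level 3) for pairwise and six-shape analyses, 162-vertex
meshes for the 24-shape (3 x 8) classification collection, a 2,562-vertex
icosphere for the spectral-accuracy check, and maps refined from 20 x 20
to 70 x 70. These sizes keep every analysis reproducible in seconds to
minutes on one CPU while leaving all algorithmic behaviour (truncation,
refinement, latent analysis) identical to larger runs; resolution and
truncation are parameters, not constants.

## Known limitations

* Intrinsic symmetry ambiguity: on exactly symmetric surfaces the WKS is
  symmetry-invariant and the correspondence problem has multiple global
  optima. Real bones (and all fixtures) are asymmetric; perfectly
  symmetric inputs will produce arbitrary-but-consistent symmetric maps.
* The reference descriptor extractor is a deliberately small pointwise
  network over spectral inputs satisfying the extractor contract; a full
  surface-convolution network (rotation-equivariant streams, pooling
  pyramids) can be dropped in behind the same interface but is not
  implemented here.
* Pairwise map estimation scales quadratically in the number of shapes
  when all ordered pairs are refined (the default); a star-graph network
  (`pairs = "star"`) trades some robustness for linear scaling.
* `D_conf` whitening divides by latent eigenvalues; for collections whose
  latent spectrum nearly degenerates (rank collapse is detected and
  reported), conformal LSSDs become noisy before area LSSDs do.
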