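# fmorph: landmark-free geometric morphometrics with functional maps

`fmorph` quantifies the shape of bone surfaces — or any closed triangular
meshes — without landmarks. Instead of matching expert-placed points, it
estimates **functional correspondences** between whole surfaces: linear
maps between the truncated Laplace–Beltrami eigenspaces of each pair of
specimens. It is aimed at morphologists and shape-analysis researchers who
want comprehensive, observer-independent shape variables for collections
of specimens.

## The method in brief

For shapes *S₁*, *S₂* with truncated eigenbases Φ, Ψ and eigenvalue
matrices Λ₁, Λ₂, descriptor fields are projected to spectral coefficients
*A*, *B* and the functional map is the regularised least-squares solution

> C = argmin‖CA − B‖²_F + α‖CΛ₁ − Λ₂C‖²_F,

solved row-wise in closed form. Point-to-point maps are recovered by exact
nearest-neighbour search between spectral embeddings. Maps over a whole
collection are refined jointly by the **Limit Shape / Consistent ZoomOut**
iteration: latent maps *Yᵢ* into a shared "limit shape" functional space
are computed from all pairwise maps (with *C_ij ≈ Y_j Y_i⁺*), new
point-to-point maps are extracted in the common latent coordinates, and
the maps are re-expressed at growing spectral resolution (20×20 up to
70×70 by default).

Shape variation is then summarised per specimen by two **shape-difference
operators** relative to the limit shape — area-based *Yᵢᵀ Yᵢ* and
conformal *Λ₀⁺ Yᵢᵀ Λᵢ Yᵢ* — whose flattened entries are the latent
shape-space differences (**LSSDs**), the package's analogue of Procrustes
shape variables. Downstream tools cover shape-space PCA, distance-matrix
correlations, cross-validated group classification (multinomial logistic,
LDA, naive Bayes, K-means), **weighted distinctive functions** that paint
where two groups differ directly onto a surface, and a landmark-transfer
protocol for validation. An unsupervised Siamese descriptor-learning
module (differentiable functional-map layer + bijectivity / orthogonality
/ commutativity losses) can replace the axiomatic Wave Kernel Signature
descriptors.

Because no public bone scans ship with the package, `make_collection()`
generates seeded synthetic collections — a shared anatomical template with
group-specific feature enlargements and exact ground-truth vertex
correspondence — on which every stage can be validated exactly.

## Worked example

```r
library(fmorph)

coll <- make_collection(n_groups = 2, n_per_group = 3, level = 3, seed = 7)
fit  <- fmorph_pipeline(coll$meshes, coll$groups,
                        k_init = 20, k_final = 70, step = 5)
summary(fit)
#> Landmark-free functional-map shape analysis
#>   shapes: 6 (g1_s1, g1_s2, g1_s3, g2_s1, g2_s2)
#>   refined maps: 30 directed pairs at k = 70
#>   bijective coverage: 0.422 before -> 0.955 after refinement
#>   latent consistency residual: 0.0424
#>   LSSD features: 4900 (area) + 4900 (conformal) per shape
#>   groups: G1 (3), G2 (3)
```

The coverage line says that before joint refinement only 42% of vertices
had a uniquely-claimed partner on the target shape, and 96% after — the
refinement made the maps nearly bijective. The latent consistency residual
is the mean relative error of expressing each pairwise map through the
limit shape (`C_ij ≈ Y_j Y_i⁺`).

```r
pc  <- pca_scores(fit$lssd_area, 0.95)
res <- classify_groups(pc$selected, coll$groups, "logistic",
                       folds = 3, seed = 1)
sprintf("accuracy %.3f +/- %.3f on %d PCs", res$mean, res$sd, pc$n_components)
#> "accuracy 1.000 +/- 0.000 on 1 PCs"

landmark_transfer_error(fit$p2p, fit$meshes, coll$landmarks)[, 1:3]
#>   landmark   mean     sd
#> 1        1 0.0246 0.0218
#> 2        2 0.0249 0.0208
#> 3        3 0.0217 0.0180
#> 4        4 0.0290 0.0241
#> 5        5 0.0246 0.0205
```

The area-based LSSD shape space separates the two synthetic groups
perfectly with a single principal component, and landmarks pushed through
the refined maps land within ~0.02–0.03 unit-area mesh units of their true
positions — below the mean edge length (0.043) of these meshes.

A thin command-line wrapper lives at `inst/cli/morph.R`
(`Rscript morph.R fixtures|preprocess|pipeline|evaluate ...`). The methods
vignette (`vignettes/functional-map-morphometrics.Rmd`) documents the
model, parameter choices, numerical details and the generator's design.

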