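# leafmorph

Comparative leaf morphometrics in R: homologous vascular **landmarks** and
normalized **elliptical Fourier descriptors (EFDs)** of the blade outline,
analysed side by side.

Leaves vary dramatically both between species and between successive nodes
of a single shoot (heteroblasty). The two standard quantifications of that
variation see different things: landmarks placed at vein junctions, lobe
tips and sinuses capture vascular architecture, while EFDs of the outline
capture the continuous curvature of the lamina. `leafmorph` implements the
full comparative pipeline for lobed, *Passiflora*-like leaves:

- **Generalized Procrustes analysis** of 15-landmark configurations
  (translation, scale and rotation removed; reflection permitted), giving
  Procrustes-aligned coordinates `x1..y15`.
- **Elliptical Fourier analysis** of closed outlines: Moore-neighbour
  boundary tracing of binary masks, Kuhl–Giardina harmonic coefficients
  \(A_n, B_n, C_n, D_n\), first-harmonic normalization (size, rotation,
  translation and starting point removed; `A1 = 1`, `B1 = C1 = 0`),
  reconstruction, group means, and amplified per-rank harmonic
  contributions to shape. After normalization, the `B`/`C` coefficients
  carry exactly the left–right **asymmetric** component of shape (mirror
  reflection negates them and preserves `A`/`D`).
- **Morphospaces**: covariance PCA of either trait block, with
  "eigenleaf" reconstructions (mean ± k·SD along a component) as
  landmark configurations or outlines.
- **Discrimination**: leave-one-out linear discriminant analysis
  predicting species (ignoring node) or heteroblastic node (ignoring
  species) from landmark traits, EFD traits, or both; confusion matrices;
  Spearman's rank correlation of actual vs. predicted node; per-group
  feature-set comparison tables.
- **Trait correlation**: pairwise Spearman's ρ across all 30 landmark
  coordinates and 80 harmonic coefficients, with hierarchical clustering
  of traits on `d = 1 − ρ`.
- A parametric **synthetic leaf generator** (species, vine, node and
  asymmetry effects; matching landmark sets and outlines by
  construction), so the whole pipeline is testable end to end without
  image data.

Plain-text formats are used throughout: wide/long landmark tables
(CSV/TSV), NEF harmonic coefficient files, PNG masks, Newick trees.

## Worked example

Generate the default synthetic study (8 species in 4 classes, 3 vines per
species, 10 nodes per vine, one leaf per node), superimpose the landmarks
and ask how well species and node can be predicted:

```r
library(leafmorph)

ds <- synth_dataset(default_species_specs(), vines_per_species = 3,
                    nodes_per_vine = 10, seed = 1)
g <- gpa(ds$table)
g
#> gpa: 240 configurations, 6 iterations, converged
#>   mean residual full-Procrustes distance: 0.1307

pca <- fit_pca(gpa_trait_matrix(g))
pca
#> pca_model: 240 samples, 30 traits
#>   variance explained (PC1..PC4): 52.4%, 21.7%, 13.6%, 4.1%

loo <- loo_predict(gpa_trait_matrix(g), ds$table$records$species)
loo$accuracy
#> [1] 0.9541667

node <- loo_predict(gpa_trait_matrix(g), ds$table$records$node)
node_rank_rho(ds$table$records$node, node$class)
#> $rho 0.3760...  $p 1.76e-09  $n 240
```

The first four landmark PCs explain ~92% of shape variance in this
template. Species identity is recovered at ~95% by leave-one-out LDA on
Procrustes coordinates, while node position — a much subtler, shared
gradient — is recovered only as a significant ordinal trend (ρ ≈ 0.38),
mirroring the usual finding that species differences dominate
heteroblastic ones. A row of the confusion matrix reads as the proportion
of each actual species assigned to each predicted species:

```r
cm <- confusion_matrix(ds$table$records$species, loo$class)
round(cm$proportions[1:3, 1:3], 2)
#>       predicted
#> actual  sp1  sp2 sp3
#>    sp1 1.00 0.00   0
#>    sp2 0.07 0.93   0
#>    sp3 0.00 0.00   1
```

`run_pipeline(run_config(...))` executes everything above plus EFDs, both
morphospaces with eigenleaves, all six LOO-LDA analyses, feature-set
comparison tables, and the trait correlation matrix with clustering,
writing every artifact and a hash manifest into one immutable output
directory.

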