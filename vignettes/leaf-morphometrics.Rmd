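---
title: "Landmarks and elliptical Fourier descriptors for lobed leaves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmarks and elliptical Fourier descriptors for lobed leaves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafmorph)
```

`leafmorph` quantifies leaf shape two complementary ways and compares the
answers. This vignette is the package's account of the underlying methods:
the models, their assumptions, the tunable parameters, the numerical
choices, and what the synthetic data generator does and does not emulate.

## The two shape representations

**Landmarks.** Each leaf carries 15 homologous points: two vein-base pairs
at the petiolar junction (1–2 for the midvein, 5–6 for the proximal
veins), distal vein bases on the midvein (3–4), the proximal lobe tips
(7, 15), distal lobe tips (9, 13), the apex (11), and the four sinus
points between them (8, 14 proximal–distal; 10, 12 distal–apex). The
vein-base pairs make vein width visible to the landmark representation —
a vascular trait the outline cannot see. Configurations are superimposed
by generalized Procrustes analysis (GPA): each is centered and scaled to
unit centroid size (the square root of summed squared distances from the
centroid), then iteratively rotated — reflection permitted — onto the
running mean shape, which is re-estimated and re-unit-sized until its
Frobenius movement falls below `tol`.

*Numerical choices.* `tol = 1e-10`, `max_iter = 200`; non-convergence is
flagged on the result, not thrown. The per-shape rotation comes from the
SVD of the 2×2 cross-product matrix; when reflection is allowed but gains
nothing (the smaller singular value is ~0), the proper rotation
(determinant +1) is chosen for determinism. The iteration is the standard
alternating scheme and converges to the leading-eigenvector
full-Procrustes mean; its objective (summed squared deviations from the
mean) is recorded per iteration and is non-increasing. PCA runs directly
on the aligned coordinates without tangent-space projection: shape
variation in leaf datasets of this kind is small enough that the
projection is second-order, and the aligned coordinates keep the trait
columns interpretable as `x1..y15`.

**Elliptical Fourier descriptors.** A closed outline traversed at
arc-length parameterization has coordinate functions \(x(t), y(t)\) with
period \(T\) (the perimeter); their Fourier series coefficients per
harmonic rank \(n\) are the EFDs \(A_n, B_n\) (for \(x\)) and
\(C_n, D_n\) (for \(y\)). For a polygon they have a closed form per
segment (the Kuhl–Giardina line integrals), which the package uses; a
`chain_code` mode instead weights every segment equally in time, the
convention of chain-code programs (and the parameterization under which
an ellipse's series is exact). Low ranks encode the coarse, trilobed
form; high ranks encode serration-scale detail, which can be visualized
by amplifying a single rank's coefficients.

Normalization uses the first-harmonic ellipse: a start-point phase
\(\theta_1 = \tfrac12 \operatorname{atan2}\!\big(2(A_1B_1 + C_1D_1),\,
A_1^2 + C_1^2 - B_1^2 - D_1^2\big)\) rotates each rank-\(n\) block by
\(n\theta_1\); the orientation \(\psi_1 = \operatorname{atan2}(C_1^*,
A_1^*)\) is removed spatially; the scale \(E = \sqrt{A_1^{*2} +
C_1^{*2}}\) divides everything. The result satisfies \(A_1 = 1\),
\(B_1 = C_1 = 0\) and is invariant to rotation, translation, scale and
start point.

*The residual 180° ambiguity.* Shifting the start by half a period while
rotating the shape 180° leaves \(A_1 = 1\) intact and flips exactly the
even-rank blocks, so a rule on the first harmonic cannot canonicalize
the frame. The package requires the **largest-magnitude even-rank
\(A\)/\(D\) entry** to be positive. Anchoring on the largest entry makes
the choice stable under perturbation (a near-zero anchor would flip sign
with noise and masquerade as shape variance), and because the
\(A\)/\(D\) coefficients are mirror-invariant the rule commutes with
reflection — so reflecting a contour about the normalization axis still
negates exactly the \(B\)/\(C\) coefficients. That identity is what
makes the \(B\)/\(C\) block interpretable as the asymmetric component of
shape variation, and the sign of \(D_1\) (first-harmonic chirality) is
deliberately retained. Contours are resampled to 500 equally spaced
points before analysis (configurable) to stabilize coefficients across
image resolutions, and 20 harmonic ranks are kept by default.

## Morphospaces and eigenleaves

Both trait blocks — 30 Procrustes coordinates, 80 harmonic coefficients —
are decomposed by **covariance** PCA (traits share units within a block;
correlation scaling would inflate noise-dominated coefficients).
Constant columns, notably the normalization invariants \(A_1, B_1,
C_1\), are dropped before decomposition and restored at their constant
values on reconstruction. Component signs follow the convention that the
largest-magnitude loading entry is positive, so eigenleaf orientations
are reproducible. An *eigenleaf* is the mean trait vector displaced
\(\pm k\sqrt{\lambda_j}\) along loading \(j\) and rendered as landmarks
or (via the inverse Fourier series) as an outline; at 0 SD it is exactly
the mean, and the ±k pair averages back to the mean by linearity.

## Discrimination and trait correlation

Species (ignoring node) and node (ignoring species) are predicted by
Gaussian LDA with pooled within-class covariance, evaluated strictly by
leave-one-out cross-validation: every leaf is predicted by a model that
never saw it, which also compensates for unequal replication across
species and vines. Priors are the class frequencies of the full label
vector in every fold (the convention of the classical leave-one-out LDA
implementation), and within folds a class reduced to one training
sample is tolerated — it contributes a mean but no scatter. Near-constant
traits are screened out; if the pooled covariance is still numerically
singular (as happens with large harmonic blocks), a ridge of
`1e-8 · trace/dim` is added once and recorded. Raw trait matrices are
the default LDA input; substituting PC scores is possible by passing
`fit_pca()` scores, but the default keeps the pipeline self-contained
and the trait attributions direct. Node is treated as a categorical
class for the confusion matrix and as an ordinal only in the Spearman
summary of actual vs. predicted node.

All traits together are cross-correlated by tie-corrected Spearman's ρ
with two-sided p from the t approximation. Traits are clustered
agglomeratively on `d = 1 − ρ` (signed, complete linkage by default):
strongly anticorrelated traits are treated as maximally distant, which
keeps sign structure visible in the dendrogram; `1 − |ρ|` and other
linkages are available. `d` satisfies symmetry and zero self-distance
but not the triangle inequality — acceptable for agglomerative use.
Columns are ordered lexicographically before clustering so leaf order is
deterministic under ties.

## The synthetic study template

The generator builds each leaf from interpretable parameters — midvein
length, lobe lengths and angles, sinus depth fractions, vein half-width,
asymmetry, serration — places the 15 landmarks from them, and draws the
outline as a periodic cubic spline through the nine blade landmarks plus
a basal closure point, so landmark and contour data are mutually
consistent by construction. The default template has 8 species in 4
classes (2 per class), 3 vines per species and 10 nodes per vine
(240 leaves), a desk-scale analogue of a multi-species heteroblasty
study; the same template at reduced size backs the fast unit tests.

Three of its choices deserve explanation:

- **Class separation is calibrated by definition.** The `separation`
  argument is the minimum pairwise distance between species mean
  parameters in units of the *effective* within-species SD — sampling
  noise plus the spread the heteroblastic gradient induces along a
  10-node vine. The species offset patterns fix directions in parameter
  space; they are rescaled as a whole so the closest pair sits exactly
  `separation` SDs apart. At the default `separation = 3` the closest
  species pair has a two-class Bayes error of Φ(−1.5) ≈ 6.7%, so
  leave-one-out species accuracy lands around 90–95%.
- **The heteroblastic gradient is monotone and shared.** Each node adds
  a fixed shift to sinus depths and distal lobe length (deeper lobing
  toward the tip) and a slight negative trend to vein width, for every
  species alike. Node is therefore recoverable as an ordinal trend but —
  being small relative to species differences — only weakly as a class,
  matching the qualitative structure such studies report.
- **Asymmetry is a balanced, signed skew.** A leaf with asymmetry \(a\)
  has left-side radii scaled by \(1+a\) and right-side by \(1/(1+a)\),
  with \(a \sim N(0, 0.03)\) per leaf, independent of species and node.
  This is the standard fluctuating-asymmetry picture and is
  antisymmetric to first order, so it feeds the \(B\)/\(C\) harmonic
  block and almost nothing else. A one-sided scaling (or a one-sided
  magnitude distribution) would leak strongly into the symmetric
  \(A\)/\(D\) coefficients through its first-order symmetric component
  and the near-collinearity of \(a\) and \(a^2\) on a half-line — which
  is why those alternatives were rejected.

What the generator does **not** emulate: real scan artefacts
(segmentation noise, petiole remnants, holes), serration at realistic
tooth counts, venation beyond the landmark skeleton, allometric
correlation between size and shape, and phylogenetic structure among
species. Passing tests therefore demonstrate that the pipeline's
mathematics and software are correct and that its statistical behaviour
matches theory on clean data of realistic geometry — not that any
particular biological dataset will reach the same accuracies.

## Degenerate inputs and edge behaviour

All-coincident landmark configurations, empty masks, multi-component
masks in single-leaf mode, contours with fewer than three distinct
points, and first harmonics with vanishing energy are rejected with
specific errors. A PCA of identical samples returns a zero-component
model rather than erroring; a single non-constant trait yields a
one-component model (reachable with `n_harmonics = 1`, where only
\(D_1\) survives screening — the pipeline completes with a warning).
Feature-set comparison resolves exact accuracy ties Both > Landmark >
EFD, and groups with a single sample are excluded from per-group tables
with a warning.

## Problem sizes

The packaged analyses are sized for a desk machine: the default template
(240 leaves, 20 harmonics, 110 traits in the combined block) runs the
full pipeline — GPA, EFDs, two PCAs, six leave-one-out LDAs, the 110×110
Spearman matrix and clustering — in well under a minute, and the unit
tests use reduced templates of 24–64 leaves.
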