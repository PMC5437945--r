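Package: leafmorph
Title: Comparative Leaf Morphometrics with Landmarks and Elliptical Fourier Descriptors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for comparative analysis of leaf shape combining two
    complementary morphometric descriptions: generalized Procrustes analysis of
    homologous vascular landmarks, and normalized elliptical Fourier descriptors
    (EFDs) of the blade outline. Both trait sets are projected into principal
    component morphospaces ("eigenleaves"), used in leave-one-out linear
    discriminant analysis to predict species identity and heteroblastic node
    position, and cross-correlated trait by trait with hierarchical clustering
    of the correlation structure. A parametric generator of lobed,
    Passiflora-like leaves (homologous landmarks plus matching closed outlines,
    with species, vine, node and asymmetry effects) makes every stage testable
    without image data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    png,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    vegan,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
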