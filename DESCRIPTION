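Package: mboplsr
Title: Multi-Block OPLS Regression for Metabolome-Trait Association
Version: 0.1.0
Authors@R: person("mboplsr", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Latent-variable regression of quantitative traits on multi-platform
    metabolomics data. Implements single-response OPLS (orthogonal projections to
    latent structures), a two-step multi-block extension (per-block OPLS filtering
    of response-orthogonal variance, concatenation, top-level OPLS), nested
    seven-fold cross-validation with the rCV2 statistic and permutation P-values,
    a bootstrap/permutation kernel-density feature-relevance score (log B),
    complementary Spearman screening with Benjamini-Hochberg FDR control, Mantel
    tests, subtype differential abundance, correlation networks, preprocessing
    (log2 transform, unit-variance scaling, missing-value filtering, annotation
    based peak summarization, population-structure correction of traits,
    missing-value tolerant NIPALS PCA), and a seeded synthetic multi-block data
    generator for testing the whole pipeline without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
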