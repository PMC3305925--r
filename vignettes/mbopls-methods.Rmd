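---
title: "Multi-block OPLS for metabolome-trait association: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-block OPLS for metabolome-trait association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mboplsr)
```

## The model

`mboplsr` regresses one quantitative trait at a time on several
sample-by-feature abundance blocks (one per analytical platform). The
statistical backbone is OPLS with a single response: a block
$X$ (autoscaled) is decomposed as

$$X = t\,p^\top + T_O P_O^\top + E,$$

where $t = Xw$ is the predictive score ($w \propto X^\top y$, unit norm),
the columns of $T_O$ are structured variance orthogonal to the response,
and $E$ is unmodelled. With a single response the predictive weight $w$ is
invariant under orthogonal deflation ($X^\top y$ does not change when
$t_O^\top y = 0$), so the package computes $w$ once and then peels
orthogonal components off one at a time: $p = X^\top t / t^\top t$,
$w_O \propto p - (w^\top p)\,w$, $t_O = X w_O$,
$p_O = X^\top t_O / t_O^\top t_O$, $X \leftarrow X - t_O p_O^\top$.
Prediction deflates new samples by the stored $(w_O, p_O)$ pairs and
applies $\hat y = c\,(X_\text{filtered} w)$ with
$c = y^\top t / t^\top t$. Exactly one predictive component is used
throughout: the response is a single vector, and additional predictive
components of a single-$y$ PLS would model variance that the orthogonal
components already absorb.

The multi-block extension is deliberately simple. Step one fits an OPLS
model per block and discards each block's trait-orthogonal part — this is
where platform-specific systematic bias is removed. Step two concatenates
the filtered blocks ($t_i p_i^\top + E_i$, equal to
$X_i - T_{i,O} P_{i,O}^\top$) along the feature axis and fits one top-level
OPLS model on the concatenation. The model therefore has $n_\text{blocks} + 1$
structural parameters: the per-block orthogonal counts and the top-level
count. With one block and a zero block-level count the two steps collapse
into ordinary OPLS exactly; the test suite asserts this to $10^{-10}$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_orth_per_block` | selected | trait-orthogonal components removed per block |
| `n_orth_top` | selected | orthogonal components of the top-level model |
| `n_folds` | 7 | internal and external CV fold count |
| `n_repeats` | 50 | external CV repeats; the median rCV² is reported |
| `n_perm` | 1000 | trait shuffles of the permutation test |
| `prior_h0` | 0.95 | a-priori null probability of the log B score |
| `max_missing_fraction` | 0.3 | feature exclusion threshold |
| `correlation_threshold` | 0.5 | same-annotation peak merging threshold |

Component counts are chosen by internal seven-fold CV with
$Q^2 = 1 - \mathrm{PRESS}/\mathrm{TSS}$ (TSS about the training-fold mean,
pooled over folds). The counts are selected *sequentially*: each block's
count independently against the trait, then the top-level count with the
block counts frozen. A joint search over all $n_\text{blocks}+1$ counts
would be exponential and is not what the two-step structure of the method
suggests; the greedy rule (climb while $Q^2$ strictly improves, stop at the
first non-improvement) is a declared design choice, not an inference from
the method's description. The $Q^2$ curve for counts $0..k_{\max}$ is
computed in one incremental fitting pass per fold, which is algebraically
identical to refitting at every count because $w$ survives deflation.

## Validation

`external_cv()` implements fully nested cross-validation: within every
external training portion the component counts are re-selected by internal
CV before fitting, and the held-out segment is predicted with training-fold
centers and scales. Anything less re-uses held-out information in the
selection step. The suite contains an explicit leakage audit: corrupting a
held-out sample's trait value must leave its out-of-fold prediction
bitwise unchanged.

`permutation_test()` shuffles the trait, reruns the identical nested
machinery once per shuffle (the observed statistic uses the full repeat
count; one CV run per permutation is the standard cost economy), and
reports the biased estimator $P_{CV} = (n_0 + 1)/(n_\text{perm} + 1)$ with
ties counted toward the null — conservative in the direction that matters.

## Feature selection

The correlation loading $p_C$ of a feature is its Pearson correlation with
the top-level predictive score, computed on the orthogonal-filtered
matrix. Its sampling density $d(p_C)$ is estimated by bootstrap refits
(samples resampled with replacement; component counts frozen at the
full-data selection to stabilise the sampling distribution and bound
cost), the null density $d(p_C \mid H_0)$ by trait-permutation refits.
Both are Gaussian KDEs (Silverman bandwidth, floor $10^{-12}$) evaluated
at the full-data loading — the formula itself does not name the evaluation
point; evaluating at the observed loading is the natural reading and is
fixed here. Then

$$b = \frac{d(p_C)\,(1 - P(H_0))}{d(p_C)\,(1 - P(H_0)) + d(p_C \mid H_0)\,P(H_0)},
\qquad \log B = \ln\frac{b}{1 - b},$$

with $P(H_0) = 0.95$; natural logarithm (the $\log B > 0$ selection rule is
base-invariant). An important structural property: under trait
permutation the predictive score aligns with the dominant variance of $X$,
so the null loading distribution of features correlated with that
structure is wide or even bimodal. The prior plus this data-driven null
makes the score conservative — under fully null synthetic data fewer than
10 % of features reach $\log B > 0$, which the acceptance suite checks.

The Spearman arm (`spearman_screen()`, t-approximation p-values, average
ranks on ties, in-package Benjamini-Hochberg step-up) is deliberately
bivariate and model-free; a feature is reported as selected when either
arm fires, with both flags stored separately.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` defaults state a small rice-diversity-panel-like world:
70 samples, four platform blocks of 200/150/100/80 features, three
subpopulations (Dirichlet memberships, concentration 0.3), one orthogonal
latent per block, 20 informative features per block with loadings of
magnitude ~1 against feature noise sd 0.3, 5 % missing cells, and 70 % of
the corrected-trait variance carried by the shared latent. Population
offsets act on both trait and features (effect size 0.5) so the
structure-correction step does real work. All draws come from one seeded
stream in a documented order; datasets are bitwise reproducible.

One generator detail matters for calibration studies:
`generate_dataset()` plants the block-specific latents strictly orthogonal
to the trait (that is the stated decomposition — platform bias is
trait-uncorrelated), but `generate_null_dataset()` must *not* do this.
Orthogonalizing block structure against a supposedly independent trait
couples the two: the observed trait becomes special among its own
permutations, and permutation p-values drift low. Null datasets therefore
draw the trait independently and leave it out of every orthogonalization.

The generator does *not* emulate instrument realities: intensity-dependent
noise, retention-time drift, batch effects within a platform, annotation
ambiguity, or missingness that correlates with abundance (its missingness
is completely at random). A green test therefore establishes that the
algorithms recover the stated latent structure at the stated noise — not
that the pipeline is robust to structured missingness or to platform
artefacts beyond a single orthogonal latent per block.

## Numerical choices and degenerate inputs

* Orthogonal extraction stops with an error when $\lVert w_O \rVert <
  10^{-10}$ before normalisation ("insufficient orthogonal variance").
* A constant trait, a zero-variance feature after scaling, and an
  all-missing feature are hard errors, each naming the offender.
* Missing cells surviving the 30 % filter are imputed with the feature
  mean (zero after scaling) — the minimal-assumption fill-in for a
  complete-matrix method; recorded in the preprocessing metadata.
* First-PC sign in peak merging is oriented to correlate positively with
  the subgroup's mean profile (PCA signs are otherwise arbitrary).
* Peak merging groups by mean pairwise *absolute* correlation: peaks of
  one metabolite can be anti-correlated (e.g. competing adducts) yet carry
  the same signal; signed averaging would cancel exactly the clearest
  merge candidates.
* The Q-matrix regression adds no intercept (membership rows sum to one,
  so the column space already contains it) and uses an SVD pseudoinverse,
  making rank-deficient Q safe.
* Fold partitions are balanced random assignments drawn from the seed;
  every repeat, permutation and bootstrap replicate derives its own child
  seed, so results are independent of execution order.

## Known limitations

* **Permutation tests on structure-corrected traits are mildly
  anticonservative.** Projecting a trait off the Q-matrix leaves the
  observed trait orthogonal to the Q-subspace, but its permutations are
  not; when the blocks themselves carry Q-driven variance, the observed
  rCV² then stochastically beats the permutation null even without any
  real association. The effect is a property of the permute-after-correct
  procedure, not of this implementation. The package's null-calibration
  check therefore uses traits that genuinely carry no population effect;
  P_CV values for corrected traits over structured panels should be read
  as slightly optimistic.

* Sequential component selection can differ from a joint optimum when a
  block's orthogonal structure only matters in combination with another
  block; the greedy stop rule also cannot skip over a locally flat $Q^2$.
* One CV run per permutation makes individual null draws noisy; with
  $n_\text{perm} = 1000$ the estimator is stable, but small permutation
  counts should be read with that in mind.
* The log B evaluation point (observed loading) is one of several
  defensible readings of the density-ratio formula; an integrated variant
  is not implemented.
* The Mantel test is the classical lower-triangle Pearson version with a
  one-sided positive alternative; no partial-Mantel or rank variant.
* Everything is single-trait; multi-response extensions (O2PLS-type) are
  out of scope.
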