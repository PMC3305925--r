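# Seeded generator for multi-block datasets with the statistical structure
# the multi-block OPLS model assumes: one shared trait-correlated latent,
# block-specific trait-orthogonal latents (platform bias), population
# structure affecting both trait and features, sparse informative features,
# Gaussian noise, and missing-at-random cells. Every draw comes from a
# single seeded RNG stream in a documented order, so fixtures are stable.

#' Specification of a synthetic multi-block dataset
#'
#' Defaults mirror the shape of a small rice diversity panel profiled on
#' four MS platforms with three genetic subpopulations: 70 samples, blocks
#' of 200/150/100/80 features, one orthogonal (platform-bias) latent per
#' block, 20 informative features per block, feature noise sd 0.3, 5\%
#' missing cells, and 70\% of the (structure-corrected) trait variance
#' carried by the shared latent.
#'
#' @param n_samples,n_blocks,features_per_block dataset shape.
#' @param n_subpopulations number of subpopulations in the Q-matrix.
#' @param dirichlet_concentration concentration of the per-sample Dirichlet
#'   membership draw (small values give crisp assignments).
#' @param trait_signal_strength fraction of trait variance carried by the
#'   shared latent, in `[0, 1]`.
#' @param n_orth_latents_per_block,orth_variance_scale count and loading sd
#'   of block-specific trait-orthogonal latents.
#' @param n_informative_features_per_block,loading_scale sparsity and
#'   magnitude of the trait-correlated loadings; `NULL` defaults to
#'   `min(20, block size)` per block.
#' @param noise_sd per-cell Gaussian noise sd.
#' @param missing_fraction fraction of cells set missing completely at
#'   random.
#' @param population_effect_size strength of the subpopulation offsets on
#'   both trait and features (0 disables).
#' @param seed integer seed.
#' @return an object of class `SyntheticSpec`.
#' @export
synthetic_spec <- function(n_samples = 70L, n_blocks = 4L,
                           features_per_block = c(200L, 150L, 100L, 80L),
                           n_subpopulations = 3L,
                           dirichlet_concentration = 0.3,
                           trait_signal_strength = 0.7,
                           n_orth_latents_per_block = 1L,
                           orth_variance_scale = 1,
                           n_informative_features_per_block = NULL,
                           loading_scale = 1, noise_sd = 0.3,
                           missing_fraction = 0.05,
                           population_effect_size = 0.5, seed = 1L) {
  features_per_block <- as.integer(rep_len(features_per_block, n_blocks))
  if (is.null(n_informative_features_per_block)) {
    n_informative_features_per_block <- pmin(20L, features_per_block)
  }
  n_inf <- as.integer(rep_len(n_informative_features_per_block, n_blocks))
  .assert(n_samples >= 4L && n_blocks >= 1L, "invalid shape")
  .assert(all(features_per_block >= 1L), "features_per_block must be positive")
  .assert(all(n_inf <= features_per_block),
          "more informative features than features in a block")
  .assert(trait_signal_strength >= 0 && trait_signal_strength <= 1,
          "trait_signal_strength must be in [0, 1]")
  .assert(missing_fraction >= 0 && missing_fraction < 1,
          "missing_fraction must be in [0, 1)")
  .assert(noise_sd >= 0 && orth_variance_scale >= 0 &&
            population_effect_size >= 0 && loading_scale >= 0,
          "scales must be nonnegative")
  structure(list(n_samples = as.integer(n_samples),
                 n_blocks = as.integer(n_blocks),
                 features_per_block = features_per_block,
                 n_subpopulations = as.integer(n_subpopulations),
                 dirichlet_concentration = dirichlet_concentration,
                 trait_signal_strength = trait_signal_strength,
                 n_orth_latents_per_block = as.integer(n_orth_latents_per_block),
                 orth_variance_scale = orth_variance_scale,
                 n_informative_features_per_block = n_inf,
                 loading_scale = loading_scale, noise_sd = noise_sd,
                 missing_fraction = missing_fraction,
                 population_effect_size = population_effect_size,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

# Standardize to exactly zero mean / unit sample sd.
.std <- function(v) (v - mean(v)) / stats::sd(v)

# Residualize v against the columns of M (with intercept), then standardize.
.orthogonalize <- function(v, M) {
  .std(stats::lm.fit(cbind(1, M), v)$residuals)
}

.generate_internal <- function(spec, null_trait = FALSE,
                               population_trait_effect = TRUE) {
  set.seed(spec$seed)
  n <- spec$n_samples
  sids <- sprintf("S%03d", seq_len(n))

  # Draw order: (1) Q rows, (2) trait group offsets, (3) shared latent,
  # (4) trait noise, (5) per block: informative index/loadings, orthogonal
  # latents + loadings, population feature offsets, noise, missing mask.
  g <- matrix(stats::rgamma(n * spec$n_subpopulations,
                            shape = spec$dirichlet_concentration),
              n, spec$n_subpopulations)
  Q <- g / rowSums(g)
  rownames(Q) <- sids
  colnames(Q) <- paste0("pop", seq_len(spec$n_subpopulations))
  q <- population_membership(Q)

  offs <- .std(stats::rnorm(spec$n_subpopulations))
  pop_term <- drop(Q %*% offs)

  t_shared <- .std(stats::rnorm(n))
  s <- spec$trait_signal_strength
  eps <- stats::rnorm(n)
  y_core <- if (null_trait) .std(eps) else
    sqrt(s) * t_shared + sqrt(1 - s) * .std(eps)
  y <- y_core + if (population_trait_effect)
    spec$population_effect_size * pop_term else 0
  trait <- trait_vector(stats::setNames(y, sids), name = "trait")

  blocks <- vector("list", spec$n_blocks)
  informative <- vector("list", spec$n_blocks)
  orth_scores <- vector("list", spec$n_blocks)
  for (i in seq_len(spec$n_blocks)) {
    p <- spec$features_per_block[i]
    n_inf <- spec$n_informative_features_per_block[i]
    w <- numeric(p)
    inf_idx <- integer(0)
    if (!null_trait && n_inf > 0) {
      inf_idx <- sort(sample.int(p, n_inf))
      w[inf_idx] <- spec$loading_scale *
        sample(c(-1, 1), n_inf, replace = TRUE) *
        stats::runif(n_inf, 0.8, 1.2)
    } else if (n_inf > 0) {
      # burn the same draws so null and signal datasets share geometry
      invisible(sample.int(p, n_inf))
      invisible(sample(c(-1, 1), n_inf, replace = TRUE))
      invisible(stats::runif(n_inf))
    }
    X <- tcrossprod(t_shared, w)
    T_o <- matrix(0, n, spec$n_orth_latents_per_block)
    for (k in seq_len(spec$n_orth_latents_per_block)) {
      # orthogonal (platform-bias) latents are planted strictly orthogonal
      # to the trait-correlated structure; a null trait is left alone —
      # exact orthogonalization against an independent trait would couple
      # the blocks to it and break permutation exchangeability
      orth_against <- if (null_trait) cbind(t_shared) else cbind(t_shared, y)
      t_o <- .orthogonalize(stats::rnorm(n), orth_against)
      p_o <- stats::rnorm(p, sd = spec$orth_variance_scale)
      X <- X + tcrossprod(t_o, p_o)
      T_o[, k] <- t_o
    }
    if (spec$population_effect_size > 0) {
      G <- matrix(stats::rnorm(spec$n_subpopulations * p,
                               sd = spec$population_effect_size),
                  spec$n_subpopulations, p)
      X <- X + Q %*% G
    }
    X <- X + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    if (spec$missing_fraction > 0) {
      X[matrix(stats::runif(n * p) < spec$missing_fraction, n, p)] <- NA
    }
    rownames(X) <- sids
    colnames(X) <- sprintf("B%d_F%03d", i, seq_len(p))
    blocks[[i]] <- omics_block(X, platform = paste0("platform", i))
    informative[[i]] <- inf_idx
    orth_scores[[i]] <- T_o
  }

  structure(list(blocks = blocks, trait = trait, q = q,
                 truth = list(informative = informative,
                              latent = t_shared,
                              orth_scores = orth_scores,
                              group_offsets = offs,
                              null = null_trait),
                 spec = spec),
            class = "SyntheticDataset")
}

#' Generate a synthetic multi-block dataset
#'
#' @param spec a [synthetic_spec()].
#' @return an object of class `SyntheticDataset`: `blocks` (list of
#'   [omics_block()]s), `trait`, `q` (population membership), `truth`
#'   (informative feature indices per block, the shared latent, orthogonal
#'   scores, group offsets), and the spec.
#' @export
generate_dataset <- function(spec) {
  .generate_internal(spec, null_trait = FALSE)
}

#' Generate a null dataset (trait independent of all latent structure)
#'
#' Identical block geometry, but the trait is drawn independently of the
#' shared latent and all informative loadings are zero; the truth lists are
#' empty. The population effect on the trait is kept or dropped by flag.
#'
#' @param spec a [synthetic_spec()].
#' @param population_trait_effect keep the subpopulation offsets on the
#'   trait (default `FALSE`: trait fully independent).
#' @export
generate_null_dataset <- function(spec, population_trait_effect = FALSE) {
  .generate_internal(spec, null_trait = TRUE,
                     population_trait_effect = population_trait_effect)
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf("SyntheticDataset: %d samples, %d block(s) [%s features]%s\n",
              x$spec$n_samples, x$spec$n_blocks,
              paste(x$spec$features_per_block, collapse = ", "),
              if (x$truth$null) ", null trait" else ""))
  invisible(x)
}
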