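# Multi-block OPLS: top-level regressor construction, fitting, prediction,
# component selection.

test_that("build_top_regressors concatenates filtered blocks", {
  set.seed(1)
  n <- 30
  y <- rnorm(n); yc <- y - mean(y)
  A <- random_scaled(n, 6, 2)
  B <- random_scaled(n, 4, 3)
  mA0 <- fit_opls(A, yc, 0)
  mB0 <- fit_opls(B, yc, 0)
  # no filtering: plain concatenation of the scaled blocks
  expect_max_abs(build_top_regressors(list(mA0, mB0)) - cbind(A, B), 1e-12)
  # one block: the block's filtered matrix
  mA1 <- fit_opls(A, yc, 1)
  expect_max_abs(build_top_regressors(list(mA1)) - mA1$X_filtered, 1e-12)
})

test_that("filtered concatenation contains no planted orthogonal variance", {
  d1 <- planted_opls_data(n = 40, p = 15, noise_sd = 0, seed = 11)
  d2 <- planted_opls_data(n = 40, p = 10, noise_sd = 0, seed = 12)
  # same y for both blocks
  X2 <- tcrossprod(d1$y, d2$p_vec) + tcrossprod(d2$t_o, d2$p_o)
  m1 <- fit_opls(d1$X, d1$y, 1)
  m2 <- fit_opls(X2, d1$y, 1)
  top <- build_top_regressors(list(m1, m2))
  # projections of X_Top columns onto the planted orthogonal score directions
  expect_max_abs(crossprod(top, d1$t_o) / sqrt(sum(d1$t_o^2)), 1e-6)
})

test_that("single-block MB-OPLS reduces to ordinary OPLS and PLS1", {
  set.seed(20)
  X <- matrix(rnorm(40 * 30), 40, 30)
  y <- rnorm(40)
  Xs <- scale(X)[, , drop = FALSE]
  yc <- y - mean(y)
  # zero everywhere: one-component PLS1
  mb0 <- fit_mbopls(list(X), y, 0, 0)
  expect_max_abs(predict_mbopls(mb0, list(X)) -
                   (pls1_oracle(Xs, yc)$fitted + mean(y)), 1e-10)
  # block count 0, top count k: ordinary OPLS(k)
  for (k in 1:2) {
    mb <- fit_mbopls(list(X), y, 0, k)
    mo <- fit_opls(Xs, yc, k)
    expect_max_abs(predict_mbopls(mb, list(X)) -
                     (predict_opls(mo, Xs)$y_hat + mean(y)), 1e-10)
  }
})

test_that("generative multi-block structure is recovered at true counts", {
  # trait essentially equal to the shared latent: the fit must recover it
  spec <- synthetic_spec(n_samples = 60, n_blocks = 3,
                         features_per_block = c(40, 30, 20),
                         n_informative_features_per_block = 10,
                         trait_signal_strength = 0.98,
                         missing_fraction = 0, population_effect_size = 0,
                         noise_sd = 0.3, seed = 30)
  ds <- generate_dataset(spec)
  blocks <- lapply(ds$blocks, function(b) b$values)
  y <- ds$trait$values
  m <- fit_mbopls(blocks, y, n_orth_per_block = 1, n_orth_top = 0)
  r2 <- cor(fitted(m), y)^2
  expect_gt(r2, 0.95)
})

test_that("prediction is invariant to block-orthogonal perturbations and
           reproduces training fits", {
  spec <- synthetic_spec(n_samples = 40, n_blocks = 2,
                         features_per_block = c(20, 15),
                         n_informative_features_per_block = 8,
                         missing_fraction = 0, population_effect_size = 0,
                         seed = 31)
  ds <- generate_dataset(spec)
  blocks <- lapply(ds$blocks, function(b) b$values)
  y <- ds$trait$values
  m <- fit_mbopls(blocks, y, 1, 1)
  pr <- predict_mbopls(m, blocks)
  expect_max_abs(pr - fitted(m), 1e-10)

  # perturb block 1 along its fitted orthogonal loading (on the scaled
  # scale, mapped back to raw units)
  set.seed(32)
  pert <- outer(rnorm(40, sd = 3), m$block_models[[1]]$P_orth[, 1] *
                  m$scales[[1]])
  blocks_p <- blocks
  blocks_p[[1]] <- blocks[[1]] + pert
  expect_max_abs(predict_mbopls(m, blocks_p) - pr, 1e-8)
})

test_that("select_components finds planted counts and is deterministic", {
  hits <- 0L; tries <- 0L
  for (seed in 1:10) {
    spec <- synthetic_spec(n_samples = 60, n_blocks = 2,
                           features_per_block = c(40, 30),
                           n_informative_features_per_block = 12,
                           n_orth_latents_per_block = 1,
                           missing_fraction = 0, population_effect_size = 0,
                           noise_sd = 0.3, seed = 400 + seed)
    ds <- generate_dataset(spec)
    blocks <- lapply(ds$blocks, function(b) b$values)
    sel <- select_components(blocks, ds$trait$values, 3, 3, seed = seed)
    hits <- hits + sum(sel$n_orth_per_block == 1L)
    tries <- tries + length(sel$n_orth_per_block)
  }
  # planted truth: one orthogonal latent per block, recovered in >= 90%
  # of block instances
  expect_gte(hits / tries, 0.9)

  # determinism: same data, same seed, identical selection
  spec <- synthetic_spec(n_samples = 40, n_blocks = 2,
                         features_per_block = c(20, 15),
                         missing_fraction = 0, seed = 77)
  ds <- generate_dataset(spec)
  blocks <- lapply(ds$blocks, function(b) b$values)
  s1 <- select_components(blocks, ds$trait$values, 2, 2, seed = 5)
  s2 <- select_components(blocks, ds$trait$values, 2, 2, seed = 5)
  expect_identical(s1[c("n_orth_per_block", "n_orth_top", "cv_curves")],
                   s2[c("n_orth_per_block", "n_orth_top", "cv_curves")])
})

test_that("pure-noise response selects the smallest scanned counts", {
  set.seed(50)
  blocks <- list(matrix(rnorm(50 * 30), 50, 30),
                 matrix(rnorm(50 * 20), 50, 20))
  y <- rnorm(50)
  sel <- select_components(blocks, y, 3, 3, seed = 50)
  # no true signal: the greedy rule should stop essentially immediately
  expect_true(all(sel$n_orth_per_block <= 1))
  expect_lte(sel$n_orth_top, 1)
})
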