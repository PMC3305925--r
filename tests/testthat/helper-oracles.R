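# Independent oracles and small fixture builders. These deliberately avoid
# the package's own code paths: PLS1 by textbook NIPALS, BH by literal
# transcription of the step-up definition, Spearman by hand-ranking.

# One-component PLS1 (NIPALS): returns fitted values for centered y,
# plus w/t for structural comparisons.
pls1_oracle <- function(X, y) {
  w <- drop(t(X) %*% y)
  w <- w / sqrt(sum(w^2))
  t_vec <- drop(X %*% w)
  q <- sum(y * t_vec) / sum(t_vec^2)
  list(fitted = q * t_vec, w = w, t = t_vec, q = q)
}

# Literal BH step-up: q_(i) = min_{j >= i} min(1, m * p_(j) / j), mapped
# back to the input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Random scaled fixture (complete).
random_scaled <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  scale(X)[, , drop = FALSE]
}

# Planted single-block OPLS structure: X = t p' + t_o p_o' + noise,
# with t proportional to y and t_o orthogonal to both y and t.
planted_opls_data <- function(n = 40, p = 25, noise_sd = 0, seed = 1) {
  set.seed(seed)
  y <- rnorm(n)
  y <- (y - mean(y)) / sd(y)
  t_o <- lm.fit(cbind(1, y), rnorm(n))$residuals
  t_o <- t_o / sd(t_o)
  p_vec <- rnorm(p)
  p_o <- rnorm(p)
  X <- tcrossprod(y, p_vec) + tcrossprod(t_o, p_o) +
    matrix(rnorm(n * p, sd = noise_sd), n, p)
  list(X = X, y = y, t_o = t_o, p_o = p_o, p_vec = p_vec)
}

# A small multi-block dataset, preprocessed and (optionally) structure-
# corrected, ready for modelling. Returns plain matrices plus the trait.
# Correction is skipped for null traits generated without a population
# effect: projecting such a trait off Q makes it orthogonal to the
# Q-subspace while permuted copies are not, which breaks permutation
# exchangeability against structure-bearing blocks.
prepared_synthetic <- function(spec, null = FALSE, correct = !null, ...) {
  ds <- if (null) generate_null_dataset(spec, ...) else generate_dataset(spec)
  blocks <- lapply(ds$blocks, function(b) preprocess_block(b)$block$values)
  y <- if (correct) correct_population_structure(ds$trait, ds$q)$values
       else ds$trait$values
  list(blocks = blocks, y = y, ds = ds)
}

expect_max_abs <- function(x, tol) {
  expect_lt(max(abs(x)), tol)
}
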