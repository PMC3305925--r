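# Single-block OPLS: fitting, prediction, correlation loadings,
# decomposition identities, serialization.

test_that("perfect univariate fit reproduces y with zero residual", {
  set.seed(1)
  y <- rnorm(10)
  yc <- y - mean(y)
  X <- cbind(f1 = yc)
  m <- fit_opls(X, yc, 0)
  expect_max_abs(predict_opls(m, X)$y_hat - yc, 1e-10)
  expect_max_abs(m$E, 1e-10)
})

test_that("OPLS with n_orth = 0 equals one-component PLS1", {
  for (seed in 1:5) {
    X <- random_scaled(30, 12, seed)
    set.seed(seed + 100)
    y <- rnorm(30)
    yc <- y - mean(y)
    m <- fit_opls(X, yc, 0)
    expect_max_abs(predict_opls(m, X)$y_hat - pls1_oracle(X, yc)$fitted,
                   1e-10)
  }
})

test_that("planted orthogonal structure is recovered", {
  d <- planted_opls_data(n = 50, p = 30, noise_sd = 0, seed = 7)
  m <- fit_opls(d$X, d$y, 1)
  expect_gt(abs(cor(m$T_orth[, 1], d$t_o)), 0.999)
  expect_gt(abs(cor(m$t, d$y)), 0.999)
})

test_that("decomposition identities hold on random fits", {
  for (seed in 1:8) {
    n <- 25 + seed; p <- 10 + 2 * seed
    X <- random_scaled(n, p, seed)
    set.seed(seed + 500)
    y <- rnorm(n)
    yc <- y - mean(y)
    k <- seed %% 3
    m <- fit_opls(X, yc, k)
    # X = t p' + T_o P_o' + E
    recon <- tcrossprod(m$t, m$p) + tcrossprod(m$T_orth, m$P_orth) + m$E
    expect_max_abs(X - recon, 1e-8)
    # score orthogonality, on training data
    if (k > 0) {
      expect_max_abs(crossprod(m$t, m$T_orth), 1e-8)
      expect_max_abs(crossprod(yc, m$T_orth), 1e-8)
      expect_max_abs(colSums(m$W_orth^2) - 1, 1e-10)
    }
    expect_equal(sum(m$w^2), 1, tolerance = 1e-10)
    # energy bookkeeping by score orthogonality
    parts <- sum(tcrossprod(m$t, m$p)^2) + sum(m$E^2)
    for (j in seq_len(k))
      parts <- parts + sum(tcrossprod(m$T_orth[, j], m$P_orth[, j])^2)
    expect_lt(abs(sum(X^2) - parts) / sum(X^2), 1e-6)
  }
})

test_that("residual sum of squares never increases with n_orth", {
  X <- random_scaled(40, 20, 3)
  set.seed(99)
  y <- rnorm(40)
  rss <- vapply(0:4, function(k) sum(fit_opls(X, y - mean(y), k)$E^2), 0)
  expect_true(all(diff(rss) <= 1e-10))
})

test_that("prediction is self-consistent and orthogonal-invariant", {
  d <- planted_opls_data(n = 40, p = 20, noise_sd = 0.3, seed = 5)
  m <- fit_opls(d$X, d$y, 1)
  pr <- predict_opls(m, d$X)
  fitted_train <- m$c * drop(m$X_filtered %*% m$w)
  expect_max_abs(pr$y_hat - fitted_train, 1e-10)

  # single new sample equal to a training sample
  one <- predict_opls(m, d$X[7, , drop = FALSE])
  expect_equal(one$y_hat, pr$y_hat[7], tolerance = 1e-12)

  # adding arbitrary multiples of p_o' to rows leaves predictions unchanged
  set.seed(8)
  Xp <- d$X + outer(rnorm(40, sd = 5), m$P_orth[, 1])
  expect_max_abs(predict_opls(m, Xp)$y_hat - pr$y_hat, 1e-8)

  expect_error(predict_opls(m, d$X[, 1:5]), "features")
})

test_that("fitted values are stable in n_orth when X has no structured
           y-orthogonal variance", {
  set.seed(61)
  n <- 60; p <- 30
  y <- rnorm(n); y <- (y - mean(y)) / sd(y)
  X <- tcrossprod(y, rnorm(p)) + matrix(rnorm(n * p, sd = 0.3), n, p)
  f0 <- predict_opls(fit_opls(X, y, 0), X)$y_hat
  f2 <- predict_opls(fit_opls(X, y, 2), X)$y_hat
  expect_lt(sqrt(mean((f0 - f2)^2)), 0.05)
})

test_that("correlation loadings match a direct correlation oracle", {
  set.seed(71)
  n <- 30
  y <- rnorm(n); yc <- y - mean(y)
  X <- cbind(random_scaled(n, 5, 72))
  m <- fit_opls(X, yc, 1)
  pc <- correlation_loadings(m)
  oracle <- apply(m$X_filtered, 2, function(col) cor(m$t, col))
  expect_max_abs(pc - oracle, 1e-10)
  expect_true(all(pc >= -1 & pc <= 1))

  # feature identical to t / orthogonal to t
  Xq <- cbind(a = m$t, b = lm.fit(cbind(1, m$t), rnorm(n))$residuals)
  mq <- fit_opls(scale(Xq), (m$t - mean(m$t)), 0)
  pcq <- correlation_loadings(mq)
  expect_equal(unname(pcq["a"]), 1, tolerance = 1e-8)
  expect_max_abs(pcq["b"], 1e-8)
})

test_that("degenerate inputs raise the documented errors", {
  X <- random_scaled(10, 4, 9)
  expect_error(fit_opls(X, rep(1, 10), 0), "constant")
  # rank-limited X: requesting too many orthogonal components fails
  X1 <- tcrossprod(rnorm(10), rnorm(4))
  set.seed(2)
  expect_error(fit_opls(X1, rnorm(10), 3), "insufficient orthogonal variance")
})

test_that("models survive a JSON round trip", {
  d <- planted_opls_data(n = 20, p = 8, noise_sd = 0.2, seed = 13)
  m <- fit_opls(d$X, d$y, 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_max_abs(predict_opls(m2, d$X)$y_hat - predict_opls(m, d$X)$y_hat,
                 1e-12)

  set.seed(14)
  blocks <- list(matrix(rnorm(20 * 6), 20, 6), matrix(rnorm(20 * 4), 20, 4))
  y <- rnorm(20)
  mb <- fit_mbopls(blocks, y, c(1, 0), 1)
  write_model(mb, path)
  mb2 <- read_model(path)
  expect_max_abs(predict_mbopls(mb2, blocks) - predict_mbopls(mb, blocks),
                 1e-12)
})
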