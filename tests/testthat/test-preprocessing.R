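# Preprocessing: transforms, scaling, filtering, summarization, population
# structure correction, NIPALS PCA.

make_block <- function(v, ...) omics_block(v, ...)

test_that("log2_transform handles powers, offsets and bad values", {
  b <- make_block(matrix(c(8, 1, 5, 2), 2, 2,
                         dimnames = list(c("a", "b"), c("f1", "f2"))))
  out <- log2_transform(b)
  expect_equal(out$values[1, 1], 3)
  expect_equal(out$values[2, 1], 0)
  expect_equal(log2_transform(b, offset = 1)$values[1, 2], log(6, base = 2))

  b$values[1, 2] <- NA
  expect_true(is.na(log2_transform(b)$values[1, 2]))
  b$values[2, 2] <- -3
  expect_error(log2_transform(b), "f2")
})

test_that("unit_variance_scale centers, scales, errors and inverts", {
  b <- make_block(cbind(f1 = c(1, 2, 3), f2 = c(5, 9, 1)))
  sc <- unit_variance_scale(b)
  expect_equal(unname(sc$block$values[, "f1"]), c(-1, 0, 1))
  expect_max_abs(colMeans(sc$block$values), 1e-10)
  expect_max_abs(apply(sc$block$values, 2, var) - 1, 1e-10)

  expect_error(unit_variance_scale(make_block(cbind(f1 = c(10, 10, 10)))),
               "f1")

  # non-missing mean/sd: column (2, NA, 4, 6) has mean 4, sd 2
  b2 <- make_block(cbind(f1 = c(2, NA, 4, 6), f2 = c(1, 2, 3, 4)))
  sc2 <- unit_variance_scale(b2)
  expect_equal(sc2$centers[["f1"]], 4)
  expect_equal(sc2$scales[["f1"]], 2)
  expect_equal(unname(sc2$block$values[, "f1"]), c(-1, NA, 0, 1))

  # inverse transform round-trips non-missing cells
  back <- unscale(sc2$block, sc2$centers, sc2$scales)
  expect_max_abs((back$values - b2$values)[!is.na(b2$values)], 1e-10)
})

test_that("filter_missing is a strict-threshold per-feature recount", {
  set.seed(11)
  v <- matrix(rnorm(200), 10, 20,
              dimnames = list(NULL, paste0("f", 1:20)))
  v[1:3, 1] <- NA               # exactly 30% missing: kept at threshold 0.3
  v[1:4, 2] <- NA               # 40%: dropped
  for (j in 3:20) v[sample(10, sample(0:5, 1)), j] <- NA
  b <- make_block(v)
  out <- filter_missing(b, 0.3)
  keep_oracle <- colnames(v)[vapply(seq_len(20), function(j)
    sum(is.na(v[, j])) / 10 <= 0.3, TRUE)]
  expect_identical(feature_ids(out), keep_oracle)
  expect_true("f1" %in% feature_ids(out))
  expect_false("f2" %in% feature_ids(out))
  # a complete feature is never removed, at any threshold in [0, 1)
  vc <- v; vc[, 5] <- rnorm(10)
  expect_true("f5" %in% feature_ids(filter_missing(make_block(vc), 0)))
  expect_error(filter_missing(b, 1), "max_missing_fraction")
})

test_that("summarize_annotated_peaks merges correlated same-annotation peaks", {
  set.seed(21)
  n <- 30
  latent <- rnorm(n)
  # three collinear features with planted loadings, same annotation
  v <- cbind(m1 = 2 * latent + rnorm(n, sd = 0.01),
             m2 = -1.5 * latent + rnorm(n, sd = 0.01),
             m3 = latent + rnorm(n, sd = 0.01),
             u1 = rnorm(n),
             d1 = rnorm(n))
  v <- cbind(v, d2 = v[, "d1"])          # exact duplicate of d1
  ann <- c(m1 = "metA", m2 = "metA", m3 = "metA",
           d1 = "metB", d2 = "metB")     # u1 stays "unknown"
  b <- make_block(v, annotations = ann)
  out <- summarize_annotated_peaks(list(b), correlation_threshold = 0.5)

  expect_equal(nrow(out$values), n)                  # samples unchanged
  expect_lte(ncol(out$values), ncol(v))              # never grows
  expect_true("u1" %in% feature_ids(out))            # unknown passes through
  # duplicates collapse to a feature identical to either input (up to scale)
  expect_true("metB.summary" %in% feature_ids(out))
  expect_equal(abs(cor(out$values[, "metB.summary"], v[, "d1"])), 1,
               tolerance = 1e-8)
  # merged score recovers the generating latent
  expect_gt(abs(cor(out$values[, "metA.summary"], latent)), 0.999)
  # provenance bookkeeping
  prov <- attr(out, "provenance")
  expect_setequal(prov[["metA.summary"]], c("m1", "m2", "m3"))

  # uncorrelated same-annotation features are retained separately
  v2 <- cbind(a1 = rnorm(n), a2 = rnorm(n))
  b2 <- make_block(v2, annotations = c(a1 = "metC", a2 = "metC"))
  out2 <- summarize_annotated_peaks(list(b2), correlation_threshold = 0.5)
  expect_setequal(feature_ids(out2), c("a1", "a2"))

  # mismatched samples error
  b3 <- make_block(matrix(rnorm(10), 5, 2))
  expect_error(summarize_annotated_peaks(list(b, b3)), "sample")
})

test_that("correct_population_structure removes Q-explained variance", {
  # intercept-only model: single all-ones column removes the mean
  q1 <- population_membership(matrix(1, 3, 1,
                                     dimnames = list(c("a", "b", "c"), "p1")))
  tr <- trait_vector(c(a = 1, b = 2, c = 3))
  out <- correct_population_structure(tr, q1)
  expect_equal(unname(out$values), c(-1, 0, 1))
  expect_true(out$corrected)

  # hard-assignment Q: residual group means vanish; matches lm oracle
  set.seed(31)
  n <- 30
  g <- rep(1:3, each = 10)
  Q <- diag(3)[g, ]
  rownames(Q) <- sprintf("s%02d", 1:n)
  colnames(Q) <- paste0("p", 1:3)
  z <- c(5, -2, 9)[g] + rnorm(n)
  tr2 <- trait_vector(setNames(z, rownames(Q)))
  out2 <- correct_population_structure(tr2, population_membership(Q))
  expect_max_abs(tapply(out2$values, g, mean), 1e-8)
  oracle <- lm.fit(Q, z)$residuals
  expect_max_abs(out2$values - oracle, 1e-8)
  expect_max_abs(crossprod(Q, out2$values), 1e-8)

  # idempotence
  out3 <- correct_population_structure(out2, population_membership(Q))
  expect_max_abs(out3$values - out2$values, 1e-10)

  # missing trait values excluded from fit, preserved in output
  z_na <- tr2$values
  z_na[3] <- NA
  out4 <- correct_population_structure(trait_vector(z_na),
                                       population_membership(Q))
  expect_true(is.na(out4$values[3]))
  expect_equal(sum(is.na(out4$values)), 1L)

  # fewer samples than subpopulations
  qbig <- matrix(1 / 5, 4, 5)
  rownames(qbig) <- letters[1:4]
  expect_error(correct_population_structure(
    trait_vector(setNames(rnorm(4), letters[1:4])),
    population_membership(qbig)), "subpopulations")
})

test_that("nipals_pca matches SVD on complete data and tolerates missing", {
  set.seed(41)
  # exact rank-1
  t_true <- rnorm(20)
  p_true <- rnorm(8)
  X1 <- tcrossprod(t_true, p_true)
  f1 <- nipals_pca(X1, 1, center = FALSE)
  expect_gt(abs(cor(f1$scores[, 1], t_true)), 1 - 1e-8)
  expect_equal(f1$r2[1], 1, tolerance = 1e-6)

  # complete matrix vs SVD of the centered matrix
  X2 <- matrix(rnorm(20 * 6), 20, 6)
  f2 <- nipals_pca(X2, 3)
  sv <- svd(scale(X2, scale = FALSE))
  for (k in 1:3) {
    expect_gt(abs(cor(f2$scores[, k], sv$u[, k] * sv$d[k])), 0.9999)
    expect_gt(abs(sum(f2$loadings[, k] * sv$v[, k])), 0.9999)
  }
  expect_max_abs(colSums(f2$loadings^2) - 1, 1e-8)

  # rank-1 with 10% missing cells: planted loading recovered
  p3 <- rnorm(10)
  X3 <- tcrossprod(rnorm(40), p3)
  X3[sample(length(X3), 40)] <- NA
  f3 <- nipals_pca(X3, 1, center = FALSE)
  expect_gt(abs(cor(f3$loadings[, 1], p3)), 0.99)

  expect_error(nipals_pca(cbind(c(NA, NA, NA), rnorm(3)), 1), "all-missing")
})
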