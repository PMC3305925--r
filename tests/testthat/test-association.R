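# Mantel test, differential abundance, correlation network.

test_that("euclidean_distance_matrix matches brute force", {
  X <- rbind(a = c(0, 0), b = c(3, 4), c = c(3, 4))
  d <- euclidean_distance_matrix(X)
  expect_equal(d["a", "b"], 5)
  expect_equal(d["b", "c"], 0)
  set.seed(1)
  X2 <- matrix(rnorm(24), 6, 4)
  d2 <- euclidean_distance_matrix(X2)
  brute <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    brute[i, j] <- sqrt(sum((X2[i, ] - X2[j, ])^2))
  expect_max_abs(unclass(d2) - brute, 1e-12)
  expect_equal(diag(unclass(d2)), rep(0, 6), ignore_attr = TRUE)
})

test_that("mantel_test: perfect scaling, symmetry, exhaustive enumeration", {
  set.seed(2)
  X <- matrix(rnorm(8 * 3), 8, 3)
  d1 <- euclidean_distance_matrix(X)
  d2 <- unclass(d1) * 2
  mt <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  expect_equal(mt$r, 1, tolerance = 1e-12)
  expect_equal(mt$p_value, 1 / 100)

  # observed statistic symmetric in the arguments
  d3 <- euclidean_distance_matrix(matrix(rnorm(24), 8, 3))
  expect_equal(mantel_test(d1, d3, n_perm = 10, seed = 1)$r,
               mantel_test(d3, d1, n_perm = 10, seed = 1)$r)

  # n = 4: sampled machinery agrees with full enumeration via the
  # exhaustive option, and the exhaustive p matches an independent oracle
  set.seed(3)
  A <- euclidean_distance_matrix(matrix(rnorm(8), 4, 2))
  B <- euclidean_distance_matrix(matrix(rnorm(8), 4, 2))
  ex <- mantel_test(A, B, exhaustive = TRUE)
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == 4), ]
  lt <- lower.tri(unclass(A))
  v1 <- unclass(A)[lt]
  null_oracle <- apply(perms, 1, function(idx) {
    m <- unclass(B)[idx, idx]
    cor(v1, m[lt])
  })
  expect_equal(ex$n_perm, 24)
  expect_equal(ex$p_value, mean(null_oracle >= ex$r))
  expect_error(mantel_test(A, unclass(B)[1:3, 1:3]), "sample sets|4 samples")
})

test_that("mantel p-values are roughly uniform under independence", {
  pvals <- vapply(1:30, function(s) {
    set.seed(1000 + s)
    a <- euclidean_distance_matrix(matrix(rnorm(30 * 3), 30, 3))
    b <- euclidean_distance_matrix(matrix(rnorm(30 * 3), 30, 3))
    mantel_test(a, b, n_perm = 99, seed = s)$p_value
  }, 0)
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_lt(unname(ks$statistic), 0.3)
})

test_that("differential_abundance applies fold and FDR rules", {
  set.seed(4)
  n_per <- 10
  g <- rep(c("A", "B"), each = n_per)
  # f_null: equal means; f_shift1: +1 log2 unit in A (equal sizes: the
  # grand-mean offset is only 0.5, below the 2-fold rule); f_shift25:
  # +2.5 units in A
  X <- cbind(f_null = rnorm(2 * n_per, 5, 0.2),
             f_shift1 = c(rnorm(n_per, 6, 1e-6), rnorm(n_per, 5, 1e-6)),
             f_shift25 = c(rnorm(n_per, 7.5, 0.2), rnorm(n_per, 5, 0.2)))
  res <- differential_abundance(X, g, min_fold = 2, fdr_max = 0.01)
  sel <- res[res$selected, ]
  expect_false("f_null" %in% sel$feature_id)
  expect_false("f_shift1" %in% sel$feature_id)
  # hand-computed grand-mean offset for the 1-unit shift
  r1 <- res[res$feature_id == "f_shift1" & res$group == "A", ]
  expect_equal(r1$delta, 0.5, tolerance = 1e-3)
  expect_true(all(c("A", "B") %in% res$group[res$feature_id == "f_shift25" &
                                               res$selected]))
  expect_equal(res$direction[res$feature_id == "f_shift25" &
                               res$group == "A"], "up")

  # planted 2.5-unit shifts detected with the right sign across seeds
  hits <- 0L
  for (s in 1:10) {
    set.seed(100 + s)
    Xs <- cbind(f = c(rnorm(n_per, 7.5, 0.2), rnorm(n_per, 5, 0.2)),
                g1 = rnorm(2 * n_per), g2 = rnorm(2 * n_per))
    rs <- differential_abundance(Xs, g, min_fold = 2, fdr_max = 0.01)
    ok <- rs$selected[rs$feature_id == "f" & rs$group == "A"] &&
      rs$direction[rs$feature_id == "f" & rs$group == "A"] == "up"
    if (isTRUE(ok)) hits <- hits + 1L
  }
  expect_gte(hits, 10L * 0.95)

  # permissive thresholds return every testable feature
  res_all <- differential_abundance(X, g, min_fold = 1, fdr_max = 1)
  expect_true(all(res_all$selected))
  expect_error(differential_abundance(X, c(rep("A", 19), "B")), "fewer than 2")
})

test_that("correlation_network builds a canonical undirected edge list", {
  set.seed(5)
  n <- 40
  a <- rnorm(n)
  X <- cbind(a = a, a2 = a, b = rnorm(n), c = rnorm(n))
  ed <- correlation_network(X, c("a", "a2", "b", "c"), p_max = 0.001)
  dup <- ed[ed$feature_a == "a" & ed$feature_b == "a2", ]
  expect_equal(nrow(dup), 1L)
  expect_equal(dup$rho_s, 1)
  expect_false(any(ed$feature_a == ed$feature_b))
  expect_false(anyDuplicated(paste(ed$feature_a, ed$feature_b)) > 0)
  expect_true(all(ed$p_value < 0.001))

  # edge set invariant under feature reordering (as unordered pairs)
  ed2 <- correlation_network(X[, c(4, 2, 1, 3)], c("a", "a2", "b", "c"))
  key <- function(e) sort(paste(pmin(e$feature_a, e$feature_b),
                                pmax(e$feature_a, e$feature_b)))
  expect_identical(key(ed), key(ed2))

  # null edge rate is low
  edges_per_seed <- vapply(1:20, function(s) {
    set.seed(200 + s)
    nrow(correlation_network(matrix(rnorm(70 * 10), 70, 10), 1:10,
                             p_max = 0.001))
  }, 0)
  expect_lt(mean(edges_per_seed), 1)
})
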