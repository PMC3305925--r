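# Supporting association analyses: Mantel tests between metabolite-space
# and genetic distances, one-vs-rest subtype differential abundance, and the
# metabolite-metabolite correlation network among selected features.

#' Euclidean distance matrix between samples
#'
#' @param X complete samples x features matrix (impute first).
#' @return an object of class `DistanceMatrix`: symmetric matrix with zero
#'   diagonal, metric attribute `"euclidean"`.
#' @export
euclidean_distance_matrix <- function(X) {
  X <- if (inherits(X, "OmicsBlock")) X$values else X
  .check_complete_matrix(X, "X")
  d <- as.matrix(stats::dist(X))
  structure(d, class = c("DistanceMatrix", class(d)), metric = "euclidean")
}

.as_dist_matrix <- function(d) {
  m <- unclass(d)
  .assert(is.matrix(m) && nrow(m) == ncol(m), "distance matrix must be square")
  .assert(max(abs(m - t(m))) <= 1e-10, "distance matrix must be symmetric")
  .assert(all(diag(m) == 0), "distance matrix diagonal must be zero")
  m
}

#' Mantel test between two distance matrices
#'
#' The observed statistic is the Pearson correlation of the lower-triangle
#' entries. The null is built by jointly permuting the rows and columns of
#' the second matrix; the one-sided (positive-association) p-value is
#' `(#\{null r >= observed r\} + 1) / (n_perm + 1)`.
#'
#' @param d1,d2 square symmetric distance matrices over the same samples
#'   (aligned by rowname when present).
#' @param n_perm number of permutations (the reference analysis uses 10000).
#' @param seed integer seed.
#' @param exhaustive enumerate all `n!` relabelings instead of sampling
#'   (only for small n); the p-value is then the exact fraction of
#'   relabelings, identity included, with `r >= r_observed`.
#' @return list with `r`, `p_value`, `n_perm`, and the null correlations.
#' @export
mantel_test <- function(d1, d2, n_perm = 10000L, seed = 1L,
                        exhaustive = FALSE) {
  m1 <- .as_dist_matrix(d1)
  m2 <- .as_dist_matrix(d2)
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    .assert(setequal(rownames(m1), rownames(m2)), "sample sets differ")
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  n <- nrow(m1)
  .assert(n >= 4L, "need at least 4 samples")
  .assert(n == nrow(m2), "dimension mismatch")
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  v2 <- m2[lt]
  .assert(stats::sd(v1) > 0 && stats::sd(v2) > 0,
          "constant distance triangle")
  r_obs <- stats::cor(v1, v2)
  if (exhaustive) {
    .assert(n <= 8L, "exhaustive enumeration is limited to n <= 8")
    perms <- .all_permutations(n)
    null_r <- vapply(perms, function(idx) stats::cor(v1, m2[idx, idx][lt]), 0)
    # identity permutation is part of the reference set, so the observed
    # statistic counts itself: p = #{r_perm >= r_obs} / n!
    return(list(r = r_obs, p_value = mean(null_r >= r_obs),
                n_perm = length(perms), null_r = null_r, exhaustive = TRUE))
  }
  set.seed(as.integer(seed))
  null_r <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n)
    stats::cor(v1, m2[idx, idx][lt])
  }, 0)
  list(r = r_obs, p_value = .empirical_p(sum(null_r >= r_obs), n_perm),
       n_perm = n_perm, null_r = null_r, exhaustive = FALSE)
}

# All permutations of 1..n as a list (n <= 8).
.all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- .all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (k in seq_len(n)) {
    for (s in sub) {
      i <- i + 1L
      v <- integer(n)
      v[k] <- n
      v[-k] <- s
      out[[i]] <- v
    }
  }
  out
}

#' One-vs-rest differential abundance across sample groups
#'
#' For every feature and group, a Student's t-test (two-sided, pooled
#' variance by default) of the group's samples against all other samples,
#' with Benjamini-Hochberg FDR over all feature-by-group tests. Data are
#' assumed to be on the log2 scale, so the fold criterion is
#' `|group mean - grand mean| >= log2(min_fold)`.
#'
#' @param X samples x features matrix (log2 scale) or [omics_block()].
#' @param group_labels factor/character of group memberships, one per sample.
#' @param min_fold minimum fold change from the grand mean (default 2).
#' @param fdr_max FDR threshold (default 0.01).
#' @param var_equal pooled-variance Student test (default); `FALSE` for
#'   Welch.
#' @return data frame of all feature x group tests: `feature_id`, `group`,
#'   `delta` (group mean - grand mean, log2 units), `direction`, `p`, `q`,
#'   `selected`.
#' @export
differential_abundance <- function(X, group_labels, min_fold = 2,
                                   fdr_max = 0.01, var_equal = TRUE) {
  X <- if (inherits(X, "OmicsBlock")) X$values else X
  g <- as.factor(group_labels)
  .assert(nrow(X) == length(g), "one group label per sample required")
  .assert(nlevels(g) >= 2L, "need at least 2 groups")
  sizes <- table(g)
  .assert(all(sizes >= 2L), "group(s) with fewer than 2 samples: %s",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  fids <- colnames(X) %||% paste0("F", seq_len(ncol(X)))
  res <- vector("list", nlevels(g))
  for (gi in seq_len(nlevels(g))) {
    in_g <- g == levels(g)[gi]
    pv <- delta <- numeric(ncol(X))
    for (j in seq_len(ncol(X))) {
      a <- X[in_g, j]; b <- X[!in_g, j]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2L || length(b) < 2L ||
          (stats::sd(a) == 0 && stats::sd(b) == 0)) {
        pv[j] <- NA_real_; delta[j] <- NA_real_
        next
      }
      pv[j] <- stats::t.test(a, b, var.equal = var_equal)$p.value
      delta[j] <- mean(a) - mean(X[!is.na(X[, j]), j])
    }
    res[[gi]] <- data.frame(feature_id = fids, group = levels(g)[gi],
                            delta = delta,
                            direction = ifelse(delta >= 0, "up", "down"),
                            p = pv, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$q <- bh_fdr(out$p)
  out$selected <- !is.na(out$q) & out$q < fdr_max &
    abs(out$delta) >= log2(min_fold)
  rownames(out) <- NULL
  out
}

#' Correlation network among selected features
#'
#' All pairwise Spearman correlations among the selected features; pairs
#' with two-sided p below `p_max` become undirected edges (canonical order:
#' first feature before second in column order).
#'
#' @param X samples x features matrix or [omics_block()].
#' @param selected_features character vector of feature IDs (subset of
#'   `colnames(X)`), or integer indices.
#' @param p_max edge p-value threshold (default 0.001).
#' @return data frame of edges: `feature_a`, `feature_b`, `rho_s`,
#'   `p_value`.
#' @export
correlation_network <- function(X, selected_features, p_max = 0.001) {
  X <- if (inherits(X, "OmicsBlock")) X$values else X
  if (is.character(selected_features)) {
    .assert(all(selected_features %in% colnames(X)),
            "unknown feature(s): %s",
            paste(setdiff(selected_features, colnames(X)), collapse = ", "))
    idx <- match(selected_features, colnames(X))
  } else idx <- as.integer(selected_features)
  fids <- colnames(X)[idx] %||% paste0("F", idx)
  k <- length(idx)
  edges <- list()
  for (a in seq_len(max(k - 1L, 0L))) {
    for (b in seq(a + 1L, k)) {
      ok <- !is.na(X[, idx[a]]) & !is.na(X[, idx[b]])
      if (sum(ok) < 4L) next
      xa <- X[ok, idx[a]]; xb <- X[ok, idx[b]]
      if (stats::sd(xa) == 0 || stats::sd(xb) == 0) next
      r <- stats::cor(xa, xb, method = "spearman")
      n <- sum(ok)
      p <- if (abs(r) >= 1) 0 else
        2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2)
      if (p < p_max) {
        edges[[length(edges) + 1L]] <- data.frame(
          feature_a = fids[a], feature_b = fids[b], rho_s = r, p_value = p,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(edges) == 0L) {
    return(data.frame(feature_a = character(0), feature_b = character(0),
                      rho_s = numeric(0), p_value = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
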