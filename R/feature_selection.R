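# Probabilistic feature selection: the log B statistic contrasts the
# bootstrap sampling distribution of a feature's correlation loading with
# its permutation-null distribution through kernel density estimates and a
# conservative prior on the null, and is complemented by a plain Spearman
# screen with Benjamini-Hochberg FDR control.

# Refit helper shared by bootstrap and null draws: blocks/y already complete;
# component counts fixed (selected once on the full data).
.refit_loadings <- function(mats, y, n_orth_per_block, n_orth_top) {
  fit <- fit_mbopls(mats, y, n_orth_per_block, n_orth_top)
  mbopls_correlation_loadings(fit)
}

#' Bootstrap sampling distribution of correlation loadings
#'
#' Resamples the samples with replacement, refits the multi-block OPLS model
#' with the already-selected component counts, and records every feature's
#' correlation loading. Degenerate resamples (constant trait) are redrawn,
#' up to 10 extra attempts each.
#'
#' @param blocks list of complete blocks.
#' @param y complete trait values.
#' @param n_orth_per_block,n_orth_top fixed component counts (from
#'   [select_components()] on the full data).
#' @param n_boot number of bootstrap replicates (>= 50 for density work).
#' @param seed integer seed.
#' @return matrix of loadings, `n_boot` rows x features; `NA` where a
#'   replicate left a feature's loading undefined.
#' @export
bootstrap_loadings <- function(blocks, y, n_orth_per_block = 0L,
                               n_orth_top = 0L, n_boot = 100L, seed = 1L) {
  .assert(n_boot >= 50L, "n_boot must be >= 50 for stable densities")
  if (!is.list(blocks) || inherits(blocks, "OmicsBlock")) blocks <- list(blocks)
  mats <- lapply(blocks, .as_block_matrix)
  y <- .as_trait_values(y)
  set.seed(as.integer(seed))
  n <- length(y)
  out <- NULL
  for (b in seq_len(n_boot)) {
    for (attempt in 1:11) {
      idx <- sample.int(n, n, replace = TRUE)
      ok <- stats::sd(y[idx]) > 0 &&
        all(vapply(mats, function(m) {
          all(.col_stats(m[idx, , drop = FALSE])$scale > 0)
        }, TRUE))
      if (ok) break
    }
    pc <- .refit_loadings(lapply(mats, function(m) m[idx, , drop = FALSE]),
                          y[idx], n_orth_per_block, n_orth_top)
    if (is.null(out)) out <- matrix(NA_real_, n_boot, length(pc),
                                    dimnames = list(NULL, names(pc)))
    out[b, ] <- pc
  }
  out
}

#' Null sampling distribution of correlation loadings
#'
#' Permutes the trait, refits, and records loadings: the empirical
#' distribution of each feature's correlation loading under the null
#' hypothesis of no trait-feature association.
#'
#' @inheritParams bootstrap_loadings
#' @param n_null number of permutation replicates.
#' @return matrix of loadings, `n_null` rows x features.
#' @export
null_loadings <- function(blocks, y, n_orth_per_block = 0L, n_orth_top = 0L,
                          n_null = 100L, seed = 1L) {
  .assert(n_null >= 50L, "n_null must be >= 50 for stable densities")
  if (!is.list(blocks) || inherits(blocks, "OmicsBlock")) blocks <- list(blocks)
  mats <- lapply(blocks, .as_block_matrix)
  y <- .as_trait_values(y)
  set.seed(as.integer(seed))
  out <- NULL
  for (b in seq_len(n_null)) {
    pc <- .refit_loadings(mats, sample(y), n_orth_per_block, n_orth_top)
    if (is.null(out)) out <- matrix(NA_real_, n_null, length(pc),
                                    dimnames = list(NULL, names(pc)))
    out[b, ] <- pc
  }
  out
}

# Gaussian KDE evaluated at a point; Silverman's rule (stats::bw.nrd0) with a
# fallback bandwidth when the sample has (near) zero spread.
.kde_at <- function(x0, samples, bw = NULL) {
  samples <- samples[is.finite(samples)]
  if (length(samples) == 0L) return(0)
  if (is.null(bw)) {
    bw <- if (stats::sd(samples) > 0) stats::bw.nrd0(samples) else 1e-3
  }
  mean(stats::dnorm(x0, mean = samples, sd = bw))
}

#' The log B feature-relevance score
#'
#' Combines the kernel density of the bootstrap loading distribution,
#' `d(p_C)`, and of the permutation-null distribution, `d(p_C | H0)`, both
#' evaluated at the observed full-data loading, into
#' `b = d(p_C) (1 - P(H0)) / (d(p_C) (1 - P(H0)) + d(p_C|H0) P(H0))`
#' with the a-priori null probability `P(H0) = 0.95`. The reported statistic
#' is the natural log-odds `log B = ln(b / (1 - b))`; `log B > 0` flags
#' loadings robustly larger than expected under the null.
#'
#' @param observed_pc observed correlation loading (full data).
#' @param boot_samples,null_samples loading draws from
#'   [bootstrap_loadings()] / [null_loadings()] for one feature.
#' @param prior_h0 prior null probability, in (0, 1); default 0.95.
#' @param bw optional fixed kernel bandwidth (default Silverman per sample
#'   set).
#' @param density_floor densities are floored here to keep the odds finite.
#' @return list with `b`, `log_b`, the two density values, and `flagged`
#'   (TRUE when both densities hit the floor).
#' @export
log_b_score <- function(observed_pc, boot_samples, null_samples,
                        prior_h0 = 0.95, bw = NULL, density_floor = 1e-12) {
  .assert(prior_h0 > 0 && prior_h0 < 1, "prior_h0 must be in (0, 1)")
  .assert(length(boot_samples) >= 1L && length(null_samples) >= 1L,
          "empty sample set")
  d_alt <- max(.kde_at(observed_pc, boot_samples, bw), density_floor)
  d_null <- max(.kde_at(observed_pc, null_samples, bw), density_floor)
  flagged <- d_alt <= density_floor && d_null <= density_floor
  num <- d_alt * (1 - prior_h0)
  den <- num + d_null * prior_h0
  b <- num / den
  log_b <- log(num) - log(d_null * prior_h0)
  list(b = b, log_b = log_b, d_alt = d_alt, d_null = d_null, flagged = flagged)
}

#' Spearman screen of features against a trait
#'
#' Rank correlation per feature (average ranks for ties), two-sided p-value
#' by the t approximation, Benjamini-Hochberg q-values across the feature
#' set. Constant features are excluded with `NA` and flagged.
#'
#' @param X samples x features matrix (missing values allowed pairwise).
#' @param y trait values.
#' @return data frame with `feature_id`, `rho_s`, `p`, `q`, `excluded`.
#' @export
spearman_screen <- function(X, y) {
  X <- if (inherits(X, "OmicsBlock")) X$values else X
  y <- .as_trait_values(y)
  .assert(nrow(X) == length(y), "dimension mismatch")
  p <- ncol(X)
  rho <- pv <- rep(NA_real_, p)
  excluded <- logical(p)
  for (j in seq_len(p)) {
    ok <- !is.na(X[, j]) & !is.na(y)
    if (sum(ok) < 4L || stats::sd(X[ok, j]) == 0 || stats::sd(y[ok]) == 0) {
      excluded[j] <- TRUE
      next
    }
    r <- stats::cor(X[ok, j], y[ok], method = "spearman")
    n <- sum(ok)
    rho[j] <- r
    pv[j] <- if (abs(r) >= 1) 0 else {
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  q <- rep(NA_real_, p)
  q[!excluded] <- bh_fdr(pv[!excluded])
  data.frame(feature_id = colnames(X) %||% paste0("F", seq_len(p)),
             rho_s = rho, p = pv, q = q, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values with monotonicity enforcement; output order matches the
#' input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (`NA` passed
#'   through).
#' @return q-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  .assert(all(pvalues[ok] >= 0 & pvalues[ok] <= 1), "p-values must be in [0, 1]")
  q <- rep(NA_real_, length(pvalues))
  p <- pvalues[ok]
  m <- length(p)
  if (m > 0) {
    o <- order(p, decreasing = TRUE)
    ro <- order(o)
    q[ok] <- pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
  }
  q
}

#' Full feature-selection table for a multi-block model
#'
#' Runs the complete scoring pipeline: full-data fit and correlation
#' loadings, bootstrap and null loading distributions, per-feature log B,
#' and the complementary Spearman screen. A feature is `selected` when
#' `log B > 0` or its Spearman q-value is below `fdr_max`; both flags are
#' also reported separately.
#'
#' @inheritParams bootstrap_loadings
#' @param n_null permutation replicates for the null densities.
#' @param prior_h0 prior null probability (default 0.95).
#' @param fdr_max q-value threshold of the Spearman arm (default 0.05).
#' @return data frame, one row per concatenated feature: `feature_id`,
#'   `p_c`, `b`, `log_b`, `rho_s`, `p_rho`, `q_rho`, `selected_logb`,
#'   `selected_fdr`, `selected`.
#' @export
feature_scores <- function(blocks, y, n_orth_per_block = 0L, n_orth_top = 0L,
                           n_boot = 100L, n_null = 100L, prior_h0 = 0.95,
                           fdr_max = 0.05, seed = 1L) {
  if (!is.list(blocks) || inherits(blocks, "OmicsBlock")) blocks <- list(blocks)
  mats <- lapply(blocks, .as_block_matrix)
  y <- .as_trait_values(y)
  fit <- fit_mbopls(mats, y, n_orth_per_block, n_orth_top)
  pc <- mbopls_correlation_loadings(fit)
  boot <- bootstrap_loadings(mats, y, n_orth_per_block, n_orth_top,
                             n_boot = n_boot, seed = .derive_seed(seed, 1))
  null <- null_loadings(mats, y, n_orth_per_block, n_orth_top,
                        n_null = n_null, seed = .derive_seed(seed, 2))
  scores <- lapply(seq_along(pc), function(j) {
    log_b_score(pc[j], boot[, j], null[, j], prior_h0 = prior_h0)
  })
  sp <- spearman_screen(do.call(cbind, mats), y)
  b <- vapply(scores, `[[`, 0, "b")
  log_b <- vapply(scores, `[[`, 0, "log_b")
  sel_logb <- !is.na(log_b) & log_b > 0
  sel_fdr <- !is.na(sp$q) & sp$q < fdr_max
  data.frame(feature_id = names(pc), p_c = unname(pc), b = b, log_b = log_b,
             rho_s = sp$rho_s, p_rho = sp$p, q_rho = sp$q,
             selected_logb = sel_logb, selected_fdr = sel_fdr,
             selected = sel_logb | sel_fdr, stringsAsFactors = FALSE)
}
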