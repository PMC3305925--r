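# External cross-validation and permutation-based significance of
# multi-block OPLS models. The external CV is fully nested: within every
# training portion the component counts are re-selected by internal CV, so
# held-out samples never influence any training computation.

#' Squared correlation between observed and cross-validated predictions
#'
#' The diagnostic statistic of external CV: the squared Pearson correlation
#' between the true trait values and the out-of-fold predictions. Equals 1
#' for perfect predictions and is sign-blind by construction.
#'
#' @param y_true,y_pred numeric vectors of equal length (>= 3), non-constant.
#' @return a number in `[0, 1]`.
#' @export
rcv2 <- function(y_true, y_pred) {
  .assert(length(y_true) == length(y_pred), "length mismatch")
  .assert(length(y_true) >= 3L, "need at least 3 values")
  .assert(stats::sd(y_true) > 0 && stats::sd(y_pred) > 0,
          "constant input to rcv2")
  stats::cor(y_true, y_pred)^2
}

# One full external-CV pass: returns the out-of-fold prediction vector.
.external_cv_run <- function(mats, y, n_folds, max_orth_block, max_orth_top,
                             run_seed) {
  n <- length(y)
  set.seed(as.integer(run_seed))
  folds <- .balanced_folds(n, n_folds)
  .assert(min(tabulate(folds, n_folds)) >= 2L, "a fold has fewer than 2 samples")
  pred <- numeric(n)
  for (f in seq_len(n_folds)) {
    te <- folds == f
    tr_mats <- lapply(mats, function(m) m[!te, , drop = FALSE])
    te_mats <- lapply(mats, function(m) m[te, , drop = FALSE])
    sel <- suppressWarnings(select_components(
      tr_mats, y[!te], max_orth_block = max_orth_block,
      max_orth_top = max_orth_top, n_folds = n_folds,
      seed = .derive_seed(run_seed, f)))
    fit <- fit_mbopls(tr_mats, y[!te], sel$n_orth_per_block, sel$n_orth_top)
    pred[te] <- predict_mbopls(fit, te_mats)
  }
  list(pred = pred, folds = folds)
}

#' Externally cross-validated model performance
#'
#' Repeated seven-fold external cross-validation of the multi-block OPLS
#' model. In every repeat the samples are partitioned into `n_folds`
#' segments; for each segment, component counts are selected by internal CV
#' on the remaining samples only, the model is refitted there, and the
#' held-out segment is predicted. The squared correlation between the trait
#' and the assembled out-of-fold predictions gives one rCV2 value per
#' repeat; the median over repeats is the headline statistic (fold
#' partitions differ between repeats, so single runs are noisy).
#'
#' @param blocks list of complete blocks (matrices or [omics_block()]s).
#' @param y complete trait values.
#' @param n_folds external (and internal) fold count, default 7.
#' @param n_repeats number of repeated runs, default 50.
#' @param max_orth_block,max_orth_top scan limits for component selection.
#' @param seed integer seed; every repeat derives its own child seed.
#' @return an object of class `CvResult` with per-run rCV2 values, their
#'   median, the out-of-fold prediction matrix (samples x repeats), fold
#'   assignments, and the seeds used.
#' @export
external_cv <- function(blocks, y, n_folds = 7L, n_repeats = 50L,
                        max_orth_block = 3L, max_orth_top = 3L, seed = 1L) {
  if (!is.list(blocks) || inherits(blocks, "OmicsBlock")) blocks <- list(blocks)
  mats <- lapply(blocks, .as_block_matrix)
  y <- .as_trait_values(y)
  .assert(length(y) >= n_folds, "need at least n_folds samples")
  for (m in mats) .check_complete_matrix(m, "block")
  run_seeds <- vapply(seq_len(n_repeats), function(r) .derive_seed(seed, r), 0)
  preds <- matrix(NA_real_, length(y), n_repeats)
  folds <- matrix(NA_integer_, length(y), n_repeats)
  r2 <- numeric(n_repeats)
  for (r in seq_len(n_repeats)) {
    run <- .external_cv_run(mats, y, n_folds, max_orth_block, max_orth_top,
                            run_seeds[r])
    preds[, r] <- run$pred
    folds[, r] <- run$folds
    r2[r] <- rcv2(y, run$pred)
  }
  structure(list(rcv2_per_run = r2, median_rcv2 = stats::median(r2),
                 predictions = preds, folds = folds, seeds = run_seeds,
                 n_folds = n_folds, n_repeats = n_repeats, y = y),
            class = "CvResult")
}

#' @export
print.CvResult <- function(x, ...) {
  cat(sprintf("CvResult: %d-fold external CV, %d repeat(s)\n", x$n_folds,
              x$n_repeats))
  cat(sprintf("  median rCV2 = %.4f (range %.4f-%.4f)\n", x$median_rcv2,
              min(x$rcv2_per_run), max(x$rcv2_per_run)))
  invisible(x)
}

#' Diagnostic scatter of cross-validated predictions
#'
#' Predicted-versus-observed plot for the median run of a [external_cv()]
#' result, with the identity line.
#'
#' @param x a `CvResult`.
#' @param ... passed to [plot()].
#' @export
plot.CvResult <- function(x, ...) {
  r <- which.min(abs(x$rcv2_per_run - x$median_rcv2))
  plot(x$y, x$predictions[, r], xlab = "observed trait",
       ylab = "out-of-fold prediction",
       main = sprintf("rCV2 = %.3f (median run)", x$rcv2_per_run[r]), ...)
  graphics::abline(0, 1, col = "grey")
  invisible(x)
}

#' Permutation test of model significance
#'
#' The observed statistic is the median external-CV rCV2 on the real trait.
#' The trait is then shuffled `n_perm` times; for each shuffle the same
#' nested CV machinery recomputes rCV2 (one run per shuffle, the standard
#' economy). With n0 the number of shuffled statistics greater than or equal
#' to the observed one, the empirical (biased) P-value is
#' `P = (n0 + 1) / (n_perm + 1)`.
#'
#' @param blocks,y,n_folds,max_orth_block,max_orth_top as in [external_cv()].
#' @param n_perm number of trait permutations (the reference analysis uses
#'   1000).
#' @param n_repeats_observed CV repeats for the observed statistic.
#' @param seed integer seed.
#' @return an object of class `PermutationResult` with the observed
#'   statistic, the `CvResult` behind it, the null statistics, `n0` and
#'   `p_value`.
#' @export
permutation_test <- function(blocks, y, n_perm = 1000L, n_folds = 7L,
                             n_repeats_observed = 10L, max_orth_block = 3L,
                             max_orth_top = 3L, seed = 1L) {
  .assert(n_perm >= 1L, "n_perm must be >= 1")
  if (!is.list(blocks) || inherits(blocks, "OmicsBlock")) blocks <- list(blocks)
  mats <- lapply(blocks, .as_block_matrix)
  y <- .as_trait_values(y)
  cv <- external_cv(mats, y, n_folds = n_folds, n_repeats = n_repeats_observed,
                    max_orth_block = max_orth_block,
                    max_orth_top = max_orth_top, seed = .derive_seed(seed, 0))
  observed <- cv$median_rcv2
  null_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    perm_seed <- .derive_seed(seed, b)
    set.seed(as.integer(perm_seed))
    y_perm <- sample(y)
    run <- .external_cv_run(mats, y_perm, n_folds, max_orth_block,
                            max_orth_top, .derive_seed(perm_seed, 1))
    null_stats[b] <- rcv2(y_perm, run$pred)
  }
  n0 <- sum(null_stats >= observed)
  structure(list(observed = observed, cv_result = cv,
                 null_stats = null_stats, n0 = n0,
                 p_value = .empirical_p(n0, n_perm), n_perm = n_perm,
                 seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("PermutationResult: observed rCV2 = %.4f, n0 = %d / %d, P = %.4g\n",
              x$observed, x$n0, x$n_perm, x$p_value))
  invisible(x)
}
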