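# Preprocessing: transforms raw abundance blocks and traits into the
# model-ready form assumed by the OPLS machinery: log2 scale, unit variance,
# missing-value filtering, annotation-based peak summarization, and
# regression-based population-structure correction of traits.

#' Log2-transform an omics block
#'
#' @param block an [omics_block()].
#' @param offset nonnegative value added before taking logs (for zero counts).
#' @return the transformed `OmicsBlock`; missing cells are preserved.
#' @export
log2_transform <- function(block, offset = 0) {
  .assert(.is_number(offset) && offset >= 0, "offset must be a nonnegative number")
  v <- .as_block_matrix(block)
  bad <- which(!is.na(v) & v + offset <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("nonpositive value after offset in feature '%s' (sample '%s')",
                 colnames(v)[bad[1, 2]], rownames(v)[bad[1, 1]]), call. = FALSE)
  }
  out <- block
  out$values <- log2(v + offset)
  out
}

#' Unit-variance scale an omics block
#'
#' Centers each feature on its non-missing mean and divides by its non-missing
#' sample standard deviation (n-1 denominator), the usual autoscaling step of
#' chemometrics pipelines.
#'
#' @param block an [omics_block()].
#' @return list with the scaled `block` plus the `centers` and `scales` used,
#'   for the inverse transform.
#' @export
unit_variance_scale <- function(block) {
  v <- .as_block_matrix(block)
  n_ok <- colSums(!is.na(v))
  .assert(all(n_ok >= 2L), "features with <2 non-missing values: %s",
          paste(colnames(v)[n_ok < 2L], collapse = ", "))
  st <- .col_stats(v)
  zero <- which(st$scale == 0 | !is.finite(st$scale))
  if (length(zero) > 0) {
    stop(sprintf("zero-variance feature(s): %s",
                 paste(colnames(v)[zero], collapse = ", ")), call. = FALSE)
  }
  out <- block
  out$values <- sweep(sweep(v, 2L, st$center, "-"), 2L, st$scale, "/")
  list(block = out, centers = st$center, scales = st$scale)
}

#' Undo unit-variance scaling
#'
#' @param block a scaled `OmicsBlock`.
#' @param centers,scales as returned by [unit_variance_scale()].
#' @export
unscale <- function(block, centers, scales) {
  out <- block
  out$values <- sweep(sweep(.as_block_matrix(block), 2L, scales, "*"),
                      2L, centers, "+")
  out
}

#' Drop features with too many missing values
#'
#' Features whose missing fraction is strictly greater than
#' `max_missing_fraction` are removed; the standard screen drops peaks with
#' more than 30\% missing measurements.
#'
#' @param block an [omics_block()].
#' @param max_missing_fraction in `[0, 1)`.
#' @return the filtered `OmicsBlock` (feature order preserved).
#' @export
filter_missing <- function(block, max_missing_fraction = 0.3) {
  .assert(.is_number(max_missing_fraction) &&
            max_missing_fraction >= 0 && max_missing_fraction < 1,
          "max_missing_fraction must lie in [0, 1)")
  v <- .as_block_matrix(block)
  keep <- colMeans(is.na(v)) <= max_missing_fraction
  out <- block
  out$values <- v[, keep, drop = FALSE]
  out$annotations <- block$annotations[keep]
  out
}

#' Impute remaining missing cells with the feature mean
#'
#' Applied after [filter_missing()]: the latent-variable models require
#' complete matrices, and on centered/scaled data the feature mean is zero, so
#' this is the minimal-assumption fill-in.
#'
#' @param block an [omics_block()].
#' @export
impute_feature_mean <- function(block) {
  v <- .as_block_matrix(block)
  .assert(all(colSums(!is.na(v)) > 0), "all-missing feature cannot be imputed")
  idx <- which(is.na(v), arr.ind = TRUE)
  if (nrow(idx) > 0) {
    m <- colMeans(v, na.rm = TRUE)
    v[idx] <- m[idx[, 2L]]
  }
  out <- block
  out$values <- v
  out
}

#' Concatenate blocks and merge correlated same-annotation peaks
#'
#' Blocks are concatenated along the feature axis. Within each group of
#' features sharing a (non-"unknown") metabolite annotation, the members whose
#' mean pairwise absolute Pearson correlation with the rest of the group
#' exceeds `correlation_threshold` are replaced by the scores of the first principal
#' component of that subgroup (computed on the autoscaled subgroup via
#' missing-value tolerant NIPALS, sign-oriented to correlate positively with
#' the subgroup mean profile). Unannotated and uncorrelated features pass
#' through unchanged.
#'
#' @param blocks list of [omics_block()]s sharing the same samples.
#' @param correlation_threshold mean pairwise Pearson correlation above which
#'   same-annotation peaks are merged (default 0.5).
#' @return an `OmicsBlock` with platform `"summarized"`; the attribute
#'   `"provenance"` records which input features each output feature came from.
#' @export
summarize_annotated_peaks <- function(blocks, correlation_threshold = 0.5) {
  if (inherits(blocks, "OmicsBlock")) blocks <- list(blocks)
  .assert(length(blocks) >= 1L, "need at least one block")
  sids <- sample_ids(blocks[[1L]])
  for (b in blocks) {
    .assert(identical(sample_ids(b), sids),
            "blocks must share the same samples in the same order")
  }
  big <- do.call(cbind, lapply(blocks, .as_block_matrix))
  fid <- unlist(lapply(blocks, feature_ids), use.names = FALSE)
  if (anyDuplicated(fid)) {
    fid <- make.unique(fid, sep = "#")
  }
  colnames(big) <- fid
  ann <- stats::setNames(
    unlist(lapply(blocks, function(b) b$annotations), use.names = FALSE), fid)

  keep_cols <- rep(TRUE, ncol(big))
  merged_scores <- list()
  merged_ann <- character(0)
  provenance <- as.list(stats::setNames(fid, fid))

  for (a in unique(ann[ann != "unknown"])) {
    grp <- which(ann == a)
    if (length(grp) < 2L) next
    cc <- suppressWarnings(stats::cor(big[, grp, drop = FALSE],
                                      use = "pairwise.complete.obs"))
    diag(cc) <- NA
    # absolute correlation: peaks of one metabolite may be anti-correlated
    # (e.g. adduct competition) yet still carry the same signal
    mean_cor <- rowMeans(abs(cc), na.rm = TRUE)
    sub <- grp[!is.na(mean_cor) & mean_cor > correlation_threshold]
    if (length(sub) < 2L) next
    sc <- .first_pc_scores(big[, sub, drop = FALSE])
    merged_id <- paste0(a, ".summary")
    merged_scores[[merged_id]] <- sc
    merged_ann[merged_id] <- a
    provenance[[merged_id]] <- fid[sub]
    keep_cols[sub] <- FALSE
    provenance[fid[sub]] <- NULL
  }

  out_vals <- big[, keep_cols, drop = FALSE]
  if (length(merged_scores) > 0) {
    out_vals <- cbind(out_vals, do.call(cbind, merged_scores))
  }
  out_ann <- c(ann[keep_cols], merged_ann)
  blk <- omics_block(out_vals, platform = "summarized", annotations = out_ann)
  attr(blk, "provenance") <- provenance[colnames(out_vals)]
  blk
}

# First-PC scores of an autoscaled submatrix, tolerant of missing cells,
# oriented to correlate positively with the row-mean profile.
.first_pc_scores <- function(sub) {
  st <- .col_stats(sub)
  st$scale[st$scale == 0] <- 1
  z <- sweep(sweep(sub, 2L, st$center, "-"), 2L, st$scale, "/")
  fit <- nipals_pca(z, n_components = 1L, center = FALSE)
  sc <- fit$scores[, 1L]
  ref <- rowMeans(z, na.rm = TRUE)
  if (isTRUE(stats::cor(sc, ref, use = "complete.obs") < 0)) sc <- -sc
  sc
}

#' Regress population structure out of a trait
#'
#' Fits the trait on the membership matrix Q by least squares,
#' `Z = Q B + Y`, and returns the residual `Y` as the structure-corrected
#' trait. Because membership rows sum to one, Q's column space contains the
#' intercept, so no separate intercept is added; a pseudoinverse handles
#' rank-deficient Q. Samples with a missing trait value are excluded from the
#' fit and stay missing in the output.
#'
#' @param trait a [trait_vector()].
#' @param q a [population_membership()].
#' @return the corrected `TraitVector` (`corrected = TRUE`), with attribute
#'   `"coefficients"` holding the estimated B.
#' @export
correct_population_structure <- function(trait, q) {
  z <- trait$values
  Q <- q$q
  .assert(setequal(names(z), rownames(Q)),
          "trait and Q-matrix sample sets differ")
  Q <- Q[names(z), , drop = FALSE]
  ok <- !is.na(z)
  .assert(sum(ok) > ncol(Q),
          "fewer samples (%d) than subpopulations (%d)", sum(ok), ncol(Q))
  B <- .pinv(Q[ok, , drop = FALSE]) %*% z[ok]
  y <- z
  y[ok] <- z[ok] - drop(Q[ok, , drop = FALSE] %*% B)
  out <- trait_vector(y, name = trait$name, corrected = TRUE)
  attr(out, "coefficients") <- stats::setNames(drop(B), colnames(Q))
  out
}

# Moore-Penrose pseudoinverse via SVD.
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  pos <- s$d > tol * max(s$d, 1)
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Missing-value tolerant PCA by NIPALS
#'
#' Iterative NIPALS principal component analysis that simply skips missing
#' cells in every inner product, the classical approach for abundance
#' matrices with scattered missing measurements. Components are extracted by
#' successive deflation and reported in order of explained variance.
#'
#' @param x numeric matrix or [omics_block()] (samples x features).
#' @param n_components number of components to extract.
#' @param center center columns on their non-missing means first.
#' @param max_iter,tol NIPALS iteration control; convergence is declared when
#'   the relative change of the score vector drops below `tol`.
#' @return list with `scores` (n x k), `loadings` (p x k, unit norm),
#'   `r2` (explained-variance fraction per component) and `converged`
#'   (logical per component).
#' @export
nipals_pca <- function(x, n_components = 2L, center = TRUE,
                       max_iter = 500L, tol = 1e-9) {
  v <- if (inherits(x, "OmicsBlock")) x$values else x
  .assert(is.matrix(v) && is.numeric(v), "x must be a numeric matrix")
  n <- nrow(v); p <- ncol(v)
  .assert(n_components >= 1L && n_components <= min(n, p),
          "n_components must be in [1, min(n, p)]")
  all_missing <- colSums(!is.na(v)) == 0
  .assert(!any(all_missing), "all-missing column(s): %s",
          paste(colnames(v)[all_missing], collapse = ", "))
  if (center) v <- sweep(v, 2L, colMeans(v, na.rm = TRUE), "-")
  miss <- is.na(v)
  w <- v
  w[miss] <- 0                       # zeros drop out of the masked products
  tss <- sum(w^2)
  scores <- matrix(0, n, n_components)
  loadings <- matrix(0, p, n_components)
  r2 <- numeric(n_components)
  converged <- logical(n_components)
  obs <- 1 - miss                    # 0/1 mask for denominator sums

  for (k in seq_len(n_components)) {
    t_vec <- w[, which.max(colSums(w^2))]
    for (it in seq_len(max_iter)) {
      # p = sum over observed cells of x*t / sum t^2, columnwise
      denom_p <- drop(crossprod(obs, t_vec^2))
      p_vec <- drop(crossprod(w, t_vec)) / pmax(denom_p, .Machine$double.eps)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      denom_t <- drop(obs %*% p_vec^2)
      t_new <- drop(w %*% p_vec) / pmax(denom_t, .Machine$double.eps)
      delta <- sqrt(sum((t_new - t_vec)^2) / max(sum(t_new^2), .Machine$double.eps))
      t_vec <- t_new
      if (delta < tol) { converged[k] <- TRUE; break }
    }
    scores[, k] <- t_vec
    loadings[, k] <- p_vec
    r2[k] <- sum((tcrossprod(t_vec, p_vec) * obs)^2) / tss
    w <- w - tcrossprod(t_vec, p_vec) * obs
  }
  ord <- order(r2, decreasing = TRUE)
  list(scores = scores[, ord, drop = FALSE],
       loadings = loadings[, ord, drop = FALSE],
       r2 = r2[ord], converged = converged[ord])
}

#' One-call preprocessing of a raw block
#'
#' Convenience wrapper chaining [log2_transform()] (optional),
#' [filter_missing()], [unit_variance_scale()] and [impute_feature_mean()].
#'
#' @param block an [omics_block()].
#' @param log2_offset offset for the log transform, or `NULL` to skip it
#'   (synthetic data is already on a signed scale).
#' @param max_missing_fraction passed to [filter_missing()].
#' @return list with the model-ready `block`, `centers` and `scales`.
#' @export
preprocess_block <- function(block, log2_offset = NULL,
                             max_missing_fraction = 0.3) {
  if (!is.null(log2_offset)) block <- log2_transform(block, log2_offset)
  block <- filter_missing(block, max_missing_fraction)
  sc <- unit_variance_scale(block)
  list(block = impute_feature_mean(sc$block),
       centers = sc$centers, scales = sc$scales)
}
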