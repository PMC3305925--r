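# Multi-block OPLS: per-block OPLS filtering of response-orthogonal
# variance, concatenation of the filtered blocks into a top-level regressor
# matrix, and a top-level OPLS model. With a single block and no block-level
# filtering the method reduces exactly to ordinary OPLS. The model has
# n_blocks + 1 structural parameters: one orthogonal count per block plus
# the top-level count, chosen by internal seven-fold cross-validation.

#' Build the top-level regressor matrix from fitted block models
#'
#' For each block, the orthogonal-filtered matrix (the response-correlated
#' part plus residual, `t p' + E = X - T_o P_o'`) is taken and the blocks are
#' concatenated along the feature axis.
#'
#' @param block_models list of `OplsModel`s trained on the same samples.
#' @return the concatenated regressor matrix.
#' @export
build_top_regressors <- function(block_models) {
  .assert(length(block_models) >= 1L, "need at least one block model")
  n <- length(block_models[[1L]]$t)
  for (m in block_models) {
    .assert(length(m$t) == n, "block models were trained on different sample sets")
  }
  mats <- lapply(block_models, function(m) {
    x <- m$X_filtered
    colnames(x) <- m$feature_ids
    x
  })
  do.call(cbind, mats)
}

#' Fit a multi-block OPLS model
#'
#' Two steps: (1) each block is regressed on the trait by OPLS with its own
#' orthogonal-component count, removing block-specific trait-orthogonal
#' variance (platform bias); (2) the filtered blocks are concatenated and a
#' top-level OPLS model is fitted on the result. Blocks are autoscaled
#' (center + unit variance) on the training data unless `scale. = FALSE`;
#' the trait is always centered internally and predictions are reported on
#' its original scale.
#'
#' @param blocks list of [omics_block()]s or complete numeric matrices
#'   sharing samples in the same order.
#' @param y trait values (numeric or [trait_vector()]), no missing entries.
#' @param n_orth_per_block integer vector (recycled) of per-block orthogonal
#'   counts.
#' @param n_orth_top orthogonal count of the top-level model.
#' @param scale. autoscale blocks on the training data (disable when the
#'   caller has already scaled them).
#' @return an object of class `MbOplsModel`.
#' @export
fit_mbopls <- function(blocks, y, n_orth_per_block = 0L, n_orth_top = 0L,
                       scale. = TRUE) {
  if (!is.list(blocks) || inherits(blocks, "OmicsBlock")) blocks <- list(blocks)
  mats <- lapply(blocks, .as_block_matrix)
  y <- .as_trait_values(y)
  n <- nrow(mats[[1L]])
  for (m in mats) {
    .check_complete_matrix(m, "block")
    .assert(nrow(m) == n, "blocks have differing sample counts")
  }
  .assert(length(y) == n && !anyNA(y), "y must be complete with one value per sample")
  n_orth_per_block <- as.integer(rep_len(n_orth_per_block, length(mats)))
  .assert(all(n_orth_per_block >= 0L) && n_orth_top >= 0L,
          "orthogonal counts must be >= 0")

  centers <- scales <- vector("list", length(mats))
  for (i in seq_along(mats)) {
    st <- .col_stats(mats[[i]])
    if (!scale.) { st$center[] <- 0; st$scale[] <- 1 }
    .assert(all(st$scale > 0), "zero-variance feature in block %d", i)
    centers[[i]] <- st$center; scales[[i]] <- st$scale
    mats[[i]] <- .center_scale_cols(mats[[i]], st$center, st$scale)
  }
  y_mean <- mean(y)
  yc <- y - y_mean

  block_models <- vector("list", length(mats))
  for (i in seq_along(mats)) {
    block_models[[i]] <- fit_opls(mats[[i]], yc, n_orth_per_block[i])
  }
  X_top <- build_top_regressors(block_models)
  top_model <- fit_opls(X_top, yc, as.integer(n_orth_top))

  block_names <- vapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    if (inherits(b, "OmicsBlock")) b$platform else paste0("block", i)
  }, character(1))
  m <- list(block_models = block_models, top_model = top_model,
            n_orth_per_block = n_orth_per_block,
            n_orth_top = as.integer(n_orth_top),
            block_names = block_names,
            feature_offsets = cumsum(c(0L, vapply(mats, ncol, 0L)))[seq_along(mats)],
            centers = centers, scales = scales,
            y_mean = y_mean, trait_name = attr(y, "name") %||% "trait",
            cv_meta = NULL)
  class(m) <- "MbOplsModel"
  m
}

#' @export
print.MbOplsModel <- function(x, ...) {
  cat(sprintf("MbOplsModel: %d block(s), orthogonal counts [%s] + top %d\n",
              length(x$block_models),
              paste(x$n_orth_per_block, collapse = ", "), x$n_orth_top))
  invisible(x)
}

#' Predict from a multi-block OPLS model
#'
#' Applies the stored training centers/scales to each new block, deflates
#' each block by its fitted orthogonal components, concatenates, and runs
#' top-level OPLS prediction. Predictions are on the original trait scale.
#'
#' @param model an `MbOplsModel`.
#' @param new_blocks list of matrices/[omics_block()]s matching the training
#'   blocks' features, in the same block order.
#' @return numeric vector of predictions.
#' @export
predict_mbopls <- function(model, new_blocks) {
  if (!is.list(new_blocks) || inherits(new_blocks, "OmicsBlock"))
    new_blocks <- list(new_blocks)
  .assert(length(new_blocks) == length(model$block_models),
          "expected %d blocks, got %d", length(model$block_models),
          length(new_blocks))
  filtered <- vector("list", length(new_blocks))
  for (i in seq_along(new_blocks)) {
    x <- .as_block_matrix(new_blocks[[i]])
    bm <- model$block_models[[i]]
    .assert(ncol(x) == length(bm$w),
            "block %d has %d features; model expects %d", i, ncol(x),
            length(bm$w))
    if (!is.null(colnames(x)) && !is.null(bm$feature_ids)) {
      .assert(identical(colnames(x), bm$feature_ids),
              "block %d feature IDs do not match the model", i)
    }
    x <- .center_scale_cols(x, model$centers[[i]], model$scales[[i]])
    filtered[[i]] <- .opls_deflate(bm, x)$X
  }
  X_top <- do.call(cbind, filtered)
  d <- .opls_deflate(model$top_model, X_top)
  drop(model$top_model$c * (d$X %*% model$top_model$w)) + model$y_mean
}

#' Fitted values of a multi-block OPLS model
#' @param object an `MbOplsModel`.
#' @param ... unused.
#' @export
fitted.MbOplsModel <- function(object, ...) {
  object$top_model$c * drop(object$top_model$X_filtered %*% object$top_model$w) +
    object$y_mean
}

#' Correlation loadings of a multi-block OPLS model
#'
#' Per concatenated feature: correlation between the top-level predictive
#' score and the feature's orthogonal-filtered values.
#'
#' @param model an `MbOplsModel`.
#' @return named numeric vector over all block features.
#' @export
mbopls_correlation_loadings <- function(model) {
  correlation_loadings(model$top_model)
}

# Internal CV Q2 curves for one regressor set: pooled PRESS/TSS over folds,
# TSS about the training-fold mean, computed for every orthogonal count
# 0..max_orth in one incremental pass per fold.
.q2_curve <- function(X, y, folds, max_orth) {
  n_folds <- max(folds)
  press <- rep(0, max_orth + 1L)
  tss <- rep(0, max_orth + 1L)
  reached <- max_orth
  for (f in seq_len(n_folds)) {
    te <- folds == f
    Xtr <- X[!te, , drop = FALSE]
    ctr <- colMeans(Xtr)
    Xtr <- .center_scale_cols(Xtr, ctr)
    Xte <- .center_scale_cols(X[te, , drop = FALSE], ctr)
    ytr <- y[!te]
    mu <- mean(ytr)
    pr <- .opls_cv_path(Xtr, ytr - mu, Xte, max_orth)
    if (is.null(pr)) return(NULL)
    kk <- ncol(pr) - 1L
    reached <- min(reached, kk)
    res2 <- (y[te] - (pr + mu))^2
    press[seq_len(kk + 1L)] <- press[seq_len(kk + 1L)] + colSums(res2)
    tss[seq_len(kk + 1L)] <- tss[seq_len(kk + 1L)] + sum((y[te] - mu)^2)
  }
  idx <- seq_len(reached + 1L)
  1 - press[idx] / tss[idx]
}

# Greedy stopping rule on a Q2 curve indexed by orthogonal count 0..K:
# climb while the next count strictly improves Q2, stop at the first
# non-improvement.
.stop_rule <- function(q2) {
  k <- 0L
  while (k + 1L < length(q2) && q2[k + 2L] > q2[k + 1L]) k <- k + 1L
  k
}

#' Choose orthogonal-component counts by internal cross-validation
#'
#' The n_blocks + 1 structural parameters are selected sequentially: each
#' block's orthogonal count is chosen independently by maximizing the
#' internal cross-validated Q2 of that block's own OPLS regression on the
#' trait (scanning 0..`max_orth_block`, stopping at the first count that no
#' longer improves Q2); then, with the block counts fixed, the top-level
#' count is chosen the same way. Q2 is `1 - PRESS/TSS` with TSS about the
#' training-fold mean. Folds are a balanced random partition drawn from
#' `seed`, so the selection is deterministic given the seed.
#'
#' @param blocks list of complete blocks (matrices or [omics_block()]s).
#' @param y complete trait values.
#' @param max_orth_block,max_orth_top largest counts scanned.
#' @param n_folds internal folds (default 7).
#' @param seed integer seed for the fold partition; `NULL` uses the current
#'   RNG state.
#' @param scale. autoscale blocks first (on all provided samples).
#' @return list with `n_orth_per_block`, `n_orth_top`, `cv_curves` (per-block
#'   and top Q2 curves), `folds` and `seed`.
#' @export
select_components <- function(blocks, y, max_orth_block = 3L, max_orth_top = 3L,
                              n_folds = 7L, seed = NULL, scale. = TRUE) {
  if (!is.list(blocks) || inherits(blocks, "OmicsBlock")) blocks <- list(blocks)
  mats <- lapply(blocks, .as_block_matrix)
  y <- .as_trait_values(y)
  n <- length(y)
  .assert(!anyNA(y), "y must be complete")
  for (m in mats) .check_complete_matrix(m, "block")
  if (scale.) {
    mats <- lapply(mats, function(m) {
      st <- .col_stats(m)
      .assert(all(st$scale > 0), "zero-variance feature")
      .center_scale_cols(m, st$center, st$scale)
    })
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  folds <- .balanced_folds(n, n_folds)

  curves <- vector("list", length(mats) + 1L)
  n_orth_blocks <- integer(length(mats))
  for (i in seq_along(mats)) {
    q2 <- .q2_curve(mats[[i]], y, folds, max_orth_block)
    .assert(!is.null(q2), "block %d is uncorrelated with the trait", i)
    if (length(q2) < max_orth_block + 1L) {
      warning(sprintf("block %d: orthogonal scan truncated at %d component(s)",
                      i, length(q2) - 1L), call. = FALSE)
    }
    n_orth_blocks[i] <- .stop_rule(q2)
    curves[[i]] <- q2
  }

  # Top-level scan: per fold, refit the blocks at their chosen counts on the
  # fold-training samples, build the filtered concatenation for both halves.
  press <- rep(0, max_orth_top + 1L)
  tss <- rep(0, max_orth_top + 1L)
  reached <- max_orth_top
  for (f in seq_len(n_folds)) {
    te <- folds == f
    ytr <- y[!te]
    mu <- mean(ytr)
    tr_f <- te_f <- vector("list", length(mats))
    for (i in seq_along(mats)) {
      Xtr <- mats[[i]][!te, , drop = FALSE]
      ctr <- colMeans(Xtr)
      Xtr <- .center_scale_cols(Xtr, ctr)
      Xte <- .center_scale_cols(mats[[i]][te, , drop = FALSE], ctr)
      bm <- .opls_core(Xtr, ytr - mu, n_orth_blocks[i])
      tr_f[[i]] <- bm$X_filtered
      te_f[[i]] <- .opls_deflate(bm, Xte)$X
    }
    pr <- .opls_cv_path(do.call(cbind, tr_f), ytr - mu,
                        do.call(cbind, te_f), max_orth_top)
    .assert(!is.null(pr), "top-level regressors uncorrelated with the trait")
    kk <- ncol(pr) - 1L
    reached <- min(reached, kk)
    res2 <- (y[te] - (pr + mu))^2
    press[seq_len(kk + 1L)] <- press[seq_len(kk + 1L)] + colSums(res2)
    tss[seq_len(kk + 1L)] <- tss[seq_len(kk + 1L)] + sum((y[te] - mu)^2)
  }
  q2_top <- 1 - press[seq_len(reached + 1L)] / tss[seq_len(reached + 1L)]
  if (reached < max_orth_top) {
    warning(sprintf("top level: orthogonal scan truncated at %d component(s)",
                    reached), call. = FALSE)
  }
  curves[[length(mats) + 1L]] <- q2_top
  names(curves) <- c(paste0("block", seq_along(mats)), "top")
  list(n_orth_per_block = n_orth_blocks, n_orth_top = .stop_rule(q2_top),
       cv_curves = curves, folds = folds, seed = seed)
}
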