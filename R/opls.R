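# Single-response OPLS (orthogonal projections to latent structures).
#
# The decomposition is X = t p' + T_o P_o' + E with a single predictive
# component: the response-correlated variance lives in t, structured
# response-orthogonal variance in the T_o columns, and E is unmodelled.
# Because the response is a single vector, the predictive weight
# w ~ X'y is invariant under orthogonal deflation (X'y is unchanged when
# t_o ' y = 0), so w is computed once up front.

# Lean fitting core used by every hot loop. X complete, columns centered
# (scaling is the caller's business), y centered. No class dressing.
.opls_core <- function(X, y, n_orth, w_tol = 1e-10) {
  w <- drop(crossprod(X, y))
  nw <- sqrt(sum(w^2))
  if (nw < w_tol) stop("response is uncorrelated with every feature", call. = FALSE)
  w <- w / nw
  k <- 0L
  W_o <- P_o <- matrix(0, ncol(X), 0L)
  T_o <- matrix(0, nrow(X), 0L)
  while (k < n_orth) {
    t_vec <- drop(X %*% w)
    tt <- sum(t_vec^2)
    p_vec <- drop(crossprod(X, t_vec)) / tt
    w_o <- p_vec - sum(w * p_vec) * w
    n_wo <- sqrt(sum(w_o^2))
    if (n_wo < w_tol) {
      stop("insufficient orthogonal variance for ", n_orth,
           " orthogonal components (", k, " available)", call. = FALSE)
    }
    w_o <- w_o / n_wo
    t_o <- drop(X %*% w_o)
    p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
    X <- X - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    T_o <- cbind(T_o, t_o)
    k <- k + 1L
  }
  t_vec <- drop(X %*% w)
  tt <- sum(t_vec^2)
  p_vec <- drop(crossprod(X, t_vec)) / tt
  c_coef <- sum(y * t_vec) / tt
  list(w = w, t = t_vec, p = p_vec, c = c_coef,
       W_orth = W_o, P_orth = P_o, T_orth = T_o,
       X_filtered = X, E = X - tcrossprod(t_vec, p_vec), n_orth = k)
}

# Deflate new data by the fitted orthogonal components.
.opls_deflate <- function(fit, X_new) {
  T_new <- matrix(0, nrow(X_new), fit$n_orth)
  for (k in seq_len(fit$n_orth)) {
    t_o <- drop(X_new %*% fit$W_orth[, k])
    X_new <- X_new - tcrossprod(t_o, fit$P_orth[, k])
    T_new[, k] <- t_o
  }
  list(X = X_new, T_orth = T_new)
}

# Cross-validation path: fit on (Xtr, ytr), predict Xte at every orthogonal
# count 0..max_orth in a single incremental pass. Returns an n_te x (K+1)
# matrix of centered-scale predictions, where K <= max_orth is the number of
# orthogonal components actually available.
.opls_cv_path <- function(Xtr, ytr, Xte, max_orth, w_tol = 1e-10) {
  w <- drop(crossprod(Xtr, ytr))
  nw <- sqrt(sum(w^2))
  if (nw < w_tol) return(NULL)
  w <- w / nw
  preds <- matrix(0, nrow(Xte), max_orth + 1L)
  t_vec <- drop(Xtr %*% w)
  tt <- sum(t_vec^2)
  c_coef <- sum(ytr * t_vec) / tt
  preds[, 1L] <- c_coef * drop(Xte %*% w)
  k <- 0L
  while (k < max_orth) {
    p_vec <- drop(crossprod(Xtr, t_vec)) / tt
    w_o <- p_vec - sum(w * p_vec) * w
    n_wo <- sqrt(sum(w_o^2))
    if (n_wo < w_tol) break
    w_o <- w_o / n_wo
    t_o <- drop(Xtr %*% w_o)
    p_o <- drop(crossprod(Xtr, t_o)) / sum(t_o^2)
    Xtr <- Xtr - tcrossprod(t_o, p_o)
    Xte <- Xte - tcrossprod(drop(Xte %*% w_o), p_o)
    t_vec <- drop(Xtr %*% w)
    tt <- sum(t_vec^2)
    c_coef <- sum(ytr * t_vec) / tt
    k <- k + 1L
    preds[, k + 1L] <- c_coef * drop(Xte %*% w)
  }
  preds[, seq_len(k + 1L), drop = FALSE]
}

#' Fit a single-block OPLS model
#'
#' NIPALS OPLS for a single response: the predictive weight is
#' `w = X'y / ||X'y||`; each orthogonal round removes from X the structured
#' variance orthogonal to the response (`w_o` from the loading residual,
#' scores `t_o = X w_o`, deflation `X <- X - t_o p_o'`); the final predictive
#' component is computed on the deflated matrix. Exactly one predictive
#' component is used, as appropriate for a single quantitative trait.
#'
#' @param X complete numeric matrix (samples x features), columns
#'   centered/scaled by the caller.
#' @param y centered response vector.
#' @param n_orth number of orthogonal components (>= 0).
#' @param w_tol below this norm an orthogonal weight is considered absent and
#'   fitting stops with an error.
#' @return an object of class `OplsModel` with fields `w`, `t`, `p`, `c`
#'   (regression coefficient of y on t), `W_orth`, `P_orth`, `T_orth`, `E`,
#'   `X_filtered` (the orthogonal-filtered matrix `t p' + E`), `n_orth` and
#'   `feature_ids`.
#' @export
fit_opls <- function(X, y, n_orth = 0L, w_tol = 1e-10) {
  .check_complete_matrix(X, "X")
  y <- .as_trait_values(y)
  .assert(length(y) == nrow(X), "length(y) must equal nrow(X)")
  .assert(nrow(X) >= 3L, "need at least 3 samples")
  .assert(!anyNA(y), "y contains missing values")
  .assert(stats::sd(y) > 0, "y is constant")
  .assert(n_orth >= 0L, "n_orth must be >= 0")
  fit <- .opls_core(X, y - mean(y), as.integer(n_orth), w_tol)
  fit$feature_ids <- colnames(X)
  fit$y_mean <- mean(y)
  class(fit) <- "OplsModel"
  fit
}

#' @export
print.OplsModel <- function(x, ...) {
  cat(sprintf("OplsModel: %d samples x %d features, 1 predictive + %d orthogonal\n",
              length(x$t), length(x$w), x$n_orth))
  invisible(x)
}

#' Predict from a fitted OPLS model
#'
#' New data are first deflated by each fitted orthogonal component
#' (`t_o = X w_o`; `X <- X - t_o p_o'`), then the prediction is
#' `y_hat = c (X_filtered w)` (centered-response scale, plus the stored
#' training mean).
#'
#' @param model an `OplsModel`.
#' @param X_new matrix with the model's features, already on the training
#'   center/scale.
#' @return list with `y_hat`, the orthogonal-filtered matrix `X_filtered`,
#'   and the new orthogonal scores `T_orth_new`.
#' @export
predict_opls <- function(model, X_new) {
  .check_complete_matrix(X_new, "X_new")
  .assert(ncol(X_new) == length(model$w),
          "X_new has %d features; model expects %d", ncol(X_new), length(model$w))
  if (!is.null(model$feature_ids) && !is.null(colnames(X_new))) {
    .assert(identical(colnames(X_new), model$feature_ids),
            "X_new feature IDs do not match the model")
  }
  d <- .opls_deflate(model, X_new)
  y_hat <- model$c * drop(d$X %*% model$w) + (model$y_mean %||% 0)
  list(y_hat = y_hat, X_filtered = d$X, T_orth_new = d$T_orth)
}

#' Correlation loadings of an OPLS model
#'
#' The interpretive weight of each feature: the Pearson correlation between
#' the predictive score t and that feature's column of the
#' orthogonal-filtered training matrix. Values lie in `[-1, 1]`; features
#' with zero variance after filtering get `NA`.
#'
#' @param model an `OplsModel`.
#' @param X the training matrix the model was fitted on (scaled); if omitted
#'   the stored filtered matrix is used.
#' @return named numeric vector `p_C`.
#' @export
correlation_loadings <- function(model, X = NULL) {
  Xf <- if (is.null(X)) model$X_filtered else .opls_deflate(model, X)$X
  t_vec <- model$t
  sds <- .col_stats(Xf)$scale
  pc <- rep(NA_real_, ncol(Xf))
  ok <- sds > 0
  if (any(ok)) pc[ok] <- drop(stats::cor(t_vec, Xf[, ok, drop = FALSE]))
  names(pc) <- model$feature_ids %||% colnames(Xf)
  pc
}

#' Serialize / restore an OPLS model
#'
#' JSON container with a version tag, feature IDs, all component vectors and
#' matrices, and preprocessing metadata, so a fitted model survives a round
#' trip to disk.
#'
#' @param model an `OplsModel` or `MbOplsModel`.
#' @param path file to write / read.
#' @export
write_model <- function(model, path) {
  ser <- .serialize_model(model)
  jsonlite::write_json(ser, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  .deserialize_model(jsonlite::read_json(path, simplifyVector = FALSE))
}

.serialize_model <- function(model) {
  if (inherits(model, "MbOplsModel")) {
    list(container = "MbOplsModel", version = "1",
         block_models = lapply(model$block_models, .serialize_model),
         top_model = .serialize_model(model$top_model),
         n_orth_per_block = model$n_orth_per_block,
         n_orth_top = model$n_orth_top,
         block_names = model$block_names,
         centers = model$centers, scales = model$scales,
         y_mean = model$y_mean, trait_name = model$trait_name,
         cv_meta = model$cv_meta)
  } else {
    m <- unclass(model)
    m$X_filtered <- NULL     # reconstructable as t p' + E; keep files small
    c(list(container = "OplsModel", version = "1"),
      lapply(m, function(v) if (is.matrix(v)) apply(v, 2L, identity, simplify = FALSE) else v))
  }
}

.deserialize_model <- function(s) {
  num <- function(v) as.numeric(unlist(v))
  if (identical(s$container, "MbOplsModel")) {
    m <- list(block_models = lapply(s$block_models, .deserialize_model),
              top_model = .deserialize_model(s$top_model),
              n_orth_per_block = as.integer(unlist(s$n_orth_per_block)),
              n_orth_top = as.integer(s$n_orth_top),
              block_names = as.character(unlist(s$block_names)),
              centers = lapply(s$centers, num),
              scales = lapply(s$scales, num),
              y_mean = as.numeric(s$y_mean),
              trait_name = s$trait_name,
              cv_meta = s$cv_meta)
    class(m) <- "MbOplsModel"
    return(m)
  }
  tomat <- function(v) {
    if (is.list(v) && length(v) > 0) do.call(cbind, lapply(v, num))
    else matrix(numeric(0), 0, 0)
  }
  m <- list(w = num(s$w), t = num(s$t), p = num(s$p),
            c = as.numeric(s$c),
            W_orth = tomat(s$W_orth), P_orth = tomat(s$P_orth),
            T_orth = tomat(s$T_orth), E = tomat(s$E),
            n_orth = as.integer(s$n_orth),
            feature_ids = as.character(unlist(s$feature_ids)),
            y_mean = as.numeric(s$y_mean))
  if (length(m$E)) m$X_filtered <- tcrossprod(m$t, m$p) + m$E
  if (m$n_orth == 0L) {
    m$W_orth <- m$P_orth <- matrix(0, length(m$w), 0L)
    m$T_orth <- matrix(0, length(m$t), 0L)
  }
  class(m) <- "OplsModel"
  m
}
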