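#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules. Nothing here is exported.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ..., call. = FALSE) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = call.)
}

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Balanced random fold assignment using the current RNG state.
.balanced_folds <- function(n, k) {
  .assert(k >= 2L, "need at least 2 folds, got %d", k)
  .assert(n >= k, "cannot split %d samples into %d folds", n, k)
  sample(rep_len(seq_len(k), n))
}

# Derive a child seed from a parent seed and a stream index; kept < 2^31.
.derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + as.double(stream) * 16807) %% 2147483647
}

# Rolling polynomial hash of a character scalar, for config fingerprints.
.fnv1a <- function(s) {
  bytes <- utf8ToInt(enc2utf8(s))
  h <- 5381
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Column means / sds over non-missing entries (sample sd, n-1 denominator).
# Vectorized: this sits on the cross-validation hot path.
.col_stats <- function(x) {
  if (anyNA(x)) {
    n_ok <- colSums(!is.na(x))
    m <- colMeans(x, na.rm = TRUE)
    ss <- colSums(x * x, na.rm = TRUE) - n_ok * m * m
    s <- sqrt(pmax(ss, 0) / pmax(n_ok - 1L, 1L))
    s[n_ok < 2L] <- NA_real_
  } else {
    n <- nrow(x)
    m <- colMeans(x)
    ss <- colSums(x * x) - n * m * m
    s <- sqrt(pmax(ss, 0) / (n - 1L))
  }
  list(center = m, scale = s)
}

# Biased empirical p-value of permutation tests: ties count toward the null.
.empirical_p <- function(n0, n_perm) (n0 + 1) / (n_perm + 1)

# Column centering/scaling without sweep()'s aperm overhead (hot path).
.center_scale_cols <- function(x, center, scale = NULL) {
  n <- nrow(x)
  x <- x - rep(center, each = n)
  if (!is.null(scale)) x <- x / rep(scale, each = n)
  x
}

.check_complete_matrix <- function(x, what = "matrix") {
  .assert(is.matrix(x) && is.numeric(x), "%s must be a numeric matrix", what)
  .assert(!anyNA(x), "%s contains missing values; filter/impute first", what)
  invisible(x)
}
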