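#' Construct an omics block
#'
#' An `OmicsBlock` is one analytical platform's sample-by-feature abundance
#' matrix, the basic unit handled by the preprocessing and multi-block
#' modelling functions. Rows are samples, columns are features; missing
#' measurements are `NA`. Features may optionally carry a metabolite
#' annotation; features without one are tagged `"unknown"`.
#'
#' @param values numeric matrix, samples in rows (rownames = sample IDs),
#'   features in columns (colnames = feature IDs). `NA` marks missing cells.
#' @param platform label of the analytical platform (e.g. `"GC-MS"`).
#' @param annotations optional named character vector mapping feature IDs to
#'   metabolite identifiers. Unlisted features are annotated `"unknown"`.
#' @return an object of class `OmicsBlock`.
#' @export
omics_block <- function(values, platform = "block", annotations = NULL) {
  .assert(is.matrix(values) && is.numeric(values),
          "values must be a numeric matrix")
  if (is.null(rownames(values)))
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("F", seq_len(ncol(values)))
  .assert(!anyDuplicated(rownames(values)),
          "duplicate sample IDs: %s",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  .assert(!anyDuplicated(colnames(values)),
          "duplicate feature IDs: %s",
          paste(unique(colnames(values)[duplicated(colnames(values))]),
                collapse = ", "))
  ann <- stats::setNames(rep("unknown", ncol(values)), colnames(values))
  if (!is.null(annotations)) {
    .assert(!is.null(names(annotations)), "annotations must be named")
    keep <- intersect(names(annotations), colnames(values))
    ann[keep] <- as.character(annotations[keep])
  }
  structure(list(values = values, platform = platform, annotations = ann),
            class = "OmicsBlock")
}

#' @export
print.OmicsBlock <- function(x, ...) {
  cat(sprintf("OmicsBlock '%s': %d samples x %d features (%.1f%% missing)\n",
              x$platform, nrow(x$values), ncol(x$values),
              100 * mean(is.na(x$values))))
  n_ann <- sum(x$annotations != "unknown")
  cat(sprintf("  annotated features: %d\n", n_ann))
  invisible(x)
}

#' @rdname omics_block
#' @param x an `OmicsBlock`.
#' @export
sample_ids <- function(x) UseMethod("sample_ids")

#' @export
sample_ids.OmicsBlock <- function(x) rownames(x$values)

#' @export
sample_ids.TraitVector <- function(x) names(x$values)

#' @export
sample_ids.PopulationMembership <- function(x) rownames(x$q)

#' @rdname omics_block
#' @export
feature_ids <- function(x) UseMethod("feature_ids")

#' @export
feature_ids.OmicsBlock <- function(x) colnames(x$values)

#' Construct a trait vector
#'
#' One quantitative trait measured across samples, either raw or after
#' population-structure correction (see [correct_population_structure()]).
#'
#' @param values numeric vector, named by sample ID. `NA` marks samples
#'   without a measurement.
#' @param name trait label.
#' @param corrected logical; `TRUE` once population structure has been
#'   regressed out.
#' @return an object of class `TraitVector`.
#' @export
trait_vector <- function(values, name = "trait", corrected = FALSE) {
  .assert(is.numeric(values), "trait values must be numeric")
  if (is.null(names(values)))
    names(values) <- paste0("S", seq_along(values))
  .assert(!anyDuplicated(names(values)), "duplicate sample IDs in trait")
  structure(list(values = values, name = name, corrected = isTRUE(corrected)),
            class = "TraitVector")
}

#' @export
print.TraitVector <- function(x, ...) {
  cat(sprintf("TraitVector '%s': %d samples (%d missing)%s\n", x$name,
              length(x$values), sum(is.na(x$values)),
              if (x$corrected) ", structure-corrected" else ""))
  invisible(x)
}

#' Construct a population-membership matrix
#'
#' Sample-by-subpopulation membership probabilities (a Q-matrix, typically
#' estimated by a population-structure program). Rows must sum to one.
#'
#' @param q numeric matrix, samples in rows (rownames = sample IDs), one
#'   column per subpopulation.
#' @param tol tolerance on the row-sum check.
#' @return an object of class `PopulationMembership`.
#' @export
population_membership <- function(q, tol = 1e-6) {
  .assert(is.matrix(q) && is.numeric(q), "q must be a numeric matrix")
  .assert(ncol(q) >= 1L, "need at least one subpopulation column")
  .assert(all(q >= -tol & q <= 1 + tol), "membership entries must lie in [0, 1]")
  .assert(all(abs(rowSums(q) - 1) <= tol),
          "membership rows must sum to 1 (max deviation %.2g)",
          max(abs(rowSums(q) - 1)))
  if (is.null(rownames(q))) rownames(q) <- paste0("S", seq_len(nrow(q)))
  if (is.null(colnames(q))) colnames(q) <- paste0("pop", seq_len(ncol(q)))
  structure(list(q = q, subpopulation_labels = colnames(q)),
            class = "PopulationMembership")
}

#' @export
print.PopulationMembership <- function(x, ...) {
  cat(sprintf("PopulationMembership: %d samples, %d subpopulations (%s)\n",
              nrow(x$q), ncol(x$q),
              paste(x$subpopulation_labels, collapse = ", ")))
  invisible(x)
}

# Coerce a block argument (OmicsBlock or plain matrix) to a numeric matrix.
.as_block_matrix <- function(b) {
  if (inherits(b, "OmicsBlock")) b$values
  else if (is.matrix(b) && is.numeric(b)) b
  else stop("block must be an OmicsBlock or a numeric matrix", call. = FALSE)
}

# Coerce a trait argument (TraitVector or numeric) to a plain vector.
.as_trait_values <- function(y) {
  if (inherits(y, "TraitVector")) y$values else as.numeric(y)
}
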