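# Readers and writers for the plain-text interchange formats: sample-by-
# feature matrices (CSV/TSV, sample IDs in the first column, feature IDs in
# the header), trait tables, Q-matrices, and two-column annotation maps.
# Empty cells, "NA" and "NaN" are missing.

.sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a sample-by-feature matrix
#'
#' CSV or TSV (delimiter sniffed from the header line, or declared), first
#' column sample IDs, header row feature IDs. Empty cells, `NA` and `NaN`
#' are read as missing. Duplicate sample IDs, ragged rows and non-numeric
#' cells raise errors naming the offending location.
#'
#' @param path file path.
#' @param sep delimiter; `NULL` to sniff.
#' @return numeric matrix with sample rownames and feature colnames.
#' @export
read_matrix <- function(path, sep = NULL) {
  .assert(file.exists(path), "file not found: %s", path)
  sep <- sep %||% .sniff_sep(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          na.strings = c("", "NA", "NaN"),
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  .assert(ncol(df) >= 2L, "no data columns in %s", path)
  ids <- df[[1L]]
  dup <- ids[duplicated(ids)]
  .assert(length(dup) == 0L, "duplicate sample ID(s) in %s: %s", path,
          paste(unique(dup), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(vals)[bad[1, 2]], path), call. = FALSE)
  }
  rownames(num) <- ids
  colnames(num) <- colnames(vals)
  num
}

#' Write a sample-by-feature matrix
#'
#' Inverse of [read_matrix()]: round-trips finite values bit-comparably.
#'
#' @param x numeric matrix (or [omics_block()]).
#' @param path output file; `.tsv` extension selects tab delimiting.
#' @param sep delimiter; `NULL` chooses from the extension.
#' @export
write_matrix <- function(x, path, sep = NULL) {
  x <- if (inherits(x, "OmicsBlock")) x$values else x
  sep <- sep %||% if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(sample_id = rownames(x) %||% seq_len(nrow(x)),
                   x, check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read an omics block from file
#'
#' @param path matrix file (see [read_matrix()]).
#' @param platform platform label (default: the file name).
#' @param annotations_path optional two-column annotation TSV.
#' @param sep delimiter; `NULL` to sniff.
#' @return an [omics_block()].
#' @export
read_block <- function(path, platform = NULL, annotations_path = NULL,
                       sep = NULL) {
  ann <- if (!is.null(annotations_path)) read_annotation_map(annotations_path)
  omics_block(read_matrix(path, sep),
              platform = platform %||% sub("\\.[^.]+$", "", basename(path)),
              annotations = ann)
}

#' Read a trait table and extract one trait
#'
#' @param path matrix file: first column sample IDs, one column per trait.
#' @param trait name of the trait column; `NULL` returns the whole matrix.
#' @param sep delimiter; `NULL` to sniff.
#' @return a [trait_vector()] (or the full numeric matrix).
#' @export
read_trait <- function(path, trait = NULL, sep = NULL) {
  m <- read_matrix(path, sep)
  if (is.null(trait)) return(m)
  .assert(trait %in% colnames(m), "trait '%s' not found in %s (has: %s)",
          trait, path, paste(colnames(m), collapse = ", "))
  trait_vector(m[, trait], name = trait)
}

#' Read a population-membership Q-matrix
#'
#' @param path matrix file: first column sample IDs, one column per
#'   subpopulation.
#' @param sep delimiter; `NULL` to sniff.
#' @return a [population_membership()].
#' @export
read_qmatrix <- function(path, sep = NULL) {
  population_membership(read_matrix(path, sep))
}

#' Read a feature annotation map
#'
#' Two-column TSV: feature ID, metabolite identifier.
#'
#' @param path file path.
#' @return named character vector (feature ID -> metabolite ID).
#' @export
read_annotation_map <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  .assert(ncol(df) >= 2L, "annotation map needs 2 columns")
  stats::setNames(df[[2L]], df[[1L]])
}

#' Write a synthetic dataset to a directory
#'
#' Blocks as CSV, trait table, Q-matrix, plus a JSON file with the planted
#' truth and the generating spec.
#'
#' @param ds a `SyntheticDataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ds$blocks)) {
    write_matrix(ds$blocks[[i]], file.path(dir, sprintf("block%d.csv", i)))
  }
  tr <- matrix(ds$trait$values, ncol = 1,
               dimnames = list(names(ds$trait$values), ds$trait$name))
  write_matrix(tr, file.path(dir, "traits.csv"))
  write_matrix(ds$q$q, file.path(dir, "qmatrix.csv"))
  jsonlite::write_json(
    list(spec = unclass(ds$spec),
         informative = ds$truth$informative,
         null = ds$truth$null),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write a network edge list as GraphML
#'
#' Minimal GraphML export of a [correlation_network()] edge table for graph
#' viewers.
#'
#' @param edges data frame with `feature_a`, `feature_b`, `rho_s`,
#'   `p_value`.
#' @param path output file.
#' @export
write_graphml <- function(edges, path) {
  esc <- function(s) {
    s <- gsub("&", "&amp;", s, fixed = TRUE)
    s <- gsub("<", "&lt;", s, fixed = TRUE)
    gsub(">", "&gt;", s, fixed = TRUE)
  }
  nodes <- unique(c(edges$feature_a, edges$feature_b))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="rho" for="edge" attr.name="rho_s" attr.type="double"/>',
    '  <key id="p" for="edge" attr.name="p_value" attr.type="double"/>',
    '  <graph edgedefault="undirected">'), con)
  for (n in nodes) writeLines(sprintf('    <node id="%s"/>', esc(n)), con)
  for (i in seq_len(nrow(edges))) {
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="rho">%.6g</data><data key="p">%.6g</data></edge>',
      esc(edges$feature_a[i]), esc(edges$feature_b[i]),
      edges$rho_s[i], edges$p_value[i]), con)
  }
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
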