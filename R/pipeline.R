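# End-to-end pipeline: preprocessing -> population-structure correction ->
# component selection -> external CV -> permutation test -> feature
# selection -> network export, each stage writing a plain-text artifact and
# a final JSON run report with seeds and parameters.

#' Assemble a pipeline configuration
#'
#' @param block_paths character vector of block matrix files.
#' @param trait_path,trait_name trait table and the trait column to model.
#' @param q_path optional Q-matrix file for population-structure correction.
#' @param annotation_paths optional annotation map per block.
#' @param out_dir output directory.
#' @param log2_offset offset for the log2 transform; `NULL` skips it.
#' @param max_missing_fraction missing-value filter threshold.
#' @param summarize_threshold mean-correlation threshold for same-annotation
#'   peak merging; `NULL` skips summarization (the multi-block model then
#'   keeps the platform blocks separate).
#' @param max_orth_block,max_orth_top component-scan limits.
#' @param n_folds,n_repeats external CV specification.
#' @param n_perm permutation count.
#' @param n_boot,n_null bootstrap/null replicates for feature scores.
#' @param prior_h0 prior null probability of the log B score.
#' @param fdr_max Spearman-arm FDR threshold.
#' @param network_p_max network edge p-value threshold.
#' @param seed master seed.
#' @return a `RunConfig` list.
#' @export
run_config <- function(block_paths, trait_path, trait_name, q_path = NULL,
                       annotation_paths = NULL, out_dir = "mbopls_out",
                       log2_offset = NULL, max_missing_fraction = 0.3,
                       summarize_threshold = NULL, max_orth_block = 3L,
                       max_orth_top = 3L, n_folds = 7L, n_repeats = 10L,
                       n_perm = 200L, n_boot = 100L, n_null = 100L,
                       prior_h0 = 0.95, fdr_max = 0.05,
                       network_p_max = 0.001, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "RunConfig"
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes the artifacts
#' (preprocessed blocks, corrected trait, fitted model JSON, out-of-fold
#' prediction TSV, permutation report, feature-score table, network edge
#' list + GraphML) plus `report.json` with seeds, timings, chosen
#' parameters and a config fingerprint. Any stage failure aborts with a
#' stage-tagged error.
#'
#' @param config a [run_config()] list, or the path to a JSON file with the
#'   same fields.
#' @return the run report, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- do.call(run_config,
                      jsonlite::read_json(config, simplifyVector = TRUE))
  }
  cfg <- config
  t0 <- Sys.time()
  .stage("config", {
    for (p in c(cfg$block_paths, cfg$trait_path, cfg$q_path,
                cfg$annotation_paths)) {
      .assert(file.exists(p), "input file not found: %s", p)
    }
  })
  # fail on a bad trait name before any heavy compute
  trait <- .stage("inputs", read_trait(cfg$trait_path, cfg$trait_name))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  timings <- list()
  tick <- function(name, expr) {
    t1 <- Sys.time()
    res <- .stage(name, expr)
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t1, units = "secs"))
    res
  }

  blocks <- tick("read", {
    lapply(seq_along(cfg$block_paths), function(i) {
      read_block(cfg$block_paths[i],
                 annotations_path = cfg$annotation_paths[i])
    })
  })

  blocks <- tick("preprocess", {
    if (!is.null(cfg$summarize_threshold)) {
      pre <- lapply(blocks, function(b) {
        if (!is.null(cfg$log2_offset)) b <- log2_transform(b, cfg$log2_offset)
        b <- filter_missing(b, cfg$max_missing_fraction)
        unit_variance_scale(b)$block
      })
      merged <- summarize_annotated_peaks(pre, cfg$summarize_threshold)
      list(impute_feature_mean(unit_variance_scale(merged)$block))
    } else {
      lapply(blocks, function(b) {
        preprocess_block(b, cfg$log2_offset, cfg$max_missing_fraction)$block
      })
    }
  })
  for (i in seq_along(blocks)) {
    write_matrix(blocks[[i]],
                 file.path(cfg$out_dir, sprintf("preprocessed_block%d.csv", i)))
  }

  trait <- tick("structure_correction", {
    if (!is.null(cfg$q_path)) {
      correct_population_structure(trait, read_qmatrix(cfg$q_path))
    } else trait
  })
  ok <- !is.na(trait$values)
  y <- trait$values[ok]
  blocks_y <- lapply(blocks, function(b) b$values[ok, , drop = FALSE])
  write_matrix(matrix(trait$values, ncol = 1,
                      dimnames = list(names(trait$values), trait$name)),
               file.path(cfg$out_dir, "trait_corrected.csv"))

  sel <- tick("select_components", {
    suppressWarnings(select_components(
      blocks_y, y, cfg$max_orth_block, cfg$max_orth_top,
      n_folds = cfg$n_folds, seed = .derive_seed(cfg$seed, 100)))
  })
  model <- tick("fit", {
    m <- fit_mbopls(blocks_y, y, sel$n_orth_per_block, sel$n_orth_top)
    m$trait_name <- cfg$trait_name
    m$cv_meta <- list(n_folds = cfg$n_folds, seed = cfg$seed)
    m
  })
  write_model(model, file.path(cfg$out_dir, "model.json"))

  perm <- tick("validate", {
    permutation_test(blocks_y, y, n_perm = cfg$n_perm, n_folds = cfg$n_folds,
                     n_repeats_observed = cfg$n_repeats,
                     max_orth_block = cfg$max_orth_block,
                     max_orth_top = cfg$max_orth_top,
                     seed = .derive_seed(cfg$seed, 200))
  })
  cv <- perm$cv_result
  oof <- data.frame(sample_id = names(y) %||% seq_along(y), observed = y,
                    cv$predictions, check.names = FALSE)
  colnames(oof)[-(1:2)] <- paste0("run", seq_len(cv$n_repeats))
  utils::write.table(oof, file.path(cfg$out_dir, "oof_predictions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  scores <- tick("feature_selection", {
    feature_scores(blocks_y, y, sel$n_orth_per_block, sel$n_orth_top,
                   n_boot = cfg$n_boot, n_null = cfg$n_null,
                   prior_h0 = cfg$prior_h0, fdr_max = cfg$fdr_max,
                   seed = .derive_seed(cfg$seed, 300))
  })
  utils::write.table(scores, file.path(cfg$out_dir, "feature_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  edges <- tick("network", {
    sel_feats <- scores$feature_id[scores$selected]
    X_all <- do.call(cbind, lapply(blocks_y, identity))
    correlation_network(X_all, sel_feats, p_max = cfg$network_p_max)
  })
  utils::write.table(edges, file.path(cfg$out_dir, "network_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_graphml(edges, file.path(cfg$out_dir, "network.graphml"))

  # fingerprint the analysis-relevant configuration (not the destination)
  cfg_hashable <- unclass(cfg)
  cfg_hashable$out_dir <- NULL
  cfg_json <- jsonlite::toJSON(cfg_hashable, auto_unbox = TRUE, digits = NA,
                               null = "null")
  report <- list(
    package_version = as.character(utils::packageVersion("mboplsr")),
    config = unclass(cfg), config_hash = .fnv1a(as.character(cfg_json)),
    seed = cfg$seed,
    n_samples = length(y), n_features = sum(vapply(blocks_y, ncol, 0L)),
    n_orth_per_block = sel$n_orth_per_block, n_orth_top = sel$n_orth_top,
    median_rcv2 = cv$median_rcv2, rcv2_per_run = cv$rcv2_per_run,
    p_cv = perm$p_value, n0 = perm$n0, n_perm = perm$n_perm,
    n_selected_features = sum(scores$selected), n_network_edges = nrow(edges),
    timings = timings,
    total_seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(report)
}
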