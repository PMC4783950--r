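# End-to-end orchestration: feature assembly in a fixed block order,
# leakage-safe cross-validated evaluation, and artifact output.

CSP_BLOCKS <- c("CSP-PSSM-DC" = "PSSM-DC",
                "CSP-BIGRAM" = "BIGRAM",
                "CSP-ED" = "ED")
RAW_BLOCKS <- c("PSSM-DC", "BIGRAM", "ED")

#' Pipeline configuration
#'
#' @param g Gap of the dipeptide-composition block (default 3, the optimum
#'   gap for this task).
#' @param blocks Feature blocks, assembled in the fixed order `"gapDC"`,
#'   `"CSP-PSSM-DC"`, `"CSP-BIGRAM"`, `"CSP-ED"`, then any raw 400-vector
#'   blocks `"PSSM-DC"`, `"BIGRAM"`, `"ED"`.  The default four blocks give
#'   the 460-dimensional fused representation.
#' @param smote Balance training data with SMOTE (default TRUE)?
#' @param smote_k SMOTE neighbour count.
#' @param select Run RF-RFE optimal-prefix selection (default FALSE; costly
#'   for wide tables)?
#' @param scheme `"kfold"`, `"jackknife"` or `"independent"`.
#' @param folds Folds for `"kfold"` (default 10).
#' @param forest A [forest_spec()].
#' @param paper_mode If TRUE, CSP models and SMOTE are fit on the whole
#'   dataset before cross-validation (whole-dataset protocol); the default
#'   FALSE refits both inside each training fold (leakage-safe).
#' @param pssm_scale `"raw"` log-odds scores (default) or `"sigmoid"`.
#' @param csp_orientation Passed to [fit_csp()].
#' @param strict Fail on a missing PSSM (default) instead of skipping the
#'   protein with a warning.
#' @param seed Integer master seed; every stochastic stage derives from it.
#' @param outdir Optional artifact directory.
#' @return Object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(g = 3,
                            blocks = c("gapDC", "CSP-PSSM-DC",
                                       "CSP-BIGRAM", "CSP-ED"),
                            smote = TRUE, smote_k = 5,
                            select = FALSE,
                            scheme = c("kfold", "jackknife", "independent"),
                            folds = 10,
                            forest = forest_spec(),
                            paper_mode = FALSE,
                            pssm_scale = c("raw", "sigmoid"),
                            csp_orientation = c("paper", "standard"),
                            strict = TRUE,
                            seed = 1,
                            outdir = NULL) {
  scheme <- match.arg(scheme)
  pssm_scale <- match.arg(pssm_scale)
  csp_orientation <- match.arg(csp_orientation)
  known <- c("gapDC", names(CSP_BLOCKS), RAW_BLOCKS)
  if (!length(blocks) || !all(blocks %in% known))
    stop("blocks must be a non-empty subset of: ",
         paste(known, collapse = ", "))
  structure(list(g = as.integer(g), blocks = unique(blocks),
                 smote = smote, smote_k = as.integer(smote_k),
                 select = select, scheme = scheme,
                 folds = as.integer(folds), forest = forest,
                 paper_mode = paper_mode, pssm_scale = pssm_scale,
                 csp_orientation = csp_orientation, strict = strict,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  args <- yaml::read_yaml(path)
  if (!is.null(args$forest)) args$forest <- do.call(forest_spec, args$forest)
  do.call(pipeline_config, args)
}

#' Write a pipeline configuration to YAML
#' @param config A `"pipeline_config"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  obj <- unclass(config)
  obj$forest <- unclass(obj$forest)
  yaml::write_yaml(obj, path)
  invisible(path)
}

# Evolutionary-matrix kinds needed by a configuration.
needed_kinds <- function(config) {
  unique(c(unname(CSP_BLOCKS[intersect(config$blocks, names(CSP_BLOCKS))]),
           intersect(config$blocks, RAW_BLOCKS)))
}

compute_evo <- function(p, kind) {
  switch(kind,
         "PSSM-DC" = pssm_dc(p),
         "BIGRAM" = bigram_pssm(p),
         "ED" = ed_pssm(p),
         stop("unknown descriptor kind: ", kind))
}

# Precompute per-protein descriptors for the ids in `labels`.
precompute_features <- function(sequences, pssms, labels, config) {
  ids <- names(labels)
  if (!all(ids %in% names(sequences)))
    stop("missing sequence for: ",
         paste(utils::head(setdiff(ids, names(sequences))), collapse = ", "))
  kinds <- needed_kinds(config)
  if (length(kinds)) {
    missing <- setdiff(ids, names(pssms %||% list()))
    if (length(missing)) {
      if (config$strict)
        stop("missing PSSM for: ", paste(utils::head(missing), collapse = ", "))
      warning("skipping ", length(missing), " proteins without a PSSM")
      ids <- setdiff(ids, missing)
    }
  }
  gapdc <- NULL
  if ("gapDC" %in% config$blocks) {
    gapdc <- t(vapply(ids, function(id)
      gap_dipeptide_composition(sequences[[id]], config$g), numeric(400)))
    colnames(gapdc) <- paste0("gapDC.", DIPEPTIDES)
  }
  evo <- list()
  for (k in kinds) {
    evo[[k]] <- lapply(ids, function(id)
      compute_evo(scale_pssm(pssms[[id]], config$pssm_scale), k))
    names(evo[[k]]) <- ids
  }
  list(ids = ids, labels = labels[ids], gapdc = gapdc, evo = evo)
}

# Fit the CSP model of every requested kind on the given training ids.
fit_csp_models <- function(pre, train_ids, config) {
  models <- list()
  for (blk in intersect(config$blocks, names(CSP_BLOCKS))) {
    kind <- CSP_BLOCKS[[blk]]
    pos <- train_ids[pre$labels[train_ids] == "cis"]
    neg <- train_ids[pre$labels[train_ids] == "trans"]
    models[[kind]] <- fit_csp(pre$evo[[kind]][pos], pre$evo[[kind]][neg],
                              orientation = config$csp_orientation)
  }
  models
}

# Assemble the feature matrix for `ids` in the fixed block order.
assemble_features <- function(pre, ids, config, csp_models) {
  parts <- list()
  if ("gapDC" %in% config$blocks)
    parts$gapDC <- pre$gapdc[ids, , drop = FALSE]
  for (blk in intersect(c("CSP-PSSM-DC", "CSP-BIGRAM", "CSP-ED"),
                        config$blocks)) {
    kind <- CSP_BLOCKS[[blk]]
    m <- t(vapply(ids, function(id)
      csp_features(csp_models[[kind]], pre$evo[[kind]][[id]]), numeric(20)))
    colnames(m) <- paste0("CSP.", gsub("-", "", kind), ".",
                          sprintf("f%02d", 1:20))
    parts[[blk]] <- m
  }
  for (blk in intersect(RAW_BLOCKS, config$blocks)) {
    m <- t(vapply(ids, function(id)
      flatten_evo(pre$evo[[blk]][[id]]), numeric(400)))
    parts[[paste0("raw.", blk)]] <- m
  }
  x <- do.call(cbind, parts)
  rownames(x) <- ids
  x
}

#' Build a labeled feature table from sequences and PSSM profiles
#'
#' Concatenates the configured feature blocks in the fixed order gapDC,
#' CSP-PSSM-DC, CSP-BIGRAM, CSP-ED (then raw 400-vector blocks).  With the
#' default four blocks the table is 400 + 20 + 20 + 20 = 460 columns wide.
#' CSP models are fitted on the full labeled input when not supplied —
#' appropriate for final models and exploration; [run_pipeline()] refits
#' them inside each training fold during evaluation.
#'
#' @param sequences Named character vector (see [read_fasta()]).
#' @param pssms Named list of `"pssm"` objects (needed for PSSM blocks).
#' @param labels Named factor (cis/trans) defining the proteins to include.
#' @param config A [pipeline_config()].
#' @param csp_models Optional named list of fitted `"csp_model"`s by kind.
#' @return A `"feature_table"` with attribute `csp_models`.
#' @export
build_feature_table <- function(sequences, pssms = NULL, labels,
                                config = pipeline_config(),
                                csp_models = NULL) {
  pre <- precompute_features(sequences, pssms, labels, config)
  if (is.null(csp_models) &&
      length(intersect(config$blocks, names(CSP_BLOCKS))))
    csp_models <- fit_csp_models(pre, pre$ids, config)
  x <- assemble_features(pre, pre$ids, config, csp_models)
  tbl <- feature_table(x, pre$labels)
  attr(tbl, "csp_models") <- csp_models
  tbl
}

#' Run the full pipeline: extract, fuse, balance, select, train, evaluate
#'
#' Under the `"kfold"` / `"jackknife"` schemes the dataset is partitioned
#' (stratified for k-fold), and per fold the CSP projections, SMOTE
#' balancing and (optionally) feature selection are fitted on the training
#' portion only before training the forest and scoring the held-out part;
#' metrics are pooled over all held-out predictions.  `paper_mode = TRUE`
#' instead fits CSP and SMOTE once on the whole dataset before
#' partitioning.  The `"independent"` scheme trains on the training inputs
#' and evaluates on `test_*`.
#'
#' @param config A [pipeline_config()].
#' @param sequences,pssms,labels Training inputs (see
#'   [build_feature_table()]).
#' @param test_sequences,test_pssms,test_labels Independent test inputs
#'   (scheme `"independent"` only).
#' @return Object of class `"pipeline_result"`: `report` (an
#'   `"eval_report"`), `config`, `csp_models` (full-training-data fit),
#'   `table` (full-data feature table), `selection` (when selection ran on
#'   the full data), `width`.
#' @export
run_pipeline <- function(config, sequences, pssms = NULL, labels,
                         test_sequences = NULL, test_pssms = NULL,
                         test_labels = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  pre <- precompute_features(sequences, pssms, labels, config)
  full_models <- if (length(intersect(config$blocks, names(CSP_BLOCKS))))
    fit_csp_models(pre, pre$ids, config) else list()
  full_x <- assemble_features(pre, pre$ids, config, full_models)
  full_tbl <- feature_table(full_x, pre$labels)
  seed <- config$seed
  selection <- NULL

  if (config$scheme == "independent") {
    if (is.null(test_labels))
      stop("scheme 'independent' requires test_sequences/test_pssms/test_labels")
    test_pre <- precompute_features(test_sequences, test_pssms,
                                    test_labels, config)
    test_x <- assemble_features(test_pre, test_pre$ids, config, full_models)
    train_tbl <- full_tbl
    test_tbl <- feature_table(test_x, test_pre$labels)
    if (config$smote)
      train_tbl <- smote_balance(train_tbl, k = config$smote_k,
                                 seed = child_seed(seed, 11))
    if (config$select) {
      ranks <- rf_rfe(train_tbl, seed = child_seed(seed, 12),
                      n_trees = config$forest$n_trees)
      selection <- select_optimal_prefix(train_tbl, ranks, folds = 5,
                                         seed = child_seed(seed, 13),
                                         n_trees = config$forest$n_trees)
      selection$ranks <- ranks
      train_tbl <- ft_cols(train_tbl, selection$features)
      test_tbl <- ft_cols(test_tbl, selection$features)
    }
    fs <- config$forest
    fs$seed <- child_seed(seed, 14)
    model <- train_forest(train_tbl, fs)
    report <- eval_report(predict(model, test_tbl), test_tbl$labels)
  } else {
    folds <- if (config$scheme == "jackknife") nrow(full_tbl$x)
             else config$folds
    if (config$paper_mode) {
      tbl <- full_tbl
      if (config$smote)
        tbl <- smote_balance(tbl, k = config$smote_k,
                             seed = child_seed(seed, 21))
      report <- cross_validate(tbl, folds = folds, seed = seed,
                               smote = FALSE, select = config$select,
                               forest = config$forest,
                               stratified = config$scheme != "jackknife")
    } else {
      n <- length(pre$ids)
      fold <- NULL
      for (attempt in 0:9) {
        cand <- make_folds(pre$labels, folds, child_seed(seed, attempt),
                           stratified = config$scheme != "jackknife")
        ok <- all(vapply(unique(cand), function(f)
          nlevels(droplevels(pre$labels[cand != f])) == 2, logical(1)))
        if (ok) { fold <- cand; break }
      }
      if (is.null(fold))
        stop("could not build folds with both classes in every training set")
      scores <- numeric(n)
      for (f in sort(unique(fold))) {
        train_ids <- pre$ids[fold != f]
        test_ids <- pre$ids[fold == f]
        models <- if (length(intersect(config$blocks, names(CSP_BLOCKS))))
          fit_csp_models(pre, train_ids, config) else list()
        train_tbl <- feature_table(
          assemble_features(pre, train_ids, config, models),
          pre$labels[train_ids])
        test_x <- assemble_features(pre, test_ids, config, models)
        if (config$smote)
          train_tbl <- smote_balance(train_tbl, k = config$smote_k,
                                     seed = child_seed(seed, 30 + f))
        if (config$select) {
          ranks <- rf_rfe(train_tbl, seed = child_seed(seed, 130 + f),
                          n_trees = config$forest$n_trees)
          sel <- select_optimal_prefix(train_tbl, ranks, folds = 5,
                                       seed = child_seed(seed, 230 + f),
                                       n_trees = config$forest$n_trees)
          train_tbl <- ft_cols(train_tbl, sel$features)
          test_x <- test_x[, sel$features, drop = FALSE]
        }
        fs <- config$forest
        fs$seed <- child_seed(seed, 330 + f)
        model <- train_forest(train_tbl, fs)
        scores[fold == f] <- predict(model, test_x)
      }
      report <- eval_report(scores, pre$labels)
      report$folds <- fold
    }
  }

  result <- structure(list(report = report, config = config,
                           csp_models = full_models, table = full_tbl,
                           selection = selection, width = ncol(full_tbl$x)),
                      class = "pipeline_result")
  if (!is.null(config$outdir)) write_pipeline_artifacts(result)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run (", x$config$scheme, ", blocks: ",
      paste(x$config$blocks, collapse = " + "), "; width ", x$width,
      ")\n", sep = "")
  print(x$report)
  invisible(x)
}

# Write feature table, CSP models, eval report, ROC points and a run log.
write_pipeline_artifacts <- function(result) {
  out <- result$config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_feature_csv(result$table, file.path(out, "features.csv"))
  for (kind in names(result$csp_models))
    write_csp_model(result$csp_models[[kind]],
                    file.path(out, paste0("csp-", gsub("-", "", kind),
                                          ".json")))
  write_eval_report(result$report, file.path(out, "eval.json"))
  utils::write.csv(result$report$roc, file.path(out, "roc.csv"),
                   row.names = FALSE)
  if (!is.null(result$selection))
    write_rank_list(result$selection$ranks,
                    file.path(out, "ranklist.csv"),
                    curve = result$selection$accuracy_curve)
  log <- c(paste("golgiCSP", as.character(utils::packageVersion("golgiCSP"))),
           paste("R", paste(R.version$major, R.version$minor, sep = ".")),
           paste("seed", result$config$seed),
           paste("scheme", result$config$scheme),
           paste("blocks", paste(result$config$blocks, collapse = "+")),
           paste("width", result$width))
  writeLines(log, file.path(out, "run.log"))
  invisible(out)
}
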