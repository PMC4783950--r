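# Random-forest classification stage and the evaluation harness: confusion
# metrics, ROC/AUC, stratified k-fold and jackknife cross-validation.

#' Random-forest hyper-parameters
#'
#' @param n_trees Number of unpruned trees (default 100).
#' @param m_try Features sampled per split; `NULL` applies `m_try_rule`.
#' @param m_try_rule `"sqrt"` (floor(sqrt(d)), the randomForest default) or
#'   `"log2"` (floor(log2(d)) + 1, mirroring historical WEKA defaults).
#' @param seed Integer seed for tree growing.
#' @return Object of class `"forest_spec"`.
#' @export
forest_spec <- function(n_trees = 100, m_try = NULL,
                        m_try_rule = c("sqrt", "log2"), seed = 1) {
  m_try_rule <- match.arg(m_try_rule)
  stopifnot(n_trees >= 1, is.null(m_try) || m_try >= 1)
  structure(list(n_trees = as.integer(n_trees), m_try = m_try,
                 m_try_rule = m_try_rule, seed = as.integer(seed)),
            class = "forest_spec")
}

#' WEKA-compatible random-forest preset
#'
#' Historical WEKA RandomForest defaults: 10 trees, floor(log2(d)) + 1
#' features per split.
#'
#' @param seed Integer seed.
#' @return A `"forest_spec"`.
#' @export
weka_forest_spec <- function(seed = 1) {
  forest_spec(n_trees = 10, m_try_rule = "log2", seed = seed)
}

resolve_mtry <- function(spec, d) {
  m <- spec$m_try %||% switch(spec$m_try_rule,
                              sqrt = max(1L, floor(sqrt(d))),
                              log2 = floor(log2(d)) + 1L)
  min(as.integer(m), d)
}

#' Train a random forest on a feature table
#'
#' Ensemble of fully grown (unpruned) trees on bootstrap samples; the
#' positive-class score of a new object is the fraction of trees voting for
#' the positive class.
#'
#' @param tbl A `"feature_table"` with at least 2 rows per class.
#' @param spec A [forest_spec()].
#' @return Object of class `"golgi_forest"`.
#' @export
train_forest <- function(tbl, spec = forest_spec()) {
  stopifnot(inherits(tbl, "feature_table"), inherits(spec, "forest_spec"))
  counts <- table(droplevels(tbl$labels))
  if (length(counts) < 2)
    stop("training table contains a single class")
  if (any(counts < 2))
    stop("each class needs at least 2 training rows")
  fit <- with_seed(spec$seed,
                   randomForest::randomForest(
                     x = tbl$x, y = tbl$labels,
                     ntree = spec$n_trees,
                     mtry = resolve_mtry(spec, ncol(tbl$x))))
  structure(list(fit = fit,
                 positive = positive_class(tbl),
                 features = colnames(tbl$x),
                 spec = spec),
            class = "golgi_forest")
}

#' Predict scores or labels from a trained forest
#'
#' @param object A `"golgi_forest"`.
#' @param newdata Numeric matrix or `"feature_table"`; columns are aligned
#'   to the training features by name.
#' @param type `"score"` (fraction of trees voting positive) or `"label"`
#'   (score >= 0.5 is called positive).
#' @param ... Unused.
#' @return Numeric scores or a factor of labels.
#' @export
predict.golgi_forest <- function(object, newdata,
                                 type = c("score", "label"), ...) {
  type <- match.arg(type)
  x <- if (inherits(newdata, "feature_table")) newdata$x else as.matrix(newdata)
  if (!all(object$features %in% colnames(x)))
    stop("newdata is missing training features")
  x <- x[, object$features, drop = FALSE]
  prob <- stats::predict(object$fit, x, type = "prob")
  score <- prob[, object$positive]
  if (type == "score") return(unname(score))
  lv <- levels(object$fit$y)
  factor(ifelse(score >= 0.5, object$positive, setdiff(lv, object$positive)),
         levels = lv)
}

#' Confusion counts from predicted and true labels
#'
#' @param truth,predicted Label vectors (factor or character).
#' @param positive Positive-class label (default `"cis"`).
#' @return Named integer vector `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive = "cis") {
  truth_pos <- as.character(truth) == positive
  pred_pos <- as.character(predicted) == positive
  c(TP = sum(truth_pos & pred_pos),
    FP = sum(!truth_pos & pred_pos),
    TN = sum(!truth_pos & !pred_pos),
    FN = sum(truth_pos & !pred_pos))
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/n and
#' MCC = (TP TN - FP FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN)).  A metric
#' whose denominator is zero is reported as 0 and flagged.
#'
#' @param counts Named vector with `TP`, `FP`, `TN`, `FN`.
#' @return List with `Sn`, `Sp`, `Acc`, `MCC` and `zero_denominator`
#'   (character vector of flagged metrics).
#' @export
confusion_metrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); FP <- as.numeric(counts[["FP"]])
  TN <- as.numeric(counts[["TN"]]); FN <- as.numeric(counts[["FN"]])
  if (min(TP, FP, TN, FN) < 0) stop("negative confusion counts")
  flags <- character(0)
  safe <- function(num, den, name) {
    if (den > 0) num / den else { flags <<- c(flags, name); 0 }
  }
  Sn <- safe(TP, TP + FN, "Sn")
  Sp <- safe(TN, TN + FP, "Sp")
  Acc <- safe(TP + TN, TP + FP + TN + FN, "Acc")
  mcc_den <- sqrt((TP + FN) * (TP + FP) * (TN + FP) * (TN + FN))
  MCC <- safe(TP * TN - FP * FN, mcc_den, "MCC")
  list(Sn = Sn, Sp = Sp, Acc = Acc, MCC = MCC, zero_denominator = flags)
}

#' ROC curve and AUC from continuous scores
#'
#' Sweeps thresholds over the distinct score values, plotting sensitivity
#' against 1 - specificity, and integrates by the trapezoidal rule.  The
#' resulting AUC equals the Mann-Whitney concordance probability.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels Labels; both classes must be present.
#' @param positive Positive-class label (default `"cis"`).
#' @return List with `roc` (data frame `threshold`, `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, labels, positive = "cis") {
  y <- as.character(labels) == positive
  P <- sum(y); N <- sum(!y)
  if (P == 0 || N == 0)
    stop("ROC requires both classes in the labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  idx <- cumsum(rle(s)$lengths)       # last index of each tied score block
  tpr <- cumsum(yy)[idx] / P
  fpr <- cumsum(!yy)[idx] / N
  roc <- data.frame(threshold = c(Inf, s[idx]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                utils::tail(roc$tpr, -1)) / 2)
  list(roc = roc, auc = auc)
}

#' Evaluation report from scores and true labels
#'
#' Applies the 0.5 decision threshold for the label metrics and the full
#' threshold sweep for ROC/AUC.
#'
#' @param scores Positive-class scores in \[0, 1\].
#' @param truth True labels.
#' @param positive Positive-class label.
#' @param threshold Decision threshold for label metrics (default 0.5).
#' @return Object of class `"eval_report"`: `counts`, `Sn`, `Sp`, `Acc`,
#'   `MCC`, `roc`, `auc`, `zero_denominator`, `predictions`.
#' @export
eval_report <- function(scores, truth, positive = "cis", threshold = 0.5) {
  neg <- setdiff(unique(as.character(truth)), positive)
  if (length(neg) != 1)
    stop("truth must contain the positive class and exactly one other class")
  predicted <- ifelse(scores >= threshold, positive, neg)
  counts <- confusion_counts(truth, predicted, positive)
  m <- confusion_metrics(counts)
  r <- roc_auc(scores, truth, positive)
  structure(list(counts = counts, Sn = m$Sn, Sp = m$Sp, Acc = m$Acc,
                 MCC = m$MCC, zero_denominator = m$zero_denominator,
                 roc = r$roc, auc = r$auc,
                 predictions = data.frame(score = scores,
                                          truth = as.character(truth),
                                          predicted = predicted)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "Evaluation: n = %d (TP %d, FP %d, TN %d, FN %d)\n",
    sum(x$counts), x$counts["TP"], x$counts["FP"], x$counts["TN"],
    x$counts["FN"]))
  cat(sprintf("  Sn = %.3f  Sp = %.3f  Acc = %.3f  MCC = %.3f  AUC = %.3f\n",
              x$Sn, x$Sp, x$Acc, x$MCC, x$auc))
  if (length(x$zero_denominator))
    cat("  zero-denominator metrics reported as 0:",
        paste(x$zero_denominator, collapse = ", "), "\n")
  invisible(x)
}

#' Write an evaluation report to JSON
#'
#' @param report An `"eval_report"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  obj <- list(counts = as.list(report$counts),
              Sn = report$Sn, Sp = report$Sp, Acc = report$Acc,
              MCC = report$MCC, auc = report$auc,
              zero_denominator = report$zero_denominator,
              roc = report$roc)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Stratified fold assignment; folds == n yields the jackknife partition.
make_folds <- function(labels, folds, seed, stratified = TRUE) {
  n <- length(labels)
  stopifnot(folds >= 2, folds <= n)
  if (folds == n) return(seq_len(n))
  with_seed(seed, {
    fold <- integer(n)
    if (stratified) {
      for (cl in levels(as.factor(labels))) {
        idx <- which(labels == cl)
        fold[sample(idx)] <- rep(seq_len(folds), length.out = length(idx))
      }
    } else {
      fold <- sample(rep(seq_len(folds), length.out = n))
    }
    fold
  })
}

#' Cross-validated evaluation of a feature table
#'
#' Stratified random partition into `folds` parts (`folds = nrow(tbl)` gives
#' the jackknife / leave-one-out test).  Per fold, the held-out part is
#' predicted by a forest trained on the rest; SMOTE and feature selection,
#' when enabled, are fit on the training portion only.  With
#' `paper_mode = TRUE`, SMOTE is instead applied to the whole table before
#' partitioning, mirroring a whole-dataset balancing protocol.  Metrics are
#' pooled over all held-out predictions.
#'
#' @param tbl A `"feature_table"`.
#' @param folds Number of folds (2..n).
#' @param seed Integer seed driving the partition and every stochastic
#'   stage.
#' @param smote Apply SMOTE balancing to training data?
#' @param smote_k SMOTE neighbour count.
#' @param select Run RF-RFE + optimal-prefix selection inside each training
#'   fold? (Costly; off by default.)
#' @param select_folds Inner folds for the selection accuracy curve.
#' @param forest A [forest_spec()].
#' @param stratified Stratify the partition by class (default TRUE).
#' @param paper_mode Balance the whole table before partitioning.
#' @return An `"eval_report"` with an extra `folds` element giving the
#'   assignment of original rows.
#' @export
cross_validate <- function(tbl, folds = 10, seed = 1,
                           smote = FALSE, smote_k = 5,
                           select = FALSE, select_folds = 5,
                           forest = forest_spec(),
                           stratified = TRUE, paper_mode = FALSE) {
  stopifnot(inherits(tbl, "feature_table"))
  if (paper_mode && smote) {
    tbl <- smote_balance(tbl, k = smote_k, seed = child_seed(seed, 999))
    smote <- FALSE
  }
  n <- nrow(tbl$x)
  fold <- NULL
  for (attempt in 0:9) {
    cand <- make_folds(tbl$labels, folds, child_seed(seed, attempt),
                       stratified)
    ok <- all(vapply(unique(cand), function(f) {
      nlevels(droplevels(tbl$labels[cand != f])) == 2
    }, logical(1)))
    if (ok) { fold <- cand; break }
  }
  if (is.null(fold))
    stop("could not build folds with both classes in every training portion")
  scores <- numeric(n)
  for (f in sort(unique(fold))) {
    train <- ft_rows(tbl, fold != f)
    if (smote)
      train <- smote_balance(train, k = smote_k, seed = child_seed(seed, f))
    if (select) {
      ranks <- rf_rfe(train, seed = child_seed(seed, 100 + f),
                      n_trees = forest$n_trees)
      sel <- select_optimal_prefix(train, ranks, folds = select_folds,
                                   seed = child_seed(seed, 200 + f),
                                   n_trees = forest$n_trees)
      train <- ft_cols(train, sel$features)
    }
    fs <- forest
    fs$seed <- child_seed(seed, 300 + f)
    model <- train_forest(train, fs)
    scores[fold == f] <- predict(model, tbl$x[fold == f, , drop = FALSE])
  }
  rep_ <- eval_report(scores, tbl$labels, positive = positive_class(tbl))
  rep_$folds <- fold
  rep_
}

#' Train on one table and evaluate on an independent one
#'
#' @param train_tbl,test_tbl `"feature_table"`s with identical features.
#' @param smote Balance the training table first?
#' @param smote_k SMOTE neighbour count.
#' @param forest A [forest_spec()].
#' @param seed Integer seed.
#' @return An `"eval_report"` on the test table.
#' @export
evaluate_independent <- function(train_tbl, test_tbl, smote = TRUE,
                                 smote_k = 5, forest = forest_spec(),
                                 seed = 1) {
  if (smote)
    train_tbl <- smote_balance(train_tbl, k = smote_k,
                               seed = child_seed(seed, 1))
  fs <- forest
  fs$seed <- child_seed(seed, 2)
  model <- train_forest(train_tbl, fs)
  scores <- predict(model, test_tbl)
  eval_report(scores, test_tbl$labels, positive = positive_class(test_tbl))
}
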