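# Random-forest recursive feature elimination: full importance ranking and
# cross-validated optimal-prefix selection.

#' Rank features by recursive elimination with random-forest importance
#'
#' Starting from all features, fits a random forest, removes the feature
#' with the lowest importance, and repeats until the set is empty (N
#' iterations for N features).  The first feature removed is the least
#' important; the rank list is returned most-important-first (rank 1 = last
#' eliminated).  Importance ties are broken by removing the feature with the
#' larger canonical column index, making the ranking deterministic under a
#' fixed seed.
#'
#' @param tbl A `"feature_table"` with >= 2 features.
#' @param seed Integer seed.
#' @param criterion `"permutation"` uses out-of-bag permutation importance
#'   (mean decrease in accuracy, the default); `"impurity"` uses mean
#'   decrease in Gini impurity.
#' @param n_trees Trees per forest fit.
#' @return Character vector of class `"rank_list"` (a permutation of the
#'   feature names) with attribute `accuracy_trace`, the out-of-bag accuracy
#'   at each elimination step.
#' @export
rf_rfe <- function(tbl, seed = 1, criterion = c("permutation", "impurity"),
                   n_trees = 100) {
  stopifnot(inherits(tbl, "feature_table"))
  criterion <- match.arg(criterion)
  d <- ncol(tbl$x)
  if (d < 2) stop("RF-RFE needs at least 2 features")
  if (nlevels(droplevels(tbl$labels)) < 2)
    stop("labels are constant; cannot rank features")
  canonical <- colnames(tbl$x)
  remaining <- canonical
  eliminated <- character(0)
  trace_acc <- numeric(d)
  with_seed(seed, {
    for (it in seq_len(d)) {
      fit <- randomForest::randomForest(
        x = tbl$x[, remaining, drop = FALSE], y = tbl$labels,
        ntree = n_trees, importance = (criterion == "permutation"))
      trace_acc[it] <- 1 - fit$err.rate[n_trees, "OOB"]
      if (length(remaining) == 1) {
        eliminated <- c(eliminated, remaining)
        break
      }
      imp <- randomForest::importance(
        fit, type = if (criterion == "permutation") 1 else 2)[, 1]
      worst <- which(imp <= min(imp) + 1e-12)
      # tie-break: larger canonical column index goes first
      worst <- worst[which.max(match(remaining[worst], canonical))]
      eliminated <- c(eliminated, remaining[worst])
      remaining <- remaining[-worst]
    }
  })
  structure(rev(eliminated), accuracy_trace = trace_acc,
            class = "rank_list")
}

#' @export
print.rank_list <- function(x, ...) {
  cat("RF-RFE rank list of", length(x), "features; top:",
      paste(utils::head(unclass(x), 5), collapse = ", "), "...\n")
  invisible(x)
}

#' Choose the optimal prefix of a rank list by cross-validated accuracy
#'
#' For every prefix size k = 1..N, trains and evaluates a random forest on
#' the top-k features by k-fold cross-validation, using one fixed fold
#' partition for all k (paired comparison).  Returns the smallest k
#' achieving the maximum accuracy, together with the full curve.
#'
#' @param tbl A `"feature_table"`.
#' @param ranks A `"rank_list"` (or character vector) over `tbl`'s features.
#' @param folds Folds for the accuracy curve (>= 2).
#' @param seed Integer seed.
#' @param n_trees Trees per forest fit.
#' @return List with `k` (optimal prefix size), `accuracy_curve` (length N),
#'   `features` (the selected top-k names) and `folds` (fold assignment).
#' @export
select_optimal_prefix <- function(tbl, ranks, folds = 5, seed = 1,
                                  n_trees = 100) {
  stopifnot(inherits(tbl, "feature_table"), folds >= 2)
  ranks <- as.character(ranks)
  if (!setequal(ranks, colnames(tbl$x)))
    stop("rank list is not a permutation of the table's features")
  N <- length(ranks)
  fold <- make_folds(tbl$labels, folds, seed, stratified = TRUE)
  n <- nrow(tbl$x)
  acc <- numeric(N)
  with_seed(child_seed(seed, 1), {
    for (k in seq_len(N)) {
      correct <- 0
      for (f in sort(unique(fold))) {
        train <- ft_cols(ft_rows(tbl, fold != f), ranks[seq_len(k)])
        fit <- randomForest::randomForest(
          x = train$x, y = train$labels, ntree = n_trees,
          mtry = max(1L, floor(sqrt(k))))
        pred <- stats::predict(fit,
                               tbl$x[fold == f, ranks[seq_len(k)],
                                     drop = FALSE])
        correct <- correct + sum(pred == tbl$labels[fold == f])
      }
      acc[k] <- correct / n
    }
  })
  k_opt <- which.max(acc)   # smallest k on ties
  list(k = k_opt, accuracy_curve = acc,
       features = ranks[seq_len(k_opt)], folds = fold)
}

#' Write a rank list and its accuracy trace to CSV
#'
#' @param ranks A `"rank_list"`.
#' @param path Output path.
#' @param curve Optional accuracy curve from [select_optimal_prefix()].
#' @return `path`, invisibly.
#' @export
write_rank_list <- function(ranks, path, curve = NULL) {
  df <- data.frame(rank = seq_along(ranks), feature = as.character(ranks))
  if (!is.null(curve)) df$prefix_cv_accuracy <- curve[df$rank]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
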