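# Labeled feature tables: the container shared by SMOTE, feature selection
# and the classifier.

#' Construct a labeled feature table
#'
#' @param x Numeric matrix (rows = proteins, columns = named features).
#' @param labels Class labels.  `"cis"`/`"trans"` strings or a two-level
#'   factor; the first level is the positive class (cis by convention).
#' @param provenance Per-row provenance, `"real"` (default) or
#'   `"synthetic-SMOTE"` for rows created by oversampling.
#' @return Object of class `"feature_table"` with elements `x`, `labels`,
#'   `provenance`.
#' @export
feature_table <- function(x, labels, provenance = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("V%03d", seq_len(ncol(x)))
  if (nrow(x) != length(labels))
    stop("labels length (", length(labels),
         ") does not match rows (", nrow(x), ")")
  if (is.factor(labels)) {
    labels <- droplevels(labels)
  } else {
    labels <- as.factor(as.character(labels))
  }
  if (nlevels(labels) > 2) stop("labels must be binary")
  if (setequal(levels(labels), c("cis", "trans")))
    labels <- factor(labels, levels = c("cis", "trans"))
  provenance <- provenance %||% rep("real", nrow(x))
  if (length(provenance) != nrow(x))
    stop("provenance length must match rows")
  structure(list(x = x, labels = labels, provenance = provenance),
            class = "feature_table")
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table:", nrow(x$x), "rows x", ncol(x$x), "features; classes:",
      paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
            collapse = ", "))
  n_syn <- sum(x$provenance != "real")
  if (n_syn) cat(";", n_syn, "synthetic rows")
  cat("\n")
  invisible(x)
}

# Row / column subsets preserving class and metadata.
ft_rows <- function(tbl, idx) {
  feature_table(tbl$x[idx, , drop = FALSE], tbl$labels[idx],
                tbl$provenance[idx])
}

ft_cols <- function(tbl, cols) {
  feature_table(tbl$x[, cols, drop = FALSE], tbl$labels, tbl$provenance)
}

# Positive class label of a table (first factor level).
positive_class <- function(tbl) levels(tbl$labels)[1]

#' Write a feature table to CSV
#'
#' Columns: `id`, one column per feature, `label`, `provenance`.
#'
#' @param tbl A `"feature_table"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(tbl, path) {
  stopifnot(inherits(tbl, "feature_table"))
  df <- data.frame(id = rownames(tbl$x) %||% seq_len(nrow(tbl$x)),
                   tbl$x,
                   label = as.character(tbl$labels),
                   provenance = tbl$provenance,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_csv()]
#'
#' @param path CSV path.
#' @return A `"feature_table"` with row names from the `id` column.
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  keep <- setdiff(colnames(df), c("id", "label", "provenance"))
  x <- as.matrix(df[, keep, drop = FALSE])
  rownames(x) <- df$id
  feature_table(x, df$label, df$provenance)
}
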