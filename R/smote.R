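# SMOTE oversampling of the minority class to parity.

#' Balance a feature table by SMOTE oversampling
#'
#' Creates synthetic minority-class rows x + u (x_nn - x), where x is a
#' minority row, x_nn one of its `k` nearest minority neighbours (Euclidean
#' distance on the unscaled features) and u uniform on \[0, 1\], until both
#' classes have equal counts.  Base points are used round-robin; the
#' remainder (the class gap is rarely a multiple of the minority size) is
#' assigned by a seeded shuffle.  Majority rows are returned bit-identical;
#' synthetic rows carry provenance `"synthetic-SMOTE"`.
#'
#' @param tbl A `"feature_table"`.
#' @param k Number of nearest neighbours considered (default 5, the
#'   canonical SMOTE setting); clamped to minority size - 1 with a warning.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A balanced `"feature_table"`.
#' @export
smote_balance <- function(tbl, k = 5, seed = 1) {
  stopifnot(inherits(tbl, "feature_table"))
  counts <- table(tbl$labels)
  if (length(counts) < 2 || any(counts == 0))
    stop("SMOTE requires both classes to be present")
  if (counts[1] == counts[2]) return(tbl)
  minority <- names(counts)[which.min(counts)]
  n_min <- min(counts)
  n_maj <- max(counts)
  if (n_min < 2)
    stop("minority class has a single member; SMOTE needs at least 2")
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k > n_min - 1) {
    warning("k = ", k, " exceeds minority size - 1; clamped to ", n_min - 1)
    k <- n_min - 1L
  }
  X <- tbl$x[tbl$labels == minority, , drop = FALSE]
  D <- as.matrix(stats::dist(X))
  # k nearest minority neighbours of each minority row (self excluded)
  nn <- vapply(seq_len(n_min), function(i) {
    ord <- order(D[i, ], seq_len(n_min))  # ties broken by index: deterministic
    ord[ord != i][seq_len(k)]
  }, integer(k))
  nn <- matrix(nn, nrow = k)
  need <- n_maj - n_min
  syn <- with_seed(seed, {
    base <- rep(seq_len(n_min), need %/% n_min)
    if (need %% n_min)
      base <- c(base, sample(n_min, need %% n_min))
    out <- matrix(0, need, ncol(X))
    for (r in seq_len(need)) {
      i <- base[r]
      j <- nn[sample.int(k, 1), i]
      u <- stats::runif(1)
      out[r, ] <- X[i, ] + u * (X[j, ] - X[i, ])
    }
    out
  })
  colnames(syn) <- colnames(tbl$x)
  rownames(syn) <- sprintf("smote_%03d", seq_len(need))
  feature_table(rbind(tbl$x, syn),
                c(as.character(tbl$labels), rep(minority, need)),
                c(tbl$provenance, rep("synthetic-SMOTE", need)))
}
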