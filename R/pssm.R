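# PSI-BLAST ASCII PSSM parsing and the three 20x20 evolutionary matrix
# descriptors (PSSM-DC, bi-gram PSSM, ED-PSSM).

#' Construct a PSSM profile object
#'
#' @param id Protein identifier.
#' @param scores `L x 20` numeric matrix of per-position substitution scores,
#'   columns in alphabetical amino-acid order ([AA_ALPHABETICAL]).
#' @param residues Length-`L` residue string (the query sequence column).
#' @return Object of class `"pssm"`.
#' @export
pssm <- function(id, scores, residues) {
  scores <- as.matrix(scores)
  storage.mode(scores) <- "double"
  if (ncol(scores) != 20) stop("PSSM must have 20 score columns")
  if (!all(is.finite(scores))) stop("PSSM scores must be finite")
  if (nchar(residues) != nrow(scores))
    stop("residue string length (", nchar(residues),
         ") does not match score rows (", nrow(scores), ")")
  colnames(scores) <- AA_ALPHABETICAL
  rownames(scores) <- NULL
  structure(list(id = as.character(id), scores = scores,
                 residues = toupper(residues)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("PSSM profile '", x$id, "': L = ", nrow(x$scores),
      ", score range [", min(x$scores), ", ", max(x$scores), "]\n", sep = "")
  invisible(x)
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the layout produced by `psiblast -out_ascii_pssm`: header lines,
#' then one row per position holding the position index, the query residue,
#' 20 log-odds integers (in PSI-BLAST column order
#' A R N D C Q E G H I L K M F P S T W Y V), 20 observed percentages and
#' trailing statistics.  Only the first block of 20 columns (log-odds) is
#' kept, re-ordered to alphabetical amino-acid order.
#'
#' @param path Path to the ASCII PSSM file.
#' @param id Identifier for the profile; defaults to the file name without
#'   extension.
#' @return Object of class `"pssm"`.
#' @export
read_ascii_pssm <- function(path, id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  data_idx <- grep("^\\s*[0-9]+\\s+[A-Za-z](\\s|$)", lines)
  if (!length(data_idx))
    stop("no PSSM data rows found in '", path, "'")
  fields <- strsplit(trimws(lines[data_idx]), "\\s+")
  nf <- lengths(fields)
  short <- which(nf < 22)
  if (length(short))
    stop("truncated PSSM row at line ", data_idx[short[1]], " of '", path, "'")
  res <- vapply(fields, `[`, character(1), 2)
  scores <- t(vapply(fields, function(f) {
    suppressWarnings(as.numeric(f[3:22]))
  }, numeric(20)))
  bad <- which(!stats::complete.cases(scores))
  if (length(bad))
    stop("non-numeric PSSM score at line ", data_idx[bad[1]], " of '", path, "'")
  if (nrow(scores) < 3)
    stop("PSSM in '", path, "' has fewer than 3 positions")
  # re-order columns from PSI-BLAST order to alphabetical
  scores <- scores[, match(AA_ALPHABETICAL, AA_PSIBLAST), drop = FALSE]
  pssm(id %||% sub("\\.[^.]*$", "", basename(path)),
       scores, paste(res, collapse = ""))
}

#' Write a PSSM profile in PSI-BLAST ASCII layout
#'
#' Intended for building test fixtures and synthetic datasets; emits the
#' header, the 20 log-odds columns in PSI-BLAST order, a zero percentage
#' block and trailing statistics so that [read_ascii_pssm()] round-trips.
#'
#' @param p A `"pssm"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(p, path) {
  stopifnot(inherits(p, "pssm"))
  E <- p$scores[, match(AA_PSIBLAST, AA_ALPHABETICAL), drop = FALSE]
  res <- strsplit(p$residues, "")[[1]]
  integerish <- all(abs(E - round(E)) < 1e-9)
  fmt_score <- function(v) {
    if (integerish) paste(sprintf("%3d", as.integer(round(v))), collapse = " ")
    else paste(sprintf("%6.2f", v), collapse = " ")
  }
  header <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted observed",
          "percentages rounded down, information per position, and relative",
          "weight of gapped matches"),
    paste0("         ",
           paste(sprintf("%3s", AA_PSIBLAST), collapse = " "), "  ",
           paste(sprintf("%3s", AA_PSIBLAST), collapse = " ")))
  pct <- paste(sprintf("%3d", rep(0L, 20)), collapse = " ")
  rows <- vapply(seq_len(nrow(E)), function(i) {
    sprintf("%5d %s  %s  %s  %5.2f %8.2f",
            i, res[i], fmt_score(E[i, ]), pct, 0, 0)
  }, character(1))
  writeLines(c(header, rows, "", "                      K         Lambda"),
             path)
  invisible(path)
}

#' Optional sigmoid rescaling of PSSM scores
#'
#' Maps every score x to 1/(1 + exp(-x)); `"raw"` leaves the log-odds scores
#' untouched (the default throughout the pipeline).
#'
#' @param p A `"pssm"` object.
#' @param scale `"raw"` or `"sigmoid"`.
#' @return A `"pssm"` object.
#' @export
scale_pssm <- function(p, scale = c("raw", "sigmoid")) {
  scale <- match.arg(scale)
  if (scale == "sigmoid") p$scores <- 1 / (1 + exp(-p$scores))
  p
}

# ---- evolutionary matrix descriptors ---------------------------------------

evo_matrix <- function(values, kind, id) {
  values <- as.matrix(values)
  stopifnot(identical(dim(values), c(20L, 20L)))
  dimnames(values) <- list(AA_ALPHABETICAL, AA_ALPHABETICAL)
  structure(values, kind = kind, id = id, class = c("evo_matrix", "matrix"))
}

#' @export
print.evo_matrix <- function(x, ...) {
  cat("20x20 ", attr(x, "kind"), " matrix for '", attr(x, "id"), "'\n",
      sep = "")
  print(unclass(x)[1:4, 1:4], ...)
  cat("...\n")
  invisible(x)
}

evo_kind <- function(m) attr(m, "kind")

#' PSSM dipeptide composition descriptor
#'
#' Collapses an `L x 20` profile into a 20x20 matrix: entry (a, b) is the sum
#' of the scores in column b over all positions whose query residue is a,
#' divided by the sequence length L.  Rows of the profile whose query residue
#' is non-standard contribute to no group; the divisor remains L.
#'
#' @param p A `"pssm"` object.
#' @return 20x20 `"evo_matrix"` of kind `"PSSM-DC"`; flatten with
#'   [flatten_evo()] for the traditional 400-dimensional descriptor.
#' @export
pssm_dc <- function(p) {
  stopifnot(inherits(p, "pssm"))
  L <- nrow(p$scores)
  res <- strsplit(p$residues, "")[[1]]
  keep <- res %in% AA_ALPHABETICAL
  M <- matrix(0, 20, 20, dimnames = list(AA_ALPHABETICAL, AA_ALPHABETICAL))
  if (any(keep)) {
    rs <- rowsum(p$scores[keep, , drop = FALSE],
                 group = factor(res[keep], levels = AA_ALPHABETICAL))
    M[rownames(rs), ] <- rs
  }
  evo_matrix(M / L, "PSSM-DC", p$id)
}

#' Bi-gram PSSM descriptor
#'
#' B\[m, n\] = sum over i = 1..L-1 of E\[i, m\] * E\[i+1, n\]: the
#' co-occurrence of substitution propensities at consecutive positions.
#'
#' @param p A `"pssm"` object with at least 2 positions.
#' @return 20x20 `"evo_matrix"` of kind `"BIGRAM"`.
#' @export
bigram_pssm <- function(p) {
  stopifnot(inherits(p, "pssm"))
  L <- nrow(p$scores)
  if (L < 2) stop("bi-gram PSSM requires L >= 2")
  E <- p$scores
  B <- crossprod(E[seq_len(L - 1), , drop = FALSE],
                 E[seq_len(L - 1) + 1, , drop = FALSE])
  evo_matrix(B, "BIGRAM", p$id)
}

#' Evolutionary-difference PSSM descriptor
#'
#' e\[m, n\] = sum over interior positions i = 2..L-1 of
#' (E\[i-1, m\] - E\[i+1, n\])^2 / (L - 2): the mean squared difference of
#' substitution scores two positions apart, capturing mutation contrast
#' between adjacent residues.  Element-wise non-negative by construction.
#'
#' @param p A `"pssm"` object with at least 3 positions.
#' @return 20x20 `"evo_matrix"` of kind `"ED"`.
#' @export
ed_pssm <- function(p) {
  stopifnot(inherits(p, "pssm"))
  L <- nrow(p$scores)
  if (L < 3) stop("ED-PSSM requires L >= 3")
  A <- p$scores[seq_len(L - 2), , drop = FALSE]        # E[i-1, ], i = 2..L-1
  C <- p$scores[seq_len(L - 2) + 2, , drop = FALSE]    # E[i+1, ], i = 2..L-1
  sa <- colSums(A^2)
  sc <- colSums(C^2)
  e <- (outer(sa, rep(1, 20)) + outer(rep(1, 20), sc) - 2 * crossprod(A, C)) /
    (L - 2)
  e[e < 0] <- 0   # guard tiny negative rounding
  evo_matrix(e, "ED", p$id)
}

#' Flatten a 20x20 evolutionary matrix to a named 400-vector
#'
#' Row-major order (first index major), matching the dipeptide ordering of
#' [gap_dipeptide_composition()].
#'
#' @param m An `"evo_matrix"`.
#' @param prefix Optional name prefix; defaults to the matrix kind.
#' @return Named numeric vector of length 400.
#' @export
flatten_evo <- function(m, prefix = NULL) {
  stopifnot(inherits(m, "evo_matrix"))
  prefix <- prefix %||% gsub("-", "", evo_kind(m))
  v <- as.vector(t(unclass(m)))
  names(v) <- paste0(prefix, ".", DIPEPTIDES)
  v
}
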