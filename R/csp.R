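# Two-class Common Spatial Patterns projection over 20x20 evolutionary
# matrices: whitening of the composite covariance, simultaneous
# diagonalization of the class covariances, and normalized log-variance
# features.

#' Normalized spatial covariance of an evolutionary matrix
#'
#' R = E E' / trace(E E'): symmetric, positive semi-definite, trace 1.
#'
#' @param m A 20x20 matrix (usually an `"evo_matrix"`).
#' @return 20x20 numeric matrix with unit trace.
#' @export
normalized_covariance <- function(m) {
  E <- unclass(as.matrix(m))
  cp <- E %*% t(E)
  tr <- sum(diag(cp))
  if (!is.finite(tr) || tr <= 0)
    stop("degenerate input: trace(EE') = ", tr)
  R <- cp / tr
  (R + t(R)) / 2
}

# Make eigenvector sign deterministic: first non-negligible entry positive.
sign_fix <- function(v) {
  i <- which(abs(v) > 1e-12)[1]
  if (!is.na(i) && v[i] < 0) -v else v
}

#' Fit a two-class Common Spatial Patterns model
#'
#' Averages the normalized covariances of each class (R1, R2), whitens the
#' composite Rc = R1 + R2 with P = lambda_c^(-1/2) Uc' so that P Rc P' = I,
#' and diagonalizes S1 = P R1 P' to obtain the common eigenbasis B.  Because
#' S1 + S2 = I, the class eigenvalues are complementary (lambda1 + lambda2 =
#' I): components with extreme eigenvalues are maximally discriminative.
#' The projection matrix is W = (B'P)'.
#'
#' @param class1,class2 Lists of `"evo_matrix"` objects (positive class
#'   first); all matrices must share one descriptor kind.
#' @param orientation `"paper"` projects Z = W E and takes column variances;
#'   `"standard"` projects Z = B'P E and takes row variances.
#' @return Object of class `"csp_model"` with elements `kind`, `W`, `P`,
#'   `B`, `eigvals_class1` (sorted decreasing, in \[0, 1\]), `orientation`,
#'   `fitted_on` and `condition_number`.
#' @export
fit_csp <- function(class1, class2, orientation = c("paper", "standard")) {
  orientation <- match.arg(orientation)
  if (!length(class1) || !length(class2))
    stop("both classes must be non-empty")
  kinds <- unique(unlist(lapply(c(class1, class2), function(m) {
    k <- attr(m, "kind")
    if (is.null(k)) NA_character_ else k
  })))
  kinds <- kinds[!is.na(kinds)]
  if (length(kinds) > 1)
    stop("all matrices must share one descriptor kind, found: ",
         paste(kinds, collapse = ", "))
  mean_cov <- function(ms)
    Reduce(`+`, lapply(ms, normalized_covariance)) / length(ms)
  R1 <- mean_cov(class1)
  R2 <- mean_cov(class2)
  Rc <- R1 + R2
  ec <- eigen(Rc, symmetric = TRUE)
  vmax <- max(ec$values)
  if (!is.finite(vmax) || vmax <= 0)
    stop("composite covariance is degenerate (max eigenvalue ", vmax, ")")
  floor_val <- 1e-10 * vmax
  cond <- vmax / max(min(ec$values), .Machine$double.xmin)
  if (min(ec$values) < floor_val) {
    warning("composite covariance is rank-deficient (condition number ",
            format(cond, digits = 3),
            "); eigenvalues clipped at 1e-10 * max before inversion")
    ec$values <- pmax(ec$values, floor_val)
  }
  P <- diag(1 / sqrt(ec$values)) %*% t(ec$vectors)
  S1 <- P %*% R1 %*% t(P)
  S1 <- (S1 + t(S1)) / 2
  eb <- eigen(S1, symmetric = TRUE)     # eigenvalues sorted decreasing
  B <- eb$vectors
  for (j in seq_len(ncol(B))) B[, j] <- sign_fix(B[, j])
  W <- t(t(B) %*% P)
  structure(list(kind = if (length(kinds)) kinds else NULL,
                 W = W, P = P, B = B,
                 eigvals_class1 = eb$values,
                 orientation = orientation,
                 fitted_on = c(class1 = length(class1),
                               class2 = length(class2)),
                 condition_number = cond),
            class = "csp_model")
}

#' @export
print.csp_model <- function(x, ...) {
  cat("CSP model", if (!is.null(x$kind)) paste0("(", x$kind, ")"),
      "fitted on", x$fitted_on["class1"], "+", x$fitted_on["class2"],
      "matrices\n")
  cat("  class-1 eigenvalues:",
      paste(sprintf("%.3f", utils::head(x$eigvals_class1, 4)), collapse = " "),
      "...",
      paste(sprintf("%.3f", utils::tail(x$eigvals_class1, 2)), collapse = " "),
      "\n")
  invisible(x)
}

#' CSP log-variance features of one evolutionary matrix
#'
#' Projects the matrix (Z = W E under the default `"paper"` orientation) and
#' returns f_j = log(var(Z_j) / sum_i var(Z_i)) for the 20 projected
#' components, where var is the population variance over the 20 entries of
#' each component.  The normalization makes the features invariant to
#' positive rescaling of E, and exp(f) sums to 1.
#'
#' @param model A fitted `"csp_model"`.
#' @param m A 20x20 matrix of the same descriptor kind.
#' @return Named numeric vector f1..f20.
#' @export
csp_features <- function(model, m) {
  stopifnot(inherits(model, "csp_model"))
  mk <- attr(m, "kind")
  if (!is.null(model$kind) && !is.null(mk) && !identical(model$kind, mk))
    stop("model fitted on kind '", model$kind,
         "' but matrix has kind '", mk, "'")
  E <- unclass(as.matrix(m))
  if (identical(model$orientation, "paper")) {
    Z <- model$W %*% E
    v <- apply(Z, 2, function(x) mean((x - mean(x))^2))
  } else {
    Z <- t(model$W) %*% E     # t(W) = B'P
    v <- apply(Z, 1, function(x) mean((x - mean(x))^2))
  }
  total <- sum(v)
  if (!is.finite(total) || total <= 0)
    stop("degenerate input: all projected components are constant")
  f <- log(pmax(v / total, 1e-300))
  stats::setNames(f, sprintf("f%02d", seq_len(20)))
}

#' Serialize a CSP model to a versioned JSON file
#'
#' @param model A `"csp_model"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_csp_model <- function(model, path) {
  stopifnot(inherits(model, "csp_model"))
  obj <- list(format = "golgiCSP/csp_model",
              version = 1L,
              kind = model$kind,
              orientation = model$orientation,
              W_row_major = as.vector(t(model$W)),
              eigvals_class1 = model$eigvals_class1,
              fitted_on = as.list(model$fitted_on),
              condition_number = model$condition_number)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a CSP model from its JSON serialization
#'
#' @param path Path written by [write_csp_model()].
#' @return A `"csp_model"` (without the intermediate `P`/`B` factors, which
#'   are not needed for feature extraction).
#' @export
read_csp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "golgiCSP/csp_model"))
    stop("'", path, "' is not a CSP model file")
  structure(list(kind = obj$kind,
                 W = matrix(obj$W_row_major, 20, 20, byrow = TRUE),
                 P = NULL, B = NULL,
                 eigvals_class1 = obj$eigvals_class1,
                 orientation = obj$orientation,
                 fitted_on = unlist(obj$fitted_on),
                 condition_number = obj$condition_number),
            class = "csp_model")
}
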