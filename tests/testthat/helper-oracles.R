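# Independent brute-force oracles and small fixture builders used across
# the test files.  Oracles are deliberately naive (explicit loops over the
# definitions) and share no code with the implementation.

AA20 <- golgiCSP::AA_ALPHABETICAL

# All 400 ordered pairs, first residue major (same canonical order).
PAIRS400 <- as.vector(t(outer(AA20, AA20, paste0)))

oracle_gapdc <- function(seq, g) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  v <- stats::setNames(numeric(400), PAIRS400)
  for (a in AA20) for (b in AA20) {
    n <- 0
    for (i in seq_len(L - g - 1))
      if (ch[i] == a && ch[i + g + 1] == b) n <- n + 1
    v[paste0(a, b)] <- n / (L - g - 1)
  }
  v
}

oracle_pssm_dc <- function(p) {
  E <- p$scores
  res <- strsplit(p$residues, "")[[1]]
  L <- nrow(E)
  M <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (a in AA20) for (j in seq_len(20))
    M[a, j] <- sum(E[res == a, j]) / L
  M
}

oracle_bigram <- function(p) {
  E <- p$scores
  L <- nrow(E)
  B <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (m in 1:20) for (n in 1:20) {
    s <- 0
    for (i in seq_len(L - 1)) s <- s + E[i, m] * E[i + 1, n]
    B[m, n] <- s
  }
  B
}

oracle_ed <- function(p) {
  E <- p$scores
  L <- nrow(E)
  M <- matrix(0, 20, 20, dimnames = list(AA20, AA20))
  for (m in 1:20) for (n in 1:20) {
    s <- 0
    for (i in 2:(L - 1)) s <- s + (E[i - 1, m] - E[i + 1, n])^2
    M[m, n] <- s / (L - 2)
  }
  M
}

# Mann-Whitney concordance probability by exhaustive pair enumeration.
oracle_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  total <- 0
  for (a in sp) for (b in sn)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(sp) * length(sn))
}

# Step-by-step recomputation of the CSP log-variance features (paper
# orientation): project, per-column population variance, normalized log.
oracle_csp_features <- function(model, E) {
  Z <- model$W %*% unclass(as.matrix(E))
  v <- numeric(20)
  for (j in 1:20) {
    col <- Z[, j]
    v[j] <- sum((col - mean(col))^2) / length(col)
  }
  log(v / sum(v))
}

# ---- fixture builders ------------------------------------------------------

rand_seq <- function(L) paste(sample(AA20, L, replace = TRUE), collapse = "")

rand_pssm <- function(L = 6, id = "p", lo = -10, hi = 10) {
  golgiCSP::pssm(id,
                 matrix(sample(lo:hi, L * 20, replace = TRUE), L, 20),
                 rand_seq(L))
}

rand_evo <- function(kind = NULL, scale = 1) {
  m <- matrix(stats::rnorm(400, sd = scale), 20, 20)
  if (!is.null(kind)) {
    attr(m, "kind") <- kind
    class(m) <- c("evo_matrix", "matrix")
  }
  m
}

# Two-class gaussian feature table with controllable mean shift.
toy_table <- function(n_per_class = 20, d = 4, shift = 0) {
  x <- rbind(matrix(stats::rnorm(n_per_class * d, shift), n_per_class, d),
             matrix(stats::rnorm(n_per_class * d, -shift), n_per_class, d))
  colnames(x) <- sprintf("v%02d", seq_len(d))
  golgiCSP::feature_table(x, rep(c("cis", "trans"), each = n_per_class))
}
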