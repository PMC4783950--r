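# Synthetic two-class fixture generator: Markov-chain sequences and
# Gaussian PSSM profiles whose class-conditional structure is controlled by
# a single separation parameter.

#' Specification of a synthetic two-class dataset
#'
#' Defaults mirror the shape of the curated Golgi benchmark: 87 cis
#' (positive) and 217 trans (negative) proteins, lengths 50-300.
#'
#' @param n_pos,n_neg Class sizes (>= 2 each).
#' @param len_range Integer range `c(Lmin, Lmax)` of sequence lengths,
#'   `Lmin >= 3`.
#' @param separation s >= 0; class-conditional biases scale with s, and
#'   s = 0 makes the two classes statistically identical.
#' @param noise Standard deviation of iid Gaussian noise added to PSSM
#'   scores.
#' @param seed Integer seed; the same spec reproduces the dataset exactly.
#' @return Object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_pos = 87, n_neg = 217, len_range = c(50, 300),
                       separation = 1, noise = 1, seed = 1) {
  stopifnot(n_pos >= 2, n_neg >= 2, length(len_range) == 2,
            len_range[1] >= 3, len_range[2] >= len_range[1],
            separation >= 0, noise >= 0)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 len_range = as.integer(len_range),
                 separation = separation, noise = noise,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

# Fixed class templates (independent of the sampling seed): Markov logit
# perturbations for sequences, and covariance templates for PSSM columns
# built as two random orthogonal rotations of a common decaying spectrum.
synth_templates <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cache <<- with_seed(7421L, {
      rot <- function() qr.Q(qr(matrix(stats::rnorm(400), 20)))
      spectrum <- diag(seq(25, 1, length.out = 20))
      Q0 <- rot(); Q1 <- rot(); Q2 <- rot()
      list(G = list(matrix(stats::rnorm(400), 20),
                    matrix(stats::rnorm(400), 20)),
           Sigma0 = Q0 %*% spectrum %*% t(Q0),
           Sigma = list(Q1 %*% spectrum %*% t(Q1),
                        Q2 %*% spectrum %*% t(Q2)))
    })
    cache
  }
})

# Class-conditional first-order Markov transition matrix over the 20 letters.
synth_transition <- function(class_idx, separation) {
  logit <- 0.5 * separation * synth_templates()$G[[class_idx]]
  Tm <- exp(logit)
  Tm <- Tm / rowSums(Tm)
  dimnames(Tm) <- list(AA_ALPHABETICAL, AA_ALPHABETICAL)
  Tm
}

#' Generate labeled synthetic protein sequences
#'
#' Each class samples from its own first-order Markov chain over the 20
#' standard amino acids; the chains' logits differ by a fixed perturbation
#' scaled by `separation` (identical chains at s = 0).
#'
#' @param spec A [synth_spec()].
#' @return List with `sequences` (named character vector, cis records
#'   first) and `labels` (named factor, levels cis/trans).
#' @export
generate_sequences <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  Tms <- list(synth_transition(1, spec$separation),
              synth_transition(2, spec$separation))
  n <- c(spec$n_pos, spec$n_neg)
  cls <- c("cis", "trans")
  with_seed(spec$seed, {
    seqs <- character(0)
    for (c_i in 1:2) {
      Tm <- Tms[[c_i]]
      for (p in seq_len(n[c_i])) {
        L <- sample(spec$len_range[1]:spec$len_range[2], 1)
        idx <- integer(L)
        idx[1] <- sample.int(20, 1)
        for (t in 2:L)
          idx[t] <- sample.int(20, 1, prob = Tm[idx[t - 1], ])
        seqs <- c(seqs, paste(AA_ALPHABETICAL[idx], collapse = ""))
      }
    }
    ids <- c(sprintf("cis_%03d", seq_len(n[1])),
             sprintf("trans_%03d", seq_len(n[2])))
    labels <- factor(rep(cls, n), levels = cls)
    names(labels) <- ids
    list(sequences = stats::setNames(seqs, ids), labels = labels)
  })
}

#' Generate labeled synthetic PSSM profiles
#'
#' Scores of each protein are drawn row-wise from a Gaussian with a
#' class-specific 20x20 column covariance: a common template and a
#' class-specific rotated template interpolated with weight
#' w = s/(1 + s), plus iid noise, then quantized to integers in
#' \[-10, 10\] as in PSI-BLAST ASCII output.  Every profile is written to an
#' ASCII PSSM file and re-read through [read_ascii_pssm()], so the standard
#' I/O path is exercised end to end.
#'
#' @param spec A [synth_spec()].
#' @param sequences Optional output of [generate_sequences()] (generated
#'   from `spec` when omitted); the query residue strings come from it.
#' @param dir Directory for the ASCII files; a temporary directory by
#'   default.
#' @return List with `pssms` (named list of `"pssm"` objects), `labels`,
#'   `sequences`, and `dir` (where the ASCII files live).
#' @export
generate_pssms <- function(spec, sequences = NULL, dir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  sequences <- sequences %||% generate_sequences(spec)
  dir <- dir %||% tempfile("synth_pssm_")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tpl <- synth_templates()
  w <- spec$separation / (1 + spec$separation)
  chol_cls <- lapply(1:2, function(c_i) {
    Sigma <- (1 - w) * tpl$Sigma0 + w * tpl$Sigma[[c_i]] +
      spec$noise^2 * diag(20)
    chol(Sigma)
  })
  ids <- names(sequences$sequences)
  cls_idx <- ifelse(sequences$labels == "cis", 1L, 2L)
  pssms <- with_seed(child_seed(spec$seed, 1000003), {
    out <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      L <- nchar(sequences$sequences[[i]])
      raw <- matrix(stats::rnorm(L * 20), L, 20) %*% chol_cls[[cls_idx[i]]]
      q <- round(raw)
      q[q > 10] <- 10
      q[q < -10] <- -10
      out[[i]] <- pssm(ids[i], q, sequences$sequences[[i]])
    }
    out
  })
  paths <- file.path(dir, paste0(ids, ".pssm"))
  for (i in seq_along(pssms)) write_ascii_pssm(pssms[[i]], paths[i])
  reread <- lapply(seq_along(paths),
                   function(i) read_ascii_pssm(paths[i], id = ids[i]))
  names(reread) <- ids
  list(pssms = reread, labels = sequences$labels,
       sequences = sequences$sequences, dir = dir)
}

#' Write a complete synthetic fixture directory
#'
#' Emits `sequences.fasta`, one ASCII PSSM per protein under `pssm/`, and
#' `labels.csv` (columns `id`, `label`).
#'
#' @param spec A [synth_spec()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_pssms(spec, dir = file.path(dir, "pssm"))
  write_fasta(gen$sequences, file.path(dir, "sequences.fasta"))
  utils::write.csv(data.frame(id = names(gen$labels),
                              label = as.character(gen$labels)),
                   file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a fixture directory written by [write_fixture_dir()]
#'
#' @param dir Fixture directory.
#' @return List with `sequences`, `pssms`, `labels`.
#' @export
read_fixture_dir <- function(dir) {
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  labels <- factor(lab$label, levels = c("cis", "trans"))
  names(labels) <- lab$id
  pssms <- lapply(lab$id, function(id)
    read_ascii_pssm(file.path(dir, "pssm", paste0(id, ".pssm")), id = id))
  names(pssms) <- lab$id
  list(sequences = seqs, pssms = pssms, labels = labels)
}
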