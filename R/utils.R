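# Amino-acid alphabets and small helpers shared across modules.

#' Standard amino acids in alphabetical one-letter order
#'
#' Column/row ordering used throughout the package for dipeptide vectors and
#' evolutionary matrices.
#' @format Character vector of length 20.
#' @export
AA_ALPHABETICAL <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                     "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid column order of PSI-BLAST ASCII PSSM files
#' @format Character vector of length 20.
#' @export
AA_PSIBLAST <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Ambiguity / non-standard codes: recorded but excluded from dipeptide counts.
AA_NONSTANDARD <- c("B", "J", "O", "U", "X", "Z")

# 400 ordered residue pairs, first residue major: AA, AC, ..., AY, CA, ...
DIPEPTIDES <- as.vector(t(outer(AA_ALPHABETICAL, AA_ALPHABETICAL, paste0)))

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL runs `code` on the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive a child seed from a base seed, staying inside 32-bit integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 37 + offset) %% .Machine$integer.max)
}
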