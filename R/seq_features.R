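# Sequence-level descriptors: FASTA I/O, amino-acid frequencies and the
# g-gap dipeptide composition.

#' Read protein sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readAAStringSet()] that upper-cases
#' residues, keeps record order, and validates records.
#'
#' @param path Path to a FASTA file; multi-line sequences are allowed.
#' @return Named character vector of residue strings; names are the FASTA
#'   identifiers (first whitespace-delimited word of each header).  An empty
#'   file yields an empty vector.
#' @seealso [write_fasta()], [gap_dipeptide_composition()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  bad <- which(is.na(ids) | !nzchar(ids))
  if (length(bad))
    stop("malformed FASTA header (empty id) at record ", bad[1])
  empty <- which(!nzchar(seqs))
  if (length(empty))
    stop("empty sequence for record '", ids[empty[1]], "'")
  stats::setNames(unname(seqs), ids)
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs Named character vector of residue strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' g-gap dipeptide composition of a protein sequence
#'
#' Counts ordered residue pairs separated by `g` intervening positions and
#' normalizes by the number of available positions, `L - g - 1`.  The result
#' is the 400-dimensional descriptor F^g with entries f_i^g = n_i^g/(L-g-1),
#' indexed by ordered pairs of the 20 standard amino acids in alphabetical
#' order, first residue major (AA, AC, ..., AY, CA, ..., YY).
#'
#' Pairs touching a non-standard residue (B, J, O, U, X, Z) are not counted;
#' the denominator stays `L - g - 1`, so the vector sums to the fraction of
#' countable pairs (exactly 1 for all-standard sequences).
#'
#' @param seq A single residue string (or one element of [read_fasta()]'s
#'   output).
#' @param g Number of intervening residues, `0 <= g <= L - 2`.  Default 3,
#'   the gap at which downstream classification performance peaks.
#' @return Named numeric vector of length 400 with attribute `g`.
#' @export
gap_dipeptide_composition <- function(seq, g = 3) {
  stopifnot(length(seq) == 1, is.character(seq))
  g <- as.integer(g)
  if (is.na(g) || g < 0) stop("g must be a non-negative integer")
  s <- toupper(seq)
  L <- nchar(s)
  if (L < g + 2)
    stop("sequence of length ", L, " is too short for g = ", g,
         " (requires L >= g + 2)")
  ch <- strsplit(s, "")[[1]]
  i <- seq_len(L - g - 1)
  first <- ch[i]
  second <- ch[i + g + 1]
  ok <- first %in% AA_ALPHABETICAL & second %in% AA_ALPHABETICAL
  counts <- table(factor(paste0(first[ok], second[ok]), levels = DIPEPTIDES))
  v <- as.numeric(counts) / (L - g - 1)
  names(v) <- DIPEPTIDES
  attr(v, "g") <- g
  v
}

#' Per-protein amino-acid frequencies
#'
#' Frequencies of the 20 standard amino acids within one sequence, computed
#' over standard residues only (so they sum to 1 whenever any standard
#' residue is present).
#'
#' @param seq A single residue string.
#' @return Named numeric vector of length 20.
#' @export
aa_frequencies <- function(seq) {
  stopifnot(length(seq) == 1, is.character(seq))
  ch <- strsplit(toupper(seq), "")[[1]]
  ch <- ch[ch %in% AA_ALPHABETICAL]
  if (!length(ch)) stop("sequence contains no standard residues")
  counts <- table(factor(ch, levels = AA_ALPHABETICAL))
  stats::setNames(as.numeric(counts) / length(ch), AA_ALPHABETICAL)
}

#' Average amino-acid frequencies over a set of proteins
#'
#' Mean of the per-protein frequency profiles, as used to compare the overall
#' composition of cis- and trans-Golgi proteins.
#'
#' @param seqs Character vector of residue strings (e.g. one class).
#' @return Named numeric vector of length 20.
#' @export
class_aa_frequencies <- function(seqs) {
  if (!length(seqs)) stop("empty sequence set")
  profiles <- vapply(seqs, aa_frequencies, numeric(20))
  stats::setNames(rowMeans(profiles), AA_ALPHABETICAL)
}
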