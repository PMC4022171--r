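# Shared sequence utilities.

#' Split a sequence string into a character vector of residues
#' @noRd
seq_chars <- function(seq) {
  strsplit(seq, "", fixed = TRUE)[[1]]
}

#' Validate a protein sequence
#'
#' Accepts the 20 standard amino-acid one-letter codes plus `X` (unknown).
#' Case-insensitive; returns the uppercased residue vector.
#'
#' @param seq single protein string.
#' @param allow_x allow the ambiguity code `X`.
#' @return uppercase character vector of residues.
#' @noRd
check_protein <- function(seq, allow_x = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  chars <- toupper(seq_chars(seq))
  ok <- chars %in% c(AA20, if (allow_x) "X")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("invalid amino-acid character '%s' at position %d",
                 chars[bad], bad), call. = FALSE)
  }
  chars
}

#' Validate a DNA sequence (A/C/G/T/N)
#' @noRd
check_dna <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  chars <- toupper(seq_chars(seq))
  ok <- chars %in% c("A", "C", "G", "T", "N")
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(sprintf("invalid nucleotide '%s' at position %d", chars[bad], bad),
         call. = FALSE)
  }
  chars
}

#' Read protein sequences from FASTA into a named character vector
#'
#' Thin wrapper around [Biostrings::readAAStringSet()]; the full header line
#' is preserved as the sequence name.
#'
#' @param path path to a (possibly multi-record) protein FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- names(ss)
  out
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  ss <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Run an expression with a locally seeded RNG
#'
#' Restores the caller's RNG state afterwards so seeded operations do not
#' perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
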