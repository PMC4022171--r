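# Short linear motif scanning: LXXLL, LXLXLX (EAR-like), HARF, W-box,
# leucine-zipper heptad heuristic.

#' Scan a protein for a defined accessory motif
#'
#' Exhaustive overlapping-window scan for the accessory motifs reported in
#' WRKY proteins. Motif definitions (all positions are residues):
#' \describe{
#'   \item{LXXLL}{coactivator motif: Leu, any, any, Leu, Leu (5 residues).}
#'   \item{LXLXLX}{EAR-like active-repressor motif: Leu alternating with any
#'     residue over 6 positions (L at window positions 1, 3, 5).}
#'   \item{HARF}{the literal RTGHARFRR(A/G)P signature of group IId members
#'     (11 residues).}
#' }
#' Matching is case-insensitive; all overlapping occurrences are reported,
#' sorted by start (0-based).
#'
#' @param seq protein string.
#' @param motif one of `"LXXLL"`, `"LXLXLX"`, `"HARF"`.
#' @param id sequence identifier copied into the output.
#' @return data.frame with columns `sequence_id`, `motif`, `start`, `match`,
#'   `strand` (always `"+"` for proteins).
#' @export
#' @examples
#' find_protein_motif("RTGHARFRRAP", "HARF")
find_protein_motif <- function(seq, motif = c("LXXLL", "LXLXLX", "HARF"),
                               id = "seq") {
  motif <- match.arg(motif)
  chars <- check_protein(seq)
  n <- length(chars)
  w <- switch(motif, LXXLL = 5L, LXLXLX = 6L, HARF = 11L)
  empty <- data.frame(sequence_id = character(), motif = character(),
                      start = integer(), match = character(),
                      strand = character(), stringsAsFactors = FALSE)
  if (n < w) return(empty)
  nwin <- n - w + 1L
  hit <- switch(motif,
    LXXLL = chars[1:nwin] == "L" & chars[4:(nwin + 3L)] == "L" &
            chars[5:(nwin + 4L)] == "L",
    LXLXLX = chars[1:nwin] == "L" & chars[3:(nwin + 2L)] == "L" &
             chars[5:(nwin + 4L)] == "L",
    HARF = {
      lit <- seq_chars("RTGHARFRR")
      ok <- rep(TRUE, nwin)
      for (k in 1:9) ok <- ok & chars[k:(nwin + k - 1L)] == lit[k]
      ok & chars[10:(nwin + 9L)] %in% c("A", "G") &
        chars[11:(nwin + 10L)] == "P"
    })
  idx <- which(hit)
  if (!length(idx)) return(empty)
  data.frame(
    sequence_id = id, motif = motif, start = idx - 1L,
    match = vapply(idx, function(i) paste(chars[i:(i + w - 1L)],
                                          collapse = ""), character(1)),
    strand = "+", stringsAsFactors = FALSE)
}

#' Scan DNA for the W-box element
#'
#' The W-box is the WRKY-binding cis-element `(C/T)TGAC(T/C)`. Minus-strand
#' hits are reported in plus-strand coordinates of the match start with
#' strand `"-"`. `N` never matches.
#'
#' @param dna DNA string (A/C/G/T/N).
#' @param both_strands also scan the reverse complement.
#' @param id sequence identifier.
#' @return data.frame with columns `sequence_id`, `motif`, `start`, `match`
#'   (plus-strand slice), `strand`.
#' @export
#' @examples
#' find_wbox("TTGACC")
find_wbox <- function(dna, both_strands = TRUE, id = "seq") {
  chars <- check_dna(dna)
  n <- length(chars)
  empty <- data.frame(sequence_id = character(), motif = character(),
                      start = integer(), match = character(),
                      strand = character(), stringsAsFactors = FALSE)
  if (n < 6L) return(empty)
  nwin <- n - 5L
  match_at <- function(cv) {
    cv[1:nwin] %in% c("C", "T") & cv[2:(nwin + 1L)] == "T" &
      cv[3:(nwin + 2L)] == "G" & cv[4:(nwin + 3L)] == "A" &
      cv[5:(nwin + 4L)] == "C" & cv[6:(nwin + 5L)] %in% c("T", "C")
  }
  slice <- function(i) paste(chars[i:(i + 5L)], collapse = "")
  plus <- which(match_at(chars))
  rows <- list()
  if (length(plus)) {
    rows[[1]] <- data.frame(sequence_id = id, motif = "WBOX",
                            start = plus - 1L,
                            match = vapply(plus, slice, character(1)),
                            strand = "+", stringsAsFactors = FALSE)
  }
  if (both_strands) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    rc <- rev(unname(comp[chars]))
    minus <- which(match_at(rc))
    if (length(minus)) {
      # position on the reverse complement -> plus-strand start of the window
      ps <- n - (minus - 1L) - 5L
      ord <- order(ps)
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = id, motif = "WBOX", start = ps[ord] - 1L,
        match = vapply(ps[ord], slice, character(1)),
        strand = "-", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out$start <- as.integer(out$start)
  out
}

#' Heptad-periodicity heuristic for leucine zippers
#'
#' Reports maximal runs of leucines spaced exactly seven residues apart
#' (positions i, i+7, i+14, ...) with at least `min_heptads` leucines. This
#' is a transparent heuristic for coiled-coil leucine zippers ("LZ-heuristic"
#' in reports), not a coiled-coil profile method: it captures the defining
#' d-position periodicity only.
#'
#' @param seq protein string.
#' @param min_heptads minimum number of periodic leucines (default 4).
#' @param allow_ile also accept isoleucine at the periodic positions.
#' @param id sequence identifier.
#' @return data.frame with columns `sequence_id`, `motif` (`"LZ-heuristic"`),
#'   `start` (0-based first Leu), `end` (one past the last Leu),
#'   `n_heptads`.
#' @export
predict_leucine_zipper <- function(seq, min_heptads = 4L, allow_ile = FALSE,
                                   id = "seq") {
  chars <- check_protein(seq)
  n <- length(chars)
  accept <- chars == "L" | (allow_ile & chars == "I")
  empty <- data.frame(sequence_id = character(), motif = character(),
                      start = integer(), end = integer(),
                      n_heptads = integer(), stringsAsFactors = FALSE)
  rows <- list()
  for (i in seq_len(n)) {
    if (!accept[i]) next
    if (i > 7L && accept[i - 7L]) next        # not a run start
    k <- 0L
    while (i + 7L * k <= n && accept[i + 7L * k]) k <- k + 1L
    if (k >= min_heptads) {
      rows[[length(rows) + 1L]] <- data.frame(
        sequence_id = id, motif = "LZ-heuristic", start = i - 1L,
        end = i + 7L * (k - 1L), n_heptads = k, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan several proteins for several motifs
#'
#' @param seqs named character vector of protein sequences.
#' @param motifs subset of `c("LXXLL", "LXLXLX", "HARF")`.
#' @return row-bound [find_protein_motif()] results.
#' @export
scan_motifs <- function(seqs, motifs = c("LXXLL", "LXLXLX", "HARF")) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  out <- list()
  for (id in names(seqs)) {
    for (m in motifs) {
      out[[length(out) + 1L]] <- find_protein_motif(seqs[[id]], m, id)
    }
  }
  do.call(rbind, out)
}
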