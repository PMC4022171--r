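# WRKY domain detection: conserved heptapeptide + zinc-finger spacing grammar.

WRKY_HEPTA <- "WRKYGQK"

#' Scanner configuration
#'
#' Bundles the tunable parameters of the WRKY domain scanner. The zinc-finger
#' grammar is `C-X(s1)-C-X(s2)-H-X(s3)-[H|C]`: two cysteines, a histidine and
#' a terminal histidine (C2H2 finger, groups I/II) or cysteine (C2HC finger,
#' group III), separated by spacers whose admissible lengths are given as
#' inclusive ranges. Defaults take the permissive union of the finger forms
#' reported for plant WRKY proteins, wide enough to cover the C-X7-C-X23-HTC
#' fingers of the grapevine group III members.
#'
#' @param spacer1 integer range (length 2) for residues between the two Cys.
#' @param spacer2 integer range between the second Cys and the first His.
#' @param spacer3 integer range between the first His and the terminal ligand.
#' @param max_mismatch maximum Hamming distance to `WRKYGQK` tolerated in the
#'   heptapeptide (default 1, matching the single-substitution variants such
#'   as `WRKYGKK` seen in the family).
#' @param require_w require the tryptophan at heptapeptide position 1 to be
#'   invariant even when mismatches are allowed (no natural variant alters it).
#' @param linker_window maximum number of residues between the heptapeptide
#'   end and the first zinc-finger cysteine (default 30, consistent with the
#'   ~60-residue span of the full domain).
#' @param max_span maximum domain span in residues, heptapeptide start to one
#'   past the terminal ligand (default 80).
#' @return a list of class `wrky_scan_config`.
#' @export
wrky_scan_config <- function(spacer1 = c(4L, 8L),
                             spacer2 = c(22L, 28L),
                             spacer3 = c(1L, 2L),
                             max_mismatch = 1L,
                             require_w = TRUE,
                             linker_window = 30L,
                             max_span = 80L) {
  for (r in list(spacer1, spacer2, spacer3)) {
    stopifnot(length(r) == 2L, r[1] >= 0, r[1] <= r[2])
  }
  stopifnot(max_mismatch >= 0, linker_window >= 0, max_span > 0)
  structure(list(spacer1 = as.integer(spacer1),
                 spacer2 = as.integer(spacer2),
                 spacer3 = as.integer(spacer3),
                 max_mismatch = as.integer(max_mismatch),
                 require_w = isTRUE(require_w),
                 linker_window = as.integer(linker_window),
                 max_span = as.integer(max_span)),
            class = "wrky_scan_config")
}

#' Scan a protein for WRKYGQK heptapeptide occurrences
#'
#' Reports every length-7 window within `max_mismatch` Hamming distance of
#' the canonical `WRKYGQK`, sorted by start. All coordinates are 0-based.
#'
#' @param seq protein sequence string.
#' @param max_mismatch maximum number of substitutions tolerated.
#' @param require_w if `TRUE`, windows whose first residue is not `W` are
#'   rejected regardless of total mismatch count.
#' @return data.frame with columns `start` (0-based), `observed`, `mismatches`.
#' @export
#' @examples
#' scan_heptapeptide("AAWRKYGKKAA", max_mismatch = 1)
scan_heptapeptide <- function(seq, max_mismatch = 1L, require_w = TRUE) {
  chars <- check_protein(seq)
  n <- length(chars)
  hep <- seq_chars(WRKY_HEPTA)
  empty <- data.frame(start = integer(), observed = character(),
                      mismatches = integer(), stringsAsFactors = FALSE)
  if (n < 7L) return(empty)
  # vectorized window comparison: mm[i] = Hamming distance of window at i
  mm <- integer(n - 6L)
  for (k in 1:7) {
    mm <- mm + (chars[k:(n - 7L + k)] != hep[k])
  }
  keep <- mm <= max_mismatch
  if (require_w) keep <- keep & chars[seq_len(n - 6L)] == "W"
  idx <- which(keep)
  if (!length(idx)) return(empty)
  data.frame(
    start = idx - 1L,
    observed = vapply(idx, function(i) paste(chars[i:(i + 6L)], collapse = ""),
                      character(1)),
    mismatches = mm[idx],
    stringsAsFactors = FALSE
  )
}

#' Construct a zinc-finger specification
#'
#' @param spacer1,spacer2,spacer3 spacer lengths between successive ligands.
#' @param terminal terminal ligand, `"H"` (C2H2) or `"C"` (C2HC).
#' @param intervening observed residues in the third spacer, or `NA` when
#'   unspecified (formatted as `X`).
#' @return object of class `zinc_finger_spec`.
#' @export
zinc_finger_spec <- function(spacer1, spacer2, spacer3 = 1L,
                             terminal = c("H", "C"), intervening = NA_character_) {
  terminal <- match.arg(terminal)
  stopifnot(spacer1 >= 0, spacer2 >= 0, spacer3 >= 1)
  if (!is.na(intervening) && nchar(intervening) != spacer3) {
    stop("intervening residues must have length spacer3", call. = FALSE)
  }
  structure(list(spacer1 = as.integer(spacer1),
                 spacer2 = as.integer(spacer2),
                 spacer3 = as.integer(spacer3),
                 terminal = terminal,
                 intervening = intervening,
                 class = if (terminal == "C") "C2HC" else "C2H2"),
            class = "zinc_finger_spec")
}

#' Parse a Table-style zinc-finger pattern string
#'
#' Understands the compact catalog notation, e.g. `"C-X4-C-X23-HXH"` (C2H2,
#' spacers 4/23/1) or `"C-X7-C-X23-HTC"` (C2HC with the observed threonine
#' between His and the terminal Cys). Underscores and whitespace (subscript
#' markup) are stripped before parsing. In the trailing token the leading `H`
#' is the first histidine ligand, the final letter (`H` or `C`) the terminal
#' ligand, and the characters in between the third spacer: each `X` is an
#' unspecified residue, any other letter is recorded as observed; `Xn` with a
#' count is also accepted.
#'
#' @param s pattern string.
#' @return a [zinc_finger_spec()].
#' @export
#' @examples
#' parse_pattern("C-X4-C-X23-HXH")
#' parse_pattern("C-X7-C-X23-HTC")
parse_pattern <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  raw <- s
  s <- toupper(gsub("[_[:space:]]", "", s))
  if (!nzchar(s)) stop("empty pattern string", call. = FALSE)
  m <- regmatches(s, regexec("^C-X([0-9]+)-C-X([0-9]+)-H(.*)$", s))[[1]]
  if (!length(m)) {
    stop(sprintf("pattern '%s' does not match the finger grammar C-Xa-C-Xb-H...",
                 raw), call. = FALSE)
  }
  spacer1 <- as.integer(m[2])
  spacer2 <- as.integer(m[3])
  tail <- m[4]
  if (nchar(tail) < 2L) {
    stop(sprintf("pattern '%s': truncated terminal token", raw), call. = FALSE)
  }
  terminal <- substr(tail, nchar(tail), nchar(tail))
  if (!terminal %in% c("H", "C")) {
    stop(sprintf("pattern '%s': terminal ligand must be H or C, got '%s'",
                 raw, terminal), call. = FALSE)
  }
  mid <- substr(tail, 1L, nchar(tail) - 1L)
  cm <- regmatches(mid, regexec("^X([0-9]+)$", mid))[[1]]
  if (length(cm)) {           # "X2" style counted spacer
    spacer3 <- as.integer(cm[2])
    intervening <- NA_character_
  } else {
    if (!grepl("^[A-Z]+$", mid)) {
      stop(sprintf("pattern '%s': bad spacer token '%s'", raw, mid),
           call. = FALSE)
    }
    spacer3 <- nchar(mid)
    intervening <- if (grepl("^X+$", mid)) NA_character_ else mid
  }
  if (spacer3 < 1L) {
    stop(sprintf("pattern '%s': third spacer must be at least 1", raw),
         call. = FALSE)
  }
  zinc_finger_spec(spacer1, spacer2, spacer3, terminal, intervening)
}

#' Format a zinc-finger specification as a pattern string
#'
#' Inverse of [parse_pattern()] up to the catalog's conventions: C2H2
#' fingers always render with unspecified spacer residues (`C-Xa-C-Xb-HXH`);
#' C2HC fingers interpolate the recorded intervening residues when present,
#' e.g. `C-X7-C-X23-HTC`.
#'
#' @param f a [zinc_finger_spec()].
#' @return pattern string.
#' @export
format_pattern <- function(f) {
  stopifnot(inherits(f, "zinc_finger_spec"))
  mid <- if (f$terminal == "H" || is.na(f$intervening)) {
    strrep("X", f$spacer3)
  } else {
    f$intervening
  }
  sprintf("C-X%d-C-X%d-H%s%s", f$spacer1, f$spacer2, mid, f$terminal)
}

#' @export
print.zinc_finger_spec <- function(x, ...) {
  cat(sprintf("<zinc finger %s: %s>\n", x$class, format_pattern(x)))
  invisible(x)
}

#' Find the leftmost zinc finger at or after a position
#'
#' Searches for the motif `C-X(s1)-C-X(s2)-H-X(s3)-[H|C]` whose first
#' cysteine lies in `[from_pos, from_pos + window)`. Among candidates the
#' smallest first-Cys position wins, then the smallest `spacer1`, then the
#' smallest `spacer2`, then the smallest `spacer3`.
#'
#' @param seq protein string.
#' @param from_pos 0-based position from which to search.
#' @param config a [wrky_scan_config()].
#' @param window search window for the first Cys; defaults to
#'   `config$linker_window`.
#' @return `NULL` if absent, else a list with `spec` (a `zinc_finger_spec`
#'   carrying the observed spacer-3 residues) and `positions`, the four
#'   0-based ligand positions (Cys, Cys, His, terminal).
#' @export
find_zinc_finger <- function(seq, from_pos = 0L, config = wrky_scan_config(),
                             window = config$linker_window) {
  chars <- check_protein(seq)
  n <- length(chars)
  if (from_pos < 0L || from_pos >= n) stop("from_pos outside sequence",
                                           call. = FALSE)
  last_c1 <- min(n - 1L, from_pos + window - 1L)
  p <- from_pos
  while (p <= last_c1) {
    if (chars[p + 1L] == "C") {
      for (s1 in config$spacer1[1]:config$spacer1[2]) {
        c2 <- p + 1L + s1
        if (c2 + 1L > n || chars[c2 + 1L] != "C") next
        for (s2 in config$spacer2[1]:config$spacer2[2]) {
          h1 <- c2 + 1L + s2
          if (h1 + 1L > n || chars[h1 + 1L] != "H") next
          for (s3 in config$spacer3[1]:config$spacer3[2]) {
            t <- h1 + 1L + s3
            if (t + 1L > n) next
            if (chars[t + 1L] %in% c("H", "C")) {
              iv <- paste(chars[(h1 + 2L):t], collapse = "")
              spec <- zinc_finger_spec(s1, s2, s3,
                                       terminal = chars[t + 1L],
                                       intervening = iv)
              return(list(spec = spec, positions = c(p, c2, h1, t)))
            }
          }
        }
      }
    }
    p <- p + 1L
  }
  NULL
}

#' Scan a protein for complete WRKY domains
#'
#' A domain is a heptapeptide hit (see [scan_heptapeptide()]) paired with the
#' leftmost zinc finger whose first Cys falls within `config$linker_window`
#' residues of the heptapeptide end. Hits without a finger are dropped;
#' pairings whose total span exceeds `config$max_span` are dropped; domains
#' fully nested inside another reported domain are removed. Domains are
#' reported N- to C-terminal. Coordinates are 0-based half-open.
#'
#' @param seq protein string.
#' @param config a [wrky_scan_config()].
#' @param protein_id identifier copied into the output.
#' @return data.frame with one row per domain: `protein_id`, `start`, `end`,
#'   `hepta_start`, `hepta_seq`, `mismatches`, ligand positions `c1`, `c2`,
#'   `h1`, `t`, `spacer1..3`, `terminal`, `finger_class`, `pattern`.
#' @export
scan_domains <- function(seq, config = wrky_scan_config(), protein_id = "seq") {
  hits <- scan_heptapeptide(seq, config$max_mismatch, config$require_w)
  cols <- c("protein_id", "start", "end", "hepta_start", "hepta_seq",
            "mismatches", "c1", "c2", "h1", "t", "spacer1", "spacer2",
            "spacer3", "terminal", "finger_class", "pattern")
  empty <- structure(
    data.frame(protein_id = character(), start = integer(), end = integer(),
               hepta_start = integer(), hepta_seq = character(),
               mismatches = integer(), c1 = integer(), c2 = integer(),
               h1 = integer(), t = integer(), spacer1 = integer(),
               spacer2 = integer(), spacer3 = integer(),
               terminal = character(), finger_class = character(),
               pattern = character(), stringsAsFactors = FALSE),
    names = cols)
  if (!nrow(hits)) return(empty)
  n <- nchar(seq)
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    h0 <- hits$start[i]
    from <- h0 + 7L
    if (from >= n) next
    zf <- find_zinc_finger(seq, from, config)
    if (is.null(zf)) next
    end <- zf$positions[4] + 1L
    if (end - h0 > config$max_span) next
    s <- zf$spec
    rows[[length(rows) + 1L]] <- data.frame(
      protein_id = protein_id, start = h0, end = end,
      hepta_start = h0, hepta_seq = hits$observed[i],
      mismatches = hits$mismatches[i],
      c1 = zf$positions[1], c2 = zf$positions[2],
      h1 = zf$positions[3], t = zf$positions[4],
      spacer1 = s$spacer1, spacer2 = s$spacer2, spacer3 = s$spacer3,
      terminal = s$terminal, finger_class = s$class,
      pattern = format_pattern(s), stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end), , drop = FALSE]
  # remove domains fully nested inside another
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    for (j in seq_len(nrow(out))) {
      if (i != j && keep[j] &&
          out$start[j] <= out$start[i] && out$end[i] <= out$end[j] &&
          (out$end[j] - out$start[j]) > (out$end[i] - out$start[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan every record of a protein FASTA file (or named vector) for domains
#'
#' @param x path to a protein FASTA file, or a named character vector.
#' @param config a [wrky_scan_config()].
#' @return row-bound [scan_domains()] results across records.
#' @export
scan_fasta <- function(x, config = wrky_scan_config()) {
  seqs <- if (is.character(x) && length(x) == 1L && file.exists(x)) {
    read_protein_fasta(x)
  } else x
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  out <- lapply(names(seqs), function(id) scan_domains(seqs[[id]], config, id))
  do.call(rbind, out)
}

#' Extract domain subsequences from scan results
#'
#' @param seqs named character vector of the scanned proteins.
#' @param domains data.frame from [scan_domains()]/[scan_fasta()].
#' @return named character vector of domain sequences, names
#'   `<protein_id>|<start>-<end>`.
#' @export
domain_sequences <- function(seqs, domains) {
  vapply(seq_len(nrow(domains)), function(i) {
    substr(seqs[[domains$protein_id[i]]], domains$start[i] + 1L,
           domains$end[i])
  }, character(1)) -> out
  names(out) <- sprintf("%s|%d-%d", domains$protein_id, domains$start,
                        domains$end)
  out
}
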