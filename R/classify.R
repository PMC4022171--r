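# Group / subgroup assignment for scanned WRKY proteins.

#' Reference set of labelled group II subgroup domains
#'
#' A small container pairing subgroup labels with representative domain
#' sequences, used by the nearest-reference layer of [assign_subgroup()].
#'
#' @param labels character vector of subgroup labels (`IIa`..`IIe`).
#' @param seqs character vector of non-empty domain sequences, same length.
#' @return data.frame of class `wrky_reference_set`.
#' @export
reference_set <- function(labels, seqs) {
  stopifnot(length(labels) == length(seqs), all(nzchar(seqs)))
  ok <- labels %in% c("IIa", "IIb", "IIc", "IId", "IIe")
  if (!all(ok)) {
    stop("reference labels must be group II subgroups, got: ",
         paste(unique(labels[!ok]), collapse = ", "), call. = FALSE)
  }
  structure(data.frame(label = labels, seq = toupper(seqs),
                       stringsAsFactors = FALSE),
            class = c("wrky_reference_set", "data.frame"))
}

#' Assign the WRKY group from scanned domains
#'
#' The group follows domain count and finger structure: two or more domains
#' make group I (the N-most domain labelled NTWD, the C-most CTWD); a single
#' C2HC domain (terminal Cys) makes group III; a single C2H2 domain makes
#' group II; no domain leaves the protein unclassified.
#'
#' @param domains data.frame from [scan_domains()] for one protein, ordered
#'   N- to C-terminal.
#' @return list of class `wrky_group_call`: `protein_id`, `group` (`I`,
#'   `II`, `III`, `unclassified`), `subgroup` (`NA` until
#'   [assign_subgroup()]), `evidence` (n_domains, finger classes, spacer1 of
#'   the single domain, domain roles).
#' @export
assign_group <- function(domains) {
  pid <- if (nrow(domains)) domains$protein_id[1] else NA_character_
  nd <- nrow(domains)
  roles <- if (nd >= 2L) {
    r <- rep("internal", nd)
    r[1] <- "NTWD"; r[nd] <- "CTWD"
    r
  } else if (nd == 1L) "single" else character(0)
  group <- if (nd >= 2L) "I"
  else if (nd == 1L && domains$terminal[1] == "C") "III"
  else if (nd == 1L) "II"
  else "unclassified"
  structure(list(
    protein_id = pid, group = group, subgroup = NA_character_,
    evidence = list(n_domains = nd,
                    finger_classes = domains$finger_class,
                    spacer1 = if (nd == 1L) domains$spacer1[1] else NA_integer_,
                    roles = roles)),
    class = "wrky_group_call")
}

#' Assign a group II subgroup
#'
#' Layered scheme for single-domain C2H2 proteins:
#' \enumerate{
#'   \item HARF motif (`RTGHARFRR(A/G)P`) anywhere in the full protein
#'     forces subgroup IId (the motif is diagnostic of that subgroup);
#'   \item a first zinc-finger spacer of 4 residues forces IIc (every IIc
#'     member of the grapevine catalog has a C-X4 finger, every other
#'     group II subgroup C-X5 or wider);
#'   \item otherwise the domain is matched against a labelled reference set
#'     by global-alignment identity, taking the nearest neighbour's label
#'     (identity ties break to the lexicographically smallest label);
#'   \item with no reference set and no rule fired, the subgroup is `none`.
#' }
#'
#' @param domain one-row data.frame from [scan_domains()].
#' @param protein_seq the full protein sequence (for the HARF rule).
#' @param refs optional [reference_set()].
#' @param domain_seq the domain subsequence (for the nearest-reference
#'   layer); extracted from `protein_seq` if omitted.
#' @return list: `subgroup` (`IIa`..`IIe` or `"none"`), `path` (which layer
#'   fired: `"HARF"`, `"spacer"`, `"nearest"`, `"none"`), `nearest`
#'   (reference label row or `NA`), `identity`.
#' @export
assign_subgroup <- function(domain, protein_seq, refs = NULL,
                            domain_seq = NULL) {
  stopifnot(nrow(domain) == 1L)
  harf <- find_protein_motif(protein_seq, "HARF")
  if (nrow(harf)) {
    return(list(subgroup = "IId", path = "HARF", nearest = NA_character_,
                identity = NA_real_))
  }
  if (domain$spacer1 == 4L) {
    return(list(subgroup = "IIc", path = "spacer", nearest = NA_character_,
                identity = NA_real_))
  }
  if (!is.null(refs) && nrow(refs)) {
    if (is.null(domain_seq)) {
      domain_seq <- substr(protein_seq, domain$start + 1L, domain$end)
    }
    idents <- vapply(refs$seq, function(r) {
      pairwise_align(domain_seq, r)$identity
    }, numeric(1))
    best <- max(idents)
    cand <- refs$label[idents >= best - 1e-12]
    lab <- sort(cand)[1]
    return(list(subgroup = lab, path = "nearest", nearest = lab,
                identity = best))
  }
  list(subgroup = "none", path = "none", nearest = NA_character_,
       identity = NA_real_)
}

#' Classify a set of proteins end to end
#'
#' Runs [scan_domains()], [assign_group()] and, for group II proteins,
#' [assign_subgroup()] over every sequence.
#'
#' @param seqs named character vector of protein sequences.
#' @param refs optional [reference_set()] for the subgroup layer.
#' @param config a [wrky_scan_config()].
#' @return data.frame with one row per protein: `protein_id`, `group`,
#'   `subgroup`, `n_domains`, `finger_classes` (comma-joined), `spacer1`,
#'   `path`, `nearest_ref`, `identity`.
#' @export
classify_proteins <- function(seqs, refs = NULL,
                              config = wrky_scan_config()) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  rows <- lapply(names(seqs), function(id) {
    dom <- scan_domains(seqs[[id]], config, id)
    call <- assign_group(dom)
    call$protein_id <- id
    sub <- list(subgroup = NA_character_, path = NA_character_,
                nearest = NA_character_, identity = NA_real_)
    if (call$group == "II") {
      sub <- assign_subgroup(dom, seqs[[id]], refs)
    }
    data.frame(protein_id = id, group = call$group,
               subgroup = sub$subgroup,
               n_domains = call$evidence$n_domains,
               finger_classes = paste(call$evidence$finger_classes,
                                      collapse = ","),
               spacer1 = if (is.null(call$evidence$spacer1)) NA_integer_
                         else call$evidence$spacer1,
               path = sub$path,
               nearest_ref = sub$nearest,
               identity = sub$identity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
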