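# Machine-readable catalog of the published grapevine WRKY family.

CATALOG_COLUMNS <- c("name", "source_label", "gi", "chromosome", "length_aa",
                     "pi", "mw_kda", "species", "group", "role",
                     "domain_label", "pattern_string", "flag")

WRKY_GROUPS <- c("I", "IIa", "IIb", "IIc", "IId", "IIe", "III")

#' Path to the packaged grapevine WRKY catalog
#'
#' @return path to the catalog TSV shipped with the package.
#' @export
wrky_catalog_path <- function() {
  system.file("extdata", "vitis_wrky_catalog.tsv", package = "wrkykit",
              mustWork = TRUE)
}

#' Load a WRKY family catalog
#'
#' Reads a tab-separated catalog with one line per WRKY domain. Group I
#' proteins (two WRKY domains) occupy two consecutive lines sharing one
#' `name`, with `role` `NTWD` then `CTWD`; all other groups have a single
#' line with `role` `single`. The packaged catalog reproduces the published
#' grapevine family table: 80 proteins across five Vitis taxa. Validation
#' enforces unique protein names, the role structure above, and that every
#' `pattern_string` parses under the zinc-finger grammar
#' (see [parse_pattern()]); a malformed pattern aborts the load naming the
#' offending row, leaving no partial catalog.
#'
#' @param path catalog TSV; defaults to the packaged grapevine catalog.
#' @return a data.frame of class `wrky_catalog`, one row per domain line,
#'   with columns `name`, `source_label`, `gi`, `chromosome` (integer as
#'   character, or `"unknown"`), `length_aa`, `pi`, `mw_kda`, `species`,
#'   `group`, `role`, `domain_label`, `pattern_string`, `flag`.
#' @export
#' @examples
#' cat <- load_catalog()
#' nrow(catalog_entries(cat))  # 80 proteins
load_catalog <- function(path = wrky_catalog_path()) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          fileEncoding = "UTF-8")
  if (!nrow(df)) stop("empty catalog file: ", path, call. = FALSE)
  missing_cols <- setdiff(CATALOG_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("catalog header lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[CATALOG_COLUMNS]
  df$length_aa <- as.integer(df$length_aa)
  df$pi <- as.numeric(df$pi)
  df$mw_kda <- as.numeric(df$mw_kda)

  # every pattern must parse; report the offending row on failure
  for (i in seq_len(nrow(df))) {
    parsed <- tryCatch(parse_pattern(df$pattern_string[i]), error = identity)
    if (inherits(parsed, "error")) {
      stop(sprintf("row %d (%s): %s", i, df$name[i], conditionMessage(parsed)),
           call. = FALSE)
    }
  }

  # duplicate names: allowed only as the two lines of one group I entry
  per_name <- table(df$name)
  dups <- names(per_name)[per_name > 1L]
  bad <- dups[vapply(dups, function(nm) {
    any(df$group[df$name == nm] != "I") || sum(df$name == nm) != 2L
  }, logical(1))]
  if (length(bad)) {
    stop("duplicate protein name(s) after normalization: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  # role structure per protein
  split_roles <- split(df$role, df$name)
  for (nm in names(split_roles)) {
    roles <- split_roles[[nm]]
    grp <- unique(df$group[df$name == nm])
    if (length(grp) != 1L) {
      stop(sprintf("protein %s: inconsistent group annotation", nm),
           call. = FALSE)
    }
    if (grp == "I") {
      if (!identical(sort(roles), c("CTWD", "NTWD"))) {
        stop(sprintf("group I protein %s must have one NTWD and one CTWD line",
                     nm), call. = FALSE)
      }
    } else {
      if (!identical(roles, "single")) {
        stop(sprintf("protein %s (group %s) must have exactly one 'single' line",
                     nm, grp), call. = FALSE)
      }
    }
  }
  bad_grp <- setdiff(unique(df$group), WRKY_GROUPS)
  if (length(bad_grp)) {
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "),
         call. = FALSE)
  }
  class(df) <- c("wrky_catalog", "data.frame")
  df
}

#' Per-protein view of a catalog
#'
#' Collapses the domain lines to one row per protein (group I entries carry
#' two domain lines but count once).
#'
#' @param catalog a `wrky_catalog`.
#' @return data.frame with one row per protein and a `finger_class` column
#'   (`C2HC` when the single domain's terminal ligand is Cys, else `C2H2`;
#'   group I entries are `C2H2`).
#' @export
catalog_entries <- function(catalog) {
  stopifnot(inherits(catalog, "wrky_catalog"))
  first <- !duplicated(catalog$name)
  ent <- catalog[first, c("name", "source_label", "gi", "chromosome",
                          "length_aa", "pi", "mw_kda", "species", "group",
                          "flag")]
  ent$finger_class <- vapply(ent$name, function(nm) {
    pats <- catalog$pattern_string[catalog$name == nm]
    cls <- vapply(pats, function(p) parse_pattern(p)$class, character(1))
    if (any(cls == "C2HC")) "C2HC" else "C2H2"
  }, character(1))
  rownames(ent) <- NULL
  ent
}

#' Summarize a WRKY catalog
#'
#' Counts proteins per group, chromosome and species, and ranges over the
#' numeric columns. Counts are over proteins, not domain lines, and are
#' invariant to row order. An empty catalog yields an all-zero summary.
#'
#' @param catalog a `wrky_catalog` (or a subset of its rows).
#' @return list of class `wrky_catalog_summary`: `n_total`, `per_group`,
#'   `per_chromosome`, `per_species`, `length_min`, `length_max`, `pi_min`,
#'   `pi_max`.
#' @export
summarize_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "data.frame"))
  if (!nrow(catalog)) {
    return(structure(list(n_total = 0L, per_group = integer(),
                          per_chromosome = integer(), per_species = integer(),
                          length_min = NA_integer_, length_max = NA_integer_,
                          pi_min = NA_real_, pi_max = NA_real_),
                     class = "wrky_catalog_summary"))
  }
  if (!inherits(catalog, "wrky_catalog")) {
    class(catalog) <- c("wrky_catalog", class(catalog))
  }
  ent <- catalog_entries(catalog)
  tab <- function(x) {
    t <- table(x)
    out <- as.integer(t)
    names(out) <- names(t)
    out
  }
  structure(list(
    n_total = nrow(ent),
    per_group = tab(factor(ent$group, levels = WRKY_GROUPS)),
    per_chromosome = tab(ent$chromosome),
    per_species = tab(ent$species),
    length_min = min(ent$length_aa),
    length_max = max(ent$length_aa),
    pi_min = min(ent$pi),
    pi_max = max(ent$pi)
  ), class = "wrky_catalog_summary")
}

#' @export
print.wrky_catalog_summary <- function(x, ...) {
  cat(sprintf("WRKY catalog: %d proteins\n", x$n_total))
  if (x$n_total) {
    cat("  per group: ",
        paste(sprintf("%s=%d", names(x$per_group), x$per_group),
              collapse = ", "), "\n", sep = "")
    cat(sprintf("  length %d-%d aa, pI %.2f-%.2f\n",
                x$length_min, x$length_max, x$pi_min, x$pi_max))
  }
  invisible(x)
}

#' Write a catalog back to TSV
#'
#' Inverse of [load_catalog()]: `load_catalog(write_catalog(cat, f))` yields
#' an identical object.
#'
#' @param catalog a `wrky_catalog`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "wrky_catalog"))
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' qRT-PCR reference-gene primer metadata
#'
#' The elongation-factor EF1-gamma primer pair used as the internal reference
#' in the expression assays, stored as catalog metadata only (never used
#' computationally).
#'
#' @return named list with `gene`, `accession`, `forward`, `reverse`.
#' @export
ef1g_primers <- function() {
  list(gene = "EF1gamma",
       accession = "AF176496",
       forward = "GCGGGCAAGAGATACCTCAA",
       reverse = "TCAATCTGTCTAGGAAAGGAAG")
}
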