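# Synthetic-data generators: proteins with planted domains and motifs,
# mutated domain families, and Ct tables with programmed response designs.
# All generators are pure functions of (specification, seed).

BACKGROUND_AA <- setdiff(AA20, "W")       # no accidental heptapeptides
FILLER_AA <- setdiff(AA20, c("C", "H", "W"))  # unambiguous finger spacers

#' Specification for a synthetic protein
#'
#' Describes a protein of `length` residues with planted elements. A domain
#' element is rendered as heptapeptide + linker + zinc finger realizing the
#' given pattern string; a motif element as a literal instance of the named
#' motif. Planted elements must be non-overlapping and in-bounds.
#'
#' Background residues are drawn uniformly from the 19 amino acids excluding
#' tryptophan, which makes accidental heptapeptide hits impossible (every
#' hit requires the invariant W); spacer fillers inside planted fingers
#' additionally exclude Cys and His so the planted ligand positions are
#' unambiguous. [make_protein()] still post-validates against spurious
#' matches and resamples if needed.
#'
#' @param length total protein length (residues).
#' @param elements list of elements, each either
#'   `list(type = "domain", pattern = "C-X4-C-X23-HXH", hepta = "WRKYGQK",
#'   pos = <0-based start>, linker = 8)` or
#'   `list(type = "motif", name = "HARF"|"LXXLL"|"LXLXLX", pos = <start>)`.
#' @param background residue alphabet for background positions.
#' @param seed RNG seed (the generator is deterministic given the spec).
#' @return list of class `wrky_protein_spec`.
#' @export
protein_spec <- function(length, elements = list(),
                         background = BACKGROUND_AA, seed = 1L) {
  spans <- lapply(elements, element_span)
  for (k in seq_along(spans)) {
    sp <- spans[[k]]
    if (sp[1] < 0L || sp[2] > length) {
      stop(sprintf("element %d exceeds protein bounds [0, %d)", k, length),
           call. = FALSE)
    }
  }
  if (length(spans) > 1L) {
    ord <- order(vapply(spans, `[`, numeric(1), 1L))
    ss <- spans[ord]
    for (k in seq_len(length(ss) - 1L)) {
      if (ss[[k]][2] > ss[[k + 1L]][1]) {
        stop("planted elements overlap", call. = FALSE)
      }
    }
  }
  structure(list(length = as.integer(length), elements = elements,
                 background = background, seed = as.integer(seed)),
            class = "wrky_protein_spec")
}

# [start, end) span of an element, 0-based
element_span <- function(el) {
  if (el$type == "domain") {
    f <- parse_pattern(el$pattern)
    linker <- if (is.null(el$linker)) 8L else as.integer(el$linker)
    len <- 7L + linker + 2L + f$spacer1 + f$spacer2 + 1L + f$spacer3 + 1L
    c(el$pos, el$pos + len)
  } else {
    w <- switch(el$name, LXXLL = 5L, LXLXLX = 6L, HARF = 11L,
                stop("unknown motif: ", el$name, call. = FALSE))
    c(el$pos, el$pos + w)
  }
}

render_element <- function(el) {
  rf <- function(n) if (n > 0L) sample(FILLER_AA, n, replace = TRUE) else character(0)
  if (el$type == "domain") {
    f <- parse_pattern(el$pattern)
    hepta <- if (is.null(el$hepta)) WRKY_HEPTA else toupper(el$hepta)
    stopifnot(nchar(hepta) == 7L)
    linker <- if (is.null(el$linker)) 8L else as.integer(el$linker)
    s3 <- if (is.na(f$intervening)) rf(f$spacer3) else seq_chars(f$intervening)
    c(seq_chars(hepta), rf(linker),
      "C", rf(f$spacer1), "C", rf(f$spacer2), "H", s3, f$terminal)
  } else {
    nl <- setdiff(FILLER_AA, "L")
    switch(el$name,
           HARF = c(seq_chars("RTGHARFRR"), sample(c("A", "G"), 1L), "P"),
           LXXLL = c("L", sample(nl, 2L, replace = TRUE), "L", "L"),
           LXLXLX = c("L", sample(nl, 1L), "L", sample(nl, 1L), "L",
                      sample(nl, 1L)))
  }
}

#' Generate a synthetic protein with planted elements
#'
#' Renders the spec's planted elements at their positions, fills the
#' remaining positions with background residues, and post-validates: the
#' domain scanner run on the product must report exactly the planted
#' domains at their planted coordinates. If validation fails (an accidental
#' grammar match involving background residues), the background is
#' resampled, up to `max_tries` times.
#'
#' @param spec a [protein_spec()].
#' @param config scanner configuration used for post-validation.
#' @param max_tries resampling bound before erroring.
#' @return list: `seq` (protein string), `truth` (data.frame of planted
#'   elements with 0-based `start`, `end`, `type`, `label`).
#' @export
make_protein <- function(spec, config = wrky_scan_config(), max_tries = 50L) {
  stopifnot(inherits(spec, "wrky_protein_spec"))
  with_seed(spec$seed, {
    spans <- lapply(spec$elements, element_span)
    truth <- data.frame(
      type = vapply(spec$elements, `[[`, character(1), "type"),
      label = vapply(spec$elements, function(el) {
        if (el$type == "domain") el$pattern else el$name
      }, character(1)),
      start = vapply(spans, `[`, numeric(1), 1L),
      end = vapply(spans, `[`, numeric(1), 2L),
      stringsAsFactors = FALSE)
    dom_truth <- truth[truth$type == "domain", , drop = FALSE]
    res <- NULL
    for (try in seq_len(max_tries)) {
      chars <- sample(spec$background, spec$length, replace = TRUE)
      for (k in seq_along(spec$elements)) {
        piece <- render_element(spec$elements[[k]])
        chars[(spans[[k]][1] + 1L):spans[[k]][2]] <- piece
      }
      seq <- paste(chars, collapse = "")
      found <- scan_domains(seq, config)
      ok <- nrow(found) == nrow(dom_truth) &&
        (nrow(found) == 0L ||
         (all(found$start == dom_truth$start) &&
          all(found$end == dom_truth$end)))
      if (ok) {
        res <- list(seq = seq, truth = truth)
        break
      }
    }
    if (is.null(res)) {
      stop("could not realize spec without spurious matches after ",
           max_tries, " tries", call. = FALSE)
    }
    res
  })
}

#' Generate labelled families of mutated domain sequences
#'
#' Each family member is its subgroup's seed sequence with i.i.d.
#' substitutions at `mutation_rate`, protected at the heptapeptide and the
#' four zinc-finger ligand positions (located by scanning the seed).
#' Substitutions are drawn from the spacer-filler alphabet (no C/H/W) so
#' mutation never creates or destroys finger ligands or heptapeptides.
#'
#' @param subgroup_seeds named character vector or list, subgroup label ->
#'   seed domain sequence (each seed must contain one scannable domain).
#' @param n_per members per subgroup.
#' @param mutation_rate per-position substitution probability outside the
#'   protected positions.
#' @param seed RNG seed.
#' @param config scanner configuration for locating protected positions.
#' @return list: `seqs` (named character vector, names `<label>_<i>`),
#'   `labels` (data.frame `id`, `label`).
#' @export
make_family <- function(subgroup_seeds, n_per = 5L, mutation_rate = 0.1,
                        seed = 1L, config = wrky_scan_config()) {
  stopifnot(length(subgroup_seeds) >= 1L, !is.null(names(subgroup_seeds)))
  with_seed(seed, {
    seqs <- character(0)
    ids <- character(0)
    labs <- character(0)
    for (lab in names(subgroup_seeds)) {
      sd <- toupper(subgroup_seeds[[lab]])
      dom <- scan_domains(sd, config)
      if (nrow(dom) != 1L) {
        stop(sprintf("seed for %s must contain exactly one domain", lab),
             call. = FALSE)
      }
      protect <- c(dom$hepta_start + 0:6, dom$c1, dom$c2, dom$h1, dom$t) + 1L
      chars0 <- seq_chars(sd)
      for (i in seq_len(n_per)) {
        chars <- chars0
        mutable <- setdiff(seq_along(chars), protect)
        hit <- mutable[stats::runif(length(mutable)) < mutation_rate]
        for (p in hit) {
          chars[p] <- sample(setdiff(FILLER_AA, chars[p]), 1L)
        }
        id <- sprintf("%s_%d", lab, i)
        seqs[id] <- paste(chars, collapse = "")
        ids <- c(ids, id)
        labs <- c(labs, lab)
      }
    }
    list(seqs = seqs,
         labels = data.frame(id = ids, label = labs, stringsAsFactors = FALSE))
  })
}

#' Design for a synthetic qRT-PCR panel
#'
#' Programs an intended response call for each (gene, treatment): induced
#' genes get `fold_induced` at `peak_time`, repressed genes `fold_repressed`,
#' unchanged genes a flat profile. The programmed folds must be consistent
#' with the calling thresholds (`fold_induced >= up_fold`,
#' `fold_repressed <= down_fold`), so the intended calls are recoverable in
#' the noise-free limit.
#'
#' @param calls data.frame with columns `gene`, `treatment`, `call`
#'   (`induced`/`repressed`/`unchanged`).
#' @param timepoints assay timepoints in hours (must include 0).
#' @param fold_induced,fold_repressed programmed peak fold changes.
#' @param peak_time timepoint (h) carrying the programmed fold.
#' @param replicates technical replicates per condition.
#' @param noise_sd Gaussian technical noise on the Ct scale (cycles).
#' @param baseline_target,baseline_ref baseline Ct levels (cycles).
#' @param seed RNG seed.
#' @param up_fold,down_fold thresholds used for the consistency check.
#' @return list of class `wrky_panel_design`.
#' @export
panel_design <- function(calls, timepoints = CT_TIMEPOINTS,
                         fold_induced = 4, fold_repressed = 0.25,
                         peak_time = 24, replicates = 3L, noise_sd = 0.15,
                         baseline_target = 24, baseline_ref = 20,
                         seed = 1L, up_fold = 2.0, down_fold = 0.5) {
  stopifnot(all(c("gene", "treatment", "call") %in% names(calls)),
            all(calls$call %in% c("induced", "repressed", "unchanged")),
            0 %in% timepoints, peak_time %in% timepoints,
            fold_induced > 0, fold_repressed > 0)
  if (fold_induced < up_fold || fold_repressed > down_fold) {
    stop("programmed folds are inconsistent with the calling thresholds",
         call. = FALSE)
  }
  structure(list(calls = calls, timepoints = sort(timepoints),
                 fold_induced = fold_induced,
                 fold_repressed = fold_repressed, peak_time = peak_time,
                 replicates = as.integer(replicates), noise_sd = noise_sd,
                 baseline_target = baseline_target,
                 baseline_ref = baseline_ref, seed = as.integer(seed)),
            class = "wrky_panel_design")
}

#' Generate a Ct table from a panel design
#'
#' Per replicate, `ct_target = baseline_target - log2(fold) + N(0, sd)` and
#' `ct_reference = baseline_ref + N(0, sd)`, where `fold` is the programmed
#' fold change at that timepoint (1 at t = 0 and off-peak). Deterministic
#' for a given design seed.
#'
#' @param design a [panel_design()].
#' @return Ct data.frame as accepted by [relative_quantity()].
#' @export
make_panel_ct <- function(design) {
  stopifnot(inherits(design, "wrky_panel_design"))
  with_seed(design$seed, {
    rows <- list()
    for (k in seq_len(nrow(design$calls))) {
      g <- design$calls$gene[k]
      tr <- design$calls$treatment[k]
      call <- design$calls$call[k]
      for (tp in design$timepoints) {
        fold <- if (tp == design$peak_time) {
          switch(call, induced = design$fold_induced,
                 repressed = design$fold_repressed, unchanged = 1)
        } else 1
        for (r in seq_len(design$replicates)) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene = g, treatment = tr, timepoint_h = tp, replicate = r,
            ct_target = design$baseline_target - log2(fold) +
              stats::rnorm(1, 0, design$noise_sd),
            ct_reference = design$baseline_ref +
              stats::rnorm(1, 0, design$noise_sd),
            stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    validate_ct(out)
    out
  })
}

#' The grapevine defense-response expression panel design
#'
#' The 28-gene qRT-PCR panel assayed under fungal-pathogen infection and
#' salicylic-acid treatment, with the published response categories as
#' intended calls: under pathogen three genes unchanged (VvWRKY48, -51,
#' -45) and two repressed (VvWRKY3, -41), the remaining 23 induced; under
#' SA five genes unchanged (VvWRKY41, -30, -42, -46, -70-1), the remaining
#' 23 induced. The published gene list enumerates 26 names for the 28-gene
#' panel; two additional family members (VvWRKY21, VvWRKY47, both induced
#' under both treatments) are supplemented to honor the stated panel size
#' and the category arithmetic, and are flagged in the output.
#'
#' @return data.frame with columns `gene`, `treatment` (`pathogen`/`SA`),
#'   `call`, `supplemented`.
#' @export
wrky_expression_panel <- function() {
  printed <- c("VvWRKY1-1", "VvWRKY2-1", "VvWRKY3", "VvWRKY6-1", "VvWRKY7-1",
               "VvWRKY11-4", "VvWRKY14", "VvWRKY18", "VvWRKY22-1",
               "VvWRKY28", "VvWRKY30", "VvWRKY32", "VvWRKY40", "VvWRKY41",
               "VvWRKY42", "VvWRKY45", "VvWRKY46", "VvWRKY48", "VvWRKY51",
               "VvWRKY53", "VvWRKY55", "VvWRKY65", "VvWRKY70-1",
               "VvWRKY70-2", "VvWRKY72", "VvWRKY74")
  supplemented <- c("VvWRKY21", "VvWRKY47")
  genes <- c(printed, supplemented)
  pathogen_unchanged <- c("VvWRKY48", "VvWRKY51", "VvWRKY45")
  pathogen_repressed <- c("VvWRKY3", "VvWRKY41")
  sa_unchanged <- c("VvWRKY41", "VvWRKY30", "VvWRKY42", "VvWRKY46",
                    "VvWRKY70-1")
  path_call <- ifelse(genes %in% pathogen_unchanged, "unchanged",
                      ifelse(genes %in% pathogen_repressed, "repressed",
                             "induced"))
  sa_call <- ifelse(genes %in% sa_unchanged, "unchanged", "induced")
  rbind(
    data.frame(gene = genes, treatment = "pathogen", call = path_call,
               supplemented = genes %in% supplemented,
               stringsAsFactors = FALSE),
    data.frame(gene = genes, treatment = "SA", call = sa_call,
               supplemented = genes %in% supplemented,
               stringsAsFactors = FALSE))
}
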