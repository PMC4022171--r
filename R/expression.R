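# qRT-PCR relative quantification (2^-ddCt) and response calling.

CT_TIMEPOINTS <- c(0, 9, 12, 24, 48)

#' Read a Ct table from TSV
#'
#' Expected columns: `gene`, `treatment`, `timepoint_h`, `replicate`,
#' `ct_target`, `ct_reference`.
#'
#' @param path TSV file.
#' @return validated Ct data.frame (see [validate_ct()]).
#' @export
read_ct_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_ct(df)
}

#' Validate a Ct table
#'
#' Checks column presence, Ct ranges (0, 45), and that every
#' (gene, treatment) series carries the t = 0 calibrator.
#'
#' @param ct data.frame with columns `gene`, `treatment`, `timepoint_h`,
#'   `replicate`, `ct_target`, `ct_reference`.
#' @return the input, invisibly classed `wrky_ct`.
#' @export
validate_ct <- function(ct) {
  need <- c("gene", "treatment", "timepoint_h", "replicate", "ct_target",
            "ct_reference")
  missing_cols <- setdiff(need, names(ct))
  if (length(missing_cols)) {
    stop("Ct table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cts <- c(ct$ct_target, ct$ct_reference)
  if (any(!is.finite(cts)) || any(cts <= 0) || any(cts >= 45)) {
    stop("Ct values must lie in (0, 45)", call. = FALSE)
  }
  for (g in unique(ct$gene)) {
    for (tr in unique(ct$treatment[ct$gene == g])) {
      tps <- ct$timepoint_h[ct$gene == g & ct$treatment == tr]
      if (!0 %in% tps) {
        stop(sprintf("missing t=0 calibrator for gene %s, treatment %s",
                     g, tr), call. = FALSE)
      }
    }
  }
  class(ct) <- unique(c("wrky_ct", class(ct)))
  invisible(ct)
}

#' Relative quantities by the 2^-ddCt method
#'
#' Replicate Ct values are averaged on the Ct scale; per condition
#' dCt = mean(Ct_target) - mean(Ct_reference), ddCt = dCt(t) - dCt(0), and
#' rq = 2^-ddCt. The calibrator timepoint has rq = 1 exactly. The result is
#' invariant to adding a constant to every Ct value.
#'
#' @param ct a Ct data.frame (see [validate_ct()]).
#' @return data.frame: `gene`, `treatment`, `timepoint_h`, `delta_ct`,
#'   `rq`.
#' @export
relative_quantity <- function(ct) {
  ct <- validate_ct(as.data.frame(ct))
  key <- interaction(ct$gene, ct$treatment, ct$timepoint_h, drop = TRUE)
  agg <- do.call(rbind, lapply(split(ct, key), function(d) {
    data.frame(gene = d$gene[1], treatment = d$treatment[1],
               timepoint_h = d$timepoint_h[1],
               delta_ct = mean(d$ct_target) - mean(d$ct_reference),
               stringsAsFactors = FALSE)
  }))
  out <- do.call(rbind, lapply(split(agg, list(agg$gene, agg$treatment),
                                     drop = TRUE), function(d) {
    base <- d$delta_ct[d$timepoint_h == 0]
    d$rq <- 2^(-(d$delta_ct - base))
    d$rq[d$timepoint_h == 0] <- 1
    d
  }))
  out <- out[order(out$gene, out$treatment, out$timepoint_h), ]
  rownames(out) <- NULL
  out
}

#' Call a response from a relative-quantity profile
#'
#' Over post-treatment timepoints (t > 0): induced if the maximum rq reaches
#' `up_fold`, repressed if the minimum rq falls to `down_fold`; if both
#' thresholds are crossed the direction with the larger |log2 rq| wins, a
#' tie going to induced; otherwise unchanged.
#'
#' @param rq named numeric vector of relative quantities, names =
#'   timepoints in hours (the t = 0 calibrator may be present and is
#'   ignored).
#' @param up_fold induction threshold (default 2).
#' @param down_fold repression threshold (default 0.5).
#' @return list: `call` (`induced`/`repressed`/`unchanged`),
#'   `trigger_timepoint` (hours, `NA` for unchanged), `max_rq`, `min_rq`.
#' @export
#' @examples
#' call_response(c(`9` = 1.1, `24` = 4.0))$call  # "induced"
call_response <- function(rq, up_fold = 2.0, down_fold = 0.5) {
  stopifnot(is.numeric(rq), !is.null(names(rq)), all(rq > 0))
  tp <- as.numeric(names(rq))
  post <- rq[tp > 0]
  tpp <- tp[tp > 0]
  if (!length(post)) {
    return(list(call = "unchanged", trigger_timepoint = NA_real_,
                max_rq = NA_real_, min_rq = NA_real_))
  }
  up <- max(post) >= up_fold
  down <- min(post) <= down_fold
  call <- if (up && down) {
    if (abs(log2(max(post))) >= abs(log2(min(post)))) "induced" else "repressed"
  } else if (up) "induced" else if (down) "repressed" else "unchanged"
  trigger <- switch(call,
                    induced = tpp[which.max(post)],
                    repressed = tpp[which.min(post)],
                    unchanged = NA_real_)
  list(call = call, trigger_timepoint = trigger,
       max_rq = max(post), min_rq = min(post))
}

#' Response calls for every gene in a Ct table
#'
#' @param ct Ct data.frame (see [validate_ct()]).
#' @param up_fold,down_fold thresholds passed to [call_response()].
#' @return data.frame: `gene`, `treatment`, `call`, `trigger_timepoint`,
#'   `max_rq`, `min_rq`.
#' @export
call_panel <- function(ct, up_fold = 2.0, down_fold = 0.5) {
  rq <- relative_quantity(ct)
  out <- do.call(rbind, lapply(split(rq, list(rq$gene, rq$treatment),
                                     drop = TRUE), function(d) {
    v <- stats::setNames(d$rq, d$timepoint_h)
    cr <- call_response(v, up_fold, down_fold)
    data.frame(gene = d$gene[1], treatment = d$treatment[1],
               call = cr$call, trigger_timepoint = cr$trigger_timepoint,
               max_rq = cr$max_rq, min_rq = cr$min_rq,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$gene, out$treatment), ]
  rownames(out) <- NULL
  out
}

#' Summarize response calls across two treatments
#'
#' Exact set algebra over the per-treatment calls: category counts per
#' treatment, the number of genes with altered (non-unchanged) expression,
#' and the intersection of the induced sets. Genes with calls under only one
#' treatment are counted in that treatment but excluded from the
#' intersection (with a message).
#'
#' @param calls_a,calls_b data.frames from [call_panel()] (one treatment
#'   each), e.g. pathogen and salicylic acid.
#' @param panel character vector of panel gene names; calls outside the
#'   panel are ignored.
#' @return list of class `wrky_panel_summary`: `n_assayed`, per-treatment
#'   counts (`n_induced`, `n_repressed`, `n_unchanged`, `n_altered`),
#'   `n_both_induced`, and gene lists per category.
#' @export
summarize_panel <- function(calls_a, calls_b, panel) {
  pick <- function(calls) calls[calls$gene %in% panel, , drop = FALSE]
  a <- pick(calls_a); b <- pick(calls_b)
  only_one <- union(setdiff(a$gene, b$gene), setdiff(b$gene, a$gene))
  if (length(only_one)) {
    message("gene(s) with calls under a single treatment excluded from the ",
            "intersection: ", paste(only_one, collapse = ", "))
  }
  cat_counts <- function(d) {
    list(n_induced = sum(d$call == "induced"),
         n_repressed = sum(d$call == "repressed"),
         n_unchanged = sum(d$call == "unchanged"),
         n_altered = sum(d$call != "unchanged"),
         induced = sort(d$gene[d$call == "induced"]),
         repressed = sort(d$gene[d$call == "repressed"]),
         unchanged = sort(d$gene[d$call == "unchanged"]))
  }
  ca <- cat_counts(a); cb <- cat_counts(b)
  both <- sort(intersect(setdiff(ca$induced, only_one),
                         setdiff(cb$induced, only_one)))
  structure(list(n_assayed = length(panel),
                 treatment_a = ca, treatment_b = cb,
                 n_both_induced = length(both), both_induced = both),
            class = "wrky_panel_summary")
}

#' @export
print.wrky_panel_summary <- function(x, ...) {
  cat(sprintf("panel of %d genes\n", x$n_assayed))
  f <- function(lbl, cc) {
    cat(sprintf("  %s: %d induced, %d repressed, %d unchanged (%d altered)\n",
                lbl, cc$n_induced, cc$n_repressed, cc$n_unchanged,
                cc$n_altered))
  }
  f("treatment A", x$treatment_a)
  f("treatment B", x$treatment_b)
  cat(sprintf("  induced under both: %d\n", x$n_both_induced))
  invisible(x)
}
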