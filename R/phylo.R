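# Distance-based phylogenetics for WRKY domain sequences: global affine-gap
# alignment, p-distances, neighbor joining, column-resampling bootstrap,
# newick serialization.

#' BLOSUM62 substitution matrix
#' @noRd
blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Global pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch with affine gaps: a gap of length k costs
#' `gap_open + k * gap_extend`. The traceback is deterministic: on ties it
#' prefers a match/mismatch step, then a gap in `a`, then a gap in `b`.
#'
#' @param a,b protein strings (non-empty).
#' @param substitution substitution matrix (residues x residues); defaults to
#'   BLOSUM62 as shipped with Biostrings.
#' @param gap_open,gap_extend positive gap penalties.
#' @return list of class `wrky_alignment`: `aligned_a`, `aligned_b` (equal
#'   length, `-` for gaps), `score`, `identity` (matches / alignment
#'   columns).
#' @export
pairwise_align <- function(a, b, substitution = NULL,
                           gap_open = 10, gap_extend = 0.5) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  S <- if (is.null(substitution)) blosum62() else substitution
  av <- check_protein(a)
  bv <- check_protein(b)
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  # state 1 = M (a_i ~ b_j), 2 = gap in a (consumes b_j), 3 = gap in b
  M <- matrix(NEG, n + 1L, m + 1L)
  GA <- matrix(NEG, n + 1L, m + 1L)  # gap in a
  GB <- matrix(NEG, n + 1L, m + 1L)  # gap in b
  ptM <- matrix(0L, n + 1L, m + 1L)
  ptA <- matrix(0L, n + 1L, m + 1L)
  ptB <- matrix(0L, n + 1L, m + 1L)
  M[1, 1] <- 0
  if (m >= 1L) {
    GA[1, 2:(m + 1L)] <- -gap_open - gap_extend * (1:m)
    ptA[1, 2:(m + 1L)] <- 2L
  }
  if (n >= 1L) {
    GB[2:(n + 1L), 1] <- -gap_open - gap_extend * (1:n)
    ptB[2:(n + 1L), 1] <- 3L
  }
  sub <- S[av, bv, drop = FALSE]
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      # M from any state at (i-1, j-1); tie preference M > GA > GB
      best <- M[i - 1L, j - 1L]; from <- 1L
      if (GA[i - 1L, j - 1L] > best) { best <- GA[i - 1L, j - 1L]; from <- 2L }
      if (GB[i - 1L, j - 1L] > best) { best <- GB[i - 1L, j - 1L]; from <- 3L }
      M[i, j] <- best + sub[i - 1L, j - 1L]
      ptM[i, j] <- from
      # GA: gap in a, consumes b_j; open from M, extend from GA
      openA <- M[i, j - 1L] - gap_open - gap_extend
      extA <- GA[i, j - 1L] - gap_extend
      if (openA >= extA) { GA[i, j] <- openA; ptA[i, j] <- 1L }
      else { GA[i, j] <- extA; ptA[i, j] <- 2L }
      # GB: gap in b, consumes a_i
      openB <- M[i - 1L, j] - gap_open - gap_extend
      extB <- GB[i - 1L, j] - gap_extend
      if (openB >= extB) { GB[i, j] <- openB; ptB[i, j] <- 1L }
      else { GB[i, j] <- extB; ptB[i, j] <- 3L }
    }
  }
  fin <- c(M[n + 1L, m + 1L], GA[n + 1L, m + 1L], GB[n + 1L, m + 1L])
  state <- which.max(fin)  # ties resolve to M > GA > GB
  score <- fin[state]
  # traceback
  ra <- character(0); rb <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    if (state == 1L) {
      ra <- c(av[i - 1L], ra); rb <- c(bv[j - 1L], rb)
      state <- ptM[i, j]; i <- i - 1L; j <- j - 1L
    } else if (state == 2L) {
      ra <- c("-", ra); rb <- c(bv[j - 1L], rb)
      state <- ptA[i, j]; j <- j - 1L
    } else {
      ra <- c(av[i - 1L], ra); rb <- c("-", rb)
      state <- ptB[i, j]; i <- i - 1L
    }
  }
  aligned_a <- paste(ra, collapse = "")
  aligned_b <- paste(rb, collapse = "")
  structure(list(aligned_a = aligned_a, aligned_b = aligned_b,
                 score = score,
                 identity = mean(ra == rb & ra != "-")),
            class = "wrky_alignment")
}

#' @export
print.wrky_alignment <- function(x, ...) {
  cat(x$aligned_a, "\n", x$aligned_b, "\n", sep = "")
  cat(sprintf("score %.1f, identity %.3f\n", x$score, x$identity))
  invisible(x)
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Mismatches divided by compared columns; columns containing a gap in
#' either sequence are excluded (pairwise deletion). If no column is
#' comparable the distance is defined as 1.
#'
#' @param x a `wrky_alignment`, or an aligned string (then `y` required).
#' @param y second aligned string of equal length.
#' @return distance in [0, 1].
#' @export
p_distance <- function(x, y = NULL) {
  if (inherits(x, "wrky_alignment")) {
    a <- x$aligned_a; b <- x$aligned_b
  } else {
    a <- x; b <- y
  }
  stopifnot(nchar(a) == nchar(b))
  av <- seq_chars(a); bv <- seq_chars(b)
  comp <- av != "-" & bv != "-"
  if (!any(comp)) return(1)
  mean(av[comp] != bv[comp])
}

#' Pairwise p-distance matrix from unaligned sequences
#'
#' Aligns every pair globally ([pairwise_align()]) and records the
#' p-distance of each pairwise alignment.
#'
#' @param seqs named character vector (>= 2 sequences).
#' @param ... passed to [pairwise_align()].
#' @return symmetric matrix with zero diagonal, dimnames = sequence names.
#' @export
distance_matrix <- function(seqs, ...) {
  stopifnot(is.character(seqs), length(seqs) >= 2L, !is.null(names(seqs)))
  ids <- names(seqs)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- pairwise_align(seqs[[i]], seqs[[j]], ...)
      d[i, j] <- d[j, i] <- p_distance(al)
    }
  }
  d
}

# ---- tree structure -------------------------------------------------------

new_leaf <- function(label, length = NA_real_) {
  list(label = label, length = length, children = NULL, support = NA_real_)
}

new_internal <- function(children, lengths, support = NA_real_) {
  for (k in seq_along(children)) children[[k]]$length <- unname(lengths[k])
  list(label = NULL, length = NA_real_, children = children,
       support = support)
}

tree_leaves <- function(node) {
  if (is.null(node$children)) return(node$label)
  unlist(lapply(node$children, tree_leaves))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. When several
#' pairs minimize Q, the pair whose (lexicographically smallest member,
#' then second member) sorts first is joined, which makes the tree a
#' deterministic function of the matrix. Negative branch lengths are clamped
#' to zero (with a message). The result is an unrooted tree represented with
#' a basal trifurcation.
#'
#' @param D symmetric distance matrix with dimnames (n >= 3 taxa).
#' @return object of class `wrky_tree`.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  ids <- rownames(D)
  if (is.null(ids) || nrow(D) < 3L) {
    stop("neighbor joining needs a labelled matrix with at least 3 taxa",
         call. = FALSE)
  }
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric",
                                      call. = FALSE)
  clamped <- FALSE
  clamp <- function(x) {
    if (any(x < 0)) clamped <<- TRUE
    pmax(x, 0)
  }
  nodes <- lapply(ids, new_leaf)
  reps <- ids                      # lexicographic representative per cluster
  d <- D
  while (length(nodes) > 3L) {
    n <- length(nodes)
    r <- rowSums(d)
    # Q matrix; pick min with deterministic tie-break
    best <- NULL
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        q <- (n - 2) * d[i, j] - r[i] - r[j]
        pr <- sort(c(reps[i], reps[j]))
        cand <- list(q = q, i = i, j = j, pr = pr)
        if (is.null(best) || q < best$q - 1e-12 ||
            (abs(q - best$q) <= 1e-12 &&
             (pr[1] < best$pr[1] ||
              (pr[1] == best$pr[1] && pr[2] < best$pr[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- d[i, j] - li
    lens <- clamp(c(li, lj))
    merged <- new_internal(list(nodes[[i]], nodes[[j]]), lens)
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], list(merged))
    reps <- c(reps[keep], min(best$pr))
    dimnames(d2) <- list(c(reps), c(reps))
    d <- d2
  }
  # final three-way join, three-point formulas
  dab <- d[1, 2]; dac <- d[1, 3]; dbc <- d[2, 3]
  la <- (dab + dac - dbc) / 2
  lb <- (dab + dbc - dac) / 2
  lc <- (dac + dbc - dab) / 2
  root <- new_internal(nodes, clamp(c(la, lb, lc)))
  if (clamped) message("negative branch length(s) clamped to 0")
  structure(list(root = root, ids = sort(ids), n_boot = NA_integer_),
            class = "wrky_tree")
}

#' @export
print.wrky_tree <- function(x, ...) {
  cat(sprintf("<unrooted NJ tree, %d leaves%s>\n", length(x$ids),
              if (!is.na(x$n_boot)) sprintf(", bootstrap n=%d", x$n_boot)
              else ""))
  cat(to_newick(x), "\n")
  invisible(x)
}

#' Internal bipartitions of a tree
#'
#' One canonical key per internal (non-root) edge. A bipartition is encoded
#' as the sorted, comma-joined leaf set of the side that does not contain
#' the alphabetically first leaf of the whole tree.
#'
#' @param tree a `wrky_tree`.
#' @return character vector of bipartition keys (possibly empty).
#' @export
tree_bipartitions <- function(tree) {
  all_ids <- tree$ids
  anchor <- all_ids[1]
  keys <- character(0)
  walk <- function(node) {
    if (is.null(node$children)) return(invisible())
    for (ch in node$children) {
      if (!is.null(ch$children)) {
        below <- sort(tree_leaves(ch))
        side <- if (anchor %in% below) sort(setdiff(all_ids, below)) else below
        if (length(side) >= 2L && length(side) <= length(all_ids) - 2L) {
          keys <<- c(keys, paste(side, collapse = ","))
        }
        walk(ch)
      }
    }
  }
  walk(tree$root)
  unique(keys)
}

#' Branch lengths of a tree
#'
#' @param tree a `wrky_tree`.
#' @return numeric vector of all branch lengths (unordered).
#' @export
tree_edge_lengths <- function(tree) {
  out <- numeric(0)
  walk <- function(node) {
    for (ch in node$children) {
      out <<- c(out, ch$length)
      if (!is.null(ch$children)) walk(ch)
    }
  }
  walk(tree$root)
  out
}

#' Bootstrap supports of a tree's internal nodes
#'
#' @param tree a `wrky_tree` produced by [bootstrap_support()].
#' @return integer vector of support counts (one per internal non-root
#'   node), possibly empty.
#' @export
tree_supports <- function(tree) {
  out <- numeric(0)
  walk <- function(node) {
    for (ch in node$children) {
      if (!is.null(ch$children)) {
        if (!is.na(ch$support)) out <<- c(out, ch$support)
        walk(ch)
      }
    }
  }
  walk(tree$root)
  out
}

#' Bootstrap support for an NJ tree from an alignment
#'
#' Builds the reference tree by neighbor joining on the p-distance matrix of
#' the alignment, then resamples alignment columns with replacement `n_boot`
#' times; each replicate's NJ tree votes for the internal bipartitions of
#' the reference tree. Supports are counts out of `n_boot`, attached to the
#' internal nodes. With the same `seed` the output is identical.
#'
#' @param msa named character vector of equal-length aligned sequences
#'   (>= 3 taxa, >= 1 column).
#' @param n_boot number of replicates (default 1000).
#' @param seed optional RNG seed; the caller's RNG state is preserved.
#' @return a `wrky_tree` with per-internal-node `support` and `n_boot` set.
#' @export
bootstrap_support <- function(msa, n_boot = 1000L, seed = NULL) {
  stopifnot(is.character(msa), length(msa) >= 3L, !is.null(names(msa)))
  L <- unique(nchar(msa))
  if (length(L) != 1L || L < 1L) stop("msa sequences must share one length >= 1",
                                      call. = FALSE)
  ids <- names(msa)
  n <- length(ids)
  chars <- do.call(rbind, lapply(msa, seq_chars))  # n x L
  pair_i <- integer(0); pair_j <- integer(0)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pair_i <- c(pair_i, i); pair_j <- c(pair_j, j)
  }
  # per-column mismatch / comparability, pairs x L
  mism <- (chars[pair_i, , drop = FALSE] != chars[pair_j, , drop = FALSE]) &
    chars[pair_i, , drop = FALSE] != "-" & chars[pair_j, , drop = FALSE] != "-"
  comp <- chars[pair_i, , drop = FALSE] != "-" &
    chars[pair_j, , drop = FALSE] != "-"
  dist_from_cols <- function(cols) {
    mm <- rowSums(mism[, cols, drop = FALSE])
    cc <- rowSums(comp[, cols, drop = FALSE])
    dv <- ifelse(cc > 0, mm / cc, 1)
    d <- matrix(0, n, n, dimnames = list(ids, ids))
    d[cbind(pair_i, pair_j)] <- dv
    d[cbind(pair_j, pair_i)] <- dv
    d
  }
  ref <- neighbor_joining(dist_from_cols(seq_len(L)))
  ref_splits <- tree_bipartitions(ref)
  counts <- stats::setNames(integer(length(ref_splits)), ref_splits)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_tree <- suppressMessages(neighbor_joining(dist_from_cols(cols)))
      hits <- intersect(tree_bipartitions(rep_tree), ref_splits)
      counts[hits] <- counts[hits] + 1L
    }
  })
  # attach supports to the reference tree's internal nodes
  all_ids <- ref$ids
  anchor <- all_ids[1]
  annotate <- function(node) {
    if (is.null(node$children)) return(node)
    node$children <- lapply(node$children, function(ch) {
      if (!is.null(ch$children)) {
        below <- sort(tree_leaves(ch))
        side <- if (anchor %in% below) sort(setdiff(all_ids, below)) else below
        key <- paste(side, collapse = ",")
        if (key %in% names(counts)) ch$support <- counts[[key]]
      }
      annotate(ch)
    })
    node
  }
  ref$root <- annotate(ref$root)
  ref$n_boot <- as.integer(n_boot)
  ref
}

#' Serialize a tree to newick
#'
#' Internal node labels carry bootstrap support counts when present. The
#' inverse for round-trip checks is [parse_newick()].
#'
#' @param tree a `wrky_tree`.
#' @param digits branch-length digits.
#' @return single newick string terminated by `;`.
#' @export
to_newick <- function(tree, digits = 10) {
  fmt_len <- function(x) {
    if (is.na(x)) "" else paste0(":", sprintf("%.*g", digits, x))
  }
  render <- function(node) {
    if (is.null(node$children)) {
      return(paste0(node$label, fmt_len(node$length)))
    }
    inner <- paste(vapply(node$children, render, character(1)),
                   collapse = ",")
    sup <- if (!is.na(node$support)) formatC(node$support, format = "d") else ""
    paste0("(", inner, ")", sup, fmt_len(node$length))
  }
  paste0(render(tree$root), ";")
}

#' Parse a newick string into an ape phylogeny
#'
#' Standard-format parsing is delegated to [ape::read.tree()]; a malformed
#' string raises an error.
#'
#' @param s newick string.
#' @return an [ape::phylo] object.
#' @export
parse_newick <- function(s) {
  tr <- tryCatch(ape::read.tree(text = s), error = identity,
                 warning = identity)
  if (inherits(tr, "condition") || is.null(tr)) {
    stop("malformed newick string", call. = FALSE)
  }
  tr
}

#' Convert a `wrky_tree` to an `ape::phylo`
#'
#' @param x a `wrky_tree`.
#' @param ... unused.
#' @return an [ape::phylo] object (node labels carry supports if present).
#' @export
as_phylo <- function(x, ...) {
  stopifnot(inherits(x, "wrky_tree"))
  parse_newick(to_newick(x))
}

# ---- progressive multiple alignment --------------------------------------

profile_columns <- function(aligned) {
  do.call(rbind, lapply(aligned, seq_chars))
}

# average substitution score between two profile columns; gaps score
# `gap_res` against residues and 0 against gaps.
profile_col_score <- function(colA, colB, S, gap_res = -4) {
  tot <- 0
  for (a in colA) {
    for (b in colB) {
      tot <- tot + if (a == "-" && b == "-") 0
      else if (a == "-" || b == "-") gap_res
      else S[a, b]
    }
  }
  tot / (length(colA) * length(colB))
}

align_profiles <- function(profA, profB, S, gap_open = 10, gap_extend = 0.5) {
  n <- ncol(profA); m <- ncol(profB)
  score <- matrix(0, n + 1L, m + 1L)
  pt <- matrix(0L, n + 1L, m + 1L)
  sub <- matrix(0, n, m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub[i, j] <- profile_col_score(profA[, i], profB[, j], S)
    }
  }
  # linear per-column gap cost at profile level, amortizing the affine
  # penalty over a typical short gap
  g <- (gap_open + 2 * gap_extend) / 2
  score[1, ] <- -g * (0:m)
  score[, 1] <- -g * (0:n)
  pt[1, -1] <- 2L; pt[-1, 1] <- 3L
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      diag <- score[i - 1L, j - 1L] + sub[i - 1L, j - 1L]
      up <- score[i - 1L, j] - g
      left <- score[i, j - 1L] - g
      best <- max(diag, left, up)
      score[i, j] <- best
      pt[i, j] <- if (diag == best) 1L else if (left == best) 2L else 3L
    }
  }
  i <- n + 1L; j <- m + 1L
  colsA <- integer(0); colsB <- integer(0)  # 0 = gap column
  while (i > 1L || j > 1L) {
    p <- pt[i, j]
    if (p == 1L) { colsA <- c(i - 1L, colsA); colsB <- c(j - 1L, colsB)
                   i <- i - 1L; j <- j - 1L }
    else if (p == 2L) { colsA <- c(0L, colsA); colsB <- c(j - 1L, colsB)
                        j <- j - 1L }
    else { colsA <- c(i - 1L, colsA); colsB <- c(0L, colsB); i <- i - 1L }
  }
  expand <- function(prof, cols) {
    out <- matrix("-", nrow(prof), length(cols))
    nz <- cols > 0L
    out[, nz] <- prof[, cols[nz], drop = FALSE]
    rownames(out) <- rownames(prof)
    out
  }
  rbind(expand(profA, colsA), expand(profB, colsB))
}

#' Progressive multiple sequence alignment
#'
#' A small progressive aligner for sets of homologous WRKY domains: a
#' neighbor-joining guide tree is built from pairwise p-distances, then
#' profiles are merged bottom-up with a profile-profile Needleman-Wunsch
#' using average BLOSUM62 column scores. Intended for the domain-sized
#' sequences this package works with, not for genome-scale alignment.
#'
#' @param seqs named character vector (>= 2).
#' @param gap_open,gap_extend gap penalties (shared with the pairwise step).
#' @return named character vector of equal-length aligned sequences.
#' @export
progressive_msa <- function(seqs, gap_open = 10, gap_extend = 0.5) {
  stopifnot(is.character(seqs), length(seqs) >= 2L, !is.null(names(seqs)))
  S <- blosum62()
  if (length(seqs) == 2L) {
    al <- pairwise_align(seqs[[1]], seqs[[2]], gap_open = gap_open,
                         gap_extend = gap_extend)
    out <- c(al$aligned_a, al$aligned_b)
    names(out) <- names(seqs)
    return(out)
  }
  D <- distance_matrix(seqs, gap_open = gap_open, gap_extend = gap_extend)
  guide <- neighbor_joining(D)
  merge_node <- function(node) {
    if (is.null(node$children)) {
      prof <- matrix(seq_chars(seqs[[node$label]]), nrow = 1L)
      rownames(prof) <- node$label
      return(prof)
    }
    profs <- lapply(node$children, merge_node)
    acc <- profs[[1]]
    for (k in 2:length(profs)) {
      acc <- align_profiles(acc, profs[[k]], S, gap_open, gap_extend)
    }
    acc
  }
  prof <- merge_node(guide$root)
  out <- apply(prof, 1L, paste, collapse = "")
  out[names(seqs)]
}
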