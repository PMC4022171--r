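# Independent brute-force oracles used across tests. Written naively and
# separately from the package implementations on purpose.

# exhaustive Hamming window scan for the heptapeptide
oracle_hepta <- function(seq, max_mismatch = 1, require_w = TRUE) {
  chars <- strsplit(seq, "")[[1]]
  hep <- strsplit("WRKYGQK", "")[[1]]
  hits <- list()
  n <- length(chars)
  if (n >= 7) {
    for (i in 1:(n - 6)) {
      win <- chars[i:(i + 6)]
      mm <- sum(win != hep)
      if (mm <= max_mismatch && (!require_w || win[1] == "W")) {
        hits[[length(hits) + 1]] <- data.frame(
          start = i - 1L, observed = paste(win, collapse = ""),
          mismatches = as.integer(mm), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), observed = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

# exhaustive enumeration of the leftmost zinc finger from a position,
# mirroring the documented preference order but via full enumeration
oracle_finger <- function(seq, from_pos, s1r = c(4, 8), s2r = c(22, 28),
                          s3r = c(1, 2), window = 30) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  cands <- list()
  for (c1 in from_pos:min(n - 1, from_pos + window - 1)) {
    if (chars[c1 + 1] != "C") next
    for (s1 in s1r[1]:s1r[2]) {
      c2 <- c1 + 1 + s1
      if (c2 + 1 > n || chars[c2 + 1] != "C") next
      for (s2 in s2r[1]:s2r[2]) {
        h1 <- c2 + 1 + s2
        if (h1 + 1 > n || chars[h1 + 1] != "H") next
        for (s3 in s3r[1]:s3r[2]) {
          t <- h1 + 1 + s3
          if (t + 1 > n) next
          if (chars[t + 1] %in% c("H", "C")) {
            cands[[length(cands) + 1]] <- c(c1, s1, s2, s3, t)
          }
        }
      }
    }
  }
  if (!length(cands)) return(NULL)
  m <- do.call(rbind, cands)
  ord <- order(m[, 1], m[, 2], m[, 3], m[, 4])
  m[ord[1], ]
}

# full brute-force domain scan: every heptapeptide window paired with its
# leftmost finger, span-filtered, then nested-domain removal
oracle_domains <- function(seq, max_mismatch = 1, window = 30,
                           max_span = 80) {
  heps <- oracle_hepta(seq, max_mismatch)
  out <- list()
  n <- nchar(seq)
  if (nrow(heps)) {
    for (i in seq_len(nrow(heps))) {
      h0 <- heps$start[i]
      if (h0 + 7 >= n) next
      f <- oracle_finger(seq, h0 + 7, window = window)
      if (is.null(f)) next
      end <- f[5] + 1
      if (end - h0 > max_span) next
      out[[length(out) + 1]] <- data.frame(start = h0, end = end,
                                           stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer()))
  }
  d <- do.call(rbind, out)
  d <- d[order(d$start, d$end), , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    for (j in seq_len(nrow(d))) {
      if (i != j && keep[j] && d$start[j] <= d$start[i] &&
          d$end[i] <= d$end[j] &&
          (d$end[j] - d$start[j]) > (d$end[i] - d$start[i])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  d <- d[keep, , drop = FALSE]
  rownames(d) <- NULL
  d
}

# exhaustive global alignment score by recursion over all alignments,
# affine gaps costing open + k * extend
oracle_nw_score <- function(a, b, S, open = 10, extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    # state: 0 none/match, 1 gap-in-a run, 2 gap-in-b run
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, S[av[i], bv[j]] + rec(i + 1, j + 1, 0))
    }
    if (j <= length(bv)) {
      cost <- if (state == 1) extend else open + extend
      best <- max(best, -cost + rec(i, j + 1, 1))
    }
    if (i <= length(av)) {
      cost <- if (state == 2) extend else open + extend
      best <- max(best, -cost + rec(i + 1, j, 2))
    }
    best
  }
  rec(1, 1, 0)
}

# random protein of length n over an alphabet
random_protein <- function(n, alphabet = c("A", "C", "D", "E", "F", "G", "H",
                                           "I", "K", "L", "M", "N", "P", "Q",
                                           "R", "S", "T", "V", "W", "Y")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# seed domain sequence generator used by classifier/phylo tests
mk_seed_domain <- function(pattern, seed, length = 60, pos = 2) {
  sp <- protein_spec(length,
                     list(list(type = "domain", pattern = pattern,
                               pos = pos)),
                     seed = seed)
  make_protein(sp)$seq
}
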