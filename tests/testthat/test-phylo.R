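test_that("self-alignment is gapless with identity 1", {
  al <- pairwise_align("WRKYGQKDEK", "WRKYGQKDEK")
  expect_equal(al$aligned_a, "WRKYGQKDEK")
  expect_equal(al$identity, 1.0)
  expect_error(pairwise_align("", "A"), "empty")
})

test_that("alignment score is symmetric and matches brute force on short pairs", {
  S <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  set.seed(17)
  for (rep in 1:15) {
    a <- random_protein(sample(2:6, 1))
    b <- random_protein(sample(2:6, 1))
    f <- pairwise_align(a, b)
    r <- pairwise_align(b, a)
    expect_equal(f$score, r$score)
    expect_equal(f$score, oracle_nw_score(a, b, S), tolerance = 1e-9)
    # reported alignment is consistent with the reported score
    av <- strsplit(f$aligned_a, "")[[1]]
    bv <- strsplit(f$aligned_b, "")[[1]]
    sc <- 0; run <- 0
    for (k in seq_along(av)) {
      if (av[k] == "-" || bv[k] == "-") {
        sc <- sc - (if (run > 0) 0.5 else 10.5)
        run <- run + 1
      } else {
        sc <- sc + S[av[k], bv[k]]
        run <- 0
      }
    }
    expect_equal(sc, f$score, tolerance = 1e-9)
  }
})

test_that("p-distance counts mismatches over gap-free columns", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "CCCC"), 1)
  # 10 columns, 2 gap-containing, 3 mismatches among the 8 compared
  expect_equal(p_distance("ACDEFGHIK-", "ACDQFGYV-V"), 3 / 8)
  expect_equal(p_distance("--", "AA"), 1)  # nothing comparable
})

test_that("three-taxon NJ uses the closed-form three-point lengths", {
  D <- matrix(c(0, 3, 5, 3, 0, 4, 5, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  ph <- as_phylo(tr)
  len <- stats::setNames(ph$edge.length,
                         ph$tip.label[ph$edge[, 2]])
  expect_equal(unname(len["A"]), (3 + 5 - 4) / 2)
  expect_equal(unname(len["B"]), (3 + 4 - 5) / 2)
  expect_equal(unname(len["C"]), (5 + 4 - 3) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers an additive four-taxon tree exactly", {
  # tree ((A:1,B:2):1,C:3,D:1) with the AB|CD internal edge of length 1
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 3
  D["B", "C"] <- 6; D["B", "D"] <- 4; D["C", "D"] <- 4
  D <- D + t(D)
  tr <- neighbor_joining(D)
  expect_equal(tree_bipartitions(tr), "C,D")
  ph <- as_phylo(tr)
  # leaf branch lengths
  tip_len <- stats::setNames(ph$edge.length[match(seq_along(ph$tip.label),
                                                  ph$edge[, 2])],
                             ph$tip.label)
  expect_equal(unname(tip_len[c("A", "B", "C", "D")]), c(1, 2, 3, 1))
  # internal edge length
  internal <- ph$edge[, 2] > length(ph$tip.label)
  expect_equal(ph$edge.length[internal], 1)
})

test_that("NJ topology is invariant to input permutation and matches ape", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    ref <- ape::rtree(n, rooted = FALSE)
    D <- ape::cophenetic.phylo(ref)
    ids <- rownames(D)
    tr <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(as_phylo(tr)), ref), 0)
    perm <- sample(ids)
    tr2 <- neighbor_joining(D[perm, perm])
    expect_equal(phangorn::RF.dist(as_phylo(tr), as_phylo(tr2)), 0)
    # independent implementation agrees on topology
    expect_equal(phangorn::RF.dist(as_phylo(tr), ape::unroot(ape::nj(D))), 0)
  }
})

test_that("newick serialization round-trips topology, lengths and supports", {
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- 3; D["A", "C"] <- 5; D["A", "D"] <- 3
  D["B", "C"] <- 6; D["B", "D"] <- 4; D["C", "D"] <- 4
  D <- D + t(D)
  tr <- neighbor_joining(D)
  ph <- parse_newick(to_newick(tr))
  expect_setequal(ph$tip.label, LETTERS[1:4])
  expect_equal(sort(ph$edge.length), c(1, 1, 1, 2, 3))
  expect_error(parse_newick("((A,B,C"), "malformed")
  # random trees round trip through the ape parser with lengths preserved
  set.seed(27)
  for (rep in 1:10) {
    ref <- ape::rtree(6, rooted = FALSE)
    D2 <- ape::cophenetic.phylo(ref)
    t2 <- neighbor_joining(D2)
    ph2 <- parse_newick(to_newick(t2))
    expect_equal(sort(ph2$edge.length), sort(tree_edge_lengths(t2)),
                 tolerance = 1e-9)
  }
})

test_that("bootstrap gives full support on variance-free signal and is seeded", {
  block <- function(ch, n) strrep(ch, n)
  msa <- c(A = paste0(block("A", 10), block("A", 10)),
           B = paste0(block("A", 10), block("C", 10)),
           C = paste0(block("G", 10), block("G", 10)),
           D = paste0(block("G", 10), block("T", 10)),
           E = paste0(block("T", 10), block("T", 10)))
  b1 <- bootstrap_support(msa, n_boot = 200, seed = 77)
  b2 <- bootstrap_support(msa, n_boot = 200, seed = 77)
  expect_identical(to_newick(b1), to_newick(b2))
  b3 <- bootstrap_support(msa, n_boot = 200, seed = 78)
  expect_false(identical(to_newick(b1), to_newick(b3)))
  # duplicated-column alignment: every resample gives the same distances
  dup <- c(A = strrep("A", 8), B = strrep("A", 8),
           C = strrep("C", 8), D = strrep("D", 8))
  bd <- bootstrap_support(dup, n_boot = 50, seed = 1)
  sups <- tree_supports(bd)
  expect_true(all(sups == 50))
})

test_that("bootstrap does not perturb the caller's RNG stream", {
  msa <- c(A = "AAAA", B = "AACC", C = "CCCC", D = "CCGG")
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(bootstrap_support(msa, n_boot = 10, seed = 5))
  after <- runif(1)
  expect_identical(before, after)
})

test_that("progressive MSA preserves pairwise identity within tolerance", {
  seeds <- c(IIa = mk_seed_domain("C-X5-C-X23-HXH", 301),
             IIb = mk_seed_domain("C-X5-C-X24-HXH", 302))
  fam <- make_family(seeds, n_per = 3, mutation_rate = 0.08, seed = 9)
  msa <- progressive_msa(fam$seqs)
  expect_equal(length(unique(nchar(msa))), 1L)
  expect_setequal(names(msa), names(fam$seqs))
  # de-gapped rows reproduce the inputs
  for (id in names(fam$seqs)) {
    expect_equal(gsub("-", "", msa[[id]]), unname(fam$seqs[[id]]))
  }
  ids <- names(fam$seqs)
  for (i in 1:(length(ids) - 1)) {
    for (j in (i + 1):length(ids)) {
      pw <- pairwise_align(fam$seqs[[ids[i]]], fam$seqs[[ids[j]]])$identity
      av <- strsplit(msa[[ids[i]]], "")[[1]]
      bv <- strsplit(msa[[ids[j]]], "")[[1]]
      msa_ident <- mean(av == bv & av != "-")
      expect_gte(msa_ident, pw - 0.1)
    }
  }
})
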