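test_that("heptapeptide scan finds canonical and single-mismatch variants", {
  exact <- scan_heptapeptide("WRKYGQK", max_mismatch = 0)
  expect_equal(exact$start, 0L)
  expect_equal(exact$mismatches, 0L)
  var <- scan_heptapeptide("AAWRKYGKKAA", max_mismatch = 1)
  expect_equal(var$start, 2L)
  expect_equal(var$observed, "WRKYGKK")
  expect_equal(var$mismatches, 1L)
  # the invariant tryptophan is required by default but can be relaxed
  expect_equal(nrow(scan_heptapeptide("ARKYGQK", max_mismatch = 1)), 0L)
  expect_equal(nrow(scan_heptapeptide("ARKYGQK", max_mismatch = 1,
                                      require_w = FALSE)), 1L)
  expect_error(scan_heptapeptide("WRKYG1K"), "position 6")
})

test_that("heptapeptide scan agrees with the exhaustive window oracle", {
  set.seed(42)
  for (rep in 1:25) {
    seq <- random_protein(200)
    for (mm in 0:2) {
      got <- scan_heptapeptide(seq, max_mismatch = mm)
      want <- oracle_hepta(seq, max_mismatch = mm)
      expect_equal(got$start, want$start)
      expect_equal(got$observed, want$observed)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
})

test_that("pattern strings parse and format per the catalog convention", {
  f <- parse_pattern("C-X4-C-X23-HXH")
  expect_equal(c(f$spacer1, f$spacer2, f$spacer3), c(4L, 23L, 1L))
  expect_equal(f$terminal, "H")
  expect_equal(f$class, "C2H2")
  g <- parse_pattern("C-X7-C-X23-HTC")
  expect_equal(c(g$spacer1, g$spacer2, g$spacer3), c(7L, 23L, 1L))
  expect_equal(g$terminal, "C")
  expect_equal(g$intervening, "T")
  expect_equal(g$class, "C2HC")
  # subscript markup is tolerated
  expect_equal(parse_pattern("C-X_4_-C-X_23_-HXH"), f)
  expect_error(parse_pattern("C-X4-H23"), "grammar")
  expect_error(parse_pattern(""), "empty")
})

test_that("format/parse round-trip holds on catalog strings and random specs", {
  cat. <- load_catalog()
  for (s in unique(cat.$pattern_string)) {
    expect_equal(format_pattern(parse_pattern(s)), s)
  }
  set.seed(7)
  for (i in 1:50) {
    term <- sample(c("H", "C"), 1)
    s3 <- sample(1:2, 1)
    iv <- if (term == "C") {
      paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), s3,
                   replace = TRUE), collapse = "")
    } else NA_character_
    spec <- zinc_finger_spec(sample(4:8, 1), sample(22:28, 1), s3, term, iv)
    back <- parse_pattern(format_pattern(spec))
    expect_equal(back$spacer1, spec$spacer1)
    expect_equal(back$spacer2, spec$spacer2)
    expect_equal(back$spacer3, spec$spacer3)
    expect_equal(back$terminal, spec$terminal)
    if (term == "C") expect_equal(back$intervening, spec$intervening)
  }
})

test_that("zinc finger search honors the grammar and preference order", {
  s1 <- paste0("C", strrep("A", 4), "C", strrep("A", 23), "HAH")
  z1 <- find_zinc_finger(s1, 0)
  expect_equal(z1$spec$spacer1, 4L)
  expect_equal(z1$spec$spacer2, 23L)
  expect_equal(z1$spec$terminal, "H")
  s2 <- paste0("C", strrep("A", 7), "C", strrep("A", 23), "HTC")
  z2 <- find_zinc_finger(s2, 0)
  expect_equal(z2$spec$class, "C2HC")
  expect_equal(z2$spec$intervening, "T")
  expect_equal(z2$positions, c(0L, 8L, 32L, 34L))
  expect_null(find_zinc_finger(strrep("A", 60), 0))
  # a leading Cys too far from any partner cannot open a finger; the scan
  # moves on to the next viable first-Cys position
  s3 <- paste0("C", strrep("A", 9), s1)
  z3 <- find_zinc_finger(s3, 0)
  expect_equal(z3$positions[1], 10L)
})

test_that("planted domains are recovered exactly, decoys are not", {
  sp <- protein_spec(260, list(
    list(type = "domain", pattern = "C-X4-C-X22-HXH", pos = 15),
    list(type = "domain", pattern = "C-X4-C-X23-HXH", pos = 140)),
    seed = 11)
  p <- make_protein(sp)
  dom <- scan_domains(p$seq)
  expect_equal(nrow(dom), 2L)
  expect_equal(dom$start, p$truth$start[p$truth$type == "domain"])
  expect_equal(dom$end, p$truth$end[p$truth$type == "domain"])
  expect_equal(dom$pattern, c("C-X4-C-X22-HXH", "C-X4-C-X23-HXH"))
  expect_true(all(diff(dom$start) > 0))
  # heptapeptide with no downstream finger yields nothing
  decoy <- paste0(strrep("A", 10), "WRKYGQK", strrep("A", 50))
  expect_equal(nrow(scan_domains(decoy)), 0L)
})

test_that("domain scan agrees with brute-force enumeration on random input", {
  set.seed(99)
  alph <- c("A", "C", "D", "E", "G", "H", "K", "W", "R", "Y", "Q")
  for (rep in 1:40) {
    # W-rich alphabet provokes heptapeptide-like windows and C/H structure
    seq <- random_protein(sample(50:300, 1), alphabet = alph)
    got <- scan_domains(seq)
    want <- oracle_domains(seq)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("scan_fasta maps over records and preserves ids", {
  sp <- protein_spec(120, list(
    list(type = "domain", pattern = "C-X5-C-X23-HXH", pos = 20)), seed = 3)
  p <- make_protein(sp)
  tmp <- tempfile(fileext = ".fa")
  write_fasta(c(one = p$seq, two = strrep("A", 50)), tmp)
  res <- scan_fasta(tmp)
  expect_equal(unique(res$protein_id), "one")
  expect_equal(nrow(res), 1L)
  ds <- domain_sequences(c(one = p$seq), res)
  expect_equal(nchar(ds[[1]]), res$end - res$start)
  expect_match(ds[[1]], "^WRKYGQK")
})
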