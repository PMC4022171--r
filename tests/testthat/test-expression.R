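make_ct <- function(rows) {
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene = r[["gene"]], treatment = r[["treatment"]],
               timepoint_h = as.numeric(r[["tp"]]), replicate = 1L,
               ct_target = as.numeric(r[["ct"]]),
               ct_reference = as.numeric(r[["ref"]]),
               stringsAsFactors = FALSE)
  }))
}

flat_ct <- function(gene = "g1", treatment = "pathogen", ct = 24, ref = 20) {
  make_ct(lapply(c(0, 9, 12, 24, 48), function(tp) {
    list(gene = gene, treatment = treatment, tp = tp, ct = ct, ref = ref)
  }))
}

test_that("relative quantity obeys the ddCt closed forms", {
  # flat Cts -> rq = 1 everywhere
  rq <- relative_quantity(flat_ct())
  expect_equal(rq$rq, rep(1, 5), tolerance = 1e-12)
  # target drops one cycle at 24 h, reference flat -> rq(24) = 2
  ct <- flat_ct()
  ct$ct_target[ct$timepoint_h == 24] <- 23
  rq <- relative_quantity(ct)
  expect_equal(rq$rq[rq$timepoint_h == 24], 2, tolerance = 1e-9)
  # reference and target both drop one cycle -> normalization cancels
  ct2 <- flat_ct()
  ct2$ct_target[ct2$timepoint_h == 24] <- 23
  ct2$ct_reference[ct2$timepoint_h == 24] <- 19
  rq2 <- relative_quantity(ct2)
  expect_equal(rq2$rq[rq2$timepoint_h == 24], 1, tolerance = 1e-9)
})

test_that("rq is invariant to adding a constant to every Ct", {
  set.seed(3)
  ct <- flat_ct()
  ct$ct_target <- ct$ct_target + rnorm(5)
  shifted <- ct
  shifted$ct_target <- shifted$ct_target + 3.7
  shifted$ct_reference <- shifted$ct_reference + 3.7
  expect_equal(relative_quantity(ct)$rq, relative_quantity(shifted)$rq,
               tolerance = 1e-9)
})

test_that("missing calibrator or bad Ct values are rejected with names", {
  ct <- flat_ct()
  ct <- ct[ct$timepoint_h != 0, ]
  expect_error(relative_quantity(ct), "g1.*pathogen")
  bad <- flat_ct()
  bad$ct_target[1] <- 50
  expect_error(validate_ct(bad), "\\(0, 45\\)")
})

test_that("response calls follow the fold-change thresholds", {
  expect_equal(call_response(c(`9` = 1.1, `12` = 0.9, `24` = 1.0,
                               `48` = 1.0))$call, "unchanged")
  r <- call_response(c(`9` = 1.0, `12` = 1.1, `24` = 4.0, `48` = 1.2))
  expect_equal(r$call, "induced")
  expect_equal(r$trigger_timepoint, 24)
  r2 <- call_response(c(`9` = 1.0, `12` = 0.25, `24` = 1.0, `48` = 0.9))
  expect_equal(r2$call, "repressed")
  expect_equal(r2$trigger_timepoint, 12)
  # both thresholds crossed: larger |log2 rq| wins, ties go to induced
  expect_equal(call_response(c(`9` = 8, `24` = 0.4))$call, "induced")
  expect_equal(call_response(c(`9` = 2.2, `24` = 0.1))$call, "repressed")
  expect_equal(call_response(c(`9` = 4, `24` = 0.25))$call, "induced")
  # thresholds are configurable
  expect_equal(call_response(c(`24` = 1.8), up_fold = 1.5)$call, "induced")
})

test_that("panel summary reproduces the published category arithmetic", {
  design <- panel_design(wrky_expression_panel(), seed = 50)
  ct <- make_panel_ct(design)
  calls <- call_panel(ct)
  panel <- unique(design$calls$gene)
  expect_length(panel, 28L)
  ps <- summarize_panel(calls[calls$treatment == "pathogen", ],
                        calls[calls$treatment == "SA", ], panel)
  expect_equal(ps$n_assayed, 28L)
  expect_equal(ps$treatment_a$n_altered, 25L)
  expect_equal(ps$treatment_a$n_induced, 23L)
  expect_equal(ps$treatment_a$n_repressed, 2L)
  expect_equal(ps$treatment_a$n_unchanged, 3L)
  expect_setequal(ps$treatment_a$unchanged,
                  c("VvWRKY48", "VvWRKY51", "VvWRKY45"))
  expect_setequal(ps$treatment_a$repressed, c("VvWRKY3", "VvWRKY41"))
  expect_equal(ps$treatment_b$n_induced, 23L)
  expect_equal(ps$treatment_b$n_unchanged, 5L)
  # arithmetic identity: categories partition the panel
  expect_equal(ps$treatment_a$n_induced + ps$treatment_a$n_repressed +
                 ps$treatment_a$n_unchanged, ps$n_assayed)
  expect_lte(ps$n_both_induced, min(ps$treatment_a$n_induced,
                                    ps$treatment_b$n_induced))
})

test_that("panel summary is permutation-invariant and handles edge cases", {
  design <- panel_design(wrky_expression_panel(), seed = 51)
  calls <- call_panel(make_panel_ct(design))
  a <- calls[calls$treatment == "pathogen", ]
  b <- calls[calls$treatment == "SA", ]
  panel <- unique(design$calls$gene)
  s1 <- summarize_panel(a, b, panel)
  s2 <- summarize_panel(a[sample(nrow(a)), ], b[sample(nrow(b)), ], panel)
  expect_equal(s1$n_both_induced, s2$n_both_induced)
  expect_equal(s1$treatment_a$induced, s2$treatment_a$induced)
  # empty panel -> all-zero summary
  s0 <- summarize_panel(a, b, character(0))
  expect_equal(s0$n_assayed, 0L)
  expect_equal(s0$n_both_induced, 0L)
  # gene assayed under one treatment only: counted there, not intersected
  expect_message(
    s3 <- summarize_panel(a, b[b$gene != "VvWRKY14", ], panel),
    "VvWRKY14")
  expect_false("VvWRKY14" %in% s3$both_induced)
  expect_equal(s3$treatment_a$n_induced, 23L)
})

test_that("Ct tables round-trip through TSV", {
  ct <- flat_ct()
  tmp <- tempfile(fileext = ".tsv")
  utils::write.table(ct, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  again <- read_ct_table(tmp)
  expect_equal(as.data.frame(again), ct, ignore_attr = TRUE)
})
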