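test_that("primary hit calls use inclusive thresholds by default", {
  scores <- c(A = -1.6, B = -1.5, C = 2.8, D = 0)
  ht <- call_primary_hits(scores)
  calls <- setNames(ht$call, ht$gene_symbol)
  expect_equal(unname(calls[c("A", "B")]), rep("positive_regulator", 2))
  expect_equal(unname(calls["C"]), "negative_regulator")
  expect_equal(unname(calls["D"]), "none")
  # strict deposit-style boundaries drop the exact-threshold genes
  hts <- call_primary_hits(scores, strict_boundaries = TRUE)
  calls_s <- setNames(hts$call, hts$gene_symbol)
  expect_equal(unname(calls_s["B"]), "none")
  expect_equal(unname(calls_s["C"]), "none")
  expect_equal(unname(calls_s["A"]), "positive_regulator")
})

test_that("hit calling is threshold-monotone and excludes listed genes", {
  set.seed(1)
  scores <- setNames(rnorm(200, sd = 2), sprintf("G%03d", 1:200))
  strict_pos <- call_primary_hits(scores, theta_pos = -2)
  loose_pos <- call_primary_hits(scores, theta_pos = -1.5)
  p1 <- strict_pos$gene_symbol[strict_pos$call == "positive_regulator"]
  p2 <- loose_pos$gene_symbol[loose_pos$call == "positive_regulator"]
  expect_true(all(p1 %in% p2))
  # all-zero scores, no exclusions -> zero hits
  ht0 <- call_primary_hits(setNames(rep(0, 5), letters[1:5]))
  expect_equal(unname(attr(ht0, "counts")[c("positive", "negative")]),
               c(0L, 0L))
  # exclusion list flags, does not call
  ht <- call_primary_hits(c(TLR4 = -2.3, NOVEL1 = -2.0),
                          exclusions = canonical_tlr4_genes())
  expect_equal(ht$call[ht$gene_symbol == "TLR4"], "none")
  expect_equal(ht$excluded_reason[ht$gene_symbol == "TLR4"], "canonical_pathway")
  expect_equal(ht$call[ht$gene_symbol == "NOVEL1"], "positive_regulator")
})

test_that("expression filter keeps p<0.1 in at least one condition, strictly", {
  expr <- structure(
    data.frame(gene_symbol = c("A", "B", "C"),
               log2_unstim = 8, log2_lps = 8,
               p_unstim = c(0.05, 0.10, 0.5), p_lps = c(0.5, 0.10, 0.5)),
    class = c("expression_table", "data.frame"))
  hits <- call_primary_hits(c(A = -2, B = -2, C = -2, D = -2))
  filt <- suppressWarnings(expression_filter(hits, expr))
  st <- setNames(filt$call, filt$gene_symbol)
  expect_equal(unname(st["A"]), "positive_regulator")     # p = (0.05, 0.5)
  expect_equal(unname(st["B"]), "none")                   # p = (0.10, 0.10): strict
  expect_equal(unname(st["C"]), "none")                   # p = (0.5, 0.5)
  expect_equal(filt$excluded_reason[filt$gene_symbol == "B"], "not_expressed")
  # unmeasured genes pass through with a warning flag
  expect_warning(f2 <- expression_filter(hits, expr),
                 class = "dualscreen_unmeasured_gene")
  expect_equal(f2$call[f2$gene_symbol == "D"], "positive_regulator")
  expect_equal(attr(f2, "unmeasured"), "D")
})

test_that("secondary candidate selection is rank-based with deterministic ties", {
  gs <- data.frame(gene_symbol = c("A", "B", "C", "D", "E"),
                   median_z = c(-2, -1, 0, 1, 2))
  cand <- select_secondary_candidates(gs, n_pos = 2, n_neg = 1)
  expect_equal(sort(cand$positive), c("A", "B"))
  expect_equal(cand$negative, "E")
  expect_equal(select_secondary_candidates(gs, n_pos = 0, n_neg = 1)$positive,
               character(0))
  expect_error(select_secondary_candidates(gs, n_pos = 4, n_neg = 2),
               class = "dualscreen_selection_error")
  # exclusions applied before ranking; list sizes preserved
  gs2 <- rbind(gs, data.frame(gene_symbol = c("PSMA1", "PSMB2"),
                              median_z = c(-5, -4)))
  cand2 <- select_secondary_candidates(gs2, n_pos = 2, n_neg = 1,
                                       exclusions = c("PSMA1", "PSMB2"))
  expect_equal(sort(cand2$positive), c("A", "B"))
  expect_equal(length(cand2$positive), 2L)
  # tie at the cut: support count, then lexicographic symbol
  gs3 <- data.frame(gene_symbol = c("ZZ", "AA", "MM"),
                    median_z = c(-1, -1, -1))
  sir <- data.frame(gene_symbol = rep(c("ZZ", "AA", "MM"), each = 6),
                    zscore = c(rep(-2, 4), 0, 0,   # ZZ: 4 supporting
                               rep(-2, 2), rep(0, 4),  # AA: 2
                               rep(-2, 2), rep(0, 4))) # MM: 2
  cand3 <- select_secondary_candidates(gs3, n_pos = 2, n_neg = 0,
                                       sirna_scores = sir)
  expect_equal(cand3$positive, c("ZZ", "AA"))
})

test_that("tertiary classification confirms via non-reference stimuli only", {
  readouts <- data.frame(
    gene_symbol = rep(c("G1", "G2", "G3"), each = 3),
    stimulus = rep(c("LPS", "P3C", "PGN"), 3),
    value = c(0.5, 0.65, 0.9,    # G1: P3C reduction 35% -> confirmed
              1.0, 1.0, 1.0,     # G2: no effect
              0.4, 0.75, 1.3))   # G3: P3C 25% (not >30), PGN +30% increase
  ntc <- data.frame(stimulus = c("LPS", "P3C", "PGN"), value = 1)
  res <- tertiary_classify(readouts, ntc)
  g <- function(x, col) res[[col]][res$gene_symbol == x]
  expect_true(g("G1", "confirmed_positive"))
  expect_equal(g("G1", "supporting_stimuli_pos"), "P3C")
  expect_false(g("G2", "confirmed_positive") || g("G2", "confirmed_negative"))
  expect_false(g("G3", "confirmed_positive"))  # 25% reduction is not >30%
  expect_true(g("G3", "confirmed_negative"))   # +30% increase is >25%
  # the reference ligand never confirms on its own
  r2 <- data.frame(gene_symbol = "G9", stimulus = c("LPS", "P3C"),
                   value = c(0.2, 1.0))
  expect_false(tertiary_classify(r2, ntc)$confirmed_positive)
})

test_that("tertiary handles degenerate controls and missing stimuli", {
  readouts <- data.frame(gene_symbol = "G1", stimulus = c("LPS", "P3C", "PGN"),
                         value = c(0.5, 0.6, 0.6))
  expect_error(tertiary_classify(readouts,
                                 data.frame(stimulus = c("LPS", "P3C", "PGN"),
                                            value = c(1, 0, 1))),
               class = "dualscreen_qc_error")
  expect_warning(
    res <- tertiary_classify(readouts,
                             data.frame(stimulus = c("LPS", "P3C"), value = 1)),
    class = "dualscreen_missing_control")
  expect_true(is.na(res$F_PGN) || !("F_PGN" %in% names(res)))
  expect_true(res$confirmed_positive)
  expect_error(
    suppressWarnings(tertiary_classify(
      data.frame(gene_symbol = "G1", stimulus = "LPS", value = 0.5),
      data.frame(stimulus = "LPS", value = 1))),
    class = "dualscreen_qc_error")
})

# Independent piecewise oracle for the deposit activity-score bins, coded
# from the bin definitions, scalar if/else only.
oracle_activity <- function(z, tier) {
  if (tier == "primary") {
    if (z > 5 || z < -2.5) 100
    else if (z > 4 || z < -2) 75
    else if (z > 2.8 || z < -1.5) 50
    else if (z > 1 || z < -1) 25
    else 0
  } else {
    if (z > 2.5 || z < -2) 100
    else if (z > 2 || z < -1.5) 75
    else if (z > 1.5 || z < -1) 50
    else if (z > 1 || z < -0.75) 25
    else 0
  }
}

test_that("activity-score binning matches the piecewise oracle exhaustively", {
  boundaries <- c(-2.5, -2, -1.5, -1, -0.75, 1, 1.5, 2, 2.5, 2.8, 4, 5)
  grid <- c(seq(-6, 6, length.out = 10000), boundaries,
            boundaries - 1e-9, boundaries + 1e-9)
  for (tier in c("primary", "secondary")) {
    got <- activity_score(grid, tier = tier)$activity_score
    want <- vapply(grid, oracle_activity, numeric(1), tier = tier)
    expect_identical(got, want)
  }
})

test_that("activity-score worked examples and outcome rule", {
  # a z equal to the strongest printed receptor-complex score
  a <- activity_score(-2.3, tier = "primary")
  expect_equal(a$activity_score, 75)
  expect_equal(a$outcome, 2)
  expect_equal(activity_score(0, "primary")$activity_score, 0)
  expect_equal(activity_score(0, "primary")$outcome, 1)
  # boundary: z = 2.8 exactly fails the strict > 2.8 bin, lands in 25
  expect_equal(activity_score(2.8, "primary")$activity_score, 25)
  expect_equal(activity_score(-1.5, "primary")$activity_score, 25)
  # secondary tier has its own bounds
  expect_equal(activity_score(-0.8, "secondary")$activity_score, 25)
  expect_equal(activity_score(-0.8, "primary")$activity_score, 0)
  # control wells: score 0, outcome 4, regardless of z
  ctl <- activity_score(c(-9, 9), "primary", control = TRUE)
  expect_equal(ctl$activity_score, c(0, 0))
  expect_equal(ctl$outcome, c(4, 4))
  # monotone non-decreasing in |z| within each tail
  zs <- seq(0, 6, by = 0.01)
  expect_false(is.unsorted(activity_score(zs, "primary")$activity_score))
  expect_false(is.unsorted(activity_score(-zs, "primary")$activity_score))
})

test_that("gene lists read one symbol per line with comments", {
  f <- tempfile()
  writeLines(c("# proteasome", "PSMA1", "", "PSMB2 "), f)
  expect_equal(read_gene_list(f), c("PSMA1", "PSMB2"))
})
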