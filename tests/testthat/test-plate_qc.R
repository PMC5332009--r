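test_that("fold induction is the stimulated/unstimulated NTC ratio of means", {
  ds <- tiny_primary_dataset(ntc_stim = c(6, 6, 6), ntc_unstim = c(1, 1, 1))
  expect_equal(fold_induction(ds, "P1"), 6.0)
  ds2 <- tiny_primary_dataset(ntc_stim = c(2, 2, 2), ntc_unstim = c(2, 2, 2))
  expect_equal(fold_induction(ds2, "P1"), 1.0)
  # missing unstimulated NTC wells -> QC-not-computable
  rec <- tiny_primary_records()
  rec <- rec[!(rec$well_anno == "NTC" & rec$stimulus == "none"), ]
  expect_error(fold_induction(screen_dataset(rec, "primary"), "P1"),
               class = "dualscreen_qc_error")
})

test_that("knockdown efficiency compares unstimulated renilla channels", {
  ds <- tiny_primary_dataset(renilla_r2 = c(50, 50, 50))  # NTC r2 = 1000
  expect_equal(knockdown_efficiency(ds, "P1"), 0.95)
  ds0 <- tiny_primary_dataset(renilla_r2 = c(1000, 1000, 1000))
  expect_equal(knockdown_efficiency(ds0, "P1"), 0.0)
})

test_that("positive-control reduction compares stimulated reporter ratios", {
  ds <- tiny_primary_dataset(ntc_stim = c(6, 6, 6), tlr4_stim = c(0.6, 0.6, 0.6))
  expect_equal(positive_control_reduction(ds, "P1"), 0.90)
  ds0 <- tiny_primary_dataset(tlr4_stim = c(6, 6, 6))
  expect_equal(positive_control_reduction(ds0, "P1"), 0.0)
})

test_that("plate acceptance resolves all four gates with boundary behavior", {
  ds <- tiny_primary_dataset()
  qc <- plate_acceptance(ds)
  expect_true(qc$passed)
  expect_equal(qc$failed_criteria, "")
  # fold induction 4.9 fails gate 1 only
  ds49 <- tiny_primary_dataset(ntc_stim = c(4.9, 4.9, 4.9))
  qc49 <- plate_acceptance(ds49)
  expect_false(qc49$passed)
  expect_match(qc49$failed_criteria, "fold induction")
  expect_false(grepl("renilla knockdown|reduction|saturation", qc49$failed_criteria))
  # exact 5-fold passes (inclusive gate)
  expect_true(plate_acceptance(tiny_primary_dataset(ntc_stim = c(5, 5, 5)))$passed)
  # renilla saturation in a single well fails gate 4
  rec <- tiny_primary_records()
  rec$r2[1] <- 2^21 - 1
  rec$r1[1] <- rec$r2[1]  # keep ratio sane
  qcs <- plate_acceptance(screen_dataset(rec, "primary"))
  expect_false(qcs$passed)
  expect_match(qcs$failed_criteria, "saturation")
})

test_that("plate pass/fail is monotone in each criterion", {
  # improving the single failing criterion flips fail -> pass and never the reverse
  ds49 <- tiny_primary_dataset(ntc_stim = c(4.9, 4.9, 4.9))
  expect_false(plate_acceptance(ds49)$passed)
  for (f in c(5.0, 6, 20)) {
    expect_true(plate_acceptance(tiny_primary_dataset(ntc_stim = rep(f, 3)))$passed)
  }
  # worsening one criterion on a passing plate never improves another
  ds_bad_kd <- tiny_primary_dataset(renilla_r2 = c(400, 400, 400))  # kd = 0.6
  qc <- plate_acceptance(ds_bad_kd)
  expect_false(qc$passed)
  expect_match(qc$failed_criteria, "renilla knockdown")
  expect_false(grepl("fold induction", qc$failed_criteria))
})

test_that("uniformity variation matches hand computation and the <20% rule", {
  expect_equal(uniformity_variation(c(100, 110, 100, 100)),
               10 / 102.5 * 100)
  expect_equal(uniformity_variation(c(100, 110, 100, 100)), 9.7561, tolerance = 1e-4)
  expect_equal(uniformity_variation(c(7, 7, 7, 7)), 0)
  # scale invariance (mean-relative), translation sensitivity
  g <- c(100, 110, 100, 100)
  expect_equal(uniformity_variation(g * 3.7), uniformity_variation(g))
  expect_false(isTRUE(all.equal(uniformity_variation(g + 500),
                                uniformity_variation(g))))
})

test_that("uniformity plates pass under the null and carry the staggered dose pattern", {
  u <- generate_uniformity_plates(sim_config(seed = 5, noise_cv = 0.10))
  ut <- uniformity_test(u$dataset, u$dose_map)
  expect_equal(nrow(ut), 9L)  # 3 plates x 3 doses
  expect_true(all(ut$variation < 20))
  expect_true(all(ut$pass))
  # column dose sequence: H,H,M,M,L,L repeating; plate 2 starts M, plate 3 L
  dm <- u$dose_map
  col1 <- function(p) dm$dose[dm$plate_id == p & grepl("^A", dm$well)][1]
  first_cols <- function(p) {
    d <- dm[dm$plate_id == p, ]
    pw <- parse_well(d$well)
    vapply(1:6, function(cc) unique(d$dose[pw$col == cc]), character(1))
  }
  expect_equal(first_cols("U1"), c("H", "H", "M", "M", "L", "L"))
  expect_equal(first_cols("U2")[1], "M")
  expect_equal(first_cols("U3")[1], "L")
})

test_that("a planted 35% column gradient fails at least one dose", {
  u <- generate_uniformity_plates(sim_config(seed = 6, edge_gradient = 0.35))
  ut <- uniformity_test(u$dataset, u$dose_map, grouping = "column_block")
  expect_true(any(!ut$pass))
})

test_that("replicate CV matches hand computation and is 0 without noise", {
  ds <- tiny_primary_dataset(sample_ratios = list(GA = c(1, 2, 3, 4),
                                                  GB = c(2, 2, 2, 2),
                                                  GC = c(1, 1, 1, 1)))
  cv <- replicate_cv(ds)
  ga <- cv$pools$cv[cv$pools$sirna_id == "POOL_GA"]
  expect_equal(ga, sd(1:4) / 2.5)
  expect_equal(ga, 0.5164, tolerance = 1e-4)
  expect_equal(cv$pools$cv[cv$pools$sirna_id == "POOL_GB"], 0)
  # noise-free generator output has exactly zero CV
  sim0 <- generate_primary_screen(sim_config(n_genes = 16, seed = 1, noise_cv = 0,
                                             viability_cv = 0, plate_factor_sd = 0))
  expect_equal(replicate_cv(sim0$dataset)$screen_mean, 0)
})

test_that("replicate correlation is 1 on noise-free replicates and symmetric", {
  genes <- sprintf("G%02d", 1:16)
  cfg0 <- sim_config(seed = 2, noise_cv = 0, viability_cv = 0,
                     plate_factor_sd = 0, frac_pos = 0.3, frac_neg = 0.2)
  sec0 <- generate_secondary_screen(cfg0, genes)
  cc0 <- replicate_correlation(sec0$dataset)
  expect_equal(unname(cc0), matrix(1, 3, 3))
  # anti-monotone construction: negate one replicate's log values -> -1
  rec <- sec0$dataset$records
  i2 <- rec$replicate == 2 & rec$well_anno == "sample"
  v <- log2(rec$r1[i2] / rec$r2[i2])
  rec$r1[i2] <- rec$r2[i2] * 2^(-v)
  cc <- replicate_correlation(screen_dataset(rec, "secondary"), normalized = FALSE)
  expect_equal(cc["rep1", "rep2"], -1, tolerance = 1e-6)
  # noisy case: symmetric with unit diagonal
  sec <- generate_secondary_screen(sim_config(seed = 2, frac_pos = 0.3), genes)
  cc2 <- replicate_correlation(sec$dataset)
  expect_equal(cc2, t(cc2))
  expect_equal(unname(diag(cc2)), rep(1, 3))
})

test_that("QC report writes a CSV row per plate plus a text summary", {
  sim <- generate_primary_screen(sim_config(n_genes = 160, seed = 8))
  qc <- plate_acceptance(sim$dataset)
  f <- tempfile(fileext = ".csv")
  write_qc_report(qc, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(qc))
  expect_true(file.exists(sub("\\.csv$", ".txt", f)))
})
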