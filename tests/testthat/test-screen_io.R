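test_that("well coordinates parse and out-of-range coordinates are rejected", {
  pw <- parse_well(c("A1", "p24", "H07"))
  expect_equal(pw$well, c("A1", "P24", "H7"))
  expect_equal(pw$row, c(1L, 16L, 8L))
  expect_equal(pw$col, c(1L, 24L, 7L))
  expect_error(parse_well("Q25"), class = "dualscreen_record_error")
  expect_error(parse_well("A0"), class = "dualscreen_record_error")
  expect_error(parse_well("AA3"), class = "dualscreen_record_error")
})

test_that("an 8-well fixture round-trips byte-identically", {
  fix <- write_fixture_csv()
  ds <- read_screen_table(fix, tier = "primary")
  expect_s3_class(ds, "screen_dataset")
  expect_equal(nrow(ds$records), 8L)
  expect_equal(sum(ds$records$well_anno == "sample"), 4L)
  out <- tempfile(fileext = ".csv")
  write_screen_table(ds, out)
  expect_identical(readLines(out), readLines(fix))
  # write -> read -> write is a fixed point on generated data too
  sim <- generate_primary_screen(sim_config(n_genes = 4, seed = 5))
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_screen_table(sim$dataset, f1)
  write_screen_table(read_screen_table(f1, tier = "primary"), f2)
  expect_identical(readLines(f2), readLines(f1))
})

test_that("reader reports schema, record and integrity errors precisely", {
  fix <- write_fixture_csv()
  lines <- readLines(fix)
  # missing mandatory column
  broken <- sub("siRNAID,", "Reagent,", lines)
  f <- tempfile(); writeLines(broken, f)
  expect_error(read_screen_table(f, "primary"), "siRNAID",
               class = "dualscreen_schema_error")
  # unparseable well coordinate
  broken <- sub("P1,A2", "P1,Q25", lines)
  writeLines(broken, f)
  expect_error(read_screen_table(f, "primary"), "Q25",
               class = "dualscreen_record_error")
  # duplicate (plate, well, replicate)
  writeLines(c(lines, lines[2]), f)
  expect_error(read_screen_table(f, "primary"),
               class = "dualscreen_integrity_error")
})

test_that("control vocabulary normalization is case-insensitive and noLPS-aware", {
  fix <- write_fixture_csv()
  lines <- readLines(fix)
  lines <- sub("NTC,LPS", "ntc5,LPS", lines)
  lines <- sub("NTC,none", "NTC5_noLPS,LPS", lines)
  lines <- sub("siRenilla,none", "RENILLA,none", lines)
  f <- tempfile(); writeLines(lines, f)
  ds <- read_screen_table(f, "primary")
  expect_equal(sum(ds$records$well_anno == "NTC"), 2L)
  expect_equal(sum(ds$records$well_anno == "NTC" & !ds$records$stimulated), 1L)
  expect_equal(sum(ds$records$well_anno == "siRenilla"), 1L)
})

test_that("wide replicate readout columns pivot to one record per replicate", {
  f <- tempfile(fileext = ".csv")
  writeLines(c(
    "PlateID,Well,GeneSymbol,EntrezID,siRNAID,WellAnno,Rep1R1,Rep1R2,Rep2R1,Rep2R2,Rep3R1,Rep3R2",
    "S1,C3,GA,101,s1,sample,100,50,110,55,90,45",
    "S1,D3,GB,102,s2,sample,200,50,210,55,190,45"), f)
  ds <- read_screen_table(f, tier = "secondary")
  expect_equal(nrow(ds$records), 6L)
  expect_equal(sort(unique(ds$records$replicate)), 1:3)
  expect_equal(ds$records$r1[ds$records$well == "C3" & ds$records$replicate == 2], 110)
})

test_that("U+2212 minus signs are accepted on read", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("PlateID,Well,GeneSymbol,EntrezID,siRNAID,WellAnno,R1,R2",
               paste0("P1,A2,GA,101,s1,sample,−5,100")), f)
  expect_error(read_screen_table(f, "primary"), class = "dualscreen_record_error")
  writeLines(c("PlateID,Well,GeneSymbol,EntrezID,siRNAID,WellAnno,R1,R2",
               "P1,A2,GA,101,s1,sample,5,100"), f)
  expect_equal(read_screen_table(f, "primary")$records$r1, 5)
})

test_that("expression table collapses probes by minimum detection p", {
  f <- write_expression_csv(c(
    "p1,GA,8.2,0.2,9.1,0.4",
    "p2,GA,7.9,0.05,8.8,0.6",
    "p3,GB,10.0,0.03,11.2,0.5"))
  expr <- read_expression_table(f)
  expect_equal(nrow(expr), 2L)
  ga <- expr[expr$gene_symbol == "GA", ]
  expect_equal(ga$p_unstim, 0.05)   # min over the two probes
  expect_equal(ga$p_lps, 0.4)
  # present-call is deferred: both values stored, filter decides later
  expect_true(is_expressed(expr, "GB"))
  expect_error(read_expression_table(write_expression_csv(
    "p1,GA,8.2,1.2,9.1,0.4")), class = "dualscreen_validation_error")
})

test_that("expression table with a single condition is rejected", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("ProbeID,GeneSymbol,Log2Signal_LPS,DetectionP_LPS",
               "p1,GA,8.2,0.02"), f)
  expect_error(read_expression_table(f), class = "dualscreen_validation_error")
})

test_that("validate_dataset flags replicate-count and control-minimum violations", {
  sim <- generate_primary_screen(sim_config(n_genes = 8, seed = 2))
  rep0 <- validate_dataset(sim$dataset)
  expect_true(attr(rep0, "valid"))
  expect_equal(nrow(rep0), 0L)
  # drop one well of a SMARTpool -> replicate count 3 != 4
  rec <- sim$dataset$records
  pool <- rec$sirna_id[rec$well_anno == "sample"][1]
  rec3 <- rec[!(rec$sirna_id == pool & rec$replicate == 4), ]
  ds3 <- screen_dataset(rec3, "primary")
  rep3 <- validate_dataset(ds3)
  expect_false(attr(rep3, "valid"))
  expect_match(rep3$detail[rep3$rule == "replicate_structure"], "3 != 4")
  # 2 NTC unstimulated wells when 3 are required
  drop_well <- rec$well[rec$well_anno == "NTC" & !rec$stimulated][1]
  rec2 <- rec[!(rec$well == drop_well & rec$well_anno == "NTC"), ]
  rep2 <- validate_dataset(screen_dataset(rec2, "primary"))
  expect_match(paste(rep2$detail, collapse = " "), "at least 3 wells each")
})

test_that("secondary structural invariants are validated", {
  genes <- sprintf("G%02d", 1:8)
  sec <- generate_secondary_screen(sim_config(seed = 4), genes)
  expect_true(attr(validate_dataset(sec$dataset), "valid"))
  # remove one siRNA entirely -> gene has 5 siRNAs
  rec <- sec$dataset$records
  s1 <- rec$sirna_id[rec$well_anno == "sample"][1]
  repv <- validate_dataset(screen_dataset(rec[rec$sirna_id != s1, ], "secondary"))
  expect_match(paste(repv$detail, collapse = " "), "5 siRNAs")
})

test_that("control schemes enforce disjoint columns and YAML round-trips", {
  sch <- control_scheme("primary")
  expect_equal(sch$sample_columns, c(2:9, 12:23))
  expect_equal(sch$control_columns, c(10L, 11L, 24L))
  expect_equal(sch$empty_columns, 1L)
  sec <- control_scheme("secondary")
  expect_equal(sec$control_columns, c(11L, 12L, 13L, 22L))
  expect_error(control_scheme("primary", sample_columns = 1:10,
                              control_columns = 10:12),
               class = "dualscreen_schema_error")
  f <- tempfile(fileext = ".yaml")
  write_control_scheme(sch, f)
  expect_equal(read_control_scheme(f), sch)
})
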