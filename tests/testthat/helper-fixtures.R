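# Fixtures are built in code: a small hand-specified primary plate whose
# control and sample readouts are chosen so every QC quantity is computable
# by hand, plus writers for canonical on-disk fixtures.

# One primary plate: 3 SMARTpools x 4 replicate wells (12 sample wells) plus
# the core control classes. Ratios are exact by construction (r2 = 1000).
tiny_primary_records <- function(sample_ratios = list(
                                   GA = c(1.0, 1.1, 0.9, 1.0),
                                   GB = c(2.0, 2.2, 1.8, 2.0),
                                   GC = c(0.5, 0.55, 0.45, 0.5)),
                                 ntc_stim = c(6, 6, 6),
                                 ntc_unstim = c(1, 1, 1),
                                 renilla_r2 = c(50, 50, 50),
                                 tlr4_stim = c(0.6, 0.6, 0.6)) {
  r2 <- 1000
  rows <- list()
  add <- function(well, anno, stimulus, ratio, gene = "", sirna = "",
                  r2_override = NULL) {
    rr2 <- r2_override %||% r2
    rows[[length(rows) + 1L]] <<- data.frame(
      plate_id = "P1", well = well, gene_symbol = gene, entrez_id = "",
      sirna_id = sirna, well_anno = anno, stimulus = stimulus,
      replicate = 1L, r1 = ratio * rr2, r2 = rr2, stringsAsFactors = FALSE)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  cols <- c(2L, 3L, 4L)
  for (gi in seq_along(sample_ratios)) {
    g <- names(sample_ratios)[gi]
    for (k in 1:4) {
      add(paste0(LETTERS[k], cols[gi]), "sample", "LPS",
          sample_ratios[[gi]][k], gene = g, sirna = paste0("POOL_", g))
    }
  }
  for (k in seq_along(ntc_stim)) add(paste0(LETTERS[k], 10), "NTC", "LPS", ntc_stim[k])
  for (k in seq_along(ntc_unstim)) add(paste0(LETTERS[k + 3], 10), "NTC", "none", ntc_unstim[k])
  for (k in seq_along(renilla_r2))
    add(paste0(LETTERS[k + 6], 10), "siRenilla", "none", 1, r2_override = renilla_r2[k])
  for (k in seq_along(tlr4_stim)) add(paste0(LETTERS[k + 9], 10), "siTLR4", "LPS", tlr4_stim[k])
  rec <- do.call(rbind, rows)
  # positional replicate index within each pool
  rec$replicate <- stats::ave(seq_len(nrow(rec)),
                              paste(rec$well_anno, rec$sirna_id),
                              FUN = seq_along)
  rec
}

tiny_primary_dataset <- function(...) {
  screen_dataset(tiny_primary_records(...), tier = "primary",
                 provenance = "hand-built test plate")
}

# Canonical long-dialect CSV text for an 8-well fixture (round-trip tests).
fixture_csv_lines <- function() {
  c("PlateID,Well,GeneSymbol,EntrezID,siRNAID,WellAnno,Stimulus,Replicate,R1,R2",
    "P1,A2,GA,101,POOL_GA,sample,LPS,1,1200,1000",
    "P1,B2,GA,101,POOL_GA,sample,LPS,2,1100,1000",
    "P1,C2,GA,101,POOL_GA,sample,LPS,3,1300,1000",
    "P1,D2,GA,101,POOL_GA,sample,LPS,4,1250,1000",
    "P1,A10,,,D-001210-05,NTC,LPS,1,6000,1000",
    "P1,B10,,,D-001210-05,NTC,none,1,1000,1000",
    "P1,C10,,,siRenilla-custom,siRenilla,none,1,50,50",
    "P1,D10,,,M-008088-01,siTLR4,LPS,1,600,1000")
}

write_fixture_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(fixture_csv_lines(), path)
  path
}

# Expression-table CSV with per-probe rows.
write_expression_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  header <- "ProbeID,GeneSymbol,Log2Signal_unstim,DetectionP_unstim,Log2Signal_LPS,DetectionP_LPS"
  writeLines(c(header, rows), path)
  path
}
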