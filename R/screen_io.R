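# Data model and readers/writers for per-well screen tables, expression
# tables and control-layout configuration.

WELL_ANNO_LEVELS <- c("sample", "NTC", "siRenilla", "siTLR4", "siIRAK1",
                      "siIKBKG", "siMAP3K7", "lipid_only", "empty")

STIMULUS_LEVELS <- c("LPS", "P3C", "PGN", "R848", "P2C", "FLG",
                     "BCG_extract", "none")

# Case-insensitive control vocabulary. Keys are lower-case input spellings
# seen in public exports; values the canonical enum.
.anno_map <- c(
  sample = "sample", sm = "sample", experimental = "sample",
  ntc = "NTC", ntc3 = "NTC", ntc5 = "NTC",
  "non-targeting" = "NTC", nontargeting = "NTC", negative = "NTC",
  sirenilla = "siRenilla", renilla = "siRenilla", si_renilla = "siRenilla",
  sitlr4 = "siTLR4", tlr4 = "siTLR4",
  siirak1 = "siIRAK1", irak1 = "siIRAK1",
  siikbkg = "siIKBKG", ikbkg = "siIKBKG",
  simap3k7 = "siMAP3K7", map3k7 = "siMAP3K7", tak1 = "siMAP3K7",
  lipid_only = "lipid_only", lipid = "lipid_only", lipidonly = "lipid_only",
  mock = "lipid_only",
  empty = "empty", unused = "empty", none = "empty"
)

# Normalizes well annotations; a "_noLPS" style suffix marks unstimulated
# control wells and is returned separately.
normalize_well_anno <- function(x) {
  x <- trimws(as.character(x))
  x[is.na(x) | x == ""] <- "empty"
  nolps <- grepl("[._ -]?no[._ -]?lps$", x, ignore.case = TRUE)
  base <- tolower(sub("[._ -]?no[._ -]?lps$", "", x, ignore.case = TRUE))
  anno <- unname(.anno_map[base])
  unknown <- is.na(anno)
  if (any(unknown)) {
    ds_abort(sprintf("unrecognized WellAnno value(s): %s",
                     paste(unique(x[unknown]), collapse = ", ")),
             "schema_error")
  }
  list(anno = anno, no_lps = nolps)
}

#' Control-layout scheme for a screen tier
#'
#' Describes which plate columns hold gene-targeting samples versus control
#' siRNAs, which wells are left unused, and the minimum number of wells per
#' control class required for QC. The primary default places samples in
#' columns 2--9 and 12--23 with controls in columns 10, 11 and 24 and column
#' 1 unused; the secondary default leaves the outer two rows and columns
#' empty and reserves columns 11, 12, 13 and 22 for controls.
#'
#' @param tier `"primary"`, `"secondary"` or `"tertiary"`.
#' @param sample_columns,control_columns integer column sets (1--24), disjoint.
#' @param empty_columns,empty_rows columns / rows (1--16) left unused.
#' @param min_control_wells minimum wells per control class (default 3).
#' @return an object of class `control_scheme`.
#' @export
control_scheme <- function(tier = c("primary", "secondary", "tertiary"),
                           sample_columns = NULL, control_columns = NULL,
                           empty_columns = integer(), empty_rows = integer(),
                           min_control_wells = 3L) {
  tier <- match.arg(tier)
  if (is.null(sample_columns) || is.null(control_columns)) {
    def <- switch(tier,
      primary = list(sample = c(2:9, 12:23), control = c(10L, 11L, 24L),
                     ecol = 1L, erow = integer()),
      secondary = list(sample = c(3:10, 14:21), control = c(11:13, 22L),
                       ecol = c(1L, 2L, 23L, 24L), erow = c(1L, 2L, 15L, 16L)),
      tertiary = list(sample = c(2:9, 12:23), control = c(10L, 11L, 24L),
                      ecol = 1L, erow = integer())
    )
    sample_columns <- sample_columns %||% def$sample
    control_columns <- control_columns %||% def$control
    if (!length(empty_columns)) empty_columns <- def$ecol
    if (!length(empty_rows)) empty_rows <- def$erow
  }
  sample_columns <- as.integer(sample_columns)
  control_columns <- as.integer(control_columns)
  if (length(intersect(sample_columns, control_columns)))
    ds_abort("sample and control columns must be disjoint", "schema_error")
  structure(
    list(tier = tier, sample_columns = sample_columns,
         control_columns = control_columns,
         empty_columns = as.integer(empty_columns),
         empty_rows = as.integer(empty_rows),
         min_control_wells = as.integer(min_control_wells)),
    class = "control_scheme"
  )
}

#' Read or write a control scheme as YAML
#'
#' @param path file path.
#' @return `read_control_scheme` returns a [control_scheme()].
#' @export
read_control_scheme <- function(path) {
  cfg <- yaml::read_yaml(path)
  control_scheme(
    tier = cfg$tier %||% "primary",
    sample_columns = cfg$sample_columns,
    control_columns = cfg$control_columns,
    empty_columns = cfg$empty_columns %||% integer(),
    empty_rows = cfg$empty_rows %||% integer(),
    min_control_wells = cfg$min_control_wells %||% 3L
  )
}

#' @rdname read_control_scheme
#' @param scheme a [control_scheme()].
#' @export
write_control_scheme <- function(scheme, path) {
  yaml::write_yaml(unclass(scheme), path)
  invisible(path)
}

#' Construct a validated screen dataset
#'
#' A `screen_dataset` couples a per-well record table with the tier's
#' control scheme. Structural invariants (parseable coordinates, unique
#' `(plate, well, replicate)` keys, finite non-negative luminescence,
#' samples carrying an siRNA id) are enforced at construction; tier-level
#' replicate-structure invariants are checked by [validate_dataset()].
#'
#' @param records data.frame with columns `plate_id`, `well`, `gene_symbol`,
#'   `entrez_id`, `sirna_id`, `well_anno`, `stimulus`, `replicate`, `r1`, `r2`.
#' @param tier screen tier.
#' @param scheme a [control_scheme()]; defaults to the tier's standard layout.
#' @param provenance free-text origin note.
#' @return object of class `screen_dataset`.
#' @export
screen_dataset <- function(records, tier = c("primary", "secondary", "tertiary"),
                           scheme = NULL, provenance = "") {
  tier <- match.arg(tier)
  scheme <- scheme %||% control_scheme(tier)
  req <- c("plate_id", "well", "gene_symbol", "entrez_id", "sirna_id",
           "well_anno", "stimulus", "replicate", "r1", "r2")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    ds_abort(paste("records missing column(s):",
                   paste(missing_cols, collapse = ", ")), "schema_error")
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  rownames(records) <- NULL
  pw <- parse_well(records$well)
  records$well <- pw$well
  records$row <- pw$row
  records$col <- pw$col
  if (!all(records$well_anno %in% WELL_ANNO_LEVELS))
    ds_abort("well_anno outside the control vocabulary", "schema_error")
  if (!all(records$stimulus %in% STIMULUS_LEVELS))
    ds_abort("stimulus outside the ligand vocabulary", "schema_error")
  records$stimulated <- records$stimulus != "none"
  records$replicate <- as.integer(records$replicate)
  key <- paste(records$plate_id, records$well, records$replicate, sep = "\r")
  if (anyDuplicated(key))
    ds_abort(sprintf("duplicate (plate, well, replicate): %s",
                     paste(utils::head(unique(gsub("\r", "/", key[duplicated(key)])), 3),
                           collapse = "; ")),
             "integrity_error")
  live <- records$well_anno != "empty"
  bad_r <- live & (!is.finite(records$r1) | !is.finite(records$r2) |
                     records$r1 < 0 | records$r2 < 0)
  if (any(bad_r))
    ds_abort("r1/r2 must be finite and >= 0 for non-empty wells", "record_error")
  no_id <- records$well_anno == "sample" &
    (is.na(records$sirna_id) | records$sirna_id == "")
  if (any(no_id))
    ds_abort("sample wells must carry a non-empty sirna_id", "record_error")
  structure(
    list(tier = tier, records = records, scheme = scheme,
         provenance = provenance),
    class = "screen_dataset"
  )
}

#' @export
print.screen_dataset <- function(x, ...) {
  r <- x$records
  cat(sprintf("<screen_dataset> tier=%s: %d records, %d plate(s), %d sample siRNA(s)\n",
              x$tier, nrow(r), length(unique(r$plate_id)),
              length(unique(r$sirna_id[r$well_anno == "sample"]))))
  tb <- table(r$well_anno)
  cat("  wells by class:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

# Canonical on-disk column order for the long (one record per row) dialect.
.long_cols <- c(PlateID = "plate_id", Well = "well", GeneSymbol = "gene_symbol",
                EntrezID = "entrez_id", siRNAID = "sirna_id",
                WellAnno = "well_anno", Stimulus = "stimulus",
                Replicate = "replicate", R1 = "r1", R2 = "r2")

#' Read a delimited per-well screen table
#'
#' Reads comma-separated screen exports carrying the minimal analysis fields
#' (`PlateID`, `Well`, `GeneSymbol`, `EntrezID`, `siRNAID`, `WellAnno`) plus
#' raw luminescence readouts. Two readout dialects are accepted:
#' per-row `R1`/`R2` columns (with an optional `Replicate` column), or wide
#' replicate columns `Rep1R1`/`Rep1R2` ... `Rep3R1`/`Rep3R2` which are
#' pivoted to one record per replicate. Precomputed ratio or score columns
#' (`Rep1R1/R2`, `Zscore`, ...) are ignored; scores are always recomputed.
#'
#' Control annotations are normalized case-insensitively and a
#' `"noLPS"`-suffixed annotation marks an unstimulated well. For the primary
#' tier, when no replicate information is present the replicate index is
#' assigned positionally (1--4, plate order) within each `(plate, siRNAID)`
#' group, matching the four-replicate-wells-per-SMARTpool layout.
#'
#' @param path CSV file path.
#' @param tier screen tier of the table.
#' @param schema optional named character vector mapping canonical column
#'   names (e.g. `"PlateID"`) to the file's column names.
#' @param scheme optional [control_scheme()] override.
#' @return a [screen_dataset()].
#' @export
read_screen_table <- function(path, tier = c("primary", "secondary", "tertiary"),
                              schema = NULL, scheme = NULL) {
  tier <- match.arg(tier)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      j <- match(schema[[canon]], names(raw))
      if (!is.na(j)) names(raw)[j] <- canon
    }
  }
  minimal <- c("PlateID", "Well", "GeneSymbol", "EntrezID", "siRNAID", "WellAnno")
  miss <- setdiff(minimal, names(raw))
  if (length(miss))
    ds_abort(paste("missing mandatory column(s):", paste(miss, collapse = ", ")),
             "schema_error")

  # locate readouts: long (R1/R2) or wide (Rep<k>R1 / Rep<k>R2)
  wide_r1 <- grep("^Rep[0-9]+R1$", names(raw), value = TRUE)
  wide_r2 <- grep("^Rep[0-9]+R2$", names(raw), value = TRUE)
  long_ok <- all(c("R1", "R2") %in% names(raw))
  if (!long_ok && !(length(wide_r1) && length(wide_r2)))
    ds_abort("missing mandatory column(s): R1/R2 (or Rep<k>R1/Rep<k>R2)",
             "schema_error")

  nw <- normalize_well_anno(raw$WellAnno)
  stimulus <- if ("Stimulus" %in% names(raw)) {
    s <- trimws(raw$Stimulus)
    if (!all(s %in% STIMULUS_LEVELS))
      ds_abort("Stimulus column contains values outside the ligand vocabulary",
               "schema_error")
    s
  } else rep("LPS", nrow(raw))
  stimulus[nw$no_lps] <- "none"
  stimulus[nw$anno == "empty"] <- "none"
  # siRenilla transfection-efficiency wells are run without stimulus
  if (!"Stimulus" %in% names(raw)) stimulus[nw$anno == "siRenilla"] <- "none"

  base <- data.frame(
    plate_id = raw$PlateID, well = raw$Well, gene_symbol = raw$GeneSymbol,
    entrez_id = raw$EntrezID, sirna_id = raw$siRNAID, well_anno = nw$anno,
    stimulus = stimulus, stringsAsFactors = FALSE
  )

  if (long_ok) {
    base$r1 <- as_num(raw$R1)
    base$r2 <- as_num(raw$R2)
    base$replicate <- if ("Replicate" %in% names(raw))
      as.integer(raw$Replicate) else NA_integer_
    rec <- base
  } else {
    reps <- sort(as.integer(sub("^Rep([0-9]+)R1$", "\\1", wide_r1)))
    rec <- do.call(rbind, lapply(reps, function(k) {
      b <- base
      b$r1 <- as_num(raw[[sprintf("Rep%dR1", k)]])
      b$r2 <- as_num(raw[[sprintf("Rep%dR2", k)]])
      b$replicate <- k
      b
    }))
  }

  if (anyNA(rec$replicate)) {
    # positional assignment within (plate, reagent) groups, file order
    grp <- paste(rec$plate_id, rec$well_anno, rec$sirna_id, sep = "\r")
    rec$replicate <- stats::ave(seq_len(nrow(rec)), grp,
                                FUN = seq_along)
  }
  ds <- screen_dataset(rec, tier = tier, scheme = scheme,
                       provenance = paste("read from", path))
  ds
}

#' Write a screen dataset as a deposit-style CSV
#'
#' Writes the long dialect (one record per row) with deterministic column
#' order `PlateID, Well, GeneSymbol, EntrezID, siRNAID, WellAnno, Stimulus,
#' Replicate, R1, R2`. With `include_scores = TRUE`, per-well `Zscore` and
#' (when present on the dataset) `ActivityScore` / `Outcome` columns are
#' appended using the public deposit naming. `write` then `read` is a fixed
#' point: re-reading and re-writing reproduces the file byte for byte.
#'
#' @param dataset a [screen_dataset()].
#' @param path output CSV path.
#' @param include_scores append score columns if attached (see
#'   [attach_scores()]).
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(dataset, path, include_scores = FALSE) {
  r <- dataset$records
  out <- r[.long_cols]
  names(out) <- names(.long_cols)
  if (include_scores) {
    for (col in c("Zscore", "ActivityScore", "Outcome")) {
      lc <- tolower(col)
      if (lc %in% names(r)) out[[col]] <- r[[lc]]
    }
  }
  ok <- tryCatch({
    utils::write.csv(format_for_csv(out), path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    ds_abort(paste("cannot write table:", conditionMessage(ok)), "io_error")
  invisible(path)
}

# deterministic numeric formatting (15 significant digits, ASCII minus)
format_for_csv <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]))
      df[[j]] <- sub("^NA$", "", sprintf("%.15g", df[[j]]))
  }
  df
}

#' Attach per-well scores to a dataset for export
#'
#' @param dataset a [screen_dataset()].
#' @param wells scored well table from [score_primary()] / [score_secondary()]
#'   (columns `plate_id`, `well`, `replicate`, `zscore`).
#' @param tier tier used for activity-score binning (defaults to the
#'   dataset's own tier).
#' @return the dataset with `zscore`, `activity_score`, `outcome` columns.
#' @export
attach_scores <- function(dataset, wells, tier = dataset$tier) {
  key <- function(d) paste(d$plate_id, d$well, d$replicate, sep = "\r")
  i <- match(key(dataset$records), key(wells))
  dataset$records$zscore <- wells$zscore[i]
  bin <- activity_score(dataset$records$zscore, tier = tier,
                        control = dataset$records$well_anno != "sample")
  dataset$records$activityscore <- bin$activity_score
  dataset$records$outcome <- bin$outcome
  dataset
}

#' Read a two-condition expression table
#'
#' Reads a CSV of per-probe (or per-gene) log2 signal intensities and
#' detection p-values for the unstimulated and LPS-stimulated conditions,
#' e.g. `ProbeID, GeneSymbol, Log2Signal_unstim, DetectionP_unstim,
#' Log2Signal_LPS, DetectionP_LPS`. Column matching is case-insensitive;
#' the unstimulated condition is recognized by `unstim`/`ctrl`/`0h` and the
#' stimulated one by `lps`/`stim`/`4h` in the column name. Probes mapping to
#' one gene are collapsed to the minimum detection p per condition (the most
#' permissive "expressed" evidence) and the maximum log2 signal.
#'
#' @param path CSV path.
#' @return object of class `expression_table`: data.frame with columns
#'   `gene_symbol`, `log2_unstim`, `log2_lps`, `p_unstim`, `p_lps`.
#' @export
read_expression_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(names(raw))
  gene_j <- which(nm %in% c("genesymbol", "gene_symbol", "gene", "symbol"))[1]
  if (is.na(gene_j))
    ds_abort("missing mandatory column(s): GeneSymbol", "schema_error")
  unstim_pat <- "unstim|ctrl|untreated|0h|no_?lps"
  find <- function(kind, cond = c("unstim", "lps")) {
    cond <- match.arg(cond)
    hit <- grepl(kind, nm) &
      (if (cond == "unstim") grepl(unstim_pat, nm)
       else (grepl("lps|stim|4h", nm) & !grepl(unstim_pat, nm)))
    j <- which(hit)
    if (length(j)) j[1] else NA_integer_
  }
  p_un <- find("detection|pval|p_", "unstim")
  p_lps <- find("detection|pval|p_", "lps")
  if (is.na(p_un) || is.na(p_lps))
    ds_abort("both conditions (+/-LPS) are required: need a detection p column per condition",
             "validation_error")
  s_un <- find("log2|signal", "unstim")
  s_lps <- find("log2|signal", "lps")
  df <- data.frame(
    gene_symbol = as.character(raw[[gene_j]]),
    log2_unstim = if (!is.na(s_un)) as_num(raw[[s_un]]) else NA_real_,
    log2_lps = if (!is.na(s_lps)) as_num(raw[[s_lps]]) else NA_real_,
    p_unstim = as_num(raw[[p_un]]),
    p_lps = as_num(raw[[p_lps]]),
    stringsAsFactors = FALSE
  )
  if (any(df$p_unstim < 0 | df$p_unstim > 1 | df$p_lps < 0 | df$p_lps > 1,
          na.rm = TRUE) || anyNA(df$p_unstim) || anyNA(df$p_lps))
    ds_abort("detection p-values must lie in [0, 1]", "validation_error")
  collapsed <- do.call(rbind, lapply(split(df, df$gene_symbol), function(g) {
    data.frame(gene_symbol = g$gene_symbol[1],
               log2_unstim = suppressWarnings(max(g$log2_unstim)),
               log2_lps = suppressWarnings(max(g$log2_lps)),
               p_unstim = min(g$p_unstim), p_lps = min(g$p_lps),
               stringsAsFactors = FALSE)
  }))
  rownames(collapsed) <- NULL
  structure(collapsed, class = c("expression_table", "data.frame"))
}

#' Expression present/absent call
#'
#' A gene is called expressed if its detection p-value is below `p_cut`
#' (strictly) in at least one of the two conditions.
#'
#' @param expr an `expression_table`.
#' @param genes character vector of genes to query.
#' @param p_cut detection p cutoff (default 0.1).
#' @return named logical vector; `NA` for genes absent from the table.
#' @export
is_expressed <- function(expr, genes, p_cut = 0.1) {
  i <- match(genes, expr$gene_symbol)
  out <- expr$p_unstim[i] < p_cut | expr$p_lps[i] < p_cut
  names(out) <- genes
  out
}

#' Validate a dataset's replicate and layout structure
#'
#' Report-based validation of tier-level invariants: primary SMARTpools occur
#' in exactly 4 wells of one plate; secondary siRNAs occur in one well with 3
#' replicate measurements and each gene maps to exactly 6 siRNAs; sample and
#' control wells sit in their scheme's columns; each core control class
#' (stimulated NTC, unstimulated NTC, unstimulated siRenilla, stimulated
#' siTLR4) has at least `min_control_wells` wells per plate.
#'
#' @param dataset a [screen_dataset()].
#' @return data.frame of violations (zero rows when the dataset conforms),
#'   with attribute `valid`.
#' @export
validate_dataset <- function(dataset) {
  r <- dataset$records
  sch <- dataset$scheme
  v <- list()
  note <- function(rule, plate, detail)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, plate_id = plate,
                                       detail = detail, stringsAsFactors = FALSE)
  smp <- r[r$well_anno == "sample", , drop = FALSE]

  if (dataset$tier == "primary" && nrow(smp)) {
    for (s in split(smp, smp$sirna_id)) {
      if (length(unique(s$plate_id)) != 1L)
        note("replicate_structure", s$plate_id[1],
             sprintf("SMARTpool %s spans %d plates (expected 1)",
                     s$sirna_id[1], length(unique(s$plate_id))))
      if (nrow(s) != 4L)
        note("replicate_structure", s$plate_id[1],
             sprintf("SMARTpool %s: replicate count %d != 4", s$sirna_id[1], nrow(s)))
    }
  }
  if (dataset$tier == "secondary" && nrow(smp)) {
    for (s in split(smp, smp$sirna_id)) {
      if (length(unique(s$well)) != 1L || length(unique(s$replicate)) != nrow(s))
        note("replicate_structure", s$plate_id[1],
             sprintf("siRNA %s: expected one well x distinct replicates", s$sirna_id[1]))
      if (nrow(s) != 3L)
        note("replicate_structure", s$plate_id[1],
             sprintf("siRNA %s: replicate count %d != 3", s$sirna_id[1], nrow(s)))
    }
    per_gene <- tapply(smp$sirna_id, smp$gene_symbol,
                       function(x) length(unique(x)))
    for (g in names(per_gene)[per_gene != 6L])
      note("sirna_per_gene", "", sprintf("gene %s has %d siRNAs (expected 6)",
                                         g, per_gene[[g]]))
  }
  # layout conformity
  off <- smp[!(smp$col %in% sch$sample_columns), , drop = FALSE]
  if (nrow(off))
    note("layout", off$plate_id[1],
         sprintf("%d sample well(s) outside sample columns (e.g. %s)",
                 nrow(off), off$well[1]))
  ctrl_classes <- setdiff(WELL_ANNO_LEVELS, c("sample", "empty"))
  offc <- r[r$well_anno %in% ctrl_classes & !(r$col %in% sch$control_columns), ,
            drop = FALSE]
  if (nrow(offc))
    note("layout", offc$plate_id[1],
         sprintf("%d control well(s) outside control columns (e.g. %s)",
                 nrow(offc), offc$well[1]))
  # control minimums per plate (core QC classes; "at least 3 wells each")
  core <- list(c("NTC", TRUE), c("NTC", FALSE), c("siRenilla", FALSE),
               c("siTLR4", TRUE))
  for (p in unique(r$plate_id)) {
    pr <- r[r$plate_id == p, ]
    if (!any(pr$well_anno %in% ctrl_classes)) next
    for (cl in core) {
      n <- length(unique(pr$well[pr$well_anno == cl[[1]] &
                                   pr$stimulated == as.logical(cl[[2]])]))
      if (n > 0 && n < sch$min_control_wells)
        note("control_minimum", p,
             sprintf("%s (%s) has %d wells; at least %d wells each required",
                     cl[[1]], if (as.logical(cl[[2]])) "stimulated" else "unstimulated",
                     n, sch$min_control_wells))
    }
  }
  out <- if (length(v)) do.call(rbind, v)
  else data.frame(rule = character(), plate_id = character(),
                  detail = character(), stringsAsFactors = FALSE)
  attr(out, "valid") <- nrow(out) == 0L
  out
}
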