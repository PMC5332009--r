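# Plate-level quality control: the four acceptance gates, plate-uniformity
# (edge effect) testing, replicate CV and replicate correlation.

ctrl_center <- function(x, center = c("mean", "median")) {
  center <- match.arg(center)
  if (center == "mean") mean(x, na.rm = TRUE) else stats::median(x, na.rm = TRUE)
}

plate_slice <- function(dataset, plate_id, replicate = NULL) {
  r <- dataset$records[dataset$records$plate_id == plate_id, , drop = FALSE]
  if (!is.null(replicate)) r <- r[r$replicate %in% replicate, , drop = FALSE]
  if (!nrow(r)) ds_abort(sprintf("no records for plate %s", plate_id), "qc_error")
  r
}

#' QC gate thresholds
#'
#' The four per-plate acceptance gates: at least five-fold LPS induction of
#' the NTC reporter ratio, at least 85% renilla knockdown in siRenilla
#' wells, at least 85% reduction of the induced readout in the
#' receptor-knockdown positive control, and no renilla saturation. The
#' saturation limit is instrument-dependent; the default (2^21 - 1 counts)
#' suits a photon-counting plate reader and is configurable.
#'
#' @param min_fold_induction minimum stimulated/unstimulated NTC ratio (5).
#' @param min_renilla_kd minimum renilla knockdown fraction (0.85).
#' @param min_positive_reduction minimum positive-control reduction (0.85).
#' @param saturation_limit renilla counts at/above which a well saturates.
#' @param positive_control control class used for gate 3 (default siTLR4).
#' @param center `"mean"` (default) or `"median"` for control summaries.
#' @return list of thresholds.
#' @export
qc_thresholds <- function(min_fold_induction = 5, min_renilla_kd = 0.85,
                          min_positive_reduction = 0.85,
                          saturation_limit = 2^21 - 1,
                          positive_control = "siTLR4",
                          center = "mean") {
  list(min_fold_induction = min_fold_induction,
       min_renilla_kd = min_renilla_kd,
       min_positive_reduction = min_positive_reduction,
       saturation_limit = saturation_limit,
       positive_control = positive_control, center = center)
}

#' Fold induction of the reporter by the stimulus
#'
#' Mean R1/R2 of stimulated NTC wells divided by mean R1/R2 of unstimulated
#' NTC wells on one plate.
#'
#' @param dataset a [screen_dataset()].
#' @param plate_id plate to evaluate.
#' @param center control summary, `"mean"` or `"median"`.
#' @return fold-induction ratio (scalar).
#' @export
fold_induction <- function(dataset, plate_id, center = "mean") {
  r <- plate_slice(dataset, plate_id)
  ratio <- suppressWarnings(reporter_ratio(r$r1, r$r2))
  stim <- ratio[r$well_anno == "NTC" & r$stimulated]
  unstim <- ratio[r$well_anno == "NTC" & !r$stimulated]
  if (!length(stim) || !length(unstim))
    ds_abort(sprintf("plate %s lacks stimulated and/or unstimulated NTC wells",
                     plate_id), "qc_error")
  ctrl_center(stim, center) / ctrl_center(unstim, center)
}

#' Transfection efficiency by renilla knockdown
#'
#' `1 - mean(R2 siRenilla) / mean(R2 NTC)` over *unstimulated* wells only
#' (the transfection-efficiency wells are run without stimulus so the
#' constitutive channel is compared like for like).
#'
#' @inheritParams fold_induction
#' @return knockdown fraction in `[0, 1]` (can be negative if knockdown
#'   failed entirely).
#' @export
knockdown_efficiency <- function(dataset, plate_id, center = "mean") {
  r <- plate_slice(dataset, plate_id)
  kd <- r$r2[r$well_anno == "siRenilla" & !r$stimulated]
  ntc <- r$r2[r$well_anno == "NTC" & !r$stimulated]
  if (!length(kd) || !length(ntc))
    ds_abort(sprintf("plate %s lacks unstimulated siRenilla and/or NTC wells",
                     plate_id), "qc_error")
  m_ntc <- ctrl_center(ntc, center)
  if (!is.finite(m_ntc) || m_ntc == 0)
    ds_abort("degenerate control: mean NTC renilla reading is zero", "qc_error")
  1 - ctrl_center(kd, center) / m_ntc
}

#' Reduction of the induced readout by a positive-control knockdown
#'
#' `1 - mean(R1/R2 control) / mean(R1/R2 NTC)` over stimulated wells.
#'
#' @inheritParams fold_induction
#' @param control control class (default `"siTLR4"`).
#' @return reduction fraction.
#' @export
positive_control_reduction <- function(dataset, plate_id, control = "siTLR4",
                                       center = "mean") {
  r <- plate_slice(dataset, plate_id)
  ratio <- suppressWarnings(reporter_ratio(r$r1, r$r2))
  ctl <- ratio[r$well_anno == control & r$stimulated]
  ntc <- ratio[r$well_anno == "NTC" & r$stimulated]
  if (!length(ctl) || !length(ntc))
    ds_abort(sprintf("plate %s lacks stimulated %s and/or NTC wells",
                     plate_id, control), "qc_error")
  m_ntc <- ctrl_center(ntc, center)
  if (!is.finite(m_ntc) || m_ntc == 0)
    ds_abort("degenerate control: mean NTC ratio is zero", "qc_error")
  1 - ctrl_center(ctl, center) / m_ntc
}

#' Evaluate the four plate-acceptance gates
#'
#' Resolves all four gates per plate: fold induction >= 5, renilla
#' knockdown >= 85%, positive-control reduction >= 85%, and no renilla
#' saturation (no R2 at or above the saturation limit). A plate passes iff
#' all four hold. Missing control classes are recorded as failed criteria
#' with the reason rather than raising.
#'
#' @param dataset a [screen_dataset()].
#' @param thresholds a [qc_thresholds()] list.
#' @param plate_ids plates to evaluate (default: all).
#' @return data.frame, one row per plate: `plate_id`, `fold_induction`,
#'   `renilla_kd`, `positive_control_reduction`, `saturated`, `passed`,
#'   `failed_criteria` (`;`-joined).
#' @export
plate_acceptance <- function(dataset, thresholds = qc_thresholds(),
                             plate_ids = unique(dataset$records$plate_id)) {
  th <- thresholds
  rows <- lapply(plate_ids, function(p) {
    failed <- character()
    gate <- function(fn) tryCatch(fn, dualscreen_qc_error = function(e) {
      failed <<- c(failed, conditionMessage(e)); NA_real_
    })
    fi <- gate(fold_induction(dataset, p, center = th$center))
    kd <- gate(knockdown_efficiency(dataset, p, center = th$center))
    pr <- gate(positive_control_reduction(dataset, p,
                                          control = th$positive_control,
                                          center = th$center))
    r <- plate_slice(dataset, p)
    sat <- any(r$r2 >= th$saturation_limit, na.rm = TRUE)
    if (!is.na(fi) && fi < th$min_fold_induction)
      failed <- c(failed, sprintf("fold induction %.3g < %g-fold over no-stimulus controls",
                                  fi, th$min_fold_induction))
    if (!is.na(kd) && kd < th$min_renilla_kd)
      failed <- c(failed, sprintf("renilla knockdown %.3g < %g", kd, th$min_renilla_kd))
    if (!is.na(pr) && pr < th$min_positive_reduction)
      failed <- c(failed, sprintf("%s reduction %.3g < %g", th$positive_control,
                                  pr, th$min_positive_reduction))
    if (sat)
      failed <- c(failed, "the renilla luciferase reading reached saturation")
    data.frame(plate_id = p, fold_induction = fi, renilla_kd = kd,
               positive_control_reduction = pr, saturated = sat,
               passed = length(failed) == 0L,
               failed_criteria = paste(failed, collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a QC report
#'
#' One CSV row per plate plus a human-readable text summary.
#'
#' @param qc result of [plate_acceptance()].
#' @param path CSV path; a `.txt` summary is written alongside.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.csv(format_for_csv(qc), path, row.names = FALSE, quote = FALSE)
  txt <- sub("\\.csv$", ".txt", path)
  if (txt == path) txt <- paste0(path, ".txt")
  lines <- c(sprintf("Plate QC: %d/%d plates passed", sum(qc$passed), nrow(qc)),
             sprintf("  %s: %s%s", qc$plate_id,
                     ifelse(qc$passed, "PASS", "FAIL"),
                     ifelse(qc$passed, "", paste0(" (", qc$failed_criteria, ")"))))
  writeLines(lines, txt)
  invisible(path)
}

group_assignment <- function(row, col, grouping) {
  if (grouping == "quadrant") {
    (row > 8L) * 2L + (col > 12L) + 1L
  } else {  # contiguous column blocks of six
    pmin((col - 1L) %/% 6L + 1L, 4L)
  }
}

#' Plate-uniformity (edge effect) test
#'
#' For each plate and dose level, the dose's wells are divided into four
#' positional groups and the variation statistic is the maximal difference
#' between a pair of group means divided by the mean of all four group
#' means, expressed as a percentage. A dose passes when the variation is
#' below 20% (no edge effect). The grouping is configurable: plate
#' quadrants (row half x column half; the standard positional-bias probe)
#' or four contiguous six-column blocks, which are more sensitive to
#' column-wise gradients.
#'
#' @param dataset a [screen_dataset()] of uniformity plates (e.g. from
#'   [generate_uniformity_plates()]).
#' @param dose_map data.frame `plate_id`, `well`, `dose` assigning every
#'   used well a dose level (H/M/L).
#' @param grouping `"quadrant"` (default) or `"column_block"`.
#' @param pass_limit variation percentage below which a dose passes (20).
#' @return data.frame: `plate_id`, `dose`, group means `g1..g4`,
#'   `variation` (percent), `pass`.
#' @export
uniformity_test <- function(dataset, dose_map,
                            grouping = c("quadrant", "column_block"),
                            pass_limit = 20) {
  grouping <- match.arg(grouping)
  r <- dataset$records
  key <- function(d) paste(d$plate_id, d$well)
  r$dose <- dose_map$dose[match(key(r), key(dose_map))]
  r <- r[!is.na(r$dose) & r$well_anno != "empty", , drop = FALSE]
  r$ratio <- suppressWarnings(reporter_ratio(r$r1, r$r2))
  r$group <- group_assignment(r$row, r$col, grouping)
  rows <- list()
  for (p in unique(r$plate_id)) {
    for (d in unique(r$dose[r$plate_id == p])) {
      w <- r[r$plate_id == p & r$dose == d, , drop = FALSE]
      if (nrow(w) < 4L || length(unique(w$group)) < 4L)
        ds_abort(sprintf("dose %s on plate %s cannot be divided into 4 groups",
                         d, p), "grouping_error")
      gm <- tapply(w$ratio, w$group, mean, na.rm = TRUE)
      variation <- (max(gm) - min(gm)) / mean(gm) * 100
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = p, dose = d, g1 = gm[[1]], g2 = gm[[2]], g3 = gm[[3]],
        g4 = gm[[4]], variation = variation, pass = variation < pass_limit,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Uniformity variation statistic on explicit group means
#'
#' @param group_means numeric vector of four group means.
#' @return percentage variation: max pairwise difference over the mean of
#'   the four group means, times 100.
#' @export
uniformity_variation <- function(group_means) {
  (max(group_means) - min(group_means)) / mean(group_means) * 100
}

#' Replicate coefficient of variation for a primary screen
#'
#' Per SMARTpool, the CV (sample standard deviation over mean) of the four
#' raw R1/R2 replicate ratios; the screen summary is the unweighted mean CV
#' over SMARTpools. Pools with a zero mean ratio have undefined CV and are
#' excluded and reported.
#'
#' @param dataset a primary-tier [screen_dataset()].
#' @return list with `pools` (per-SMARTpool data.frame), `screen_mean` and
#'   `excluded` (siRNA ids with undefined CV).
#' @export
replicate_cv <- function(dataset) {
  r <- dataset$records
  smp <- r[r$well_anno == "sample" & r$stimulated, , drop = FALSE]
  smp$ratio <- suppressWarnings(reporter_ratio(smp$r1, smp$r2))
  pools <- do.call(rbind, lapply(split(smp, smp$sirna_id), function(s) {
    x <- s$ratio[is.finite(s$ratio)]
    m <- mean(x)
    data.frame(sirna_id = s$sirna_id[1], gene_symbol = s$gene_symbol[1],
               n = length(x),
               cv = if (length(x) >= 2L && m != 0) stats::sd(x) / m else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(pools) <- NULL
  list(pools = pools,
       screen_mean = mean(pools$cv, na.rm = TRUE),
       excluded = pools$sirna_id[!is.finite(pools$cv)])
}

#' Pairwise replicate correlation
#'
#' Pearson correlations between replicate experiments, computed by default
#' on log2 plate-median-normalized sample-well ratios (the scale on which
#' secondary replicates are compared); set `log = FALSE, normalized = FALSE`
#' for raw-ratio correlations. Vectors are aligned on `(plate, well)` sample
#' keys. Zero-variance replicates yield `NA` with a warning.
#'
#' @param dataset a [screen_dataset()] with >= 2 replicates.
#' @param log log2-transform normalized values first (default TRUE).
#' @param normalized per plate-replicate median normalization first (TRUE).
#' @return symmetric correlation matrix (replicates x replicates) with unit
#'   diagonal.
#' @export
replicate_correlation <- function(dataset, log = TRUE, normalized = TRUE) {
  r <- dataset$records
  smp <- r[r$well_anno == "sample" & r$stimulated, , drop = FALSE]
  smp$value <- suppressWarnings(reporter_ratio(smp$r1, smp$r2))
  if (normalized) {
    grp <- paste(smp$plate_id, smp$replicate)
    for (g in unique(grp)) {
      i <- grp == g
      smp$value[i] <- plate_median_normalize(smp$value[i])
    }
  }
  if (log) smp$value <- suppressWarnings(log_transform(smp$value))
  reps <- sort(unique(smp$replicate))
  if (length(reps) < 2L)
    ds_abort("replicate correlation needs at least 2 replicates", "qc_error")
  wide <- stats::reshape(
    smp[c("plate_id", "well", "replicate", "value")],
    idvar = c("plate_id", "well"), timevar = "replicate", direction = "wide")
  m <- as.matrix(wide[paste0("value.", reps)])
  if (nrow(m) < 3L)
    ds_abort("replicate correlation needs >= 3 aligned sample wells", "qc_error")
  zv <- apply(m, 2L, function(x) stats::var(x, na.rm = TRUE) == 0)
  if (any(zv))
    ds_warn(sprintf("zero-variance replicate(s): %s",
                    paste(reps[zv], collapse = ", ")), "degenerate_replicate")
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  dimnames(cc) <- list(paste0("rep", reps), paste0("rep", reps))
  diag(cc) <- 1
  cc
}

#' Control-performance boxplot
#'
#' Boxplots of plate-median-normalized reporter ratios by well class, the
#' standard visual guide for placing hit thresholds relative to control
#' perturbations.
#'
#' @param dataset a scored or raw [screen_dataset()].
#' @param file optional PNG path; when given the plot is written there.
#' @return invisibly, the per-class value list.
#' @export
plot_control_performance <- function(dataset, file = NULL) {
  scored <- score_wells(dataset$records, log_values = FALSE)
  keep <- scored$well_anno != "empty" & !is.na(scored$norm) & scored$stimulated
  vals <- split(scored$norm[keep], scored$well_anno[keep])
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::boxplot(vals, las = 2, ylab = "normalized R1/R2",
                    main = "control performance")
  graphics::abline(h = 1, lty = 2, col = "grey50")
  invisible(vals)
}
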