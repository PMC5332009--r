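# Normalization and scoring: reporter ratio, per-plate median normalization,
# log transform, robust z-scores, and the tier-specific aggregation from
# wells to gene scores.

#' Firefly/renilla reporter ratio
#'
#' The ratio of firefly (inducible promoter) to renilla (constitutive
#' promoter) luminescence corrects the reporter readout for cell number and
#' viability. Wells with a zero renilla reading are flagged: the ratio is
#' `NA` and the well is excluded from downstream scoring.
#'
#' @param r1,r2 numeric luminescence vectors (counts).
#' @return numeric ratio vector; `NA` where `r2 == 0`, with a
#'   `dualscreen_flagged_well` warning.
#' @export
reporter_ratio <- function(r1, r2) {
  bad <- !is.na(r2) & r2 == 0
  out <- r1 / r2
  if (any(bad)) {
    out[bad] <- NA_real_
    ds_warn(sprintf("%d well(s) with zero renilla reading flagged and excluded",
                    sum(bad)), "flagged_well")
  }
  out
}

#' Per-plate median normalization
#'
#' Divides every value on a plate by the median of its *sample* wells, the
#' intra-plate median normalization used before z-scoring. Control wells are
#' divided by the same sample-well median.
#'
#' @param values numeric vector (one plate's ratios).
#' @param sample logical mask of sample wells used for the median
#'   (default: all values).
#' @return normalized values; the sample-well median of the output is 1.
#' @export
plate_median_normalize <- function(values, sample = rep(TRUE, length(values))) {
  med <- stats::median(values[sample], na.rm = TRUE)
  if (!is.finite(med) || med <= 0)
    ds_abort("plate normalization requires a positive sample-well median",
             "normalization_error")
  values / med
}

#' Log transform of normalized ratios
#'
#' @param values positive numeric vector.
#' @param base logarithm base (default 2).
#' @return transformed vector; non-positive values become `NA` with a
#'   flagged-well warning.
#' @export
log_transform <- function(values, base = 2) {
  bad <- !is.na(values) & values <= 0
  if (any(bad)) {
    values[bad] <- NA_real_
    ds_warn(sprintf("%d non-positive value(s) flagged before log transform",
                    sum(bad)), "flagged_well")
  }
  log(values, base = base)
}

#' Robust z-score
#'
#' Standardizes values as `(x - median) / (1.4826 * MAD)`, the
#' outlier-resistant z-score standard in HTS hit calling. The center and
#' scale are estimated on the wells indexed by `estimate_on` (typically the
#' sample wells of one plate replicate) and applied to all values, so
#' control wells are expressed on the sample distribution's scale. When the
#' MAD is zero the sample standard deviation is used with a warning.
#'
#' @param values numeric vector.
#' @param estimate_on indices (or logical mask) of the estimation set;
#'   default: all finite values.
#' @param min_n minimum estimation-set size (default 8).
#' @return list with `z`, `center`, `scale` and `used_fallback`.
#' @export
robust_z <- function(values, estimate_on = NULL, min_n = 8L) {
  est <- if (is.null(estimate_on)) values else values[estimate_on]
  est <- est[is.finite(est)]
  if (length(est) < min_n)
    ds_abort(sprintf("robust z needs >= %d finite values to estimate center/scale (got %d)",
                     min_n, length(est)), "scoring_error")
  center <- stats::median(est)
  scale <- stats::mad(est, center = center)  # 1.4826 * median(|x - median|)
  fallback <- FALSE
  if (scale == 0) {
    scale <- stats::sd(est)
    fallback <- TRUE
    if (is.na(scale) || scale == 0)
      ds_abort("robust z undefined: MAD and standard deviation are both zero",
               "scoring_error")
    ds_warn("MAD is zero; falling back to the sample standard deviation",
            "mad_fallback")
  }
  list(z = (values - center) / scale, center = center, scale = scale,
       used_fallback = fallback)
}

#' Primary-tier gene score: replicate-mean of robust z
#'
#' The final primary score of a gene is the arithmetic mean of the robust
#' z-scores of its four replicate wells. Flagged wells drop out of the mean;
#' fewer than `min_wells` usable wells renders the gene unscorable (`NA`).
#'
#' @param z numeric vector of per-well z-scores for one SMARTpool.
#' @param min_wells minimum usable wells (default 2).
#' @return scalar mean z, or `NA_real_` if unscorable.
#' @export
aggregate_primary <- function(z, min_wells = 2L) {
  z <- z[is.finite(z)]
  if (length(z) < min_wells) return(NA_real_)
  mean(z)
}

#' Secondary-tier aggregation: replicate mean per siRNA, gene median over six
#'
#' Each siRNA's score is the mean of its (up to three) replicate z-scores;
#' the gene score is the median of its six per-siRNA scores. With six values
#' the median is the mean of the 3rd and 4th order statistics, which is what
#' makes the score robust to a single off-target siRNA.
#'
#' @param z_by_sirna named list: per siRNA, its replicate z vector.
#' @param min_replicates minimum usable replicates per siRNA (default 2).
#' @return list with `sirna` (named per-siRNA means) and `gene_median`.
#' @export
aggregate_secondary <- function(z_by_sirna, min_replicates = 2L) {
  if (length(z_by_sirna) != 6L)
    ds_abort(sprintf("secondary aggregation requires exactly 6 siRNAs per gene (got %d)",
                     length(z_by_sirna)), "structural_error")
  per <- vapply(z_by_sirna, function(z) {
    z <- z[is.finite(z)]
    if (length(z) < min_replicates) NA_real_ else mean(z)
  }, numeric(1))
  list(sirna = per, gene_median = stats::median(per, na.rm = TRUE))
}

# Internal: per plate-replicate normalization + robust z on sample wells.
score_wells <- function(records, log_values = FALSE) {
  records$ratio <- reporter_ratio(records$r1, records$r2)
  records$norm <- NA_real_
  records$zscore <- NA_real_
  grp <- paste(records$plate_id, records$replicate, sep = "\r")
  # primary: the four replicate wells share one plate, so center/scale are
  # per plate; grouping by (plate, replicate) covers both tier geometries
  # once primary replicate grouping is collapsed by the caller.
  for (g in unique(grp)) {
    i <- which(grp == g)
    scorable <- records$well_anno[i] != "empty" & records$stimulated[i]
    smp <- records$well_anno[i] == "sample" & records$stimulated[i] &
      is.finite(records$ratio[i])
    if (!any(smp)) next
    norm <- plate_median_normalize(records$ratio[i], sample = smp)
    if (log_values) norm <- suppressWarnings(log_transform(norm))
    records$norm[i] <- norm
    if (length(unique(norm[smp])) == 1L) {
      # constant (noise-free) plate: every sample well sits at the center,
      # so its z is exactly 0; off-center controls are unscorable
      z <- ifelse(norm == norm[smp][1], 0, NA_real_)
      records$zscore[i][scorable] <- z[scorable]
      next
    }
    rz <- robust_z(norm, estimate_on = smp)
    records$zscore[i][scorable] <- rz$z[scorable]
  }
  records
}

#' Score a primary screen
#'
#' Runs the primary analysis chain on a validated primary-tier dataset: raw
#' R1/R2 ratio, per-plate median normalization against the plate's sample
#' wells, robust z-score per plate (sample-well center/scale, applied to
#' controls too), then the mean z over the four replicate wells of each
#' SMARTpool as the gene score.
#'
#' @param dataset a primary-tier [screen_dataset()].
#' @param min_wells minimum usable wells per SMARTpool (default 2).
#' @return list with `wells` (per-well table incl. `ratio`, `norm`,
#'   `zscore`) and `genes` (per-gene table with `score`, `n_wells`).
#' @export
score_primary <- function(dataset, min_wells = 2L) {
  if (dataset$tier != "primary")
    ds_abort("score_primary expects a primary-tier dataset", "scoring_error")
  rec <- dataset$records
  # within-plate replicate wells share the plate's center/scale
  rec2 <- rec
  rec2$replicate <- 1L
  scored <- score_wells(rec2, log_values = FALSE)
  scored$replicate <- rec$replicate
  smp <- scored[scored$well_anno == "sample" & scored$stimulated, , drop = FALSE]
  genes <- do.call(rbind, lapply(split(smp, smp$sirna_id), function(s) {
    data.frame(gene_symbol = s$gene_symbol[1], sirna_id = s$sirna_id[1],
               plate_id = s$plate_id[1],
               n_wells = sum(is.finite(s$zscore)),
               score = aggregate_primary(s$zscore, min_wells = min_wells),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  genes <- genes[order(genes$gene_symbol, genes$sirna_id), , drop = FALSE]
  list(wells = scored, genes = genes)
}

#' Score a secondary screen
#'
#' Runs the secondary analysis chain: ratio, per plate-replicate median
#' normalization, log2 transform (replicate distributions are closer to
#' normal on the log scale), robust z per plate-replicate, mean of the three
#' replicate z-scores per siRNA, and the median over the six siRNAs of each
#' gene as the gene score.
#'
#' @param dataset a secondary-tier [screen_dataset()].
#' @param min_replicates minimum usable replicates per siRNA (default 2).
#' @return list with `wells`, `sirnas` (per-siRNA mean z) and `genes`
#'   (per-gene `median_z`, `n_sirnas`).
#' @export
score_secondary <- function(dataset, min_replicates = 2L) {
  if (dataset$tier != "secondary")
    ds_abort("score_secondary expects a secondary-tier dataset", "scoring_error")
  scored <- score_wells(dataset$records, log_values = TRUE)
  smp <- scored[scored$well_anno == "sample" & scored$stimulated, , drop = FALSE]
  sirnas <- do.call(rbind, lapply(split(smp, smp$sirna_id), function(s) {
    z <- s$zscore[is.finite(s$zscore)]
    data.frame(sirna_id = s$sirna_id[1], gene_symbol = s$gene_symbol[1],
               n_replicates = length(z),
               zscore = if (length(z) >= min_replicates) mean(z) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(sirnas) <- NULL
  genes <- do.call(rbind, lapply(split(sirnas, sirnas$gene_symbol), function(g) {
    data.frame(gene_symbol = g$gene_symbol[1], n_sirnas = nrow(g),
               median_z = stats::median(g$zscore, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL
  bad <- genes$gene_symbol[genes$n_sirnas != 6L]
  if (length(bad))
    ds_warn(sprintf("%d gene(s) without exactly 6 siRNAs (e.g. %s)",
                    length(bad), bad[1]), "structural")
  list(wells = scored, sirnas = sirnas, genes = genes)
}

#' Export a score table with deposit column names
#'
#' Writes per-gene (primary) or per-siRNA/per-gene (secondary) scores using
#' the public deposit naming (`Zscore`, `ZscoreGeneMedian`, `ActivityScore`,
#' `Outcome`) so the output is directly diffable against a deposit export.
#'
#' @param scores result of [score_primary()] or [score_secondary()].
#' @param path output CSV path.
#' @param tier binning tier for activity scores.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path, tier = c("primary", "secondary")) {
  tier <- match.arg(tier)
  if (tier == "primary") {
    g <- scores$genes
    bin <- activity_score(g$score, tier = "primary")
    out <- data.frame(GeneSymbol = g$gene_symbol, siRNAID = g$sirna_id,
                      PlateID = g$plate_id, Zscore = g$score,
                      ActivityScore = bin$activity_score, Outcome = bin$outcome,
                      stringsAsFactors = FALSE)
  } else {
    s <- scores$sirnas
    med <- scores$genes$median_z[match(s$gene_symbol, scores$genes$gene_symbol)]
    bin <- activity_score(s$zscore, tier = "secondary")
    out <- data.frame(GeneSymbol = s$gene_symbol, siRNAID = s$sirna_id,
                      Zscore = s$zscore, ZscoreGeneMedian = med,
                      ActivityScore = bin$activity_score, Outcome = bin$outcome,
                      stringsAsFactors = FALSE)
  }
  utils::write.csv(format_for_csv(out), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
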