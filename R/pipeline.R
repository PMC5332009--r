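# End-to-end tier orchestration and deposit validation.

make_manifest <- function(tier, config, counts, qc_summary = NULL,
                          outputs = character()) {
  list(tier = tier, config_hash = config_hash(config), counts = counts,
       qc = qc_summary, outputs = outputs)
}

#' Run the primary-screen analysis end-to-end
#'
#' Validates the dataset, applies the four plate-acceptance gates (failing
#' plates are excluded and reported), scores the surviving plates
#' (per-plate median normalization, robust z, four-replicate mean), calls
#' hits at the configured thresholds and assigns activity scores. Gene
#' accounting reconciles: every input gene is either called, excluded,
#' unscorable or on an excluded plate.
#'
#' @param dataset a primary-tier [screen_dataset()] or a path readable by
#'   [read_screen_table()].
#' @param thresholds [qc_thresholds()] for plate acceptance.
#' @param theta_pos,theta_neg hit thresholds (defaults -1.5 / 2.8).
#' @param exclusions canonical-pathway genes flagged, not called.
#' @param strict_boundaries strict threshold inequalities (see
#'   [call_primary_hits()]).
#' @param waive_validation proceed despite validation-report violations.
#' @param out_dir optional directory for CSV exports (scores, hits, QC).
#' @return list: `scores`, `hits`, `qc`, `manifest`.
#' @export
run_primary <- function(dataset, thresholds = qc_thresholds(),
                        theta_pos = -1.5, theta_neg = 2.8,
                        exclusions = canonical_tlr4_genes(),
                        strict_boundaries = FALSE,
                        waive_validation = FALSE, out_dir = NULL) {
  if (is.character(dataset)) dataset <- read_screen_table(dataset, "primary")
  report <- validate_dataset(dataset)
  if (!attr(report, "valid") && !waive_validation)
    ds_abort(sprintf("dataset fails validation (%d violation(s), e.g. %s); use waive_validation = TRUE to proceed",
                     nrow(report), report$detail[1]), "validation_error")
  qc <- plate_acceptance(dataset, thresholds)
  keep <- qc$plate_id[qc$passed]
  if (!length(keep))
    ds_abort("all plates fail the acceptance gates", "pipeline_error")
  excluded_plates <- setdiff(qc$plate_id, keep)
  ds_kept <- dataset
  ds_kept$records <- dataset$records[dataset$records$plate_id %in% keep, ,
                                     drop = FALSE]
  scores <- score_primary(ds_kept)
  hits <- call_primary_hits(scores$genes[c("gene_symbol", "score")],
                            theta_pos = theta_pos, theta_neg = theta_neg,
                            exclusions = exclusions,
                            strict_boundaries = strict_boundaries)
  n_input <- length(unique(dataset$records$gene_symbol[
    dataset$records$well_anno == "sample"]))
  counts <- c(
    genes_input = n_input,
    genes_scored = sum(is.finite(scores$genes$score)),
    genes_unscorable = sum(!is.finite(scores$genes$score)),
    genes_on_excluded_plates = n_input - nrow(scores$genes),
    plates_total = nrow(qc), plates_excluded = length(excluded_plates),
    attr(hits, "counts")
  )
  outputs <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    outputs <- file.path(out_dir, c("primary_scores.csv", "primary_hits.csv",
                                    "primary_qc.csv"))
    write_score_table(scores, outputs[1], tier = "primary")
    utils::write.csv(format_for_csv(as.data.frame(hits)), outputs[2],
                     row.names = FALSE, quote = FALSE)
    write_qc_report(qc, outputs[3])
  }
  manifest <- make_manifest(
    "primary",
    list(thresholds = thresholds, theta_pos = theta_pos,
         theta_neg = theta_neg, exclusions = exclusions,
         strict_boundaries = strict_boundaries),
    counts, qc_summary = qc[c("plate_id", "passed")], outputs = outputs)
  list(scores = scores, hits = hits, qc = qc, validation = report,
       manifest = manifest)
}

#' Run the secondary-screen analysis end-to-end
#'
#' Scores a secondary-tier dataset (log2 plate-median-normalized robust z,
#' replicate mean per siRNA, six-siRNA gene median), checks replicate
#' correlations against a floor, applies the expression filter, and selects
#' the rank-based candidate lists.
#'
#' @param dataset a secondary-tier [screen_dataset()].
#' @param expression optional `expression_table` for the expressed-gene
#'   filter.
#' @param n_pos,n_neg candidate list sizes (26 / 13).
#' @param exclusions genes removed before selection (e.g. proteasome
#'   components).
#' @param p_cut expression detection-p cutoff (0.1).
#' @param corr_floor replicate-correlation floor; pairs below it raise a
#'   manifest warning (default 0.65).
#' @param out_dir optional export directory.
#' @return list: `scores`, `correlation`, `candidates`, `manifest`.
#' @export
run_secondary <- function(dataset, expression = NULL, n_pos = 26L, n_neg = 13L,
                          exclusions = character(), p_cut = 0.1,
                          corr_floor = 0.65, out_dir = NULL) {
  scores <- score_secondary(dataset)
  cc <- replicate_correlation(dataset)
  low <- cc[upper.tri(cc)] < corr_floor
  warnings <- character()
  if (any(low, na.rm = TRUE)) {
    warnings <- sprintf("replicate correlation below floor %.2f (min %.3f)",
                        corr_floor, min(cc[upper.tri(cc)], na.rm = TRUE))
    ds_warn(warnings, "replicate_correlation")
  }
  genes <- scores$genes
  dropped_expr <- character()
  if (!is.null(expression)) {
    ex <- is_expressed(expression, genes$gene_symbol, p_cut = p_cut)
    dropped_expr <- genes$gene_symbol[!is.na(ex) & !ex]
    genes <- genes[is.na(ex) | ex, , drop = FALSE]
  }
  cand <- select_secondary_candidates(
    genes, n_pos = n_pos, n_neg = n_neg, exclusions = exclusions,
    sirna_scores = scores$sirnas)
  counts <- c(genes_input = nrow(scores$genes),
              sirnas_input = nrow(scores$sirnas),
              genes_not_expressed = length(dropped_expr),
              genes_excluded = sum(scores$genes$gene_symbol %in% exclusions),
              candidates_positive = length(cand$positive),
              candidates_negative = length(cand$negative))
  outputs <- character()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    outputs <- file.path(out_dir, "secondary_scores.csv")
    write_score_table(scores, outputs, tier = "secondary")
  }
  manifest <- make_manifest(
    "secondary",
    list(n_pos = n_pos, n_neg = n_neg, exclusions = exclusions,
         p_cut = p_cut, corr_floor = corr_floor),
    counts, qc_summary = list(correlation = cc, warnings = warnings),
    outputs = outputs)
  list(scores = scores, correlation = cc, candidates = cand,
       not_expressed = dropped_expr, manifest = manifest)
}

#' Run the tertiary multi-ligand confirmation
#'
#' @param readouts per gene x stimulus replicate-averaged readouts (see
#'   [tertiary_classify()]).
#' @param ntc_readouts NTC readout per stimulus.
#' @param candidates list with `positive` and `negative` gene vectors from
#'   [run_secondary()]; confirmation is counted within each list.
#' @param reduce_cut,increase_cut confirmation cuts (0.30 / 0.25).
#' @return list: `results`, `confirmed_positive`, `confirmed_negative`,
#'   `manifest`.
#' @export
run_tertiary <- function(readouts, ntc_readouts, candidates,
                         reduce_cut = 0.30, increase_cut = 0.25) {
  res <- tertiary_classify(readouts, ntc_readouts, reduce_cut = reduce_cut,
                           increase_cut = increase_cut)
  cp <- res$gene_symbol[res$confirmed_positive &
                          res$gene_symbol %in% candidates$positive]
  cn <- res$gene_symbol[res$confirmed_negative &
                          res$gene_symbol %in% candidates$negative]
  counts <- c(candidates_positive = length(candidates$positive),
              candidates_negative = length(candidates$negative),
              confirmed_positive = length(cp), confirmed_negative = length(cn))
  manifest <- make_manifest(
    "tertiary", list(reduce_cut = reduce_cut, increase_cut = increase_cut),
    counts)
  list(results = res, confirmed_positive = cp, confirmed_negative = cn,
       manifest = manifest)
}

#' Recompute summary statistics from a deposit-schema export
#'
#' Reads a user-supplied per-well CSV export (no network access is ever
#' performed), reruns the tier's scoring chain and reports recomputed
#' library-level statistics side by side with any deposited `Zscore`
#' column: unique sample gene and siRNA counts, plate count, screen-average
#' replicate CV (primary), pairwise replicate correlations (secondary),
#' mean renilla knockdown, and threshold-passing gene counts. When the file
#' carries a deposited `Zscore`, the recomputed per-well z is compared
#' under both center/scale conventions (sample wells only vs all scorable
#' wells) and the better-matching convention is reported.
#'
#' @param path CSV export path.
#' @param tier `"primary"` or `"secondary"`.
#' @param theta_pos,theta_neg thresholds for the count summaries.
#' @return list of recomputed statistics.
#' @export
validate_deposit <- function(path, tier = c("primary", "secondary"),
                             theta_pos = -1.5, theta_neg = 2.8) {
  tier <- match.arg(tier)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  dataset <- read_screen_table(path, tier = tier)
  r <- dataset$records
  smp <- r[r$well_anno == "sample", , drop = FALSE]
  out <- list(
    n_genes = length(unique(smp$gene_symbol)),
    n_sirnas = length(unique(smp$sirna_id)),
    n_plates = length(unique(r$plate_id)),
    n_wells = nrow(r)
  )
  out$renilla_kd_mean <- tryCatch(
    mean(vapply(unique(r$plate_id), function(p)
      knockdown_efficiency(dataset, p), numeric(1))),
    dualscreen_error = function(e) NA_real_)
  if (tier == "primary") {
    cv <- replicate_cv(dataset)
    scores <- score_primary(dataset)
    hits <- call_primary_hits(scores$genes[c("gene_symbol", "score")],
                              theta_pos = theta_pos, theta_neg = theta_neg)
    out$screen_mean_cv <- cv$screen_mean
    out$n_positive <- unname(attr(hits, "counts")["positive"])
    out$n_negative <- unname(attr(hits, "counts")["negative"])
    out$scores <- scores$genes
    wells <- scores$wells
  } else {
    scores <- score_secondary(dataset)
    out$replicate_correlation <- replicate_correlation(dataset)
    out$n_positive <- sum(scores$genes$median_z <= theta_pos, na.rm = TRUE)
    out$n_negative <- sum(scores$genes$median_z >= theta_neg, na.rm = TRUE)
    out$scores <- scores$genes
    wells <- scores$wells
  }
  if ("Zscore" %in% names(raw) && tier == "primary") {
    dep <- as_num(raw$Zscore)
    key <- paste(raw$PlateID, toupper(raw$Well))
    rec_key <- paste(wells$plate_id, toupper(wells$well))
    recomputed <- wells$zscore[match(key, rec_key)]
    # alternative convention: center/scale over all scorable wells
    alt <- wells
    grp <- alt$plate_id
    for (g in unique(grp)) {
      i <- which(grp == g)
      use <- is.finite(alt$norm[i]) & alt$stimulated[i]
      if (sum(use) >= 8L)
        alt$zscore[i][use] <- robust_z(alt$norm[i], estimate_on = use)$z[use]
    }
    recomputed_all <- alt$zscore[match(key, rec_key)]
    d_smp <- stats::median(abs(recomputed - dep), na.rm = TRUE)
    d_all <- stats::median(abs(recomputed_all - dep), na.rm = TRUE)
    out$zscore_convention <- if (!is.na(d_all) && d_all < d_smp)
      "all_scorable_wells" else "sample_wells_only"
    out$zscore_median_abs_diff <- min(d_smp, d_all, na.rm = TRUE)
  }
  out
}
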