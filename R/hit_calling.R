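# Tiered hit selection: primary thresholds and exclusion lists, expression
# filtering, secondary rank-based candidate selection, tertiary multi-ligand
# confirmation, and deposit-style activity-score / outcome binning.

#' Default canonical-pathway exclusion list
#'
#' Known components of the canonical LPS/TLR4 signalling pathway that a
#' novel-regulator screen notes but does not carry into validation: the
#' receptor complex, TIR-domain adaptors and core downstream kinases. The
#' full exclusion list used for any given screen is study-specific and
#' should be supplied by the user; this default ships the universally
#' canonical members.
#'
#' @return character vector of gene symbols.
#' @export
canonical_tlr4_genes <- function() {
  c("TLR4", "LY96", "CD14", "MYD88", "TIRAP", "IRAK1", "IRAK4", "TRAF6",
    "MAP3K7", "TAB1", "TAB2", "IKBKG", "IKBKB", "CHUK", "NFKB1", "RELA")
}

#' Read a one-gene-per-line exclusion list
#'
#' @param path text file, one gene symbol per line (blank lines and `#`
#'   comments ignored).
#' @return character vector.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[x != "" & !startsWith(x, "#")]
}

#' Call primary-screen hits by score thresholds
#'
#' Positive regulators are genes whose knockdown lowers the induced reporter
#' score to `theta_pos` or below; negative regulators raise it to
#' `theta_neg` or above. Both thresholds are inclusive by default, following
#' the stated selection rule; `strict_boundaries = TRUE` switches to the
#' strict inequalities used by the deposit's activity-score bins. Genes on
#' the exclusion list keep their score but are flagged rather than called.
#'
#' @param scores data.frame with `gene_symbol` and `score` columns (as from
#'   `score_primary()$genes`), or a named numeric vector.
#' @param theta_pos positive-regulator threshold (default -1.5).
#' @param theta_neg negative-regulator threshold (default 2.8).
#' @param exclusions character vector of genes to flag (canonical pathway).
#' @param excluded_reason reason recorded for excluded genes.
#' @param strict_boundaries use strict `<` / `>` instead of `<=` / `>=`.
#' @return `hit_table` data.frame: `gene_symbol`, `score`, `call`,
#'   `excluded_reason`; attribute `counts` holds the class tally.
#' @export
call_primary_hits <- function(scores, theta_pos = -1.5, theta_neg = 2.8,
                              exclusions = character(),
                              excluded_reason = "canonical_pathway",
                              strict_boundaries = FALSE) {
  if (is.numeric(scores))
    scores <- data.frame(gene_symbol = names(scores), score = unname(scores),
                         stringsAsFactors = FALSE)
  ht <- data.frame(gene_symbol = scores$gene_symbol, score = scores$score,
                   call = "none", excluded_reason = "none",
                   stringsAsFactors = FALSE)
  pos <- if (strict_boundaries) ht$score < theta_pos else ht$score <= theta_pos
  neg <- if (strict_boundaries) ht$score > theta_neg else ht$score >= theta_neg
  ht$call[pos %in% TRUE] <- "positive_regulator"
  ht$call[neg %in% TRUE] <- "negative_regulator"
  ht$call[is.na(ht$score)] <- "none"
  excl <- ht$gene_symbol %in% exclusions
  ht$excluded_reason[excl] <- excluded_reason
  ht$call[excl] <- "none"
  attr(ht, "counts") <- c(
    positive = sum(ht$call == "positive_regulator"),
    negative = sum(ht$call == "negative_regulator"),
    excluded = sum(excl),
    none = sum(ht$call == "none" & !excl)
  )
  class(ht) <- c("hit_table", "data.frame")
  ht
}

#' Filter hits by macrophage expression calls
#'
#' A gene is considered expressed if its detection p-value is strictly below
#' `p_cut` in at least one of the two conditions (+/- LPS). Hits failing the
#' call in both conditions are re-flagged `not_expressed` and dropped from
#' the called set. Genes absent from the expression table are retained with
#' a warning (an unmeasured gene is not evidence of absence).
#'
#' @param hits a `hit_table` from [call_primary_hits()].
#' @param expr an `expression_table` from [read_expression_table()].
#' @param p_cut detection p cutoff (default 0.1, strict).
#' @return the filtered `hit_table`; attribute `unmeasured` lists genes not
#'   found in the expression table.
#' @export
expression_filter <- function(hits, expr, p_cut = 0.1) {
  ex <- is_expressed(expr, hits$gene_symbol, p_cut = p_cut)
  unmeasured <- hits$gene_symbol[is.na(ex)]
  if (length(unmeasured))
    ds_warn(sprintf("%d hit gene(s) absent from the expression table retained (e.g. %s)",
                    length(unmeasured), unmeasured[1]), "unmeasured_gene")
  drop <- !is.na(ex) & !ex & hits$call != "none"
  hits$excluded_reason[drop] <- "not_expressed"
  hits$call[drop] <- "none"
  attr(hits, "unmeasured") <- unmeasured
  attr(hits, "counts") <- c(
    positive = sum(hits$call == "positive_regulator"),
    negative = sum(hits$call == "negative_regulator"),
    not_expressed = sum(drop)
  )
  hits
}

#' Select secondary-screen candidates by rank
#'
#' After removing excluded genes (e.g. proteasome components), selects the
#' `n_pos` genes with the lowest gene-median z-scores as candidate positive
#' regulators and the `n_neg` genes with the highest as candidate negative
#' regulators. Ties at the cut are broken deterministically by (a) the
#' number of supporting siRNAs beyond the tier threshold, then (b)
#' lexicographic gene symbol.
#'
#' @param gene_scores data.frame with `gene_symbol` and `median_z` (as from
#'   `score_secondary()$genes`).
#' @param n_pos,n_neg list sizes (defaults 26 and 13).
#' @param exclusions genes removed before ranking (proteasome list etc.).
#' @param sirna_scores optional per-siRNA table (`gene_symbol`, `zscore`)
#'   used for the support tie-break.
#' @param support_theta_pos,support_theta_neg siRNA-level thresholds that
#'   define "supporting" (defaults -1.5 / 2.8).
#' @return list with `positive` and `negative` character vectors and the
#'   ranked `table`.
#' @export
select_secondary_candidates <- function(gene_scores, n_pos = 26L, n_neg = 13L,
                                        exclusions = character(),
                                        sirna_scores = NULL,
                                        support_theta_pos = -1.5,
                                        support_theta_neg = 2.8) {
  g <- gene_scores[!(gene_scores$gene_symbol %in% exclusions) &
                     is.finite(gene_scores$median_z), , drop = FALSE]
  if (n_pos + n_neg > nrow(g))
    ds_abort(sprintf("cannot select %d + %d candidates from %d scored genes",
                     n_pos, n_neg, nrow(g)), "selection_error")
  support <- function(theta, lower) {
    if (is.null(sirna_scores)) return(rep(0L, nrow(g)))
    n <- tapply(sirna_scores$zscore, sirna_scores$gene_symbol, function(z) {
      if (lower) sum(z <= theta, na.rm = TRUE) else sum(z >= theta, na.rm = TRUE)
    })
    out <- n[g$gene_symbol]
    out[is.na(out)] <- 0L
    as.integer(out)
  }
  sup_pos <- support(support_theta_pos, lower = TRUE)
  sup_neg <- support(support_theta_neg, lower = FALSE)
  ord_pos <- order(g$median_z, -sup_pos, g$gene_symbol)
  ord_neg <- order(-g$median_z, -sup_neg, g$gene_symbol)
  positive <- g$gene_symbol[utils::head(ord_pos, n_pos)]
  negative <- g$gene_symbol[utils::head(ord_neg, n_neg)]
  if (length(intersect(positive, negative)))
    ds_warn("positive and negative candidate lists overlap; reduce n_pos/n_neg",
            "selection")
  g$candidate <- ifelse(g$gene_symbol %in% positive, "positive",
                        ifelse(g$gene_symbol %in% negative, "negative", "none"))
  list(positive = positive, negative = negative, table = g)
}

#' Classify tertiary multi-ligand confirmation
#'
#' For each candidate gene the fractional effect under each stimulus is
#' `F = readout / NTC readout` (non-targeting control under the same
#' stimulus). A positive-regulator candidate is confirmed when at least one
#' stimulus other than the reference ligand shows a signal reduction greater
#' than `reduce_cut` (`1 - F > 0.30`); a negative-regulator candidate when
#' at least one shows an increase greater than `increase_cut`
#' (`F - 1 > 0.25`).
#'
#' @param readouts data.frame with `gene_symbol`, `stimulus`, `value`
#'   (replicate-averaged reporter ratio per gene x stimulus).
#' @param ntc_readouts data.frame with `stimulus`, `value` for the NTC
#'   control under each stimulus.
#' @param reduce_cut fractional reduction required (default 0.30).
#' @param increase_cut fractional increase required (default 0.25).
#' @param reference_stimulus stimulus excluded from confirmation counting
#'   (default `"LPS"`, the ligand the candidates were selected under).
#' @return data.frame per gene: `confirmed_positive`, `confirmed_negative`,
#'   `supporting_stimuli_pos`, `supporting_stimuli_neg`, plus one
#'   `F_<stimulus>` column per stimulus.
#' @export
tertiary_classify <- function(readouts, ntc_readouts, reduce_cut = 0.30,
                              increase_cut = 0.25,
                              reference_stimulus = "LPS") {
  if (any(!is.finite(ntc_readouts$value) | ntc_readouts$value <= 0))
    ds_abort("NTC readout must be positive for every stimulus", "qc_error")
  stimuli <- unique(readouts$stimulus)
  no_ntc <- setdiff(stimuli, ntc_readouts$stimulus)
  if (length(no_ntc)) {
    ds_warn(sprintf("stimulus(es) without NTC readout dropped: %s",
                    paste(no_ntc, collapse = ", ")), "missing_control")
    readouts <- readouts[!(readouts$stimulus %in% no_ntc), , drop = FALSE]
    stimuli <- setdiff(stimuli, no_ntc)
  }
  if (!length(setdiff(stimuli, reference_stimulus)))
    ds_abort("tertiary panel needs at least one stimulus beyond the reference ligand",
             "qc_error")
  ntc <- stats::setNames(ntc_readouts$value, ntc_readouts$stimulus)
  readouts$F <- readouts$value / ntc[readouts$stimulus]
  res <- do.call(rbind, lapply(split(readouts, readouts$gene_symbol), function(d) {
    extra <- d[d$stimulus != reference_stimulus, , drop = FALSE]
    red <- extra$stimulus[(1 - extra$F) > reduce_cut]
    inc <- extra$stimulus[(extra$F - 1) > increase_cut]
    row <- data.frame(gene_symbol = d$gene_symbol[1],
                      confirmed_positive = length(red) > 0L,
                      confirmed_negative = length(inc) > 0L,
                      supporting_stimuli_pos = paste(red, collapse = ";"),
                      supporting_stimuli_neg = paste(inc, collapse = ";"),
                      stringsAsFactors = FALSE)
    for (s in stimuli) row[[paste0("F_", s)]] <-
        if (s %in% d$stimulus) d$F[match(s, d$stimulus)] else NA_real_
    row
  }))
  rownames(res) <- NULL
  res
}

# bin definitions: (score, neg bound, pos bound) -- score assigned when
# z > pos bound or z < neg bound, strict, highest bin wins.
.activity_bins <- list(
  primary = list(c(100, -2.5, 5), c(75, -2, 4), c(50, -1.5, 2.8), c(25, -1, 1)),
  secondary = list(c(100, -2, 2.5), c(75, -1.5, 2), c(50, -1, 1.5), c(25, -0.75, 1))
)

#' Deposit-style activity score and outcome binning
#'
#' Maps a z-score to the public deposit's activity score. For the primary
#' tier: 0 for z between -1 and 1; 25 for z > 1 or z < -1; 50 for z > 2.8
#' or z < -1.5; 75 for z > 4 or z < -2; 100 for z > 5 or z < -2.5. The
#' secondary tier uses bounds (-0.75, 1), (-1, 1.5), (-1.5, 2), (-2, 2.5).
#' All inequalities are strict and the highest bin whose inequality holds
#' is assigned. The outcome is 2 ("active") when the activity score is at
#' least 50 (the bin whose bounds equal the tier's hit thresholds) and 1
#' otherwise; control wells are assigned score 0 and outcome 4.
#'
#' @param z numeric z-score vector.
#' @param tier `"primary"` or `"secondary"`.
#' @param control logical vector: control wells bypass binning.
#' @param active_min minimum activity score for outcome "active" (default 50).
#' @return data.frame with `activity_score` and `outcome`.
#' @export
activity_score <- function(z, tier = c("primary", "secondary"),
                           control = FALSE, active_min = 50) {
  tier <- match.arg(tier)
  bins <- .activity_bins[[tier]]
  control <- rep_len(control, length(z))
  score <- numeric(length(z))
  for (b in rev(bins)) score[!is.na(z) & (z > b[3] | z < b[2])] <- b[1]
  score[is.na(z)] <- NA_real_
  outcome <- ifelse(is.na(score), NA_real_, ifelse(score >= active_min, 2, 1))
  score[control] <- 0
  outcome[control] <- 4
  data.frame(activity_score = score, outcome = outcome)
}
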