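# Synthetic dual-luciferase screen generator with planted ground truth.
#
# The readout model is multiplicative: both luminescence channels share a
# lognormal viability component (which the R1/R2 ratio cancels -- the
# purpose of the constitutive renilla channel), the renilla channel carries
# plate and positional artifacts, and the firefly channel adds the LPS
# induction, the planted gene effect and lognormal measurement noise.

#' Simulation configuration for synthetic screens
#'
#' Defaults emulate the study conditions of a genome-scale dual-luciferase
#' TLR4 screen: 10 ng/ml LPS driving a ten-fold reporter induction
#' (comfortably past the five-fold QC gate), replicate noise CV 0.15
#' (matching the observed screen-average replicate CV of 0.145), a renilla
#' knockdown control retaining 5% of the constitutive signal (95% knockdown,
#' matching the observed 96% efficiency against its 85% gate) and a
#' receptor-knockdown positive control retaining 10% of the induced signal
#' (90% reduction against its 85% gate). Planted regulator effects multiply
#' the induced signal: positive-regulator knockdowns draw U(0.1, 0.6),
#' negative-regulator knockdowns U(1.8, 4).
#'
#' @param n_genes genes in the simulated library.
#' @param induction_fold LPS induction of the reporter ratio (default 10).
#' @param baseline_r2 constitutive renilla counts (default 20000).
#' @param basal_ratio unstimulated R1/R2 ratio (default 0.1).
#' @param noise_cv replicate (measurement) CV of the ratio (default 0.15).
#' @param viability_cv CV of the shared viability component (default 0.2).
#' @param frac_pos,frac_neg fractions of planted positive/negative regulators.
#' @param pos_effect_range,neg_effect_range uniform effect-multiplier ranges.
#' @param renilla_kd_effect fraction of R2 remaining under siRenilla (0.05).
#' @param tlr4_effect,irak1_effect,ikbkg_effect,map3k7_effect fraction of the
#'   induced signal remaining under each positive-control knockdown.
#' @param ote_rate probability a secondary siRNA acquires an off-target effect.
#' @param efficacy_range per-siRNA on-target efficacy range (secondary tier).
#' @param plate_factor_sd lognormal sd of the per-plate (or per-week) factor.
#' @param edge_gradient total fractional depth of a multiplicative
#'   column-wise linear trend (0 = no artifact).
#' @param expressed_fraction fraction of genes expressed (detection p < 0.1
#'   in at least one condition) in the simulated expression table.
#' @param dose_folds named induction folds for uniformity plates (H/M/L).
#' @param seed RNG seed; generation is a pure function of (config, seed).
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 80L, induction_fold = 10, baseline_r2 = 20000,
                       basal_ratio = 0.1, noise_cv = 0.15, viability_cv = 0.2,
                       frac_pos = 0, frac_neg = 0,
                       pos_effect_range = c(0.1, 0.6),
                       neg_effect_range = c(1.8, 4),
                       renilla_kd_effect = 0.05, tlr4_effect = 0.10,
                       irak1_effect = 0.25, ikbkg_effect = 0.20,
                       map3k7_effect = 0.25,
                       ote_rate = 0, efficacy_range = c(0.75, 1),
                       plate_factor_sd = 0.1, edge_gradient = 0,
                       expressed_fraction = 0.9,
                       dose_folds = c(H = 10, M = 5, L = 1),
                       seed = 1L) {
  cfg <- as.list(environment())
  fr <- c(frac_pos = frac_pos, frac_neg = frac_neg,
          expressed_fraction = expressed_fraction, ote_rate = ote_rate)
  if (any(fr < 0 | fr > 1))
    ds_abort("fractions must lie in [0, 1]", "config_error")
  if (induction_fold < 1 || any(c(pos_effect_range, neg_effect_range) <= 0) ||
      baseline_r2 <= 0 || basal_ratio <= 0)
    ds_abort("effects, induction and baselines must be positive", "config_error")
  if (noise_cv < 0 || viability_cv < 0 || plate_factor_sd < 0 ||
      edge_gradient < 0 || edge_gradient >= 1)
    ds_abort("noise, plate factor and edge gradient must be >= 0 (gradient < 1)",
             "config_error")
  structure(cfg, class = "sim_config")
}

#' Read or write a simulation config as YAML
#' @param path file path.
#' @return `read_sim_config` returns a [sim_config()].
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' @rdname read_sim_config
#' @param config a [sim_config()].
#' @export
write_sim_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

edge_factor <- function(col, gradient) 1 - gradient * (col - 1) / 23

# Draw per-gene classes and effect multipliers.
draw_gene_truth <- function(genes, cfg) {
  n <- length(genes)
  cls <- rep("null", n)
  n_pos <- round(cfg$frac_pos * n)
  n_neg <- round(cfg$frac_neg * n)
  idx <- sample.int(n, n_pos + n_neg)
  cls[idx[seq_len(n_pos)]] <- "positive"
  if (n_neg) cls[idx[n_pos + seq_len(n_neg)]] <- "negative"
  effect <- rep(1, n)
  effect[cls == "positive"] <- stats::runif(sum(cls == "positive"),
                                            cfg$pos_effect_range[1],
                                            cfg$pos_effect_range[2])
  effect[cls == "negative"] <- stats::runif(sum(cls == "negative"),
                                            cfg$neg_effect_range[1],
                                            cfg$neg_effect_range[2])
  data.frame(gene_symbol = genes, class = cls, effect = effect,
             stringsAsFactors = FALSE)
}

control_effect <- function(anno, cfg) {
  switch(anno,
         siTLR4 = cfg$tlr4_effect, siIRAK1 = cfg$irak1_effect,
         siIKBKG = cfg$ikbkg_effect, siMAP3K7 = cfg$map3k7_effect,
         1)
}

# Emit luminescence for a block of wells given per-well effect multipliers.
emit_readouts <- function(df, cfg, plate_factor, renilla_effect, effect) {
  n <- nrow(df)
  viab <- rlnorm_cv(n, cfg$viability_cv)
  noise <- rlnorm_cv(n, cfg$noise_cv)
  # viability hits both channels (and cancels in the ratio); plate/week and
  # positional artifacts perturb the reporter response, so they survive into
  # the ratio and are what median normalization / uniformity testing target
  r2 <- cfg$baseline_r2 * viab * renilla_effect
  ind <- ifelse(df$stimulus == "none", 1, cfg$induction_fold * effect)
  r1 <- r2 * cfg$basal_ratio * ind * plate_factor *
    edge_factor(df$col, cfg$edge_gradient) * noise
  df$r1 <- r1
  df$r2 <- r2
  df
}

# Control-column layout shared by the generators. Returns a data.frame of
# control wells (well_anno, stimulus) for one plate.
primary_control_wells <- function() {
  blocks <- list(
    list(col = 10L, rows = 1:3, anno = "NTC", stim = "LPS"),
    list(col = 10L, rows = 4:6, anno = "NTC", stim = "none"),
    list(col = 10L, rows = 7:9, anno = "siRenilla", stim = "none"),
    list(col = 10L, rows = 10:12, anno = "siTLR4", stim = "LPS"),
    list(col = 10L, rows = 13:15, anno = "lipid_only", stim = "LPS"),
    list(col = 10L, rows = 16L, anno = "NTC", stim = "LPS"),
    list(col = 11L, rows = 1:3, anno = "siIRAK1", stim = "LPS"),
    list(col = 11L, rows = 4:6, anno = "siIKBKG", stim = "LPS"),
    list(col = 11L, rows = 7:9, anno = "siMAP3K7", stim = "LPS"),
    list(col = 11L, rows = 10:16, anno = "NTC", stim = "LPS"),
    list(col = 24L, rows = 1:16, anno = "NTC", stim = "LPS")
  )
  do.call(rbind, lapply(blocks, function(b)
    data.frame(row = b$rows, col = b$col, well_anno = b$anno,
               stimulus = b$stim, stringsAsFactors = FALSE)))
}

secondary_control_wells <- function() {
  blocks <- list(
    list(col = 11L, rows = 3:5, anno = "NTC", stim = "LPS"),
    list(col = 11L, rows = 6:8, anno = "NTC", stim = "none"),
    list(col = 11L, rows = 9:11, anno = "siRenilla", stim = "none"),
    list(col = 11L, rows = 12:14, anno = "siTLR4", stim = "LPS"),
    list(col = 12L, rows = 3:5, anno = "siIRAK1", stim = "LPS"),
    list(col = 12L, rows = 6:8, anno = "siIKBKG", stim = "LPS"),
    list(col = 12L, rows = 9:11, anno = "siMAP3K7", stim = "LPS"),
    list(col = 12L, rows = 12:14, anno = "NTC", stim = "LPS"),
    list(col = 13L, rows = 3:14, anno = "NTC", stim = "LPS"),
    list(col = 22L, rows = 3:14, anno = "NTC", stim = "LPS")
  )
  do.call(rbind, lapply(blocks, function(b)
    data.frame(row = b$rows, col = b$col, well_anno = b$anno,
               stimulus = b$stim, stringsAsFactors = FALSE)))
}

control_id <- function(anno) {
  c(NTC = "D-001210-05", siRenilla = "siRenilla-custom",
    siTLR4 = "M-008088-01", siIRAK1 = "M-004760-03", siIKBKG = "M-003767-02",
    siMAP3K7 = "S100300741", lipid_only = "", empty = "")[anno]
}

build_plate_frame <- function(plate_id, sample_map, control_map, scheme) {
  ctrl <- control_map
  ctrl$plate_id <- plate_id
  ctrl$gene_symbol <- ""
  ctrl$entrez_id <- ""
  ctrl$sirna_id <- unname(control_id(ctrl$well_anno))
  grid <- expand.grid(row = 1:16, col = 1:24)
  used <- paste(c(sample_map$row, ctrl$row), c(sample_map$col, ctrl$col))
  emp <- grid[!(paste(grid$row, grid$col) %in% used), , drop = FALSE]
  empty <- data.frame(row = emp$row, col = emp$col, well_anno = "empty",
                      stimulus = "none", plate_id = plate_id, gene_symbol = "",
                      entrez_id = "", sirna_id = "", stringsAsFactors = FALSE)
  sm <- sample_map
  sm$plate_id <- plate_id
  cols <- c("plate_id", "row", "col", "well_anno", "stimulus", "gene_symbol",
            "entrez_id", "sirna_id")
  out <- rbind(sm[cols], ctrl[cols], empty[cols])
  out$well <- well_name(out$row, out$col)
  out[order(out$col, out$row), , drop = FALSE]
}

#' Generate a synthetic primary screen with planted truth
#'
#' Emits 384-well plates in the primary layout (samples in columns 2--9 and
#' 12--23, controls in columns 10, 11 and 24, column 1 unused) with four
#' replicate wells per siRNA SMARTpool (80 SMARTpools per plate), planted
#' regulator effects, per-plate factors, optional positional artifacts and
#' the full control complement.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a [screen_dataset()]) and `truth` (list of
#'   `genes`, `plates`, `config`).
#' @export
generate_primary_screen <- function(config = sim_config()) {
  scheme <- control_scheme("primary")
  per_plate <- length(scheme$sample_columns) * 16L / 4L  # 80 SMARTpools
  n_plates <- ceiling(config$n_genes / per_plate)
  with_seed(config$seed, {
    genes <- sprintf("GENE%05d", seq_len(config$n_genes))
    truth_genes <- draw_gene_truth(genes, config)
    plate_factors <- rlnorm_cv(n_plates, config$plate_factor_sd)
    ctrl_map <- primary_control_wells()
    plates <- lapply(seq_len(n_plates), function(p) {
      gi <- seq((p - 1L) * per_plate + 1L, min(p * per_plate, config$n_genes))
      pg <- truth_genes[gi, , drop = FALSE]
      grid <- expand.grid(row = 1:16, col = scheme$sample_columns)
      grid <- grid[order(grid$col, grid$row), ]
      nwell <- 4L * nrow(pg)
      sm <- grid[seq_len(nwell), , drop = FALSE]
      k <- rep(seq_len(nrow(pg)), each = 4L)
      sm$well_anno <- "sample"
      sm$stimulus <- "LPS"
      sm$gene_symbol <- pg$gene_symbol[k]
      sm$entrez_id <- as.character(match(pg$gene_symbol[k], genes))
      sm$sirna_id <- sprintf("M-%06d-01", match(pg$gene_symbol[k], genes))
      plate_id <- sprintf("P%03d", p)
      fr <- build_plate_frame(plate_id, sm, ctrl_map, scheme)
      eff <- ifelse(fr$well_anno == "sample",
                    truth_genes$effect[match(fr$gene_symbol, truth_genes$gene_symbol)],
                    vapply(fr$well_anno, control_effect, numeric(1), cfg = config))
      eff[is.na(eff)] <- 1
      ren <- ifelse(fr$well_anno == "siRenilla", config$renilla_kd_effect, 1)
      fr <- emit_readouts(fr, config, plate_factors[p], ren, eff)
      fr$r1[fr$well_anno == "empty"] <- NA_real_
      fr$r2[fr$well_anno == "empty"] <- NA_real_
      fr
    })
    rec <- do.call(rbind, plates)
    rec$replicate <- stats::ave(seq_len(nrow(rec)),
                                paste(rec$plate_id, rec$well_anno, rec$sirna_id),
                                FUN = seq_along)
    ds <- screen_dataset(rec, tier = "primary", scheme = scheme,
                         provenance = "synthetic primary screen")
    list(dataset = ds,
         truth = list(genes = truth_genes,
                      plates = data.frame(plate_id = sprintf("P%03d", seq_len(n_plates)),
                                          plate_factor = plate_factors),
                      config = config))
  })
}

#' Generate a synthetic secondary screen
#'
#' Emits the secondary-tier geometry: six independent siRNAs per candidate
#' gene (32 genes per plate; a gene's six siRNAs are dispersed across plate
#' regions), three replicate plate copies with independent week factors, and
#' the outer-frame-empty control layout (controls in columns 11, 12, 13 and
#' 22). Each siRNA draws an independent on-target efficacy; with probability
#' `ote_rate` (or for genes listed in `force_ote_genes`, exactly one siRNA)
#' an off-target effect from the positive-regulator effect distribution is
#' planted on a single siRNA.
#'
#' @param config a [sim_config()].
#' @param genes candidate gene symbols to screen.
#' @param truth optional primary-screen truth; candidate genes inherit their
#'   planted class and effect from it.
#' @param force_ote_genes genes given exactly one off-target siRNA each.
#' @return list with `dataset` and `truth` (`genes`, `sirnas`, `weeks`).
#' @export
generate_secondary_screen <- function(config = sim_config(), genes,
                                      truth = NULL,
                                      force_ote_genes = character()) {
  scheme <- control_scheme("secondary")
  if (!length(genes)) {
    rec <- data.frame(plate_id = character(), well = character(),
                      gene_symbol = character(), entrez_id = character(),
                      sirna_id = character(), well_anno = character(),
                      stimulus = character(), replicate = integer(),
                      r1 = numeric(), r2 = numeric(), stringsAsFactors = FALSE)
    return(list(dataset = screen_dataset(rec, tier = "secondary", scheme = scheme,
                                         provenance = "synthetic secondary screen (empty)"),
                truth = list(genes = NULL, sirnas = NULL)))
  }
  per_plate <- 32L
  n_plates <- ceiling(length(genes) / per_plate)
  with_seed(config$seed + 1L, {
    gt <- if (!is.null(truth)) {
      i <- match(genes, truth$genes$gene_symbol)
      data.frame(gene_symbol = genes,
                 class = ifelse(is.na(i), "null", truth$genes$class[i]),
                 effect = ifelse(is.na(i), 1, truth$genes$effect[i]),
                 stringsAsFactors = FALSE)
    } else draw_gene_truth(genes, config)
    # per-siRNA truth: efficacy blends the gene effect toward no effect
    st <- data.frame(
      sirna_id = sprintf("s%05d_%d", rep(seq_along(genes), each = 6L), 1:6),
      gene_symbol = rep(genes, each = 6L),
      sirna_number = rep(1:6, length(genes)),
      efficacy = stats::runif(6L * length(genes), config$efficacy_range[1],
                              config$efficacy_range[2]),
      ote_effect = NA_real_, stringsAsFactors = FALSE
    )
    ote <- stats::runif(nrow(st)) < config$ote_rate
    for (g in force_ote_genes) {
      j <- which(st$gene_symbol == g)
      ote[j] <- FALSE
      ote[sample(j, 1L)] <- TRUE
    }
    st$ote_effect[ote] <- stats::runif(sum(ote), config$pos_effect_range[1],
                                       config$pos_effect_range[2])
    gene_eff <- gt$effect[match(st$gene_symbol, gt$gene_symbol)]
    st$realized_effect <- (1 + st$efficacy * (gene_eff - 1)) *
      ifelse(is.na(st$ote_effect), 1, st$ote_effect)

    week_factors <- rlnorm_cv(3L, config$plate_factor_sd)
    ctrl_map <- secondary_control_wells()
    rows <- 3:14
    cols <- scheme$sample_columns
    grid <- expand.grid(row = rows, col = cols)
    grid <- grid[order(grid$col, grid$row), ]
    plates <- list()
    for (p in seq_len(n_plates)) {
      gi <- seq((p - 1L) * per_plate + 1L, min(p * per_plate, length(genes)))
      pg <- genes[gi]
      ps <- st[st$gene_symbol %in% pg, , drop = FALSE]
      # disperse: position index i gets gene (i-1) %% n_genes + 1, siRNA block
      n_g <- length(pg)
      idx <- order(ps$sirna_number, match(ps$gene_symbol, pg))
      ps <- ps[idx, , drop = FALSE]
      sm <- grid[seq_len(nrow(ps)), , drop = FALSE]
      sm$well_anno <- "sample"
      sm$stimulus <- "LPS"
      sm$gene_symbol <- ps$gene_symbol
      sm$entrez_id <- as.character(match(ps$gene_symbol, genes))
      sm$sirna_id <- ps$sirna_id
      plate_id <- sprintf("S%03d", p)
      fr0 <- build_plate_frame(plate_id, sm, ctrl_map, scheme)
      for (w in 1:3) {
        fr <- fr0
        eff <- ifelse(fr$well_anno == "sample",
                      st$realized_effect[match(fr$sirna_id, st$sirna_id)],
                      vapply(fr$well_anno, control_effect, numeric(1),
                             cfg = config))
        eff[is.na(eff)] <- 1
        ren <- ifelse(fr$well_anno == "siRenilla", config$renilla_kd_effect, 1)
        fr <- emit_readouts(fr, config, week_factors[w], ren, eff)
        fr$r1[fr$well_anno == "empty"] <- NA_real_
        fr$r2[fr$well_anno == "empty"] <- NA_real_
        fr$replicate <- w
        plates[[length(plates) + 1L]] <- fr
      }
    }
    rec <- do.call(rbind, plates)
    ds <- screen_dataset(rec, tier = "secondary", scheme = scheme,
                         provenance = "synthetic secondary screen")
    list(dataset = ds,
         truth = list(genes = gt, sirnas = st,
                      weeks = data.frame(replicate = 1:3,
                                         week_factor = week_factors),
                      config = config))
  })
}

#' Generate plate-uniformity assessment plates
#'
#' Emits three full 384-well NTC plates dosed in the alternating
#' two-column High/Medium/Low pattern, staggered across the replicate
#' plates (plate 1 starts H,H,M,M,L,L; plate 2 starts M; plate 3 starts L),
#' with dose-dependent induction given by `config$dose_folds`.
#'
#' @param config a [sim_config()].
#' @return list with `dataset` and `dose_map` (data.frame `plate_id`,
#'   `well`, `dose`).
#' @export
generate_uniformity_plates <- function(config = sim_config()) {
  base <- rep(c("H", "H", "M", "M", "L", "L"), 4L)
  with_seed(config$seed + 2L, {
    plates <- lapply(1:3, function(p) {
      dose_by_col <- base[((seq_len(24L) - 1L + 2L * (p - 1L)) %% 6L) + 1L]
      grid <- expand.grid(row = 1:16, col = 1:24)
      grid <- grid[order(grid$col, grid$row), ]
      grid$dose <- dose_by_col[grid$col]
      grid$plate_id <- sprintf("U%d", p)
      grid$well_anno <- "NTC"
      grid$stimulus <- ifelse(grid$dose == "L", "none", "LPS")
      grid$gene_symbol <- ""
      grid$entrez_id <- ""
      grid$sirna_id <- "D-001210-05"
      fold <- config$dose_folds[grid$dose] / config$induction_fold
      # dose scales the induced signal; L (no LPS) wells sit at basal level
      eff <- ifelse(grid$dose == "L", 1, fold)
      fr <- emit_readouts(grid, config, plate_factor = 1,
                          renilla_effect = 1, effect = eff)
      fr$well <- well_name(fr$row, fr$col)
      fr
    })
    rec <- do.call(rbind, plates)
    rec$replicate <- 1L
    ds <- screen_dataset(
      rec[c("plate_id", "well", "gene_symbol", "entrez_id", "sirna_id",
            "well_anno", "stimulus", "replicate", "r1", "r2")],
      tier = "primary",
      scheme = control_scheme("primary", sample_columns = integer(),
                              control_columns = 1:24,
                              empty_columns = integer()),
      provenance = "synthetic uniformity plates")
    list(dataset = ds,
         dose_map = data.frame(plate_id = rec$plate_id, well = rec$well,
                               dose = rec$dose, stringsAsFactors = FALSE))
  })
}

#' Generate a synthetic two-condition expression table
#'
#' A configurable fraction of genes is expressed: expressed genes receive a
#' detection p-value below 0.1 in at least one condition (and a high log2
#' signal there); non-expressed genes receive p in (0.1, 1) in both.
#'
#' @param genes character vector of gene symbols.
#' @param config a [sim_config()] (`expressed_fraction`, `seed`).
#' @return an `expression_table`.
#' @export
generate_expression_table <- function(genes, config = sim_config()) {
  with_seed(config$seed + 3L, {
    n <- length(genes)
    expressed <- stats::runif(n) < config$expressed_fraction
    which_cond <- sample(c("unstim", "lps", "both"), n, replace = TRUE,
                         prob = c(0.2, 0.3, 0.5))
    p_un <- stats::runif(n, 0.1, 1)
    p_lps <- stats::runif(n, 0.1, 1)
    hit_un <- expressed & which_cond %in% c("unstim", "both")
    hit_lps <- expressed & which_cond %in% c("lps", "both")
    p_un[hit_un] <- stats::runif(sum(hit_un), 0, 0.0999)
    p_lps[hit_lps] <- stats::runif(sum(hit_lps), 0, 0.0999)
    df <- data.frame(
      gene_symbol = genes,
      log2_unstim = ifelse(hit_un, stats::runif(n, 7, 14), stats::runif(n, 4, 7)),
      log2_lps = ifelse(hit_lps, stats::runif(n, 7, 14), stats::runif(n, 4, 7)),
      p_unstim = p_un, p_lps = p_lps, stringsAsFactors = FALSE
    )
    structure(df, class = c("expression_table", "data.frame"),
              expressed = stats::setNames(expressed, genes))
  })
}

#' Write the planted truth of a synthetic screen as CSV
#'
#' @param truth truth list from a generator.
#' @param path output CSV path (gene-level truth).
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.csv(format_for_csv(truth$genes), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
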