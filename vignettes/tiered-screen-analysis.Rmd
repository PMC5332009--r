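---
title: "Tiered analysis of dual-luciferase siRNA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tiered analysis of dual-luciferase siRNA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualscreen)
```

## The assay and its statistical model

`dualscreen` analyses tiered RNAi screens read out with a two-reporter
luciferase assay in 384-well plates. Each well carries two luminescence
measurements: R1, firefly luciferase driven by an inducible promoter (here
the *TNF* promoter responding to LPS/TLR4 stimulation), and R2, renilla
luciferase driven by a constitutive promoter (*UBC*). Perturbations that
kill cells or block transfection depress both channels; the ratio R1/R2
therefore cancels cell number and viability and isolates the transcriptional
response. Everything downstream operates on this ratio.

The analysis chain is deliberately simple and robust:

1. **Per-plate median normalization.** Each plate's ratios are divided by
   the median of that plate's *sample* wells, absorbing plate-to-plate
   scale (reagent batches, reader drift, week effects). Controls are
   divided by the same sample median so they stay on the samples' scale.
2. **Robust z-score.** Within each plate replicate,
   `z = (x − median) / (1.4826 · MAD)`, with center and scale estimated on
   sample wells only and then applied to controls. The MAD-based scale is
   insensitive to the very hits the screen is looking for; the constant
   1.4826 makes the scale consistent with the standard deviation under
   normality. A zero MAD falls back to the standard deviation with a
   warning; a constant (noise-free) plate yields exact zeros for its
   sample wells.
3. **Tier-specific aggregation.**
   - *Primary tier:* each siRNA SMARTpool occupies four replicate wells of
     one plate (within-plate replication correlates better than
     across-plate in this assay), and the gene score is the arithmetic
     mean of the four well z-scores. Wells flagged as invalid (zero
     renilla, non-positive normalized value) drop out of the mean; fewer
     than two usable wells renders the gene unscorable rather than scored
     from a single well.
   - *Secondary tier:* six independent siRNA sequences per gene, each run
     once per plate across three replicate plate copies in successive
     weeks. Values are log2-transformed after normalization (replicate
     distributions are visibly closer to normal on the log scale), scored
     per plate replicate, averaged over the three replicates per siRNA,
     and the **median of the six per-siRNA scores** is the gene score.
     With six values the median averages the 3rd and 4th order statistics,
     so a single rogue siRNA — the signature of a seed-driven off-target
     effect — cannot move the gene call. This robustness is the entire
     reason the secondary tier exists, and it is asserted directly in the
     test suite.

Primary-tier z-scores are computed on unlogged normalized ratios and
secondary-tier scores on logged ones, mirroring where the log transform
demonstrably helps; both choices are fixed per tier rather than
configurable, because mixing them breaks comparability of the thresholds
below.

## Hit calling

Positive regulators (knockdown lowers the induced response) are called at a
gene score of −1.5 or below; negative regulators at +2.8 or above. The
asymmetry reflects the asymmetric null distribution of the ratio scores and
was anchored on the scores of well-established pathway members. Both
thresholds are inclusive by default; `strict_boundaries = TRUE` switches to
the strict inequalities used by the public deposits' activity-score bins,
and the package reports both behaviors rather than silently picking one.

Canonical-pathway genes are flagged, not called: a novel-regulator screen
notes them as assay validation but does not carry them forward. The shipped
default list (`canonical_tlr4_genes()`) contains only universally canonical
members; study-specific exclusion lists (e.g. proteasome components, which
enrich strongly among positive regulators because TLR signalling requires
proteasomal degradation steps) are supplied as one-gene-per-line files.

The expression filter removes hits that are not detectably expressed in the
assayed cell type: a gene passes if its microarray detection p-value is
strictly below 0.1 in at least one of the two profiled conditions
(unstimulated, LPS-stimulated). Probes are collapsed to genes by the
minimum detection p per condition — the most permissive reading of
"expressed", chosen so the filter only removes genes with no supporting
probe at all. Genes absent from the expression table are retained with a
warning: an unmeasured gene is not evidence of absence, and silently
dropping it would bias the candidate list.

Secondary candidates are selected by rank, not threshold: the `n_pos` = 26
lowest and `n_neg` = 13 highest gene medians after exclusions. Ties at the
cut are broken by the number of supporting siRNAs beyond the tier
threshold, then lexicographically — the selection is fully deterministic.
Tertiary confirmation computes the fractional effect F = readout/NTC per
stimulus and confirms a positive candidate when some stimulus other than
the selection ligand shows a reduction greater than 30% (F < 0.70,
strict), a negative candidate at an increase greater than 25%.

Activity scores reproduce the public deposit binning exactly (both tiers,
strict inequalities, highest bin wins; controls score 0 with outcome 4).
The deposits do not define "active"; the package sets outcome 2 at
activity score ≥ 50, because the 50-bin's bounds coincide with the tier's
hit thresholds. This is configurable.

## Plate quality control

Four per-plate gates, all computed from controls:

| gate | statistic | pass |
|---|---|---|
| induction | mean stimulated NTC ratio / mean unstimulated NTC ratio | ≥ 5-fold |
| transfection | 1 − mean(siRenilla R2)/mean(NTC R2), unstimulated wells | ≥ 0.85 |
| pathway control | 1 − mean(siTLR4 ratio)/mean(NTC ratio), stimulated wells | ≥ 0.85 |
| saturation | any R2 at/above the instrument limit | none |

Control summaries use the arithmetic mean over wells by default (the
acceptance rules are stated in terms of plain control readouts; the median
is available via `qc_thresholds(center = "median")` for screens with
erratic control wells). The saturation limit is instrument-dependent and
not part of the assay definition; the default 2^21 − 1 counts suits a
photon-counting reader and is configurable.

Plate uniformity follows the standard edge-effect protocol: three
all-control plates dosed High/Medium/Low in alternating two-column stripes,
staggered across plates. Per dose, wells are divided into four positional
groups; the variation statistic is the maximal pairwise difference of the
group means over the mean of the four group means, and a dose passes below
20%. The grouping is not uniquely defined by the protocol, so it is
configurable: plate quadrants (the default, the generic positional-bias
probe) or four contiguous six-column blocks. Column blocks are the right
probe for column-wise trends — a left-to-right gradient splits cleanly
across blocks but averages out to roughly half its contrast between
quadrant halves — and the gradient-detection tests therefore use them.

Replicate agreement is summarized two ways, matching the two replicate
geometries: the per-SMARTpool CV of the four raw within-plate ratios
(primary; screen mean ≈ the configured noise CV), and pairwise Pearson
correlations of log2 plate-median-normalized values across the three
weekly replicates (secondary), with 0.65 as the warning floor.

## The synthetic-screen generator

Every stage above is testable without downloads because the package ships a
generator that emulates the study conditions with planted ground truth. Its
defaults are the study conditions, fixed once:

- 384-well primary layout: samples in columns 2–9 and 12–23, controls in
  columns 10, 11 and 24 (at least three wells per class), column 1 unused;
  80 SMARTpools × 4 replicate wells per plate. Secondary layout: outer two
  rows and columns empty, controls in columns 11, 12, 13 and 22; 32 genes
  × 6 siRNAs per plate, three weekly plate copies.
- Induction fold 10 (the screening dose sits well past the 5-fold gate).
- Ratio noise CV 0.15, matching the observed screen-average replicate CV
  of 0.145.
- siRenilla retains 5% of R2 (95% knockdown against the 85% gate, matching
  the observed ≈96%). The receptor-knockdown control retains 10% of the
  induced signal (90% reduction). A control engineered exactly at its 85%
  gate would fail half the time on sampling noise alone, which is not how
  a functioning screen behaves: real control performance clears the gates
  with margin, as the renilla pair above illustrates, so the default is
  placed one comfortable step past the gate rather than on it.
- Planted effects multiply the induced signal: positive regulators draw
  U(0.1, 0.6), negative U(1.8, 4). Secondary siRNAs draw an independent
  on-target efficacy in U(0.75, 1); off-target siRNAs (rate `ote_rate`, or
  planted explicitly) additionally draw from the positive-effect
  distribution — the effect-level abstraction of a seed-sequence
  off-target, attached to a single sequence.
- Noise structure: a shared lognormal viability factor on both channels
  (cancelled by the ratio — the renilla channel's purpose), lognormal
  measurement noise on the ratio, and per-plate/per-week factors and the
  optional column gradient applied to the reporter response so they
  survive into the ratio, which is what median normalization and the
  uniformity test exist to handle. All lognormal components have unit mean
  and degenerate to exactly 1 at zero CV, so noise-free runs are exact:
  CV is exactly 0, replicate correlation exactly 1, and all null z-scores
  exactly 0.

What the generator does *not* emulate: sequence-level siRNA/seed matching,
spatially structured cell-seeding artifacts beyond a monotone column
gradient, heteroskedastic reader noise, and plate-to-plate layout errors.
Passing tests on synthetic screens therefore demonstrate that the analysis
recovers what it is designed to recover under its own assumptions — not
that any particular real screen is artifact-free.

Generation is a pure function of `(config, seed)`: identical inputs give
byte-identical CSVs, and the caller's RNG stream is left untouched. The
secondary, uniformity and expression generators offset the seed so the
tiers are independent but jointly reproducible.

## Numerical and design choices

- **Robust-z estimation window.** Scores are standardized "per replicate
  experiment". In the primary tier the four replicate wells share a plate,
  so center/scale are estimated once per plate on sample wells and shared
  by the four wells; in the secondary tier each weekly plate copy is its
  own replicate experiment. This is the only reading consistent with both
  replicate geometries.
- **Sample-only center/scale.** Controls are excluded from estimation (a
  plate's many strong controls would inflate the MAD) but scored with the
  sample parameters. `validate_deposit()` also recomputes the all-well
  convention and reports which one matches a deposited score column.
- **Flagged wells.** Zero-renilla wells and non-positive normalized values
  are excluded from means with a classed warning, never silently zeroed.
  Minimum two wells (primary) / two replicates (secondary) to score.
- **Ties and determinism.** Candidate selection breaks ties by support
  count then gene symbol; manifests hash the configuration with MD5 and
  contain no timestamps, so a rerun on identical inputs is bit-identical.
- **Boundary conventions.** Text thresholds are inclusive (score −1.5 *is*
  a positive regulator); deposit bins are strict (z = 2.8 bins at 25, not
  50). Both are implemented; the text behavior is the default and the
  boundary disagreement is surfaced in the documentation rather than
  harmonized away.

## Problem sizes used in the shipped checks

The package's own test suite runs entirely on generated data: single-plate
(80-gene) primary screens for null calibration (100 seeds), 25-seed
recovery and off-target false-call simulations, 200-seed uniformity
simulations, and a 500-gene screen for the effect-recovery regression.
These sizes give the binomial margins the assertions need (e.g. 8 000 null
genes for a <1% tail bound) while keeping the whole suite under a minute
on one core; the generator scales linearly for users who want
full-genome-scale (≈18 000 gene, 230 plate) rehearsals.

## Known limitations

- The uniformity statistic detects positional trends aligned with its
  grouping; a radially symmetric edge effect cancels in both offered
  groupings and would need a dedicated edge-vs-interior contrast.
- The expression filter is only as good as the probe→gene mapping of the
  supplied table; the min-p collapse cannot rescue genes with no probe.
- `validate_deposit()` recomputes statistics from a *local* export; the
  package never performs network access, and column-name drift in future
  deposit exports must be bridged with the reader's `schema` mapping.
- Tertiary replicate handling is the simplest defensible one (average
  replicate wells before forming F); the protocol leaves it unstated.
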