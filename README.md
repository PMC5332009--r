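# dualscreen

Tiered analysis of dual-luciferase siRNA screens: plate QC, robust
z-scoring, multi-siRNA validation, expression filtering, multi-ligand
confirmation — plus a calibrated synthetic-screen generator so the whole
pipeline is testable without any downloads.

## Who this is for

Genome-scale RNAi screens of inflammatory signalling (e.g. the macrophage
TNF-α response to LPS/TLR4 stimulation) are typically read out with a
two-reporter luciferase assay: firefly luciferase (R1) under an inducible
promoter reports the response, renilla luciferase (R2) under a constitutive
promoter reports cell number and viability, and the ratio R1/R2 is the
viability-corrected readout. `dualscreen` implements the full analysis tier
chain for such screens — the statistics a screening facility actually runs
between the plate reader and a candidate gene list — as tested, reusable R
functions.

## The statistics at the core

Per plate replicate, sample-well ratios are normalized to the intra-plate
median and standardized with the robust z-score

```
z_i = (x_i − median(x)) / (1.4826 · MAD(x)),    MAD(x) = median(|x − median(x)|)
```

with center and scale estimated on sample wells only and applied to control
wells too. Gene scores are the mean of the four within-plate replicate
z-scores (primary tier), or — after log2 transformation — the median of six
independent siRNA scores, each the mean of three weekly replicates
(secondary tier); the six-siRNA median is what makes the validation tier
robust to single-sequence off-target effects. Hits are called at score
≤ −1.5 (positive regulators, knockdown lowers the response) and ≥ +2.8
(negative regulators), filtered for expression in the assayed cells
(detection p < 0.1 in at least one of ±LPS conditions), and confirmed in a
tertiary tier by >30% reduction (or >25% increase) of the fractional effect
F = readout/NTC under at least one additional TLR ligand. Plates pass QC
only with ≥5-fold induction, ≥85% renilla knockdown, ≥85%
positive-control reduction and no renilla saturation; plate uniformity,
replicate CV and replicate correlations round out the QC surface.

See `vignettes/tiered-screen-analysis.Rmd` for the full model description,
parameter rationale and design decisions.

## Worked example

Simulate a two-plate primary screen with planted regulators, run the full
primary analysis, and inspect what comes out:

```r
library(dualscreen)

cfg <- sim_config(n_genes = 160, frac_pos = 0.05, frac_neg = 0.03, seed = 42)
sim <- generate_primary_screen(cfg)
res <- run_primary(sim$dataset, exclusions = character())

res$qc[c("plate_id", "fold_induction", "renilla_kd",
         "positive_control_reduction", "passed")]
#>   plate_id fold_induction renilla_kd positive_control_reduction passed
#> 1     P001       9.321769  0.9566507                  0.8875123   TRUE
#> 2     P002      10.160468  0.9560193                  0.8905959   TRUE

res$manifest$counts[c("genes_input", "genes_scored", "positive", "negative")]
#> genes_input genes_scored    positive    negative
#>         160          160           8           5
```

Both plates clear all four acceptance gates (induction ≈ 10-fold against
the 5-fold gate, both knockdown controls ≈ 90–96% against their 85% gates),
all 160 genes are scored, and the thresholds call 8 positive and 5 negative
regulators. The strongest scores belong to planted positive regulators:

```r
head(res$scores$genes[order(res$scores$genes$score), c("gene_symbol", "score")], 5)
#>  gene_symbol     score
#>    GENE00074 -5.552723
#>    GENE00153 -5.280037
#>    GENE00122 -4.011921
#>    GENE00128 -3.938759
#>    GENE00065 -3.195275

sim$truth$genes[sim$truth$genes$gene_symbol == "GENE00074", ]
#>   gene_symbol    class    effect
#>     GENE00074 positive 0.1587437
```

`GENE00074` was planted with an induced-signal multiplier of 0.16 — an 84%
knockdown of the response — and is recovered at z ≈ −5.6. A score of −2.3
(the scale of a strong receptor-complex knockdown) bins at deposit activity
score 75, outcome "active":

```r
activity_score(-2.3, tier = "primary")
#>   activity_score outcome
#> 1             75       2
```

From here, `generate_secondary_screen()` / `run_secondary()` validate
candidates with six siRNAs per gene, and `run_tertiary()` tests them
against a multi-ligand panel. `validate_deposit()` recomputes library
statistics (gene/siRNA/plate counts, screen-average CV, knockdown
efficiency, replicate correlations, z-scores) from a locally saved
deposit-schema CSV export; the package never accesses the network.

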