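# stratiq — stratified transcriptomics enrichment for QTL-positional candidate genes

`stratiq` is an R package for prioritising adipose-tissue candidate obesity
genes in a divergently selected Fat (F) × Lean (L) mouse-line design. It is
aimed at analysts working with normalised expression matrices from
multi-tissue line comparisons who need a reproducible implementation of a
stratified filter cascade rather than a one-off script.

The strategy intersects four kinds of evidence:

1. **Snapshot fold-change screens** over one pooled chip per tissue per
   line: three white adipose depots (SC, EPI, MES) against liver, muscle
   and kidney. With no replication, inference is by signed fold-change
   thresholds: `sfc(F, L) = F/L` if `F ≥ L`, else `−(L/F)` (positive =
   higher in the Fat line).
2. **Adipose selectivity**: a candidate must change coordinately (common
   sign) in all three WAT depots while its non-adipose folds stay inside a
   window `(−w, +w)` — excluding all-tissue "bystander" genes. The
   stringent stage requires ≥2-fold in all WATs, window < 2, and mean
   intensity of the higher line across the WATs above 100 AU.
3. **QTL positional filtering**: gene midpoints are tested for containment
   in fat-mass QTL confidence intervals (Fob1–Fob4, user-supplied BED);
   candidate lists are stratified into per-QTL total/known counts with
   both percentage bases.
4. **Quantitative differential expression** in subcutaneous fat (groups
   FC, FF, LC, LF; n = 4): an empirical-Bayes moderated t-statistic with
   variance shrinkage `s̃² = (d₀s₀² + d·s²)/(d₀ + d)`, hyperparameters by
   method of moments on log variances, Benjamini–Hochberg FDR, the
   fold > 2 / adjusted p < 0.05 / 100 AU reporting filter, and
   classification of diet-amplified line effects.

Candidate lists can be screened against GMT gene-set collections with a
one-sided hypergeometric over-representation test (observed vs expected
counts). A synthetic-data generator with planted truth (coordinate adipose,
depot-specific, bystander, diet-amplified and null classes on a synthetic
genome with placeholder QTLs) supports end-to-end validation of the whole
cascade.

## Worked example

Signed fold changes for a single all-tissue divergent gene (the bundled
`Depdc6` example: intensely expressed in every F tissue, near-silent in L):

```r
library(stratiq)
s <- read_expression_study(
  system.file("extdata", "depdc6_snapshot_matrix.tsv", package = "stratiq"),
  system.file("extdata", "depdc6_snapshot_samples.tsv", package = "stratiq"))
round(sfc_matrix(s), 2)
#>           SC    EPI   MES   LIV MUS   KID
#> Depdc6 139.2 136.91 67.64 43.94  74 21.92
```

Folds of 22–139 in *every* tissue mark a line difference unrelated to
adipose biology: any non-adipose window excludes this gene from all depot
lists (`depot_filter(s, "SC", filter_config(1.5, 1.5))` returns empty
lists), which is precisely the bystander-exclusion role of the window.

The full pipeline on the default synthetic design (2,000 probes, 100
planted coordinate-adipose genes at 4-fold, noise sd 0.2 log2, pools of 3):

```r
report <- run_pipeline(pipeline_config(seed = 1))
render_funnel(report)
#>               stage direction count                    threshold
#> 1   1_per_depot_any      up_F   170              >1.5, no window
#> 2   1_per_depot_any      up_L    10            >1.5, no window
#> 3 2_coordinate_3wat      up_F   100            >1.5, window <1.5
#> 4 2_coordinate_3wat      up_L    10            >1.5, window <1.5
#> 5       3_stringent      up_F    99 >=2, window <2, floor 100 AU
#> 6       3_stringent      up_L    10 >=2, window <2, floor 100 AU
```

The funnel shrinks monotonically as the filters stack. Against the planted
truth, the stringent stage recovered 99/100 planted adipose-up genes
(sensitivity 0.99), and the over-representation stage ranks the planted
gene set first by a wide margin:

```r
head(report$enrichment[, c("category", "observed", "expected", "p_value")], 2)
#>               category observed  expected       p_value
#> 1 planted_adipose_F_up       84  4.260143 3.384418e-142
#> 2        decoy_uniform       13 12.028640  4.269582e-01

table(report$diet_labels$label)
#> diet_amplified      diet_only      line_only           null
#>             50              2            147           1801
```

All 50 planted diet-amplified probes are labelled `diet_amplified`; the 147
`line_only` labels are the other planted line-effect classes. Per-QTL
stratification of the stringent list (`report$stratified$stringent`)
reports total/known counts per interval with both percentage bases.

File-based runs use the same functions on TSV/BED/GMT inputs — see
`?read_expression_study`, `?pipeline_config`, and the methods vignette
(`vignettes/stratified-enrichment.Rmd`) for the model, parameter meanings
and design decisions. A thin command-line wrapper is installed at
`system.file("scripts", "stratiq.R", package = "stratiq")`.

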