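# connectopls

Imaging-transcriptomics analysis of structural connectome atrophy:
`connectopls` asks whether the cortical regions that lose white-matter (WM)
connectivity in a patient cohort are the regions where particular gene
programmes are expressed in the healthy brain. It is written for
neuroimaging/systems-biology analysts who have grouped structural
connectomes (patients and controls, possibly longitudinal), a regional
gene-expression resource, and gene-set annotations — and for method
development, since every input can be simulated with planted ground truth.

## The method

For each cortical region *r*, connectivity is summarised per connection
class — corticostriatal (to each of L/R caudate and putamen),
interhemispheric, intrahemispheric — on a consensus edge mask defined from
baseline controls. Patients are z-scored against controls cell-wise and
sign-flipped so loss is positive (the *atrophy score*); longitudinal mode
normalises per-subject OLS slopes instead (*rate of atrophy*).

With `X` the ROI × gene expression matrix (probe-collapsed, donor-averaged,
QC-filtered) and `Y` the ROI × response atrophy matrix, partial least
squares finds components maximising covariance between expression and
loss: the component-1 gene weights are the dominant singular vector of the
z-scored cross-covariance `XᵀY`, ROI scores are `Xw`, and per-component
fractions of response variance explained are incremental R². Genes ranked
by signed weight feed:

- **minimum-hypergeometric (mHG) ranked enrichment** with an exact p-value
  (dynamic programming over all placements of a term's members in the
  ranked list), BH-FDR across terms, and the enrichment ratio
  `E = (b/n)/(B/N)` at the optimal cutoff;
- **mean-weight permutation tests** for curated gene lists (add-one
  empirical p against random same-size sets), and competitive comparisons
  against curated competitor sets;
- **hypergeometric overlap tests** between analyses' top gene lists;
- **Spearman correlation** between PLS weights and log2 fold-change tables;
- **robustness checks**: gene/ROI permutation nulls, Gaussian noise on the
  predictor, consensus-threshold variation, donor leave-one-out and
  k-of-n resampling.

## Worked example

Simulate a complete study (68 cortical ROIs + 4 striatal nodes, 2,000
genes × 2 probes, 6 donors, 20 patients / 20 controls at months 0/12/24,
planted atrophy gradient and gene loadings) and run the full analysis:

```r
library(connectopls)
dir <- tempfile("study")
config <- simulate_study(dir, seed = 1)
report <- run_pipeline(config)
report
#> analysis_report: 6 analyses
#>   corticostriatal    cross_sectional  comp1 varfrac 0.844, top term planted_A (q=4.1e-15)
#>   interhemispheric   cross_sectional  comp1 varfrac 0.817, top term planted_A (q=5e-18)
#>   intrahemispheric   cross_sectional  comp1 varfrac 0.797, top term planted_A (q=2.5e-18)
#>   corticostriatal    longitudinal     comp1 varfrac 0.800, top term planted_A (q=5e-16)
#>   interhemispheric   longitudinal     comp1 varfrac 0.795, top term planted_A (q=6.7e-19)
#>   intrahemispheric   longitudinal     comp1 varfrac 0.793, top term planted_A (q=1.4e-17)
```

The first PLS component of every analysis explains ~80–84% of the regional
atrophy variance (the planted expression gradient drives all three
connection classes in this study), and the planted gene set is the top
enrichment hit everywhere. Looking closer at one analysis:

```r
cs <- report$analyses[["corticostriatal.cross_sectional"]]
head(cs$enrichment[, c("term_id", "p_value", "q_value", "enrichment", "B", "n", "b")], 3)
#>     term_id      p_value      q_value enrichment  B   n  b
#> 1 planted_A 9.917891e-17 4.066335e-15   8.080808 22 225 20
#> 2    set038 1.031070e-02 1.566375e-01   3.898635 38 108  8
#> 3    set021 1.146128e-02 1.566375e-01  38.461538 26   4  2

cs$variance
#>   component   fraction cumulative
#> 1         1 0.84392511  0.8439251
#> 2         2 0.04217496  0.8861001

cs$foldchange_correlation$rho   # planted target: -0.23
#> [1] -0.2022583
```

Reading the enrichment row: of the planted term's `B = 22` members in the
2,000-gene universe, `b = 20` fall within the optimal cutoff `n = 225` of
the weight-ranked list — an 8.1-fold enrichment with exact mHG
p ≈ 1e-16, far past BH-FDR. The fold-change correlation recovers the
planted negative association between atrophy-aligned gene weights and
differential expression.

The synthetic study's ground truth (planted gradient, loadings, enriched
sets) is written alongside the inputs (`truth.json`), so recovery can be
quantified directly; `roi_weight_dissociation()` compares ROI score maps
between analyses. A thin command-line wrapper over `simulate_study()` /
`run_pipeline()` is installed at `inst/scripts/run_pipeline.R`.

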